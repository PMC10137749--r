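# Kinship likelihood ratios, Mendelian inconsistencies, simulation studies,
# and naive-Bayes ancestry.

test_that("duo, trio and pairwise LRs match their textbook values", {
  # dosages count the alt allele; "A" below is the ref at p = 0.5
  expect_equal(duo_lr(0, 0, 0.5), 2)      # parent A/A, child A/A: 1/p
  expect_equal(duo_lr(1, 0, 0.5), 1)      # parent A/B, child A/A: (p/2)/p^2
  expect_equal(duo_lr(0, 2, 0.5), 0)      # opposite homozygotes exclude
  expect_equal(trio_lr(1, 0, 0, 0.5), 2)  # paternal allele must be ref
  expect_equal(trio_lr(1, 0, 1, 0.5), 1)
  expect_equal(trio_lr(1, 0, 2, 0.5), 0)
  hs <- relationship("half_siblings")
  expect_equal(pairwise_lr(0, 0, 0.5, hs), 1.5)   # k0 + k1/p
  un <- relationship("unrelated")
  for (g1 in 0:2) for (g2 in 0:2)
    expect_equal(pairwise_lr(g1, g2, 0.3, un), 1)
  pc <- relationship("parent_child")
  expect_equal(pairwise_lr(2, 0, 0.4, pc), 0)
})

test_that("all LRs agree with enumeration oracles over the genotype grid", {
  rels <- lapply(c("parent_child", "half_siblings", "first_cousins",
                   "first_cousins_once_removed", "second_cousins",
                   "unrelated"), relationship)
  for (q in seq(0.1, 0.9, by = 0.1)) {
    for (g1 in 0:2) {
      for (g2 in 0:2) {
        expect_equal(duo_lr(g1, g2, q), oracle_duo_lr(g1, g2, q),
                     tolerance = 1e-12)
        # duo_lr is pairwise_lr at kappa = (0,1,0)
        expect_equal(duo_lr(g1, g2, q),
                     pairwise_lr(g1, g2, q, relationship("parent_child")),
                     tolerance = 1e-12)
        for (rel in rels)
          expect_equal(pairwise_lr(g1, g2, q, rel),
                       oracle_pairwise_lr(g1, g2, q, rel$kappa),
                       tolerance = 1e-12)
        for (gm in 0:2)
          expect_equal(trio_lr(gm, g2, g1, q),
                       oracle_trio_lr(gm, g2, g1, q), tolerance = 1e-12)
      }
    }
  }
})

test_that("frequencies are floored and invalid inputs rejected", {
  expect_equal(duo_lr(0, 0, 0), duo_lr(0, 0, 1e-3))
  expect_error(duo_lr(0, 0, 1.2), "outside")
  expect_error(relationship("custom", kappa = c(0.5, 0.6, 0)), "summing")
})

test_that("Mendelian inconsistencies count opposite homozygotes and trios", {
  expect_equal(count_inconsistencies(c(0, 0, 1), c(2, 0, 2)), 1L)
  expect_equal(count_inconsistencies(1, 0, 0), 1L)   # hom x hom -> het child
  expect_equal(count_inconsistencies(c(1, NA), c(0, 0), c(1, 2)), 0L)
})

test_that("lr_summary zeroes the strict LR on any exclusion", {
  s <- lr_summary(c(2, 4, 0.5))
  expect_equal(s$log10_lr, log10(4))
  expect_equal(s$n_inconsistencies, 0L)
  s0 <- lr_summary(c(2, 0, 4))
  expect_equal(s0$log10_lr, -Inf)
  expect_equal(s0$log10_lr_excluding, log10(8))
  expect_equal(s0$n_inconsistencies, 1L)
})

test_that("the per-locus duo LR is unbiased under each hypothesis", {
  set.seed(12)
  n <- 50000L
  q <- 0.3
  p <- 1 - q
  g1 <- rbinom(n, 2, q)
  g2 <- rbinom(n, 2, q)                      # H2: unrelated draws
  lr <- duo_lr(g1, g2, q, freq_floor = 0.999e-3)
  expect_lt(abs(mean(lr) - 1), 3 * sd(lr) / sqrt(n))
  # under H1, 1/LR integrates to the H2 mass on H1's support: exclusion
  # states (opposite homozygotes, H2 mass 2 p^2 q^2) never arise under H1
  pat <- rbinom(n, 1, g1 / 2)                # H1: Mendelian child
  gc <- pat + rbinom(n, 1, q)
  inv <- 1 / duo_lr(g1, gc, q)
  expect_lt(abs(mean(inv) - (1 - 2 * p^2 * q^2)), 3 * sd(inv) / sqrt(n))
})

test_that("paternity simulations match the analytic inconsistency rate", {
  q <- rep(0.5, 500)
  h2 <- simulate_paternity(q, n_sims = 400, "H2", seed = 3)
  expected <- 500 * 2 * 0.5^2 * 0.5^2      # 2 p^2 q^2 per locus
  se <- sd(h2$inconsistencies) / sqrt(400)
  expect_lt(abs(mean(h2$inconsistencies) - expected), 3 * se)
  h1 <- simulate_paternity(q, n_sims = 100, "H1", seed = 4)
  expect_equal(max(h1$inconsistencies), 0L)
  expect_true(all(h1$n_excluded == 0))
  expect_true(mean(h1$log10_lr) > 0)
  # zero-LR loci are exactly the Mendelian exclusions; dropping them from
  # the product leaves an LR that overstates H1 (which is why inconsistency
  # counts, not the pruned LR, carry the evidence under H2)
  expect_identical(h2$n_excluded, h2$inconsistencies)
})

test_that("gene-dropped half siblings recover their kappa coefficients", {
  q <- rep(0.5, 800)
  s <- simulate_pairwise("half_siblings", q, n_sims = 150, seed = 5)
  # no map: loci independent; IBD-1 fraction 0.5 within 3 SE
  n <- 150 * 800
  expect_lt(abs(s$ibd_fractions[["1"]] - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(s$ibd_fractions[["2"]], 0)
  expect_true(median(s$log10_lr_h1) > 0)
  expect_true(median(s$log10_lr_h2) < 0)
})

test_that("ancestry posteriors follow two-cell Bayes and normalise", {
  panel <- tiny_panel(1, category = "ancestry")
  mf <- structure(data.frame(locus_id = "rs1", P1 = 0.9, P2 = 0.1),
                  class = c("freq_table", "data.frame"))
  gt <- genotype_table("rs1", "G", "G")     # alt/alt
  post <- ancestry_posterior(gt, mf, panel)
  expect_equal(unname(post["P1"]), 0.81 / 0.82, tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  # identical frequencies give a uniform posterior
  mf2 <- structure(data.frame(locus_id = "rs1", P1 = 0.4, P2 = 0.4,
                              P3 = 0.4),
                   class = c("freq_table", "data.frame"))
  post2 <- ancestry_posterior(gt, mf2, panel)
  expect_equal(unname(c(post2)), rep(1 / 3, 3), tolerance = 1e-12)
  # an informative prior shifts the posterior proportionally
  post3 <- ancestry_posterior(gt, mf, panel, prior = c(P1 = 1, P2 = 80))
  expect_equal(unname(post3["P1"]), 0.81 / (0.81 + 80 * 0.01),
               tolerance = 1e-12)
})

test_that("simulated individuals classify to their source population", {
  # ~253 ancestry-informative markers, as in large all-in-one panels
  panel <- synthetic_panel(5500, seed = 8)
  pops <- c("AFR", "AMR", "EAS", "EUR", "MES", "OCE", "SAS")
  mf <- synthetic_frequencies(panel, populations = pops, fst = 0.15,
                              seed = 8)
  hits <- 0L
  n <- 35L
  for (i in seq_len(n)) {
    k <- ((i - 1L) %% length(pops)) + 1L
    gt <- sample_individual(mf, panel, "female", seed = 5000 + i,
                            population = pops[k])
    post <- ancestry_posterior(gt, mf, panel)
    hits <- hits + (names(post)[which.max(post)] == pops[k])
  }
  expect_gte(hits / n, 0.9)
})
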