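# Synthetic-data generator: HWE sampling, pedigree gene dropping, template
# molecules, amplification/sequencing, mixtures, determinism.

test_that("HWE sampling matches degenerate and binomial expectations", {
  panel <- tiny_panel(3)
  q0 <- setNames(c(0, 1, 0.5), panel$locus_id)
  gt <- sample_individual(q0, panel, "female", seed = 1)
  expect_equal(gt$a1[1], "A")  # q = 0 -> always ref/ref
  expect_equal(gt$a2[1], "A")
  expect_equal(gt$a1[2], "G")  # q = 1 -> always alt/alt
  expect_equal(gt$a2[2], "G")

  # q = 0.5: het fraction 0.5 +/- 3*SE over 10,000 draws (binomial oracle)
  big <- tiny_panel(10000)
  qq <- setNames(rep(0.5, 10000), big$locus_id)
  g <- sample_individual(qq, big, "female", seed = 2)
  het <- mean(g$a1 != g$a2)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
})

test_that("sex handling gives hemizygous Y calls and female Y no-types", {
  panel <- as_panel(data.frame(locus_id = c("a1", "x1", "y1"),
                               chrom = c("1", "X", "Y"),
                               pos = c(1L, 2L, 3L), ref = "A", alt = "G",
                               category = c("identity", "X", "Y")))
  q <- setNames(rep(0.5, 3), panel$locus_id)
  f <- sample_individual(q, panel, "female", seed = 3)
  expect_equal(f$status[f$locus_id == "y1"], "not_typed")
  expect_false(is.na(f$a2[f$locus_id == "x1"]))   # female X diploid
  m <- sample_individual(q, panel, "male", seed = 3)
  expect_true(is.na(m$a2[m$locus_id == "y1"]))
  expect_true(is.na(m$a2[m$locus_id == "x1"]))    # male X hemizygous
  expect_equal(m$status[m$locus_id == "y1"], "called")
})

test_that("template counts follow the configured Poisson model", {
  # with full conversion and no capture bias the per-allele-copy mean is
  # mass / (2 * 3.3): 660 pg -> 100
  panel <- tiny_panel(400)
  q <- setNames(rep(0.5, 400), panel$locus_id)
  gt <- sample_individual(q, panel, "female", seed = 4)
  cfg <- sim_config(input_mass_pg = 660, library_efficiency = 1,
                    capture_bias_sigma = 0, seed = 5)
  ts <- sample_templates(gt, panel, cfg)
  mean_per_copy <- nrow(ts) / (2 * 400)
  expect_lt(abs(mean_per_copy - 100), 3 * sqrt(100 / 800))

  # 6.6 pg -> mean 1 per allele copy; P(no template at a locus) = e^-2
  cfg2 <- sim_config(input_mass_pg = 6.6, library_efficiency = 1,
                     capture_bias_sigma = 0, seed = 6)
  big <- tiny_panel(5000)
  gt2 <- sample_individual(setNames(rep(0.5, 5000), big$locus_id), big,
                           "female", seed = 7)
  ts2 <- sample_templates(gt2, big, cfg2)
  p_zero <- 1 - length(unique(ts2$locus)) / 5000
  expect_lt(abs(p_zero - exp(-2)), 3 * sqrt(exp(-2) * (1 - exp(-2)) / 5000))
})

test_that("each template gets its own UMI and reads conserve them", {
  panel <- tiny_panel(50)
  q <- setNames(rep(0.5, 50), panel$locus_id)
  gt <- sample_individual(q, panel, "female", seed = 8)
  cfg <- sim_config(input_mass_pg = 300, reads_target = 30000, seed = 9)
  ts <- sample_templates(gt, panel, cfg)
  reads <- amplify_and_sequence(ts, cfg)
  expect_true(all(nchar(reads$umi) == cfg$umi_length))
  # every read maps to one template; distinct UMIs per locus <= templates
  per_locus_templates <- table(ts$locus)
  per_locus_umis <- tapply(reads$umi, reads$locus_id,
                           function(x) length(unique(x)))
  loci <- panel$locus_id[as.integer(names(per_locus_templates))]
  expect_true(all(per_locus_umis[loci] <= as.vector(per_locus_templates),
                  na.rm = TRUE))
})

test_that("error-free simulation yields truth genotypes in both modes", {
  panel <- synthetic_panel(300, seed = 10)
  freqs <- synthetic_frequencies(panel, seed = 10)
  truth <- sample_individual(freqs, panel, "male", seed = 11)
  cfg <- sim_config(input_mass_pg = 5000, reads_target = 150000,
                    pcr_error_rate = 0, seq_error_rate = 0, seed = 12)
  reads <- simulate_reads(truth, panel, cfg)
  expect_true(all(reads$allele == reads$true_allele))
  for (mode in c("umi", "raw")) {
    dep <- tabulate_depths(reads, mode, panel = panel)
    calls <- call_genotypes(dep, panel, call_thresholds(), "male")
    rep <- concordance(calls, truth)
    expect_equal(rep$accuracy, 1.0)
  }
})

test_that("identical config and seed give byte-identical read streams", {
  panel <- tiny_panel(30)
  q <- setNames(rep(0.4, 30), panel$locus_id)
  gt <- sample_individual(q, panel, "female", seed = 13)
  cfg <- sim_config(input_mass_pg = 200, reads_target = 5000, seed = 14)
  r1 <- simulate_reads(gt, panel, cfg)
  r2 <- simulate_reads(gt, panel, cfg)
  expect_identical(r1, r2)
  r3 <- simulate_reads(gt, panel, sim_config(input_mass_pg = 200,
                                             reads_target = 5000, seed = 15))
  expect_false(identical(r1, r3))
})

test_that("pedigree validation rejects broken structures", {
  expect_error(pedigree(c("a", "b"), c(NA, "a"), c(NA, NA)),
               "both parents")
  expect_error(pedigree(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b"),
                        c("male", "male", "female")),
               "parent sex mismatch")
  ped <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                  c("male", "female", "female"))
  expect_s3_class(ped, "pedigree")
})

test_that("gene dropping transmits Mendelianly and respects the map", {
  panel <- tiny_panel(4000)
  q <- setNames(rep(0.5, 4000), panel$locus_id)
  ped <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                  c("male", "female", "female"))
  gts <- gene_drop(ped, q, panel, seed = 16)
  df <- genotype_dosage(gts$f, panel, loci = panel$locus_id)
  dm <- genotype_dosage(gts$m, panel, loci = panel$locus_id)
  dc <- genotype_dosage(gts$c, panel, loci = panel$locus_id)
  # no-mutation model: parent-child duos have zero inconsistencies, always
  expect_equal(count_inconsistencies(dc, df), 0L)
  expect_equal(count_inconsistencies(dc, dm), 0L)
  expect_equal(count_inconsistencies(dc, df, dm), 0L)
  # het father x ref-hom mother: the child's alt dosage is the paternal
  # transmission; alt transmitted half the time (Mendelian oracle)
  sel <- df == 1 & dm == 0
  tr <- mean(dc[sel])
  expect_lt(abs(tr - 0.5), 3 * sqrt(0.25 / sum(sel)))

  # Haldane map: r = (1 - exp(-2d/100))/2, 0.5 across chromosomes
  p2 <- as_panel(data.frame(locus_id = c("l1", "l2", "l3"),
                            chrom = c("1", "1", "2"),
                            pos = c(1L, 2L, 1L), ref = "A", alt = "G",
                            category = "kinship"))
  map <- as_genetic_map(data.frame(locus_id = c("l1", "l2", "l3"),
                                   chrom = c("1", "1", "2"),
                                   cm = c(0, 10, 0)))
  r <- umisnp:::.recomb_fractions(p2, map)
  expect_equal(r, c(0.5 * (1 - exp(-0.2)), 0.5))

  # zero map distance: the transmitted haplotype is always parental
  set.seed(1)
  for (i in 1:20) {
    h <- umisnp:::.meiosis(rep(0L, 50), rep(1L, 50), rep(0, 49))
    expect_true(all(h == 0L) || all(h == 1L))
  }
})

test_that("mixtures scale template means by contributor proportion", {
  panel <- tiny_panel(500)
  q <- setNames(rep(0.5, 500), panel$locus_id)
  g1 <- sample_individual(q, panel, "female", seed = 17)
  g2 <- sample_individual(q, panel, "female", seed = 18)
  cfg <- sim_config(input_mass_pg = 2000, library_efficiency = 1,
                    capture_bias_sigma = 0, seed = 19)
  expect_error(make_mixture(list(g1, g2), c(0.6, 0.5), panel, cfg),
               "sum to 1")
  ts <- make_mixture(list(g1, g2), c(100, 1) / 101, panel, cfg)
  share <- mean(ts$contributor == 2L)
  expect_lt(abs(share - 1 / 101), 3 * sqrt((1 / 101) * (100 / 101) / nrow(ts)))

  # degenerate mixture equals the single-source path distributionally:
  # same number of molecules as a single-source draw with the same seed
  ts1 <- make_mixture(list(g1), 1, panel, cfg)
  expect_true(all(ts1$contributor == 1L))
})

test_that("a 1:1 mixture of opposite homozygotes concentrates ARF near 0.5", {
  panel <- tiny_panel(200, ref = "A", alt = "G")
  gAA <- genotype_table(panel$locus_id, "A", "A")
  gGG <- genotype_table(panel$locus_id, "G", "G")
  cfg <- sim_config(input_mass_pg = 10000, reads_target = 200000,
                    capture_bias_sigma = 0, seed = 20)
  ts <- make_mixture(list(gAA, gGG), c(0.5, 0.5), panel, cfg)
  reads <- amplify_and_sequence(ts, cfg)
  dep <- tabulate_depths(reads, "umi", panel = panel)
  arf <- arf_distribution(dep)
  expect_lt(mean(arf), 0.56)
  expect_gt(min(total_depth(dep)), 100)
})
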