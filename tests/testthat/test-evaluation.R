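# Concordance classification, matched-threshold scans, paired t-test.

test_that("discordances classify into drop-outs and drop-ins", {
  truth <- genotype_table(c("rs1", "rs2", "rs3", "rs4"),
                          a1 = c("A", "A", "A", "A"),
                          a2 = c("G", "A", "A", "G"))
  calls <- genotype_table(c("rs1", "rs2", "rs3", "rs4"),
                          a1 = c("A", "A", "G", NA),
                          a2 = c("A", "G", "G", NA),
                          status = c(rep("called", 3), "no_call_imbalance"))
  rep <- concordance(calls, truth)
  expect_equal(rep$n_loci, 4L)
  expect_equal(rep$n_called, 3L)
  expect_equal(rep$n_dropout, 1L)   # truth A/G called A/A
  expect_equal(rep$n_dropin, 2L)    # truth A/A called A/G; truth A/A called G/G
  expect_equal(rep$n_other_discordant, 0L)
  expect_equal(rep$call_rate, 0.75)
  expect_error(concordance(genotype_table("rs9", "A", "A"), truth),
               "absent from truth")
})

test_that("the concordance partition identity holds on fuzzed inputs", {
  set.seed(5)
  for (i in 1:20) {
    n <- 50L
    ids <- paste0("rs", 1:n)
    pick <- function() sample(c("A", "G"), n, TRUE)
    truth <- genotype_table(ids, pmin(a <- pick(), b <- pick()),
                            pmax(a, b))
    called <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2))
    ca <- pick(); cb <- pick()
    calls <- genotype_table(ids, ifelse(called, pmin(ca, cb), NA),
                            ifelse(called, pmax(ca, cb), NA),
                            ifelse(called, "called", "no_call_low_coverage"))
    rep <- concordance(calls, truth)
    expect_equal(rep$n_called,
                 rep$n_concordant + rep$n_dropout + rep$n_dropin +
                   rep$n_other_discordant)
    expect_equal(rep$call_rate, rep$n_called / rep$n_loci)
  }
})

# toy scan fixture: 10 accurate loci whose raw depths make the call rate
# 1.0 for t <= 10, 0.9 for t in 11..20, 0.7 for t in 21..30
.scan_fixture <- function() {
  panel <- tiny_panel(10)
  truth <- genotype_table(panel$locus_id, "A", "A")
  depths <- depth_table(panel$locus_id,
                        A = c(rep(30, 7), 20, 20, 10))
  list(panel = panel, truth = truth, depths = depths)
}

test_that("call-rate matching picks the nearest threshold, ties upward", {
  fx <- .scan_fixture()
  th <- call_thresholds()
  m <- match_call_rate(fx$depths, 0.9, th, fx$truth, fx$panel)
  expect_equal(m$threshold, 20L)
  expect_equal(m$report$call_rate, 0.9)
  # 0.8 is equidistant from 0.9 and 0.7: the tie goes to the larger
  # threshold, i.e. the 0.7 side
  m2 <- match_call_rate(fx$depths, 0.8, th, fx$truth, fx$panel)
  expect_equal(m2$threshold, 30L)
  expect_equal(m2$report$call_rate, 0.7)
  # identical umi/raw counts match at the profile's own coverage threshold
  m3 <- match_call_rate(fx$depths, 1.0, th, fx$truth, fx$panel)
  expect_equal(m3$report$call_rate, 1.0)
})

test_that("error-rate matching falls back to call rate, then larger t", {
  # an error-free fixture: every threshold matches error 0; the secondary
  # call-rate criterion then selects the umi call rate
  fx <- .scan_fixture()
  th <- call_thresholds()
  umi_rep <- list(call_rate = 0.9, accuracy = 1.0)
  m <- match_error_rate(fx$depths, umi_rep, th, fx$truth, fx$panel)
  expect_equal(m$threshold, 20L)
  expect_equal(1 - m$report$accuracy, 0)
  # with no call-rate secondary (scalar error target) the tie among equal
  # error gaps resolves to the largest threshold
  m2 <- match_error_rate(fx$depths, 0, th, fx$truth, fx$panel)
  expect_equal(m2$threshold, 30L)
  expect_error(match_call_rate(depth_table("rs1", A = 0), 0.5,
                               call_thresholds(), fx$truth, fx$panel),
               "no coverage threshold")
})

test_that("paired comparison reproduces the closed-form t statistic", {
  r <- paired_comparison(c(0.99, 0.98, 0.97), c(0.98, 0.96, 0.94))
  expect_equal(r$mean_difference, 0.02)
  expect_equal(r$t, 0.02 / (0.01 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  # agreement with stats::t.test away from the degenerate case
  set.seed(9)
  u <- runif(8); v <- runif(8)
  tt <- t.test(u, v, paired = TRUE, alternative = "greater")
  r2 <- paired_comparison(u, v)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p.value, tt$p.value, tolerance = 1e-12)
  # degenerate all-zero differences are defined: t = 0, p = 0.5
  r3 <- paired_comparison(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r3$t, 0)
  expect_equal(r3$p.value, 0.5)
  expect_error(paired_comparison(1, 0.9), "two pairs")
})
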