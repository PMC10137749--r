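# Concordance metrics (drop-in / drop-out accounting) and the matched
# call-rate / matched error-rate comparison of UMI versus raw-read calling.

# NA-safe elementwise equality
.eqna <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)

# per-locus concordance classification over truth-called loci
.concordance_vectors <- function(called, truth) {
  extra <- setdiff(called$locus_id, truth$locus_id)
  if (length(extra))
    stop("called locus absent from truth: ", extra[1L], call. = FALSE)
  truth <- truth[truth$status == "called", ]   # not_typed truth loci excluded
  i <- match(truth$locus_id, called$locus_id)
  c1 <- called$a1[i]; c2 <- called$a2[i]
  cst <- called$status[i]
  cst[is.na(cst)] <- "no_call_low_coverage"   # loci with no call row at all
  t_lo <- pmin(truth$a1, truth$a2, na.rm = TRUE)
  t_hi <- ifelse(is.na(truth$a2), NA_character_,
                 pmax(truth$a1, truth$a2))
  c_lo <- ifelse(is.na(c2), c1, pmin(c1, c2))
  c_hi <- ifelse(is.na(c2), NA_character_, pmax(c1, c2))
  is_called <- cst == "called"
  eq <- .eqna(c_lo, t_lo) & .eqna(c_hi, t_hi)
  in_truth <- function(a)
    is.na(a) | .eqna(a, truth$a1) | (!is.na(truth$a2) & .eqna(a, truth$a2))
  novel <- !in_truth(c_lo) | !in_truth(c_hi)
  category <- rep(NA_character_, nrow(truth))
  category[is_called & eq] <- "concordant"
  category[is_called & !eq & novel] <- "dropin"
  category[is_called & !eq & !novel] <- "dropout"
  data.frame(locus_id = truth$locus_id, called = is_called,
             category = category,
             depth = if (!is.null(called$depth)) called$depth[i] else NA,
             stringsAsFactors = FALSE)
}

.report_from_counts <- function(n_loci, n_called, n_conc, n_dropout,
                                n_dropin) {
  out <- list(n_loci = n_loci, n_called = n_called,
              call_rate = if (n_loci > 0) n_called / n_loci else NA_real_,
              n_concordant = n_conc,
              accuracy = if (n_called > 0) n_conc / n_called else NA_real_,
              n_dropout = n_dropout, n_dropin = n_dropin,
              n_other_discordant = n_called - n_conc - n_dropout - n_dropin)
  class(out) <- "concordance_report"
  out
}

#' Genotype concordance against a truth table
#'
#' Evaluated loci are those called in the truth (a female truth therefore
#' excludes its Y loci automatically). Per called locus: an identical
#' genotype is concordant; a call containing an allele absent from the truth
#' is an allele drop-in; a call whose alleles are a strict subset of a
#' heterozygous truth is an allele drop-out.
#'
#' @param called a `genotype_table` of calls.
#' @param truth the truth `genotype_table`; must cover every called locus.
#' @return a `concordance_report` list (counts, call rate, accuracy =
#'   concordant / called).
#' @export
concordance <- function(called, truth) {
  v <- .concordance_vectors(called, truth)
  .report_from_counts(nrow(v), sum(v$called),
                      sum(v$category == "concordant", na.rm = TRUE),
                      sum(v$category == "dropout", na.rm = TRUE),
                      sum(v$category == "dropin", na.rm = TRUE))
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: %d/%d called (call rate %.4f), accuracy %.4f\n  concordant %d | drop-out %d | drop-in %d | other %d\n",
    x$n_called, x$n_loci, x$call_rate, x$accuracy, x$n_concordant,
    x$n_dropout, x$n_dropin, x$n_other_discordant))
  invisible(x)
}

# shared raw-threshold scan: per-threshold call/concordance tallies
.threshold_scan <- function(raw_depths, thresholds, truth, panel,
                            sex = "female") {
  th1 <- thresholds
  th1$min_coverage <- 1L
  calls <- call_genotypes(raw_depths, panel, th1, sex)
  v <- .concordance_vectors(calls, truth)
  n_loci <- nrow(v)
  dmax <- suppressWarnings(max(v$depth[v$called], na.rm = TRUE))
  if (!is.finite(dmax) || dmax < 1)
    stop("no coverage threshold yields any raw-mode calls", call. = FALSE)
  cum_ge <- function(mask) {
    cnt <- tabulate(pmin(v$depth[mask & !is.na(v$depth)], dmax), dmax)
    rev(cumsum(rev(cnt)))
  }
  list(t_grid = seq_len(dmax),
       n_loci = n_loci,
       n_called = cum_ge(v$called),
       n_conc = cum_ge(v$called & .eqna(v$category, "concordant")),
       n_dropout = cum_ge(v$called & .eqna(v$category, "dropout")),
       n_dropin = cum_ge(v$called & .eqna(v$category, "dropin")))
}

.scan_pick <- function(scan, idx) {
  list(threshold = scan$t_grid[idx],
       report = .report_from_counts(scan$n_loci, scan$n_called[idx],
                                    scan$n_conc[idx], scan$n_dropout[idx],
                                    scan$n_dropin[idx]))
}

#' Raw-mode coverage threshold matching a UMI call rate
#'
#' Scans integer coverage thresholds >= 1 for raw-mode calling and selects
#' the one minimising the absolute call-rate difference to the UMI data
#' (ties resolved toward the larger, more conservative threshold).
#'
#' @param raw_depths raw-mode `allele_depths`.
#' @param umi_report the UMI-mode `concordance_report` (or a call rate).
#' @param thresholds ARF/quality thresholds shared by both workflows.
#' @param truth truth `genotype_table`.
#' @param panel a `snp_panel`.
#' @param sex sample sex for hemizygous handling.
#' @return list with `threshold` and the raw `concordance_report` at it.
#' @export
match_call_rate <- function(raw_depths, umi_report, thresholds, truth, panel,
                            sex = "female") {
  target <- if (is.list(umi_report)) umi_report$call_rate else umi_report
  scan <- .threshold_scan(raw_depths, thresholds, truth, panel, sex)
  obj <- round(abs(scan$n_called / scan$n_loci - target), 9)
  valid <- scan$n_called > 0
  if (!any(valid))
    stop("no coverage threshold yields any raw-mode calls", call. = FALSE)
  obj[!valid] <- Inf
  .scan_pick(scan, order(obj, -scan$t_grid)[1L])
}

#' Raw-mode coverage threshold matching a UMI error rate
#'
#' As [match_call_rate()], but minimising the absolute difference in error
#' rate (1 - accuracy); exact ties fall back to the call-rate difference,
#' then to the larger threshold.
#'
#' @inheritParams match_call_rate
#' @return list with `threshold` and the raw `concordance_report` at it.
#' @export
match_error_rate <- function(raw_depths, umi_report, thresholds, truth, panel,
                             sex = "female") {
  t_err <- if (is.list(umi_report)) 1 - umi_report$accuracy else umi_report
  t_cr <- if (is.list(umi_report)) umi_report$call_rate else NA_real_
  scan <- .threshold_scan(raw_depths, thresholds, truth, panel, sex)
  valid <- scan$n_called > 0
  if (!any(valid))
    stop("no coverage threshold yields any raw-mode calls", call. = FALSE)
  err <- 1 - scan$n_conc / scan$n_called
  obj1 <- round(abs(err - t_err), 9)
  obj2 <- if (is.na(t_cr)) rep(0, length(err)) else
    round(abs(scan$n_called / scan$n_loci - t_cr), 9)
  obj1[!valid] <- Inf
  .scan_pick(scan, order(obj1, obj2, -scan$t_grid)[1L])
}

#' One-sided paired t-test for a UMI-vs-raw series
#'
#' Tests the directional hypothesis that the UMI metric exceeds the raw
#' metric over paired observations (one per input amount or replicate).
#' The statistic is computed in closed form so the all-zero-difference case
#' is defined (t = 0, p = 0.5); it agrees with `stats::t.test(...,
#' paired = TRUE, alternative = "greater")` otherwise.
#'
#' @param umi,raw paired numeric vectors, or a data.frame with columns of
#'   those names passed as `umi`.
#' @return list: `mean_difference`, `t`, `df`, `p.value`, `n`.
#' @export
paired_comparison <- function(umi, raw = NULL) {
  if (is.data.frame(umi)) {
    raw <- umi$raw
    umi <- umi$umi
  }
  if (length(umi) != length(raw)) stop("unequal series", call. = FALSE)
  d <- umi - raw
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  m <- mean(d)
  s <- sd(d)
  t <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else m / (s / sqrt(n))
  structure(list(mean_difference = m, t = t, df = n - 1L,
                 p.value = pt(t, n - 1L, lower.tail = FALSE), n = n),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired one-sided t-test: mean diff %.4g, t = %.3f, df = %d, p = %.4g\n",
              x$mean_difference, x$t, x$df, x$p.value))
  invisible(x)
}
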