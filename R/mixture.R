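# DNA-mixture detection (heterozygosity rate, ARF distribution) and
# quantitative deconvolution of one unknown contributor.

#' Observed heterozygosity rate of called autosomal genotypes
#'
#' @param calls a `genotype_table`.
#' @param panel a `snp_panel` (X/Y loci are excluded).
#' @return fraction of called autosomal loci typed heterozygous.
#' @export
heterozygosity_rate <- function(calls, panel) {
  panel <- as_panel(panel)
  aut <- panel$locus_id[!panel$category %in% c("X", "Y")]
  g <- calls[calls$locus_id %in% aut & calls$status == "called", ]
  if (!nrow(g)) stop("no called autosomal loci", call. = FALSE)
  mean(!is.na(g$a2) & g$a1 != g$a2)
}

#' Expected heterozygosity rate for 1 or 2 contributors
#'
#' Single source: mean of 2pq over loci. Two unrelated contributors: mean of
#' 1 - p^4 - q^4, the probability that four independent HWE allele draws are
#' not monoallelic — i.e. the apparent heterozygosity if every allele
#' present in the mixture were detected.
#'
#' @param freqs frequency table or named alt-frequency vector.
#' @param n_contributors 1 or 2.
#' @param panel optional `snp_panel` restricting (and ordering) the loci to
#'   its autosomal markers.
#' @param population optional population column.
#' @return expected heterozygosity rate.
#' @export
expected_heterozygosity_rate <- function(freqs, n_contributors = 1,
                                         panel = NULL, population = NULL) {
  if (!n_contributors %in% c(1, 2))
    stop("n_contributors must be 1 or 2", call. = FALSE)
  loci <- NULL
  if (!is.null(panel)) {
    panel <- as_panel(panel)
    loci <- panel$locus_id[!panel$category %in% c("X", "Y")]
  }
  q <- freq_vector(freqs, population = population, loci = loci)
  p <- 1 - q
  if (n_contributors == 1) mean(2 * p * q) else mean(1 - p^4 - q^4)
}

#' Detect a DNA mixture from an elevated heterozygosity rate
#'
#' Compares the observed heterozygosity rate of called autosomal genotypes
#' with the single-source expectation; the null standard deviation is the
#' binomial approximation sqrt(h(1-h)/n_called) unless an empirical estimate
#' is supplied. A z-score above 3 flags a mixture.
#'
#' @param calls a `genotype_table` from the questioned sample.
#' @param freqs population frequencies.
#' @param panel a `snp_panel`.
#' @param null_sd optional empirical null standard deviation.
#' @param population optional population column.
#' @return `mixture_detection` list: `flag`, `z`, observed and expected
#'   rates, `n_called`.
#' @export
detect_mixture <- function(calls, freqs, panel, null_sd = NULL,
                           population = NULL) {
  panel <- as_panel(panel)
  h_obs <- heterozygosity_rate(calls, panel)
  h0 <- expected_heterozygosity_rate(freqs, 1, panel, population)
  h2 <- expected_heterozygosity_rate(freqs, 2, panel, population)
  aut <- panel$locus_id[!panel$category %in% c("X", "Y")]
  n <- sum(calls$locus_id %in% aut & calls$status == "called")
  if (is.null(null_sd)) null_sd <- sqrt(h0 * (1 - h0) / n)
  z <- (h_obs - h0) / null_sd
  structure(list(flag = z > 3, z = z, observed = h_obs,
                 expected_single_source = h0, expected_two_person = h2,
                 n_called = n),
            class = "mixture_detection")
}

#' @export
print.mixture_detection <- function(x, ...) {
  cat(sprintf(
    "heterozygosity %.4f (single-source expectation %.4f, two-person %.4f)\n  z = %.2f over %d called loci -> %s\n",
    x$observed, x$expected_single_source, x$expected_two_person, x$z,
    x$n_called, if (x$flag) "mixture flagged" else "no mixture flagged"))
  invisible(x)
}

#' Per-locus ARF values of a depth table
#'
#' @param depths an `allele_depths` table.
#' @return named numeric vector (loci with zero depth omitted); the basis
#'   for mixture ARF density plots.
#' @export
arf_distribution <- function(depths) {
  m <- as.matrix(as.data.frame(depths)[.ALLELES])
  total <- rowSums(m)
  keep <- total > 0
  setNames(apply(m[keep, , drop = FALSE], 1L, max) / total[keep],
           depths$locus_id[keep])
}

#' Binned ARF histogram over \[0.5, 1\]
#'
#' @param depths an `allele_depths` table.
#' @param bins number of equal-width bins.
#' @return integer vector of counts (names give bin upper edges).
#' @export
arf_histogram <- function(depths, bins = 50L) {
  arf <- arf_distribution(depths)
  edges <- seq(0.5, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(arf, edges, rightmost.closed = TRUE), 1L),
              bins)
  setNames(tabulate(idx, bins), format(edges[-1L], digits = 3))
}

#' Quantitative deconvolution of a two-person mixture
#'
#' Removes the read share attributed to a known contributor — assuming the
#' given mixture proportion — and calls the residual depths with the
#' conservative deconvolution threshold profile. At each locus with total
#' depth T, round(proportion * T) reads are removed: all from the known
#' contributor's allele if it is homozygous, split equally between its two
#' alleles if heterozygous (an odd remainder goes to the lexicographically
#' first allele). Subtraction floors at zero per allele; un-removable
#' excess is discarded.
#'
#' @param depths mixture `allele_depths` (UMI mode in the intended
#'   workflow).
#' @param known the known contributor's `genotype_table`; loci absent from
#'   it are skipped with a warning.
#' @param proportion known contributor's proportion, in (0, 1).
#' @param thresholds calling thresholds for the residual (defaults to the
#'   `deconvolution` profile: 10x, hom >= 0.90, het <= 0.55).
#' @param panel a `snp_panel`.
#' @param sex sex of the unknown contributor (hemizygous handling).
#' @return `deconvolution_result` list: `residual` depths, `calls`,
#'   `assumed_proportion`, `n_skipped`.
#' @export
deconvolve <- function(depths, known, proportion = 0.5,
                       thresholds = call_thresholds("deconvolution"),
                       panel, sex = "female") {
  if (proportion <= 0 || proportion >= 1)
    stop("proportion must be in (0,1)", call. = FALSE)
  dd <- as.data.frame(depths)
  i <- match(dd$locus_id, known$locus_id)
  known_called <- !is.na(i)
  known_called[known_called] <- known$status[i[known_called]] == "called"
  n_skip <- sum(!known_called)
  if (n_skip)
    warning(n_skip, " locus/loci missing from the known genotype; skipped")
  dd <- dd[known_called, , drop = FALSE]
  i <- i[known_called]
  m <- as.matrix(dd[.ALLELES])
  total <- rowSums(m)
  removed <- floor(proportion * total + 0.5)
  a1 <- known$a1[i]; a2 <- known$a2[i]
  hom <- is.na(a2) | a1 == a2
  lo <- ifelse(hom, a1, pmin(a1, a2))
  hi <- ifelse(hom, a1, pmax(a1, a2))
  r_lo <- ifelse(hom, removed, removed %/% 2 + removed %% 2)
  r_hi <- ifelse(hom, 0, removed %/% 2)
  rows <- seq_len(nrow(m))
  c_lo <- cbind(rows, match(lo, .ALLELES))
  c_hi <- cbind(rows, match(hi, .ALLELES))
  m[c_lo] <- pmax(0L, m[c_lo] - as.integer(r_lo))
  m[c_hi] <- pmax(0L, m[c_hi] - as.integer(r_hi))
  residual <- allele_depths(dd$locus_id, m, mode = attr(depths, "mode"))
  calls <- call_genotypes(residual, panel, thresholds, sex)
  structure(list(residual = residual, calls = calls,
                 assumed_proportion = proportion, n_skipped = n_skip),
            class = "deconvolution_result")
}
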