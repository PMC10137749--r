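# Biallelic-SNP kinship likelihood ratios (duo, trio, kappa-based pairwise
# relationships), Mendelian-inconsistency counting, and gene-dropping
# simulation studies.
#
# Genotypes enter these functions as alt-allele dosages (0, 1, 2); q is the
# alt-allele frequency, p = 1 - q. All LRs assume HWE, zero mutation rate
# and linkage equilibrium; an exclusion therefore zeroes the combined LR
# unless explicitly dropped (see lr_summary).

#' Built-in pairwise relationships (IBD kappa coefficients)
#'
#' kappa = (k0, k1, k2) are the probabilities that a non-inbred pair shares
#' 0, 1 or 2 alleles identical by descent at a locus.
#'
#' @param name one of `parent_child`, `half_siblings`, `first_cousins`,
#'   `first_cousins_once_removed`, `second_cousins`, `unrelated`; or
#'   `"custom"` with `kappa` supplied.
#' @param kappa numeric length-3 vector for `custom`.
#' @return a `relationship` list (`name`, `kappa`, `degree`).
#' @export
relationship <- function(name = c("parent_child", "half_siblings",
                                  "first_cousins",
                                  "first_cousins_once_removed",
                                  "second_cousins", "unrelated", "custom"),
                         kappa = NULL) {
  name <- match.arg(name)
  builtin <- list(
    parent_child = list(kappa = c(0, 1, 0), degree = 1L),
    half_siblings = list(kappa = c(0.5, 0.5, 0), degree = 2L),
    first_cousins = list(kappa = c(0.75, 0.25, 0), degree = 3L),
    first_cousins_once_removed = list(kappa = c(0.875, 0.125, 0),
                                      degree = 4L),
    second_cousins = list(kappa = c(0.9375, 0.0625, 0), degree = 5L),
    unrelated = list(kappa = c(1, 0, 0), degree = NA_integer_))
  if (name == "custom") {
    if (is.null(kappa)) stop("custom relationship needs kappa", call. = FALSE)
    spec <- list(kappa = kappa, degree = NA_integer_)
  } else spec <- builtin[[name]]
  k <- spec$kappa
  if (length(k) != 3L || any(k < 0) || abs(sum(k) - 1) > 1e-12)
    stop("kappa must be 3 nonnegative values summing to 1", call. = FALSE)
  structure(list(name = name, kappa = k, degree = spec$degree),
            class = "relationship")
}

# HWE genotype probability of dosage g at alt frequency q
.p_hwe <- function(g, q) {
  p <- 1 - q
  ifelse(g == 0L, p * p, ifelse(g == 1L, 2 * p * q, q * q))
}

# P(g2 | g1, pair shares exactly one allele IBD): the IBD allele is a random
# allele of g1, the other allele of g2 is drawn from the population
.p_ibd1 <- function(g1, g2, q) {
  p <- 1 - q
  t <- g1 / 2                       # P(IBD allele is alt)
  ifelse(g2 == 0L, (1 - t) * p,
         ifelse(g2 == 1L, t * p + (1 - t) * q, t * q))
}

.check_q <- function(q, floor) {
  q <- .floor_freq(q, floor)
  if (any(q <= 0 | q >= 1))
    stop("allele frequency degenerate after flooring", call. = FALSE)
  q
}

#' Pairwise kinship likelihood ratio at one or more loci
#'
#' LR = k0 + k1 P(g2 | g1, 1 IBD) / P(g2) + k2 \[g1 = g2\] / P(g2), the
#' standard identity-by-descent decomposition for a non-inbred pair under
#' HWE, against the unrelated alternative.
#'
#' @param g1,g2 alt-allele dosages (0/1/2), vectorised over loci.
#' @param q alt-allele frequencies.
#' @param rel a [relationship()].
#' @param freq_floor frequencies are clamped to
#'   \[freq_floor, 1 - freq_floor\].
#' @return numeric LR vector.
#' @export
pairwise_lr <- function(g1, g2, q, rel, freq_floor = 1e-3) {
  q <- .check_q(q, freq_floor)
  k <- rel$kappa
  pg2 <- .p_hwe(g2, q)
  k[1L] + k[2L] * .p_ibd1(g1, g2, q) / pg2 +
    k[3L] * as.numeric(g1 == g2) / pg2
}

#' Paternity/maternity duo likelihood ratio
#'
#' P(child | parent is a biological parent) / P(child | unrelated), with
#' Mendelian transmission and zero mutation: opposite homozygotes give
#' LR = 0. Identical to [pairwise_lr()] with kappa = (0, 1, 0).
#'
#' @param parent,child alt-allele dosages (0/1/2).
#' @param q alt-allele frequencies.
#' @param freq_floor frequency clamp.
#' @return numeric LR vector.
#' @export
duo_lr <- function(parent, child, q, freq_floor = 1e-3) {
  q <- .check_q(q, freq_floor)
  .p_ibd1(parent, child, q) / .p_hwe(child, q)
}

#' Trio (known mother, alleged father, child) likelihood ratio
#'
#' P(child | mother, alleged father) / P(child | mother, random father);
#' when the maternal origin of the child's alleles is ambiguous both
#' assignments are summed over. A mother-child incompatibility makes both
#' terms zero; the LR is reported as 0 and should be treated as an
#' inconsistency.
#'
#' @param mother,child,father alt-allele dosages (0/1/2).
#' @param q alt-allele frequencies.
#' @param freq_floor frequency clamp.
#' @return numeric LR vector.
#' @export
trio_lr <- function(mother, child, father, q, freq_floor = 1e-3) {
  q <- .check_q(q, freq_floor)
  p <- 1 - q
  tm <- mother / 2
  tf <- father / 2
  num <- ifelse(child == 0L, (1 - tm) * (1 - tf),
                ifelse(child == 1L, (1 - tm) * tf + tm * (1 - tf), tm * tf))
  den <- ifelse(child == 0L, (1 - tm) * p,
                ifelse(child == 1L, (1 - tm) * q + tm * p, tm * q))
  out <- ifelse(den > 0, num / den, 0)
  out
}

#' Count Mendelian inconsistencies over loci
#'
#' Duo: opposite homozygotes. Trio: any child genotype impossible given
#' both parents (zero mutation rate). `NA` dosages are skipped.
#'
#' @param child,parent1 alt-allele dosages.
#' @param parent2 second parent's dosages for the trio check, or `NULL`.
#' @return integer count of inconsistent loci.
#' @export
count_inconsistencies <- function(child, parent1, parent2 = NULL) {
  if (is.null(parent2)) {
    ok <- !is.na(child) & !is.na(parent1)
    return(sum(abs(child[ok] - parent1[ok]) == 2L))
  }
  ok <- !is.na(child) & !is.na(parent1) & !is.na(parent2)
  t1 <- parent1[ok] / 2
  t2 <- parent2[ok] / 2
  g <- child[ok]
  pr <- ifelse(g == 0L, (1 - t1) * (1 - t2),
               ifelse(g == 1L, (1 - t1) * t2 + t1 * (1 - t2), t1 * t2))
  sum(pr == 0)
}

#' Combine per-locus LRs into a case result
#'
#' The combined log10 LR sums over loci with LR > 0; any zero-LR locus is a
#' genetic inconsistency and forces the strict combined LR to zero (no
#' mutation model), so the summary reports both the strict result and the
#' LR with exclusions dropped.
#'
#' @param lr numeric per-locus LR vector (`NA` loci are ignored).
#' @return `kinship_result` list: `log10_lr` (strict; `-Inf` when excluded
#'   loci exist), `log10_lr_excluding`, `n_loci`, `n_inconsistencies`.
#' @export
lr_summary <- function(lr) {
  lr <- lr[!is.na(lr)]
  nz <- lr > 0
  out <- list(log10_lr = if (all(nz)) sum(log10(lr)) else -Inf,
              log10_lr_excluding = sum(log10(lr[nz])),
              n_loci = length(lr),
              n_inconsistencies = sum(!nz))
  class(out) <- "kinship_result"
  out
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf(
    "kinship LR over %d loci: log10 LR = %s (%d exclusion(s); excluding them: %.2f)\n",
    x$n_loci, format(x$log10_lr, digits = 4), x$n_inconsistencies,
    x$log10_lr_excluding))
  invisible(x)
}

#' Convert genotype tables to alt-allele dosages
#'
#' @param genotypes a `genotype_table`.
#' @param panel a `snp_panel`; dosage counts the panel alt allele.
#' @param loci loci to extract (default: the panel's autosomal kinship
#'   markers).
#' @return named integer vector of dosages (`NA` for no-calls).
#' @export
genotype_dosage <- function(genotypes, panel,
                            loci = panel$locus_id[panel$category == "kinship"]) {
  panel <- as_panel(panel)
  i <- match(loci, genotypes$locus_id)
  j <- match(loci, panel$locus_id)
  if (anyNA(j)) stop("locus not in panel", call. = FALSE)
  a1 <- genotypes$a1[i]; a2 <- genotypes$a2[i]
  alt <- panel$alt[j]
  d <- (!is.na(a1) & a1 == alt) + (!is.na(a2) & a2 == alt)
  d[is.na(a1)] <- NA_integer_
  setNames(as.integer(d), loci)
}

# -- simulation studies ------------------------------------------------------

#' Simulate paternity duos and count inconsistencies
#'
#' Draws alleged-father/child duos under the true hypothesis (H1: father;
#' H2: unrelated), counts Mendelian inconsistencies (expected 2 p^2 q^2 per
#' locus under H2, zero under H1) and computes the duo LR per simulation,
#' excluding zero-LR loci from the product and reporting them as
#' exclusions.
#'
#' @param q alt-allele frequency vector over the marker set.
#' @param n_sims number of simulated duos.
#' @param true_hypothesis `"H1"` or `"H2"`.
#' @param seed integer seed.
#' @param freq_floor frequency clamp used in the LR.
#' @return `paternity_sim` list with per-simulation `inconsistencies`,
#'   `log10_lr` (exclusions dropped), `n_excluded`, and a `summary`.
#' @export
simulate_paternity <- function(q, n_sims = 1000,
                               true_hypothesis = c("H2", "H1"), seed = 1,
                               freq_floor = 1e-3) {
  true_hypothesis <- match.arg(true_hypothesis)
  L <- length(q)
  set.seed(.substream(seed, 31))
  qrep <- rep(q, each = n_sims)
  gF <- matrix(rbinom(n_sims * L, 2L, qrep), n_sims, L)
  if (true_hypothesis == "H1") {
    pat <- matrix(rbinom(n_sims * L, 1L, as.vector(gF) / 2), n_sims, L)
    mat <- matrix(rbinom(n_sims * L, 1L, qrep), n_sims, L)
    gC <- pat + mat
  } else {
    gC <- matrix(rbinom(n_sims * L, 2L, qrep), n_sims, L)
  }
  inc <- rowSums(abs(gF - gC) == 2L)
  lr <- matrix(duo_lr(as.vector(gF), as.vector(gC), qrep, freq_floor),
               n_sims, L)
  zero <- lr == 0
  n_excluded <- rowSums(zero)
  lr[zero] <- 1
  log10_lr <- rowSums(log10(lr))
  structure(list(
    true_hypothesis = true_hypothesis,
    inconsistencies = inc,
    log10_lr = log10_lr,
    n_excluded = n_excluded,
    summary = list(mean_inconsistencies = mean(inc),
                   min_inconsistencies = min(inc),
                   max_inconsistencies = max(inc),
                   mean_log10_lr = mean(log10_lr))),
    class = "paternity_sim")
}

#' @export
print.paternity_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%d paternity-duo simulations under %s: inconsistencies mean %.1f (min %d, max %d); mean log10 LR (exclusions dropped) %.1f\n",
    length(x$inconsistencies), x$true_hypothesis, s$mean_inconsistencies,
    s$min_inconsistencies, s$max_inconsistencies, s$mean_log10_lr))
  invisible(x)
}

# pedigrees realising each built-in pairwise relationship; the named pair is
# evaluated
.rel_pedigree <- function(name) {
  switch(name,
    parent_child = list(
      ped = pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
                     c("male", "female", "female")),
      pair = c("F", "C")),
    half_siblings = list(
      ped = pedigree(c("F", "M1", "M2", "C1", "C2"),
                     c(NA, NA, NA, "F", "F"), c(NA, NA, NA, "M1", "M2"),
                     c("male", "female", "female", "female", "female")),
      pair = c("C1", "C2")),
    first_cousins = list(
      ped = pedigree(c("GF", "GM", "S1", "S2", "W1", "W2", "C1", "C2"),
                     c(NA, NA, "GF", "GF", NA, NA, "S1", "S2"),
                     c(NA, NA, "GM", "GM", NA, NA, "W1", "W2"),
                     c("male", "female", "male", "male", "female", "female",
                       "female", "female")),
      pair = c("C1", "C2")),
    first_cousins_once_removed = list(
      ped = pedigree(c("GF", "GM", "S1", "S2", "W1", "W2", "C1", "C2", "W3",
                       "D"),
                     c(NA, NA, "GF", "GF", NA, NA, "S1", "S2", NA, "C2"),
                     c(NA, NA, "GM", "GM", NA, NA, "W1", "W2", NA, "W3"),
                     c("male", "female", "male", "male", "female", "female",
                       "female", "male", "female", "female")),
      pair = c("C1", "D")),
    second_cousins = list(
      ped = pedigree(c("GF", "GM", "S1", "S2", "W1", "W2", "C1", "C2", "W3",
                       "W4", "E1", "E2"),
                     c(NA, NA, "GF", "GF", NA, NA, "S1", "S2", NA, NA, "C1",
                       "C2"),
                     c(NA, NA, "GM", "GM", NA, NA, "W1", "W2", NA, NA, "W3",
                       "W4"),
                     c("male", "female", "male", "male", "female", "female",
                       "male", "male", "female", "female", "female",
                       "female")),
      pair = c("E1", "E2")),
    stop("no pedigree for relationship ", name, call. = FALSE))
}

# drop founder-haplotype labels through a pedigree once; returns per member
# a list(l1, l2) of integer label vectors over L loci
.drop_labels <- function(ped, L, r) {
  labels <- list()
  next_label <- 1L
  for (k in seq_len(nrow(ped))) {
    m <- ped[k, ]
    if (is.na(m$father)) {
      labels[[m$id]] <- list(l1 = rep(next_label, L),
                             l2 = rep(next_label + 1L, L))
      next_label <- next_label + 2L
    } else {
      f <- labels[[m$father]]; mo <- labels[[m$mother]]
      labels[[m$id]] <- list(l1 = .meiosis(f$l1, f$l2, r),
                             l2 = .meiosis(mo$l1, mo$l2, r))
    }
  }
  attr(labels, "n_founder_haps") <- next_label - 1L
  labels
}

#' Simulate pairwise-kinship LR distributions by gene dropping
#'
#' Under H1 the named relationship's pedigree is gene-dropped (linkage-aware
#' when a genetic map is supplied: Haldane crossover process along each
#' chromosome); under H2 two unrelated individuals are drawn. The LR is the
#' per-locus [pairwise_lr()] product, i.e. it assumes linkage equilibrium
#' even when the simulation is linked. Also reports the locus-wise IBD-state
#' fractions under H1 and the H1/H2 distribution overlap at LR = 1
#' (mean of the two misclassification rates).
#'
#' @param rel a [relationship()] name or object (pairwise built-ins other
#'   than `unrelated`).
#' @param q alt-allele frequency vector over the loci (ordered along the
#'   genome when a map is used).
#' @param panel optional `snp_panel` (needed when `map` is given; loci are
#'   its autosomal kinship markers sorted by position).
#' @param map optional `genetic_map`.
#' @param n_sims simulations per hypothesis.
#' @param seed integer seed.
#' @param freq_floor frequency clamp.
#' @return `pairwise_sim` list: `log10_lr_h1`, `log10_lr_h2`,
#'   `ibd_fractions` (under H1), `overlap`, `rel`.
#' @export
simulate_pairwise <- function(rel, q, panel = NULL, map = NULL,
                              n_sims = 1000, seed = 1, freq_floor = 1e-3) {
  if (is.character(rel)) rel <- relationship(rel)
  if (!is.null(panel)) {
    panel <- as_panel(panel)
    panel <- panel[panel$category == "kinship", ]
    panel <- panel[order(.chrom_rank(panel$chrom), panel$pos), ]
    q <- freq_vector(q, loci = panel$locus_id)
  }
  L <- length(q)
  r <- if (is.null(panel)) rep(0.5, max(L - 1L, 0L)) else
    .recomb_fractions(panel, map)
  qf <- .check_q(q, freq_floor)
  plan <- .rel_pedigree(rel$name)
  set.seed(.substream(seed, 41))
  log10_h1 <- numeric(n_sims)
  ibd_counts <- c(`0` = 0, `1` = 0, `2` = 0)
  nh_guess <- 2L * sum(is.na(plan$ped$father))
  for (s in seq_len(n_sims)) {
    lab <- .drop_labels(plan$ped, L, r)
    nh <- attr(lab, "n_founder_haps")
    hap_alleles <- matrix(as.integer(runif(nh * L) < q), nh, L, byrow = TRUE)
    idx <- function(l) hap_alleles[cbind(l, seq_len(L))]
    A <- lab[[plan$pair[1L]]]; B <- lab[[plan$pair[2L]]]
    g1 <- idx(A$l1) + idx(A$l2)
    g2 <- idx(B$l1) + idx(B$l2)
    ibd <- (A$l1 == B$l1 | A$l1 == B$l2) + (A$l2 == B$l1 | A$l2 == B$l2)
    ibd_counts <- ibd_counts + tabulate(ibd + 1L, 3L)
    log10_h1[s] <- sum(log10(pairwise_lr(g1, g2, qf, rel, freq_floor)))
  }
  # H2: unrelated pairs; loci independent within an individual under HWE
  qrep <- rep(q, each = n_sims)
  u1 <- matrix(rbinom(n_sims * L, 2L, qrep), n_sims, L)
  u2 <- matrix(rbinom(n_sims * L, 2L, qrep), n_sims, L)
  lrm <- matrix(pairwise_lr(as.vector(u1), as.vector(u2),
                            rep(qf, each = n_sims), rel, freq_floor),
                n_sims, L)
  log10_h2 <- rowSums(log10(lrm))
  overlap <- 0.5 * (mean(log10_h1 < 0) + mean(log10_h2 > 0))
  structure(list(rel = rel,
                 log10_lr_h1 = log10_h1,
                 log10_lr_h2 = log10_h2,
                 ibd_fractions = ibd_counts / sum(ibd_counts),
                 overlap = overlap,
                 n_sims = n_sims, n_loci = L),
            class = "pairwise_sim")
}

#' @export
print.pairwise_sim <- function(x, ...) {
  cat(sprintf(
    "%s: %d sims x %d loci; median log10 LR H1 %.1f / H2 %.1f; IBD fractions (%.3f, %.3f, %.3f); overlap at LR=1: %.4f\n",
    x$rel$name, x$n_sims, x$n_loci, stats::median(x$log10_lr_h1),
    stats::median(x$log10_lr_h2), x$ibd_fractions[1L], x$ibd_fractions[2L],
    x$ibd_fractions[3L], x$overlap))
  invisible(x)
}
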