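# Naive-Bayes biogeographic ancestry prediction from autosomal
# ancestry-informative SNPs and per-population allele frequencies.

#' Naive-Bayes ancestry posterior
#'
#' Log-likelihood per reference population is the sum over called autosomal
#' ancestry loci of the log HWE genotype probability at that population's
#' (floored) allele frequencies; loci are treated as independent (the naive
#' assumption). Posterior = prior x likelihood, normalised; uniform prior
#' by default.
#'
#' @param genotypes a `genotype_table`.
#' @param meta_freqs `freq_table` with one column per reference population
#'   (e.g. seven meta-populations).
#' @param panel a `snp_panel`; loci restrict to `category == "ancestry"`
#'   unless `loci` is given.
#' @param prior named prior over populations (default uniform).
#' @param loci optional explicit locus set.
#' @param freq_floor frequencies clamped to \[freq_floor, 1 - freq_floor\].
#' @return named posterior probability vector (sums to 1), with the
#'   per-population log10 likelihoods as attribute `log10_lik`.
#' @export
ancestry_posterior <- function(genotypes, meta_freqs, panel, prior = NULL,
                               loci = NULL, freq_floor = 1e-3) {
  panel <- as_panel(panel)
  pops <- setdiff(names(meta_freqs), "locus_id")
  if (!length(pops)) stop("no reference populations", call. = FALSE)
  if (is.null(loci))
    loci <- panel$locus_id[panel$category == "ancestry"]
  loci <- intersect(loci, meta_freqs$locus_id)
  d <- genotype_dosage(genotypes, panel, loci = loci)
  d <- d[!is.na(d)]
  if (!length(d)) stop("no called ancestry loci", call. = FALSE)
  if (is.null(prior)) prior <- setNames(rep(1 / length(pops), length(pops)),
                                        pops)
  if (!all(pops %in% names(prior)))
    stop("prior must cover every population", call. = FALSE)
  prior <- prior[pops] / sum(prior[pops])
  ll <- vapply(pops, function(pop) {
    q <- .floor_freq(freq_vector(meta_freqs, pop, names(d)), freq_floor)
    sum(log(.p_hwe(unname(d), q)))
  }, numeric(1))
  w <- log(prior) + ll
  w <- exp(w - max(w))
  post <- w / sum(w)
  attr(post, "log10_lik") <- ll / log(10)
  post
}
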