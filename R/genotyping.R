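# ARF computation and threshold-based genotype calling.

#' Genotype-calling threshold profiles
#'
#' Three named profiles ship with the package:
#' * `default` — 10x coverage, homozygote ARF >= 0.95, heterozygote
#'   ARF <= 0.80, base quality >= 15;
#' * `liberal` — ARF bounds relaxed to 0.90 / 0.85, trading a small loss of
#'   accuracy for call rate;
#' * `deconvolution` — 0.90 / 0.55, the conservative bounds used when
#'   calling the residual reads of a deconvolved mixture.
#'
#' @param profile profile name, or `"custom"` with explicit values.
#' @param min_coverage minimum total depth for a call.
#' @param hom_arf minimum ARF for a homozygote call.
#' @param het_arf maximum ARF for a heterozygote call.
#' @param min_quality per-read SNP-site base-quality cutoff applied before
#'   counting.
#' @return a `call_thresholds` list.
#' @export
call_thresholds <- function(profile = c("default", "liberal",
                                        "deconvolution", "custom"),
                            min_coverage = 10L, hom_arf = 0.95,
                            het_arf = 0.80, min_quality = 15L) {
  profile <- match.arg(profile)
  preset <- switch(profile,
                   default = c(0.95, 0.80),
                   liberal = c(0.90, 0.85),
                   deconvolution = c(0.90, 0.55),
                   custom = c(hom_arf, het_arf))
  th <- list(min_coverage = as.integer(min_coverage),
             hom_arf = preset[1L], het_arf = preset[2L],
             min_quality = as.integer(min_quality),
             profile_name = profile)
  stopifnot(th$het_arf >= 0.5, th$het_arf < th$hom_arf, th$hom_arf <= 1,
            th$min_coverage >= 1L)
  class(th) <- "call_thresholds"
  th
}

#' Allele read frequency of a locus
#'
#' The read depth of the allele with the most reads divided by the total
#' read depth; >= 0.5 for biallelic loci. Ties on the maximum leave the ARF
#' unchanged (the major-allele identity is then the lexicographically first
#' allele).
#'
#' @param counts named allele->count vector (or unnamed numeric).
#' @return the ARF, a real in (0, 1\].
#' @export
compute_arf <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("zero total depth", call. = FALSE)
  max(counts) / total
}

# vectorised calling core; depths as an integer matrix over .ALLELES columns
.call_matrix <- function(m, ref, alt, hemi, th) {
  n <- nrow(m)
  total <- rowSums(m)
  top1 <- max.col(m, ties.method = "first")      # lexicographic tie-break
  top1n <- m[cbind(seq_len(n), top1)]
  m2 <- m
  m2[cbind(seq_len(n), top1)] <- -1L
  top2 <- max.col(m2, ties.method = "first")
  top2n <- m2[cbind(seq_len(n), top2)]
  arf <- ifelse(total > 0, top1n / total, NA_real_)
  a_major <- .ALLELES[top1]
  a_second <- ifelse(top2n > 0, .ALLELES[top2], NA_character_)
  status <- rep("called", n)
  a1 <- a2 <- rep(NA_character_, n)
  low <- total < th$min_coverage
  hom <- !low & arf >= th$hom_arf
  het <- !low & !hom & arf <= th$het_arf & !hemi
  imb <- !low & !hom & !het
  # hemizygous: single-allele call at the homozygote bound, else imbalance
  status[low] <- "no_call_low_coverage"
  status[imb] <- "no_call_imbalance"
  a1[hom] <- a_major[hom]
  a2[hom & !hemi] <- a_major[hom & !hemi]
  a1[het] <- pmin(a_major[het], a_second[het])
  a2[het] <- pmax(a_major[het], a_second[het])
  # called alleles must lie within the panel's ref/alt pair
  called <- status == "called"
  offp <- called &
    (!(a1 %in% .BASES) | !(is.na(a2) | a2 %in% .BASES) |
       (a1 != ref & a1 != alt) |
       (!is.na(a2) & a2 != ref & a2 != alt))
  status[offp] <- "no_call_off_panel"
  a1[offp] <- NA_character_
  a2[offp] <- NA_character_
  list(a1 = a1, a2 = a2, status = status, arf = arf, depth = as.integer(total))
}

#' Call one genotype from allele counts
#'
#' Total depth below `min_coverage` gives `no_call_low_coverage`; otherwise
#' ARF >= `hom_arf` calls a homozygote for the major allele, ARF <=
#' `het_arf` a heterozygote of the two most-read alleles, and anything in
#' between `no_call_imbalance`. A major or second allele outside the
#' panel's ref/alt pair gives `no_call_off_panel`. Hemizygous loci are
#' called as a single allele when ARF >= `hom_arf`, else
#' `no_call_imbalance`.
#'
#' @param counts named allele->count vector (names from A,C,G,T,other).
#' @param thresholds a [call_thresholds()].
#' @param ref,alt the panel alleles at the locus.
#' @param hemizygous single-copy locus?
#' @return one-row `genotype_table` with `arf` and `depth`.
#' @export
call_genotype <- function(counts, thresholds = call_thresholds(),
                          ref, alt, hemizygous = FALSE) {
  v <- setNames(integer(5L), .ALLELES)
  v[names(counts)] <- as.integer(counts)
  res <- .call_matrix(matrix(v, 1L, dimnames = list(NULL, .ALLELES)),
                      ref, alt, hemizygous, thresholds)
  genotype_table("locus", res$a1, res$a2, res$status,
                 arf = res$arf, depth = res$depth)
}

#' Call genotypes for a whole depth table
#'
#' @param depths an `allele_depths` table (post-quality-filter counts).
#' @param panel a `snp_panel` covering the depth loci.
#' @param thresholds a [call_thresholds()] or profile name.
#' @param sex sample sex; male X loci are treated hemizygous.
#' @return a `genotype_table` with `arf` and `depth` columns, in depth-table
#'   order.
#' @export
call_genotypes <- function(depths, panel, thresholds = call_thresholds(),
                           sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (is.character(thresholds)) thresholds <- call_thresholds(thresholds)
  panel <- as_panel(panel)
  dd <- as.data.frame(depths)
  i <- match(dd$locus_id, panel$locus_id)
  if (anyNA(i)) stop("depth locus not in panel: ",
                     dd$locus_id[which(is.na(i))[1L]], call. = FALSE)
  hemi <- .is_hemizygous(panel, sex)[i]
  m <- as.matrix(dd[.ALLELES])
  res <- .call_matrix(m, panel$ref[i], panel$alt[i], hemi, thresholds)
  genotype_table(dd$locus_id, res$a1, res$a2, res$status,
                 arf = res$arf, depth = res$depth)
}
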