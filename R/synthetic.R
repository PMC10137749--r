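# Synthetic panel resources: a FORCE-like marker set, population allele
# frequencies, and an approximate genetic map. These stand in for the real
# panel annotation and reference frequency tables, which are not bundled;
# everything downstream treats them exactly like file-loaded resources.

# approximate autosome lengths in Mb (hg-scale, rounded)
.CHR_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
             115, 107, 102, 90, 83, 80, 59, 64, 47, 51)

#' Generate a synthetic forensic SNP panel
#'
#' Marker categories follow the make-up of large all-in-one forensic panels:
#' mostly kinship-informative autosomal SNPs, plus identity, ancestry and
#' phenotype markers and X-/Y-chromosomal SNPs. Positions are drawn uniformly
#' along approximate chromosome lengths.
#'
#' @param n_loci total number of SNPs.
#' @param seed integer seed.
#' @param proportions named numeric of category proportions (normalised).
#' @return a `snp_panel`.
#' @export
synthetic_panel <- function(n_loci = 5000, seed = 1,
                            proportions = c(kinship = 0.715, identity = 0.070,
                                            ancestry = 0.046, phenotype = 0.008,
                                            X = 0.010, Y = 0.151)) {
  stopifnot(n_loci >= 1)
  set.seed(.substream(seed, 101))
  proportions <- proportions / sum(proportions)
  counts <- floor(proportions * n_loci)
  rest <- n_loci - sum(counts)
  if (rest > 0)  # leftovers to the largest class
    counts[which.max(proportions)] <- counts[which.max(proportions)] + rest
  category <- rep(names(counts), counts)
  n_aut <- sum(counts[!names(counts) %in% c("X", "Y")])
  chrom <- character(n_loci)
  aut_idx <- which(!category %in% c("X", "Y"))
  chrom[aut_idx] <- sample(as.character(1:22), n_aut, replace = TRUE,
                           prob = .CHR_MB)
  chrom[category == "X"] <- "X"
  chrom[category == "Y"] <- "Y"
  len_mb <- c(setNames(.CHR_MB, as.character(1:22)), X = 155, Y = 57)
  pos <- as.integer(floor(runif(n_loci, 1, len_mb[chrom] * 1e6)))
  df <- data.frame(locus_id = "", chrom = chrom, pos = pos,
                   ref = "", alt = "", category = category,
                   stringsAsFactors = FALSE)
  df <- df[order(.chrom_rank(df$chrom), df$pos), ]
  # de-duplicate positions within chromosome (vanishingly rare but possible)
  dup <- duplicated(paste(df$chrom, df$pos))
  while (any(dup)) {
    df$pos[dup] <- df$pos[dup] + 1L
    df <- df[order(.chrom_rank(df$chrom), df$pos), ]
    dup <- duplicated(paste(df$chrom, df$pos))
  }
  df$locus_id <- sprintf("snp%05d", seq_len(n_loci))
  ref <- sample(.BASES, n_loci, replace = TRUE)
  alt <- sample(.BASES[-1], n_loci, replace = TRUE)
  alt <- ifelse(alt == ref, "A", alt)   # any base other than ref
  df$ref <- ref; df$alt <- alt
  as_panel(df)
}

#' Generate synthetic population allele frequencies for a panel
#'
#' Alt-allele frequencies are drawn per marker category: kinship and identity
#' SNPs are common variants (q ~ U(0.2, 0.8), as such markers are chosen for
#' informativeness), others q ~ U(0.05, 0.95). With several populations,
#' per-population frequencies scatter around the shared ancestral frequency
#' under a Balding-Nichols model with divergence `fst`, giving
#' well-separated ancestry-informative frequencies.
#'
#' @param panel a `snp_panel`.
#' @param populations character vector of population names.
#' @param fst Balding-Nichols divergence among populations (ignored for a
#'   single population).
#' @param seed integer seed.
#' @return a `freq_table`.
#' @export
synthetic_frequencies <- function(panel, populations = "POP1", fst = 0.15,
                                  seed = 1) {
  panel <- as_panel(panel)
  set.seed(.substream(seed, 102))
  n <- nrow(panel)
  base <- runif(n, 0.05, 0.95)
  common <- panel$category %in% c("kinship", "identity")
  base[common] <- runif(sum(common), 0.2, 0.8)
  out <- data.frame(locus_id = panel$locus_id, stringsAsFactors = FALSE)
  if (length(populations) == 1L || fst <= 0) {
    for (p in populations) out[[p]] <- base
  } else {
    k <- (1 - fst) / fst
    for (p in populations) {
      q <- stats::rbeta(n, base * k, (1 - base) * k)
      out[[p]] <- pmin(pmax(q, 1e-4), 1 - 1e-4)
    }
  }
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Generate an approximate genetic map for a panel
#'
#' Linear interpolation at `cm_per_mb` centimorgans per megabase, a standard
#' genome-wide average. Y-chromosomal loci are excluded (no recombination).
#'
#' @param panel a `snp_panel`.
#' @param cm_per_mb average recombination rate.
#' @return a `genetic_map` data.frame (`locus_id`, `chrom`, `cm`).
#' @export
synthetic_map <- function(panel, cm_per_mb = 1.13) {
  panel <- as_panel(panel)
  keep <- panel$category != "Y"
  df <- data.frame(locus_id = panel$locus_id[keep],
                   chrom = panel$chrom[keep],
                   cm = panel$pos[keep] / 1e6 * cm_per_mb,
                   stringsAsFactors = FALSE)
  as_genetic_map(df)
}

#' Construct / validate a genetic map
#'
#' @param df data.frame with `locus_id`, `chrom`, `cm` (nonnegative map
#'   positions in centimorgans, nondecreasing within chromosome after
#'   sorting).
#' @return a `genetic_map` data.frame.
#' @export
as_genetic_map <- function(df) {
  need <- c("locus_id", "chrom", "cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genetic map missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  df$cm <- as.numeric(df$cm)
  if (any(is.na(df$cm)) || any(df$cm < 0))
    stop("map positions must be nonnegative", call. = FALSE)
  df <- df[order(.chrom_rank(df$chrom), df$cm), ]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}
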