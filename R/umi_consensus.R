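# UMI grouping, consensus (UMI) reads, and allele-depth tabulation in
# "umi" (consensus-read) and "raw" (all-read) counting modes.

#' Consensus-calling parameters
#'
#' @param majority_fraction fraction of family members a base must exceed to
#'   become the consensus (strict inequality; the default 0.5 is plain
#'   strict majority). Exact ties are always ambiguous.
#' @param min_family_size smallest UMI family that yields a consensus read.
#'   The default 1 lets singleton reads through, mirroring permissive
#'   grouping defaults in commercial pipelines.
#' @param merge_hamming1 if `TRUE`, a UMI group is absorbed into a group at
#'   Hamming distance 1 that is at least 10x larger (directional merge,
#'   largest groups first). Off by default.
#' @return a `consensus_params` list.
#' @export
consensus_params <- function(majority_fraction = 0.5, min_family_size = 1L,
                             merge_hamming1 = FALSE) {
  stopifnot(majority_fraction >= 0.5, majority_fraction <= 1,
            min_family_size >= 1L)
  structure(list(majority_fraction = majority_fraction,
                 min_family_size = as.integer(min_family_size),
                 merge_hamming1 = isTRUE(merge_hamming1)),
            class = "consensus_params")
}

.hamming1_neighbors <- function(umi) {
  L <- nchar(umi)
  out <- character(0)
  for (j in seq_len(L)) {
    b <- substr(umi, j, j)
    for (nb in setdiff(.BASES, b)) {
      x <- umi
      substr(x, j, j) <- nb
      out <- c(out, x)
    }
  }
  out
}

# directional Hamming-1 merge within a locus: group sizes named by UMI;
# returns a named map umi -> surviving umi
.merge_umis_locus <- function(sizes) {
  ord <- order(-sizes, names(sizes))
  umis <- names(sizes)[ord]
  sz <- as.numeric(sizes[ord])
  target <- setNames(umis, umis)
  eff <- setNames(sz, umis)         # running (post-merge) sizes
  for (u in umis) {
    if (target[[u]] != u) next
    for (nb in .hamming1_neighbors(u)) {
      i <- match(nb, names(eff))
      if (!is.na(i) && target[[nb]] == nb && nb != u &&
          eff[[u]] >= 10 * eff[[nb]]) {
        target[[nb]] <- u
        eff[[u]] <- eff[[u]] + eff[[nb]]
      }
    }
  }
  target
}

#' Group reads by (locus, UMI) and build consensus calls
#'
#' Exact-match grouping on the `(locus_id, umi)` pair. With
#' `merge_hamming1`, any group whose UMI lies within Hamming distance 1 of a
#' group at least 10 times larger is absorbed into it before consensus.
#' The consensus base is the allele held by more than
#' `majority_fraction` of family members; exact ties or absence of such a
#' majority give an ambiguous group (`consensus` `NA`).
#'
#' @param reads read table (`locus_id`, `allele`, `umi`, `qual`).
#' @param params a [consensus_params()].
#' @param quality_threshold minimum SNP-site base quality; lower-quality
#'   reads are discarded before grouping.
#' @return `data.table` of UMI groups: `locus_id`, `umi`, `size`,
#'   `consensus`.
#' @export
group_umis <- function(reads, params = consensus_params(),
                       quality_threshold = 0L) {
  dt <- data.table::as.data.table(reads)
  dt <- dt[qual >= quality_threshold]
  if (!nrow(dt))
    return(data.table::data.table(locus_id = character(0), umi = character(0),
                                  size = integer(0), consensus = character(0)))
  if (params$merge_hamming1) {
    sizes <- dt[, .N, by = .(locus_id, umi)]
    for (loc in unique(sizes$locus_id)) {
      s <- sizes[locus_id == loc]
      map <- .merge_umis_locus(setNames(s$N, s$umi))
      if (any(map != names(map))) {
        sel <- dt$locus_id == loc
        dt$umi[sel] <- unname(map[dt$umi[sel]])
      }
    }
  }
  tab <- dt[, .N, by = .(locus_id, umi, allele)]
  data.table::setorder(tab, locus_id, umi, -N, allele)
  sizes <- tab[, .(size = sum(N), top = allele[1L], topN = N[1L]),
               by = .(locus_id, umi)]
  mf <- params$majority_fraction
  sizes[, consensus := data.table::fifelse(topN > mf * size, top,
                                           NA_character_)]
  sizes[, c("top", "topN") := NULL]
  sizes[]
}

#' Consensus call for a single UMI family
#'
#' @param alleles character vector of member alleles (family size >= 1).
#' @param params a [consensus_params()].
#' @return the majority allele, or `NA` when ambiguous.
#' @export
consensus_call <- function(alleles, params = consensus_params()) {
  if (!length(alleles)) stop("empty UMI family", call. = FALSE)
  tab <- sort(table(alleles), decreasing = TRUE)
  if (tab[1L] > params$majority_fraction * length(alleles) &&
      (length(tab) == 1L || tab[1L] > tab[2L]))
    names(tab)[1L]
  else
    NA_character_
}

#' Tabulate allele depths in UMI or raw counting mode
#'
#' Reads below `quality_threshold` are discarded first. Raw mode counts the
#' retained reads per allele (PCR duplicates included); UMI mode counts one
#' per non-ambiguous UMI group of at least `min_family_size` members, at its
#' consensus allele. Ambiguous groups contribute nothing.
#'
#' @param reads read table.
#' @param mode `"umi"` or `"raw"`.
#' @param params a [consensus_params()] (UMI mode).
#' @param quality_threshold minimum SNP-site base quality.
#' @param panel optional `snp_panel`: the result then has one row per panel
#'   locus (zeros where no reads survive), in panel order.
#' @return an `allele_depths` table.
#' @export
tabulate_depths <- function(reads, mode = c("umi", "raw"),
                            params = consensus_params(),
                            quality_threshold = 15L, panel = NULL) {
  mode <- match.arg(mode)
  if (mode == "raw") {
    dt <- data.table::as.data.table(reads)
    tab <- dt[qual >= quality_threshold, .N, by = .(locus_id, allele)]
  } else {
    grp <- group_umis(reads, params, quality_threshold)
    grp <- grp[!is.na(consensus) & size >= params$min_family_size]
    tab <- grp[, .(N = .N), by = .(locus_id, allele = consensus)]
  }
  wide <- data.table::dcast(tab, locus_id ~ factor(allele, levels = .ALLELES),
                            value.var = "N", fill = 0L, drop = c(TRUE, FALSE))
  if (!is.null(panel)) {
    panel <- as_panel(panel)
    wide <- wide[match(panel$locus_id, wide$locus_id), ]
    wide$locus_id <- panel$locus_id
    for (a in .ALLELES) {
      if (is.null(wide[[a]])) wide[[a]] <- 0L
      wide[[a]][is.na(wide[[a]])] <- 0L
    }
  }
  for (a in .ALLELES) if (is.null(wide[[a]])) wide[[a]] <- 0L
  allele_depths(wide$locus_id, as.data.frame(wide)[.ALLELES], mode = mode)
}
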