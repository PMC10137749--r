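# Data model and file I/O: panel definitions, allele frequencies, read
# records, allele-depth tables, genotype tables, minimal VCF output.
#
# TSV dialect: tab-separated, UTF-8, mandatory header, '#'-prefixed comment
# lines ignored. All coordinates are 1-based inclusive (VCF convention).

# -- low-level TSV parser ----------------------------------------------------

# readLines-based so that errors can name the offending physical line.
.parse_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) < 1L) stop("no header line found in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!is.null(required)) {
    miss <- setdiff(required, header)
    if (length(miss))
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  body <- fields[-1L]
  if (length(body)) {
    nf <- lengths(body)
    bad <- which(nf != length(header))
    if (length(bad))
      stop(sprintf("malformed row in %s at line %d: expected %d fields, got %d",
                   path, keep[-1L][bad[1L]], length(header), nf[bad[1L]]),
           call. = FALSE)
    out <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(matrix(character(0), 0L, length(header)),
                         stringsAsFactors = FALSE)
  }
  names(out) <- header
  attr(out, "source_lines") <- keep[-1L]
  out
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "."
      x
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

# -- panel -------------------------------------------------------------------

#' Read a SNP panel definition
#'
#' The panel TSV has mandatory header columns `locus_id`, `chrom`, `pos`,
#' `ref`, `alt`, `category`. Categories follow the usual forensic marker
#' classes: `kinship`, `identity`, `ancestry`, `phenotype`, `X`, `Y`.
#' Positions are 1-based.
#'
#' @param path path to a tab-separated panel file (`#` comments allowed).
#' @return a `snp_panel` data.frame with typed, validated columns.
#' @export
read_panel <- function(path) {
  df <- .parse_tsv(path, required = c("locus_id", "chrom", "pos", "ref",
                                      "alt", "category"))
  lines <- attr(df, "source_lines")
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop(sprintf("invalid position at line %d of %s", lines[bad[1L]], path),
         call. = FALSE)
  df$pos <- pos
  as_panel(df)
}

#' Construct / validate a SNP panel
#'
#' @param df data.frame with columns `locus_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `category`.
#' @return validated `snp_panel` data.frame.
#' @export
as_panel <- function(df) {
  need <- c("locus_id", "chrom", "pos", "ref", "alt", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  df$locus_id <- as.character(df$locus_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$category <- as.character(df$category)
  dup <- df$locus_id[duplicated(df$locus_id)]
  if (length(dup))
    stop("duplicated locus_id in panel: ", dup[1L], call. = FALSE)
  if (!all(df$ref %in% .BASES) || !all(df$alt %in% .BASES))
    stop("panel ref/alt alleles must be one of A, C, G, T", call. = FALSE)
  same <- which(df$ref == df$alt)
  if (length(same))
    stop("ref equals alt at locus ", df$locus_id[same[1L]], call. = FALSE)
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stop("panel positions must be integers >= 1", call. = FALSE)
  badc <- setdiff(unique(df$category), .CATEGORIES)
  if (length(badc))
    stop("unknown marker category: ", badc[1L], call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Write a panel definition TSV
#' @param panel a `snp_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  panel <- as_panel(panel)
  .write_tsv(as.data.frame(panel), path)
}

# hemizygous loci for a given sex: Y always; X in males
.is_hemizygous <- function(panel, sex = c("female", "male")) {
  sex <- match.arg(sex)
  panel$category == "Y" | (panel$category == "X" & sex == "male")
}

# -- allele frequencies ------------------------------------------------------

#' Read a population allele-frequency table
#'
#' TSV with a `locus_id` column and one column per population holding the
#' alt-allele frequency q (ref frequency is 1 - q). Values outside \[0, 1\]
#' are rejected. Loci absent from `panel` are dropped with a warning.
#'
#' @param path frequency TSV path.
#' @param panel optional `snp_panel` used to filter and validate loci.
#' @return a `freq_table` data.frame (`locus_id` + one numeric column per
#'   population).
#' @export
read_frequencies <- function(path, panel = NULL) {
  df <- .parse_tsv(path, required = "locus_id")
  pops <- setdiff(names(df), "locus_id")
  if (!length(pops)) stop("frequency table has no population columns",
                          call. = FALSE)
  for (p in pops) {
    v <- suppressWarnings(as.numeric(df[[p]]))
    if (any(is.na(v)))
      stop("non-numeric frequency in column ", p, call. = FALSE)
    if (any(v < 0 | v > 1))
      stop("frequency outside [0,1] in column ", p, call. = FALSE)
    df[[p]] <- v
  }
  if (!is.null(panel)) {
    extra <- setdiff(df$locus_id, panel$locus_id)
    if (length(extra)) {
      warning(length(extra), " frequency locus/loci not in panel; dropped")
      df <- df[df$locus_id %in% panel$locus_id, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("freq_table", "data.frame")
  df
}

#' Extract a named alt-allele frequency vector for one population
#'
#' A locus queried but absent from the table is an error, not a zero.
#'
#' @param freqs a `freq_table` (or named numeric vector, returned unchanged
#'   after validation).
#' @param population population column; defaults to the only one present.
#' @param loci loci to extract, in order; default all rows.
#' @return named numeric vector of alt-allele frequencies.
#' @export
freq_vector <- function(freqs, population = NULL, loci = NULL) {
  if (is.numeric(freqs) && !is.null(names(freqs))) {
    q <- freqs
  } else {
    pops <- setdiff(names(freqs), "locus_id")
    if (is.null(population)) {
      if (length(pops) != 1L)
        stop("population must be named when table has several", call. = FALSE)
      population <- pops
    }
    if (!population %in% pops)
      stop("no such population: ", population, call. = FALSE)
    q <- setNames(freqs[[population]], freqs$locus_id)
  }
  if (any(q < 0 | q > 1)) stop("frequency outside [0,1]", call. = FALSE)
  if (!is.null(loci)) {
    miss <- setdiff(loci, names(q))
    if (length(miss))
      stop("no frequency for locus ", miss[1L], call. = FALSE)
    q <- q[loci]
  }
  q
}

# -- read records ------------------------------------------------------------

#' Read a per-read record table
#'
#' Columns: `locus_id`, `allele` (A/C/G/T/other), `umi` (fixed-length
#' nucleotide tag), `qual` (Phred-like, >= 0).
#'
#' @param path reads TSV.
#' @param umi_length expected UMI length; checked when not `NULL`.
#' @return a `data.table` of validated reads.
#' @export
read_reads <- function(path, umi_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("locus_id", "allele", "umi")))
  need <- c("locus_id", "allele", "umi", "qual")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("reads file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_reads(dt[, need, with = FALSE], umi_length = umi_length)
}

#' Validate a read table
#' @param reads data.frame/data.table of reads.
#' @param umi_length expected UMI length or `NULL` to skip the check.
#' @return the reads as a `data.table`.
#' @export
validate_reads <- function(reads, umi_length = NULL) {
  dt <- data.table::as.data.table(reads)
  if (!all(dt$allele %in% .ALLELES))
    stop("read allele must be one of ", paste(.ALLELES, collapse = ", "),
         call. = FALSE)
  dt$qual <- as.integer(dt$qual)
  if (any(is.na(dt$qual)) || any(dt$qual < 0L))
    stop("read quality must be an integer >= 0", call. = FALSE)
  if (!is.null(umi_length) && nrow(dt) && any(nchar(dt$umi) != umi_length))
    stop("UMI length differs from configured length ", umi_length,
         call. = FALSE)
  dt
}

#' Write a read table TSV
#' @param reads read table.
#' @param path output path.
#' @export
write_reads <- function(reads, path) {
  cols <- intersect(c("locus_id", "allele", "umi", "qual",
                      "template", "true_allele", "contributor"),
                    names(reads))
  .write_tsv(as.data.frame(reads)[cols], path)
}

# -- genotype tables ---------------------------------------------------------

#' Construct a genotype table
#'
#' One row per locus: unordered diploid pair (`a1`, `a2`), a single allele
#' for hemizygous loci (`a2` `NA`), or a no-call (both `NA`) with a reason in
#' `status`.
#'
#' @param locus_id character vector.
#' @param a1,a2 alleles (`NA` where absent).
#' @param status one of `called`, `no_call_low_coverage`,
#'   `no_call_imbalance`, `no_call_off_panel`, `not_typed`.
#' @param ... extra columns (e.g. `arf`, `depth`) recycled as needed.
#' @return a `genotype_table` data.frame.
#' @export
genotype_table <- function(locus_id, a1, a2 = NA_character_,
                           status = "called", ...) {
  df <- data.frame(locus_id = as.character(locus_id),
                   a1 = as.character(a1), a2 = as.character(a2),
                   status = as.character(status),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  ok <- is.na(df$a1) | df$a1 %in% .BASES
  ok2 <- is.na(df$a2) | df$a2 %in% .BASES
  if (!all(ok & ok2)) stop("genotype alleles must be A/C/G/T or NA",
                           call. = FALSE)
  bad <- df$status == "called" & is.na(df$a1)
  if (any(bad)) stop("called genotype without alleles", call. = FALSE)
  bad2 <- df$status != "called" & !is.na(df$a1)
  if (any(bad2)) stop("no-call rows must not carry alleles", call. = FALSE)
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Read a genotype table TSV ('.' encodes NA)
#' @param path genotype TSV with columns `locus_id`, `a1`, `a2`, `status`.
#' @return a `genotype_table`.
#' @export
read_genotypes <- function(path) {
  df <- .parse_tsv(path, required = c("locus_id", "a1", "a2", "status"))
  df[df == "."] <- NA
  gt <- genotype_table(df$locus_id, df$a1, df$a2, df$status)
  for (nm in setdiff(names(df), names(gt))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    gt[[nm]] <- if (all(is.na(v) == is.na(df[[nm]]))) v else df[[nm]]
  }
  gt
}

#' Write a genotype table TSV
#' @param genotypes a `genotype_table`.
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  .write_tsv(as.data.frame(genotypes), path)
}

# unordered allele-set comparison helpers
.gt_set <- function(a1, a2) {
  if (is.na(a1)) return(character(0))
  if (is.na(a2)) return(a1)
  sort(c(a1, a2))
}

# -- allele depth tables -----------------------------------------------------

#' Construct an allele-depth table
#'
#' Wide per-locus counts for A, C, G, T and `other`, with a counting `mode`:
#' `"raw"` (all retained reads, PCR duplicates included) or `"umi"` (one
#' count per qualifying UMI consensus read).
#'
#' @param locus_id character vector.
#' @param counts numeric matrix/data.frame with columns A,C,G,T,other.
#' @param mode `"umi"` or `"raw"`.
#' @return an `allele_depths` data.frame with attribute `mode`.
#' @export
allele_depths <- function(locus_id, counts, mode = c("umi", "raw")) {
  mode <- match.arg(mode)
  counts <- as.data.frame(counts)
  for (a in .ALLELES) if (is.null(counts[[a]])) counts[[a]] <- 0L
  counts <- counts[.ALLELES]
  if (any(unlist(counts) < 0)) stop("negative allele count", call. = FALSE)
  df <- data.frame(locus_id = as.character(locus_id), counts,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (a in .ALLELES) df[[a]] <- as.integer(df[[a]])
  attr(df, "mode") <- mode
  class(df) <- c("allele_depths", "data.frame")
  df
}

#' Total depth per locus of a depth table
#' @param depths an `allele_depths` table.
#' @return integer vector of per-locus totals.
#' @export
total_depth <- function(depths) {
  as.integer(rowSums(as.matrix(as.data.frame(depths)[.ALLELES])))
}

#' Write an allele-depth table TSV
#' @param depths an `allele_depths` table.
#' @param path output path.
#' @export
write_depths <- function(depths, path) {
  df <- as.data.frame(depths)
  df$mode <- attr(depths, "mode")
  df$total <- total_depth(depths)
  .write_tsv(df[c("locus_id", "mode", .ALLELES, "total")], path)
}

#' Read an allele-depth table written by [write_depths()]
#' @param path depth TSV.
#' @return an `allele_depths` table.
#' @export
read_depths <- function(path) {
  df <- .parse_tsv(path, required = c("locus_id", "mode", .ALLELES))
  for (a in .ALLELES) df[[a]] <- as.integer(df[[a]])
  allele_depths(df$locus_id, df[.ALLELES], mode = df$mode[1L])
}

# -- VCF output --------------------------------------------------------------

#' Write calls as a minimal VCF v4.2
#'
#' Emits CHROM/POS/ID/REF/ALT with FORMAT `GT:AD:DP` for a single sample.
#' No-calls are written as `./.`; hemizygous calls as a single allele. A
#' called allele outside the panel's ref/alt pair is demoted to a no-call
#' with a warning. Records are sorted by (chrom, pos); `DP` equals the sum
#' of `AD` at every record.
#'
#' @param genotypes a `genotype_table`.
#' @param depths an `allele_depths` table covering the genotype loci (may be
#'   `NULL`: AD/DP reported as 0).
#' @param panel a `snp_panel`; every genotype locus must be present.
#' @param path output path.
#' @param sample_name sample column header.
#' @export
write_vcf <- function(genotypes, depths, panel, path, sample_name = "SAMPLE") {
  panel <- as_panel(panel)
  miss <- setdiff(genotypes$locus_id, panel$locus_id)
  if (length(miss))
    stop("genotype locus not in panel: ", miss[1L], call. = FALSE)
  i <- match(genotypes$locus_id, panel$locus_id)
  ref <- panel$ref[i]; alt <- panel$alt[i]
  if (is.null(depths)) {
    ad_ref <- ad_alt <- integer(nrow(genotypes))
  } else {
    dd <- as.data.frame(depths)
    j <- match(genotypes$locus_id, dd$locus_id)
    m <- as.matrix(dd[.ALLELES])
    ad_ref <- ifelse(is.na(j), 0L, m[cbind(j, match(ref, .ALLELES))])
    ad_alt <- ifelse(is.na(j), 0L, m[cbind(j, match(alt, .ALLELES))])
    ad_ref[is.na(ad_ref)] <- 0L; ad_alt[is.na(ad_alt)] <- 0L
  }
  code <- function(a, ref, alt) ifelse(a == ref, "0", "1")
  gt <- character(nrow(genotypes))
  for (k in seq_len(nrow(genotypes))) {
    a1 <- genotypes$a1[k]; a2 <- genotypes$a2[k]
    if (is.na(a1)) { gt[k] <- "./."; next }
    onpanel <- a1 %in% c(ref[k], alt[k]) &&
      (is.na(a2) || a2 %in% c(ref[k], alt[k]))
    if (!onpanel) {
      warning("allele outside ref/alt at ", genotypes$locus_id[k],
              "; written as no-call")
      gt[k] <- "./."
      next
    }
    gt[k] <- if (is.na(a2)) code(a1, ref[k], alt[k]) else
      paste(sort(c(code(a1, ref[k], alt[k]), code(a2, ref[k], alt[k]))),
            collapse = "/")
  }
  dp <- ad_ref + ad_alt
  rec <- data.frame(CHROM = panel$chrom[i], POS = panel$pos[i],
                    ID = genotypes$locus_id, REF = ref, ALT = alt,
                    QUAL = ".", FILTER = ".", INFO = ".",
                    FORMAT = "GT:AD:DP",
                    S = paste0(gt, ":", ad_ref, ",", ad_alt, ":", dp),
                    stringsAsFactors = FALSE)
  rec <- rec[order(.chrom_rank(rec$CHROM), rec$POS), ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=umisnp",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth over ref and alt\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(rec))
    writeLines(do.call(paste, c(rec, sep = "\t")), con)
  invisible(path)
}
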