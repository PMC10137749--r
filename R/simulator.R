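# Molecule-level simulator of a UMI-tagged multiplex PCR sequencing assay:
# genotypes (HWE or pedigree gene drop), template molecules sampled from DNA
# input mass, UMI ligation, branching PCR with substitution errors, read
# sampling with sequencing errors, and two-person mixtures.

#' Simulation configuration
#'
#' @param input_mass_pg DNA input in picograms.
#' @param pg_per_haploid_genome mass of one haploid genome copy (3.3 pg).
#' @param library_efficiency fraction of input molecules converted into
#'   amplifiable, UMI-tagged library molecules. Ligation-based preps convert
#'   a minority of molecules; this drives allele drop-out at low input.
#' @param capture_bias_sigma lognormal sd of the per-locus template-capture
#'   weight (locus-to-locus variation in conversion/primer efficiency).
#' @param umi_length UMI length in nt (4^length tag space; max 15).
#' @param pcr_cycles_total total amplification cycles (target enrichment +
#'   universal PCR).
#' @param explicit_error_cycles early cycles simulated as an explicit
#'   branching process, where substitution errors can take over a UMI family;
#'   later cycles expand all lineages deterministically.
#' @param pcr_efficiency per-cycle duplication probability.
#' @param pcr_error_rate per-base, per-duplication substitution probability.
#' @param seq_error_rate per-base sequencing error probability.
#' @param reads_target total reads sequenced for the sample.
#' @param locus_bias_sigma lognormal sd of the per-locus amplification
#'   weight.
#' @param quality_mean,quality_sd Phred base-quality distribution at the SNP
#'   site (normal, rounded, truncated to 0..41).
#' @param seed master seed; all stages derive deterministic substreams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(input_mass_pg = 1000,
                       pg_per_haploid_genome = 3.3,
                       library_efficiency = 0.3,
                       capture_bias_sigma = 0.7,
                       umi_length = 12,
                       pcr_cycles_total = 25,
                       explicit_error_cycles = 8,
                       pcr_efficiency = 0.9,
                       pcr_error_rate = 1e-5,
                       seq_error_rate = 1e-3,
                       reads_target = 1.5e6,
                       locus_bias_sigma = 0.3,
                       quality_mean = 30,
                       quality_sd = 6,
                       seed = 1) {
  cfg <- list(input_mass_pg = input_mass_pg,
              pg_per_haploid_genome = pg_per_haploid_genome,
              library_efficiency = library_efficiency,
              capture_bias_sigma = capture_bias_sigma,
              umi_length = as.integer(umi_length),
              pcr_cycles_total = as.integer(pcr_cycles_total),
              explicit_error_cycles = as.integer(explicit_error_cycles),
              pcr_efficiency = pcr_efficiency,
              pcr_error_rate = pcr_error_rate,
              seq_error_rate = seq_error_rate,
              reads_target = as.integer(reads_target),
              locus_bias_sigma = locus_bias_sigma,
              quality_mean = quality_mean,
              quality_sd = quality_sd,
              seed = as.integer(seed))
  stopifnot(cfg$input_mass_pg > 0, cfg$pg_per_haploid_genome > 0,
            cfg$library_efficiency > 0, cfg$library_efficiency <= 1,
            cfg$capture_bias_sigma >= 0, cfg$locus_bias_sigma >= 0,
            cfg$umi_length >= 1, cfg$umi_length <= 15,
            cfg$explicit_error_cycles <= cfg$pcr_cycles_total,
            cfg$pcr_efficiency > 0, cfg$pcr_efficiency <= 1,
            cfg$pcr_error_rate >= 0, cfg$pcr_error_rate <= 1,
            cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# integer UMI code (0-based, < 4^L) -> nucleotide string
.umi_string <- function(code, L) {
  n <- length(code)
  if (!n) return(character(0))
  cols <- vector("list", L)
  c0 <- as.double(code)
  for (j in L:1) {
    cols[[j]] <- .BASES[(c0 %% 4) + 1]
    c0 <- c0 %/% 4
  }
  do.call(paste0, cols)
}

# substitute a base: r in 1..3 selects one of the three other bases
.mutate_base <- function(allele, r) {
  ((allele - 1L + r) %% 4L) + 1L
}

#' Sample one individual's genotypes under Hardy-Weinberg equilibrium
#'
#' Autosomal (and female X) genotypes are drawn with probabilities p^2, 2pq,
#' q^2; Y (and male X) loci get a single allele with the haploid frequency.
#' Y loci of females are reported as `not_typed`.
#'
#' @param freqs `freq_table` or named frequency vector covering the panel.
#' @param panel a `snp_panel`.
#' @param sex `"female"` or `"male"`.
#' @param seed integer seed.
#' @param population population column when `freqs` is a multi-population
#'   table.
#' @return a truth `genotype_table` in panel order.
#' @export
sample_individual <- function(freqs, panel, sex = c("female", "male"),
                              seed = 1, population = NULL) {
  sex <- match.arg(sex)
  panel <- as_panel(panel)
  q <- freq_vector(freqs, population = population, loci = panel$locus_id)
  set.seed(.substream(seed, 1))
  n <- nrow(panel)
  hemi <- .is_hemizygous(panel, sex)
  a1 <- a2 <- rep(NA_character_, n)
  status <- rep("called", n)
  dip <- !hemi
  d <- rbinom(sum(dip), 2L, q[dip])          # alt-allele dosage under HWE
  a1[dip] <- ifelse(d >= 1L, panel$alt[dip], panel$ref[dip])
  a2[dip] <- ifelse(d == 2L, panel$alt[dip], panel$ref[dip])
  if (any(hemi)) {
    if (sex == "female") {
      drop <- hemi & panel$category == "Y"
      status[drop] <- "not_typed"
      hx <- hemi & !drop                      # (nothing: female X is diploid)
      if (any(hx)) {
        h <- rbinom(sum(hx), 1L, q[hx])
        a1[hx] <- ifelse(h == 1L, panel$alt[hx], panel$ref[hx])
      }
    } else {
      h <- rbinom(sum(hemi), 1L, q[hemi])
      a1[hemi] <- ifelse(h == 1L, panel$alt[hemi], panel$ref[hemi])
    }
  }
  genotype_table(panel$locus_id, a1, a2, status)
}

# -- pedigrees and gene dropping --------------------------------------------

#' Define a pedigree
#'
#' @param id member identifiers.
#' @param father,mother parent ids (`NA` for founders; non-founders need
#'   both parents).
#' @param sex `"male"`/`"female"` per member.
#' @return a `pedigree` data.frame in generation order.
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "female") {
  df <- data.frame(id = as.character(id),
                   father = as.character(father),
                   mother = as.character(mother),
                   sex = rep_len(as.character(sex), length(id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicated pedigree id", call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be male or female", call. = FALSE)
  one <- xor(is.na(df$father), is.na(df$mother))
  if (any(one))
    stop("non-founders need both parents: ", df$id[one][1L], call. = FALSE)
  for (p in c("father", "mother")) {
    known <- !is.na(df[[p]])
    if (!all(df[[p]][known] %in% df$id))
      stop("unknown parent id in pedigree", call. = FALSE)
    want <- if (p == "father") "male" else "female"
    psex <- df$sex[match(df[[p]][known], df$id)]
    if (!all(psex == want))
      stop("parent sex mismatch in pedigree", call. = FALSE)
  }
  # topological order; also rejects cycles
  placed <- character(0)
  order_ids <- character(0)
  remaining <- df$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- df[df$id == i, ]
      is.na(r$father) || (r$father %in% placed && r$mother %in% placed)
    }, logical(1))
    if (!any(ready)) stop("pedigree contains a cycle", call. = FALSE)
    order_ids <- c(order_ids, remaining[ready])
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  df <- df[match(order_ids, df$id), ]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

# recombination fractions between adjacent loci (Haldane); 0.5 across
# chromosome boundaries and everywhere when no map is given
.recomb_fractions <- function(panel, map = NULL) {
  n <- nrow(panel)
  if (n <= 1L) return(numeric(0))
  if (is.null(map)) return(rep(0.5, n - 1L))
  i <- match(panel$locus_id, map$locus_id)
  if (anyNA(i)) stop("genetic map does not cover locus ",
                     panel$locus_id[which(is.na(i))[1L]], call. = FALSE)
  cm <- map$cm[i]
  same <- panel$chrom[-1L] == panel$chrom[-n]
  d <- cm[-1L] - cm[-n]
  if (any(same & d < 0)) stop("map positions decrease along chromosome",
                              call. = FALSE)
  r <- 0.5 * (1 - exp(-2 * d / 100))
  r[!same] <- 0.5
  r
}

# one meiosis: transmit one allele per locus from a phased pair, with a
# Markov crossover pattern given adjacent recombination fractions
.meiosis <- function(h1, h2, r) {
  L <- length(h1)
  start <- runif(1) < 0.5
  if (L > 1L) {
    sw <- runif(L - 1L) < r
    pat <- cumsum(c(start, sw)) %% 2
  } else pat <- as.numeric(start)
  ifelse(pat == 0, h1, h2)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders are sampled phased under HWE; each meiosis transmits one allele
#' per locus. With a genetic map, transmission follows a Haldane crossover
#' process along each chromosome (recombination fraction
#' r = (1 - exp(-2d/100))/2 for adjacent map distance d cM); without a map,
#' loci segregate independently. Autosomal loci only.
#'
#' @param ped a [pedigree()].
#' @param freqs frequency table or named vector.
#' @param panel a `snp_panel`.
#' @param map optional `genetic_map`.
#' @param seed integer seed.
#' @param population optional population column of `freqs`.
#' @return named list of truth `genotype_table`s, one per member, over the
#'   autosomal panel loci sorted by (chrom, pos).
#' @export
gene_drop <- function(ped, freqs, panel, map = NULL, seed = 1,
                      population = NULL) {
  if (!inherits(ped, "pedigree")) stop("ped must be a pedigree",
                                       call. = FALSE)
  panel <- as_panel(panel)
  panel <- panel[!panel$category %in% c("X", "Y"), ]
  panel <- panel[order(.chrom_rank(panel$chrom), panel$pos), ]
  q <- freq_vector(freqs, population = population, loci = panel$locus_id)
  r <- .recomb_fractions(panel, map)
  set.seed(.substream(seed, 2))
  L <- nrow(panel)
  haps <- list()   # per member: list(h1, h2) of 0/1 alt indicators
  for (k in seq_len(nrow(ped))) {
    m <- ped[k, ]
    if (is.na(m$father)) {
      haps[[m$id]] <- list(h1 = as.integer(runif(L) < q),
                           h2 = as.integer(runif(L) < q))
    } else {
      f <- haps[[m$father]]; mo <- haps[[m$mother]]
      haps[[m$id]] <- list(h1 = .meiosis(f$h1, f$h2, r),
                           h2 = .meiosis(mo$h1, mo$h2, r))
    }
  }
  lapply(haps, function(h) {
    d <- h$h1 + h$h2
    genotype_table(panel$locus_id,
                   ifelse(d >= 1L, panel$alt, panel$ref),
                   ifelse(d == 2L, panel$alt, panel$ref))
  })
}

# -- template molecules ------------------------------------------------------

#' Sample UMI-tagged template molecules from a genotype
#'
#' Each allele copy of a diploid locus contributes
#' Poisson(eff * mass / (2 * pg_per_haploid) * capture) library molecules,
#' where `eff` is the library conversion efficiency and `capture` a per-locus
#' lognormal weight (mean 1) shared by all contributors under one
#' configuration. Hemizygous loci contribute one such Poisson count in total.
#' Every molecule receives an independent uniform-random UMI.
#'
#' @param genotype a truth `genotype_table` (panel order).
#' @param panel a `snp_panel`.
#' @param config a [sim_config()].
#' @param seed seed for the template draws (defaults to a substream of
#'   `config$seed`); the capture-bias weights always derive from
#'   `config$seed` so mixtures share them.
#' @param mass_pg override of `config$input_mass_pg` (used for mixture
#'   proportions).
#' @param contributor integer label stored with each molecule.
#' @return a `template_set` data.table (`locus`, `allele`, `umi`,
#'   `contributor`) with the panel as attribute.
#' @export
sample_templates <- function(genotype, panel, config,
                             seed = .substream(config$seed, 202),
                             mass_pg = config$input_mass_pg,
                             contributor = 1L) {
  panel <- as_panel(panel)
  stopifnot(mass_pg > 0)
  i <- match(panel$locus_id, genotype$locus_id)
  if (anyNA(i)) stop("genotype does not cover panel", call. = FALSE)
  gt <- genotype[i, ]
  n <- nrow(panel)
  set.seed(.substream(config$seed, 201))
  capture <- if (config$capture_bias_sigma > 0)
    stats::rlnorm(n, -config$capture_bias_sigma^2 / 2,
                  config$capture_bias_sigma) else rep(1, n)
  lam <- config$library_efficiency * mass_pg /
    (2 * config$pg_per_haploid_genome) * capture
  set.seed(seed)
  a1 <- match(gt$a1, .BASES)
  a2 <- match(gt$a2, .BASES)
  copy_locus <- c(which(!is.na(a1)), which(!is.na(a2)))
  copy_allele <- c(a1[!is.na(a1)], a2[!is.na(a2)])
  k <- rpois(length(copy_locus), lam[copy_locus])
  locus <- rep.int(copy_locus, k)
  allele <- rep.int(copy_allele, k)
  m <- length(locus)
  umi <- as.double(sample.int(4^config$umi_length, m, replace = TRUE)) - 1
  ts <- data.table::data.table(locus = locus, allele = allele, umi = umi,
                               contributor = rep(as.integer(contributor), m))
  data.table::setattr(ts, "panel", panel)
  data.table::setattr(ts, "class", c("template_set", class(ts)))
  ts
}

#' Pool template molecules of a DNA mixture
#'
#' Contributor i's template means are scaled by `proportions[i]` of the
#' configured input mass; downstream amplification and sequencing are
#' identical to the single-source path.
#'
#' @param genotypes list of truth `genotype_table`s, one per contributor.
#' @param proportions positive reals summing to 1 (tolerance 1e-9).
#' @param panel a `snp_panel`.
#' @param config a [sim_config()].
#' @return a pooled `template_set` with per-molecule contributor labels.
#' @export
make_mixture <- function(genotypes, proportions, panel, config) {
  if (length(genotypes) != length(proportions))
    stop("one proportion per contributor", call. = FALSE)
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be positive and sum to 1", call. = FALSE)
  parts <- lapply(seq_along(genotypes), function(i) {
    sample_templates(genotypes[[i]], panel, config,
                     seed = .substream(config$seed, 210 + i),
                     mass_pg = config$input_mass_pg * proportions[i],
                     contributor = i)
  })
  ts <- data.table::rbindlist(parts)
  data.table::setattr(ts, "panel", as_panel(attr(parts[[1L]], "panel")))
  data.table::setattr(ts, "class", c("template_set", class(ts)))
  ts
}

# -- PCR amplification and sequencing ---------------------------------------

#' Amplify templates and sample sequencing reads
#'
#' Two-phase PCR model. (i) For `explicit_error_cycles` cycles each molecule
#' duplicates with probability `pcr_efficiency`; each duplication copies the
#' SNP base with substitution probability `pcr_error_rate` (uniform over the
#' three other bases) and a substituted copy founds its own lineage within
#' the UMI family. (ii) Remaining cycles expand every lineage by the common
#' deterministic factor (1 + efficiency)^(total - explicit); a per-locus
#' lognormal amplification weight multiplies the lineage weights.
#' `reads_target` reads are then drawn multinomially over lineages; each
#' read inherits its lineage's base, suffers an independent sequencing error
#' with probability `seq_error_rate`, receives a Phred quality from the
#' configured distribution, and carries its template's UMI.
#'
#' @param templates a `template_set`.
#' @param config a [sim_config()].
#' @param seed read-sampling substream seed (default derived from
#'   `config$seed`).
#' @return a `data.table` of reads: `locus_id`, `allele`, `umi`, `qual`,
#'   plus ground truth per read (`template`, `true_allele`, `contributor`).
#' @export
amplify_and_sequence <- function(templates, config,
                                 seed = .substream(config$seed, 203)) {
  panel <- attr(templates, "panel")
  n <- nrow(templates)
  if (!n) stop("no template molecules to amplify", call. = FALSE)
  if (config$reads_target <= 0L) stop("reads_target must be positive",
                                      call. = FALSE)
  set.seed(.substream(config$seed, 204))
  nl <- nrow(panel)
  amp_bias <- if (config$locus_bias_sigma > 0)
    stats::rlnorm(nl, -config$locus_bias_sigma^2 / 2,
                  config$locus_bias_sigma) else rep(1, nl)
  set.seed(seed)
  E <- config$explicit_error_cycles
  eff <- config$pcr_efficiency
  rate <- config$pcr_error_rate
  N <- rep(1L, n)                    # unmutated lineage size per template
  ev_parent <- integer(0); ev_cycle <- integer(0); ev_size <- integer(0)
  ev_base <- integer(0)
  for (k in seq_len(E)) {
    d <- rbinom(n, N, eff)
    if (rate > 0) {
      mut <- rbinom(n, d, rate)
      idx <- which(mut > 0L)
      if (length(idx)) {
        # each substituted copy founds a lineage; further errors within a
        # mutant lineage are second order and ignored
        reps <- mut[idx]
        ev_parent <- c(ev_parent, rep.int(idx, reps))
        ev_cycle <- c(ev_cycle, rep.int(rep(k, length(idx)), reps))
        ev_size <- c(ev_size, rep.int(1L, sum(reps)))
        ev_base <- c(ev_base,
                     .mutate_base(rep.int(templates$allele[idx], reps),
                                  sample.int(3L, sum(reps), replace = TRUE)))
        d <- d - mut
      }
      N <- N + d
    } else {
      N <- N + d
    }
    if (length(ev_size)) {
      act <- ev_cycle < k
      if (any(act))
        ev_size[act] <- ev_size[act] + rbinom(sum(act), ev_size[act], eff)
    }
  }
  # lineages: unmutated families first, then mutant lineages
  g_locus <- c(templates$locus, templates$locus[ev_parent])
  g_allele <- c(templates$allele, ev_base)
  g_true <- c(templates$allele, templates$allele[ev_parent])
  g_umi <- c(templates$umi, templates$umi[ev_parent])
  g_tid <- c(seq_len(n), ev_parent)
  g_contrib <- c(templates$contributor, templates$contributor[ev_parent])
  # the deterministic late-cycle factor (1+eff)^(total-E) is common to all
  # lineages and cancels in the multinomial; locus amplification bias does not
  w <- as.double(c(N, ev_size)) * amp_bias[g_locus]
  if (sum(w) <= 0) stop("no amplifiable lineage", call. = FALSE)
  cnt <- rmultinom(1L, config$reads_target, w)[, 1L]
  ri <- rep.int(seq_along(cnt), cnt)
  nr <- length(ri)
  allele <- g_allele[ri]
  err <- runif(nr) < config$seq_error_rate
  if (any(err))
    allele[err] <- .mutate_base(allele[err],
                                sample.int(3L, sum(err), replace = TRUE))
  qual <- as.integer(pmin(41, pmax(0, round(rnorm(nr, config$quality_mean,
                                                  config$quality_sd)))))
  codes <- g_umi[ri]
  uc <- unique(codes)
  umi <- .umi_string(uc, config$umi_length)[match(codes, uc)]
  data.table::data.table(
    locus_id = panel$locus_id[g_locus[ri]],
    allele = .ALLELES[allele],
    umi = umi,
    qual = qual,
    template = g_tid[ri],
    true_allele = .ALLELES[g_true[ri]],
    contributor = g_contrib[ri])
}

#' Simulate reads for one genotype (convenience wrapper)
#'
#' @param genotype truth `genotype_table`.
#' @param panel a `snp_panel`.
#' @param config a [sim_config()].
#' @return read `data.table` (see [amplify_and_sequence()]).
#' @export
simulate_reads <- function(genotype, panel, config) {
  ts <- sample_templates(genotype, panel, config)
  amplify_and_sequence(ts, config)
}
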