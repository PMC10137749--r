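# End-to-end study designs: the dilution-series UMI-vs-raw comparison and
# the two-person mixture detection / deconvolution experiment.

# rebuild a sim_config with some fields replaced (revalidates)
.update_config <- function(config, ...) {
  args <- utils::modifyList(unclass(config), list(...))
  do.call(sim_config, args)
}

#' Dilution-series comparison of UMI and raw-read genotyping
#'
#' Simulates one individual sequenced at a series of DNA input amounts with
#' replicates, calls genotypes from UMI-consensus depths at the given
#' thresholds, and for each sample finds the raw-read coverage thresholds
#' that match the UMI call rate and the UMI error rate (the two ways of
#' making the with/without-UMI workflows comparable on the same reads).
#'
#' @param panel a `snp_panel`.
#' @param freqs population frequencies covering the panel.
#' @param amounts_ng DNA input amounts in nanograms.
#' @param n_replicates replicates per amount.
#' @param config base [sim_config()]; mass and seed are set per sample.
#' @param thresholds a [call_thresholds()] for the UMI workflow (ARF and
#'   quality bounds are shared with the raw workflow).
#' @param sex simulated individual's sex.
#' @param seed master seed.
#' @param population optional population column of `freqs`.
#' @return `umi_comparison` list: `table` (one row per sample with UMI and
#'   matched raw metrics), `truth`, `amounts_ng`.
#' @export
dilution_experiment <- function(panel, freqs,
                                amounts_ng = c(10, 1, 0.5, 0.25, 0.125, 0.06),
                                n_replicates = 3,
                                config = sim_config(),
                                thresholds = call_thresholds(),
                                sex = "male", seed = 1,
                                population = NULL) {
  panel <- as_panel(panel)
  truth <- sample_individual(freqs, panel, sex, seed = .substream(seed, 11),
                             population = population)
  rows <- list()
  for (a in seq_along(amounts_ng)) {
    for (rep_i in seq_len(n_replicates)) {
      cfg <- .update_config(config,
                            input_mass_pg = amounts_ng[a] * 1000,
                            seed = .substream(seed, 1000 + a * 37 + rep_i))
      reads <- simulate_reads(truth, panel, cfg)
      umi_d <- tabulate_depths(reads, "umi",
                               quality_threshold = thresholds$min_quality,
                               panel = panel)
      raw_d <- tabulate_depths(reads, "raw",
                               quality_threshold = thresholds$min_quality,
                               panel = panel)
      umi_calls <- call_genotypes(umi_d, panel, thresholds, sex)
      umi_rep <- concordance(umi_calls, truth)
      mcr <- match_call_rate(raw_d, umi_rep, thresholds, truth, panel, sex)
      mer <- match_error_rate(raw_d, umi_rep, thresholds, truth, panel, sex)
      rows[[length(rows) + 1L]] <- data.frame(
        amount_ng = amounts_ng[a], replicate = rep_i,
        umi_call_rate = umi_rep$call_rate,
        umi_accuracy = umi_rep$accuracy,
        umi_error = 1 - umi_rep$accuracy,
        umi_dropout = umi_rep$n_dropout, umi_dropin = umi_rep$n_dropin,
        raw_threshold_cr = mcr$threshold,
        raw_call_rate_cr = mcr$report$call_rate,
        raw_accuracy_cr = mcr$report$accuracy,
        raw_dropout_cr = mcr$report$n_dropout,
        raw_dropin_cr = mcr$report$n_dropin,
        raw_threshold_err = mer$threshold,
        raw_call_rate_err = mer$report$call_rate,
        raw_error_err = 1 - mer$report$accuracy)
    }
  }
  structure(list(table = do.call(rbind, rows), truth = truth,
                 amounts_ng = amounts_ng),
            class = "umi_comparison")
}

#' @export
print.umi_comparison <- function(x, ...) {
  agg <- stats::aggregate(
    x$table[c("umi_call_rate", "umi_accuracy", "raw_accuracy_cr",
              "raw_call_rate_err")],
    by = list(amount_ng = x$table$amount_ng), FUN = mean)
  cat("UMI vs raw-read genotyping across the dilution series (replicate means):\n")
  print(format(agg, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Two-person mixture detection and deconvolution experiment
#'
#' Simulates a single-source reference and two-person mixtures at the given
#' major:minor ratios from a shared pair of individuals, computes the
#' heterozygosity-rate mixture-detection statistic for each sample, and
#' deconvolves the balanced (1:1) mixture assuming the major contributor's
#' genotypes are known. Autosomal panel loci only.
#'
#' @param panel a `snp_panel` (X/Y markers are dropped internally).
#' @param freqs population frequencies.
#' @param ratios major:minor ratios as the vector of majors (1 = balanced).
#' @param config base [sim_config()] (mass = total mixture input).
#' @param thresholds calling thresholds for detection-stage calls.
#' @param seed master seed.
#' @param population optional population column.
#' @return `mixture_experiment` list: `single` (reference detection),
#'   `mixtures` (per ratio: detection + depths), `deconvolution` (result +
#'   concordance vs the minor contributor, for ratio 1), `truth_major`,
#'   `truth_minor`.
#' @export
mixture_experiment <- function(panel, freqs, ratios = c(1, 10, 50, 100),
                               config = sim_config(input_mass_pg = 10000,
                                                   reads_target = 2e6),
                               thresholds = call_thresholds(),
                               seed = 1, population = NULL) {
  panel <- as_panel(panel)
  panel <- panel[!panel$category %in% c("X", "Y"), ]
  truth_major <- sample_individual(freqs, panel, "female",
                                   seed = .substream(seed, 21),
                                   population = population)
  truth_minor <- sample_individual(freqs, panel, "female",
                                   seed = .substream(seed, 22),
                                   population = population)
  run_sample <- function(templates, stage) {
    cfg <- .update_config(config, seed = .substream(seed, stage))
    reads <- amplify_and_sequence(templates, cfg)
    umi_d <- tabulate_depths(reads, "umi",
                             quality_threshold = thresholds$min_quality,
                             panel = panel)
    calls <- call_genotypes(umi_d, panel, thresholds, "female")
    list(depths = umi_d, calls = calls,
         detection = detect_mixture(calls, freqs, panel,
                                    population = population))
  }
  cfg0 <- .update_config(config, seed = .substream(seed, 30))
  single <- run_sample(sample_templates(truth_major, panel, cfg0), 50)
  mixtures <- list()
  deconv <- NULL
  for (i in seq_along(ratios)) {
    rho <- ratios[i]
    cfg <- .update_config(config, seed = .substream(seed, 60 + i))
    ts <- make_mixture(list(truth_major, truth_minor),
                       c(rho, 1) / (rho + 1), panel, cfg)
    mx <- run_sample(ts, 80 + i)
    mx$ratio <- rho
    mixtures[[paste0("1:", rho)]] <- mx
    if (rho == 1) {
      dec <- deconvolve(mx$depths, truth_major, proportion = 0.5,
                        panel = panel)
      deconv <- list(result = dec,
                     report = concordance(dec$calls, truth_minor))
    }
  }
  structure(list(single = single, mixtures = mixtures,
                 deconvolution = deconv,
                 truth_major = truth_major, truth_minor = truth_minor),
            class = "mixture_experiment")
}

#' @export
print.mixture_experiment <- function(x, ...) {
  cat(sprintf("single source: z = %.2f\n", x$single$detection$z))
  for (nm in names(x$mixtures)) {
    d <- x$mixtures[[nm]]$detection
    cat(sprintf("mixture %s: heterozygosity %.4f, z = %.2f -> %s\n", nm,
                d$observed, d$z, if (d$flag) "flagged" else "not flagged"))
  }
  if (!is.null(x$deconvolution)) {
    r <- x$deconvolution$report
    cat(sprintf("1:1 deconvolution: call rate %.3f, accuracy %.4f\n",
                r$call_rate, r$accuracy))
  }
  invisible(x)
}
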