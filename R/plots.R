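# Optional figures (ggplot2 in Suggests).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' ARF density plot for mixture detection
#'
#' Density of per-locus allele read frequencies, one curve per sample;
#' a balanced mixture concentrates mass near 0.5 while a single source
#' splits into heterozygote (~0.5) and homozygote (~1.0) modes.
#'
#' @param depths_list named list of `allele_depths` tables.
#' @return a ggplot object.
#' @export
plot_arf_density <- function(depths_list) {
  .need_ggplot()
  df <- do.call(rbind, lapply(names(depths_list), function(nm) {
    data.frame(sample = nm, arf = unname(arf_distribution(depths_list[[nm]])))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = arf, colour = sample)) +
    ggplot2::geom_density() +
    ggplot2::xlim(0.5, 1) +
    ggplot2::labs(x = "allele read frequency", y = "density")
}

#' Dilution-series comparison plot
#'
#' Replicate-mean UMI and raw metrics against DNA input amount:
#' genotype accuracy at matched call rates, or call rate at matched error
#' rates.
#'
#' @param comparison a `umi_comparison` from [dilution_experiment()].
#' @param metric `"accuracy"` or `"call_rate"`.
#' @return a ggplot object.
#' @export
plot_dilution <- function(comparison, metric = c("accuracy", "call_rate")) {
  .need_ggplot()
  metric <- match.arg(metric)
  tb <- comparison$table
  cols <- if (metric == "accuracy") c("umi_accuracy", "raw_accuracy_cr")
          else c("umi_call_rate", "raw_call_rate_err")
  agg <- stats::aggregate(tb[cols], by = list(amount_ng = tb$amount_ng),
                          FUN = mean)
  df <- rbind(
    data.frame(amount_ng = agg$amount_ng, workflow = "UMI",
               value = agg[[cols[1L]]]),
    data.frame(amount_ng = agg$amount_ng, workflow = "raw",
               value = agg[[cols[2L]]]))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(amount_ng), y = value,
                                   group = workflow, colour = workflow)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "DNA input (ng)",
                  y = if (metric == "accuracy") "genotype accuracy"
                      else "call rate")
}

#' Kinship LR density plot
#'
#' H1-true and H2-true log10 LR distributions of a pairwise simulation,
#' with the LR = 1 decision line.
#'
#' @param sim a `pairwise_sim` from [simulate_pairwise()].
#' @return a ggplot object.
#' @export
plot_lr_densities <- function(sim) {
  .need_ggplot()
  df <- rbind(data.frame(hypothesis = "H1 true", log10_lr = sim$log10_lr_h1),
              data.frame(hypothesis = "H2 true", log10_lr = sim$log10_lr_h2))
  ggplot2::ggplot(df, ggplot2::aes(x = log10_lr, fill = hypothesis)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log10 LR", y = "density", title = sim$rel$name)
}
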