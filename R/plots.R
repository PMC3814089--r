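#' Plot separation fidelity (CCC) against the sweep condition
#'
#' Mean CCC per compartment with the minimum-to-maximum band over
#' realizations, against the noise multiplier or the DCE error level.
#'
#' @param results A `"study_result"` from [run_noise_sweep()] or
#'   [run_dce_error_sweep()].
#' @return A ggplot object.
#' @export
plot_ccc_sweep <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  xvar <- intersect(c("noise_multiplier", "dce_error_pct"), names(results))[1]
  d <- sweep_summary(results, c("ccc_cb", "ccc_cees", "ccc_ceis"), xvar,
                     mode = "minmax")
  d$compartment <- factor(d$metric, levels = c("ccc_cb", "ccc_cees", "ccc_ceis"),
                          labels = c("Cb", "C_EES", "C_EIS"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[["x"]], y = .data[["mean"]],
                                  colour = .data[["compartment"]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[["lo"]],
                                          ymax = .data[["hi"]]),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = if (xvar == "noise_multiplier") "noise multiplier"
                      else "DCE parameter error (% 95% CI)",
                  y = "CCC (mean, min-max)") +
    ggplot2::theme_minimal()
}

#' Plot fitted-parameter error against the sweep condition
#'
#' Mean per-parameter relative error with +/- one standard error, against
#' the noise multiplier or the DCE error level.
#'
#' @param results A `"study_result"` with fitted parameters.
#' @return A ggplot object.
#' @export
plot_error_sweep <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  xvar <- intersect(c("noise_multiplier", "dce_error_pct"), names(results))[1]
  cols <- c("err_K1_pct", "err_k2_pct", "err_k3_pct", "err_k4_pct")
  if (all(is.na(results[cols]))) {
    stop("no fitted parameters in this result table (config$fit was FALSE)",
         call. = FALSE)
  }
  d <- sweep_summary(results, cols, xvar, mode = "se")
  d$parameter <- factor(d$metric, levels = cols,
                        labels = c("K1", "k2", "k3", "k4"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[["x"]], y = .data[["mean"]],
                                  colour = .data[["parameter"]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[["lo"]],
                                          ymax = .data[["hi"]]),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = if (xvar == "noise_multiplier") "noise multiplier"
                      else "DCE parameter error (% 95% CI)",
                  y = "relative error (%, mean +/- SE)") +
    ggplot2::theme_minimal()
}

# long-format condition x metric summary used by both plots
sweep_summary <- function(results, metrics, xvar, mode) {
  conds <- sort(unique(results[[xvar]]))
  do.call(rbind, lapply(conds, function(cv) {
    sub <- results[results[[xvar]] == cv, ]
    do.call(rbind, lapply(metrics, function(m) {
      s <- summarize_values(sub[[m]][!is.na(sub[[m]])], mode = mode)
      data.frame(x = cv, metric = m, mean = s[["mean"]],
                 lo = s[["lo"]], hi = s[["hi"]])
    }))
  }))
}
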