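## Presentation helpers. All plots are diagnostics over quantities the
## package computes elsewhere; nothing downstream depends on them.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the raw tables",
         call. = FALSE)
  }
}

#' Plot PPV versus TPR (or FPR versus TPR) from a sweep summary
#'
#' @param sweep A `sweep_result`.
#' @param x,y Summary metric names (without the `mean_` prefix), e.g.
#'   `x = "TPR", y = "PPV"` or `x = "FPR", y = "TPR"`.
#' @return A ggplot object.
#' @export
plot_sweep_points <- function(sweep, x = "TPR", y = "PPV") {
  .need_ggplot()
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep$summary
  df$measure[is.na(df$measure)] <- "(none)"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[paste0("mean_", x)]], y = .data[[paste0("mean_", y)]],
    colour = .data$measure, shape = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("mean", x), y = paste("mean", y)) +
    ggplot2::theme_minimal()
}

#' Plot mean F1 against a sweep parameter
#'
#' @param sweep A `sweep_result`.
#' @param parameter One of `"k"`, `"rho"`, `"w"`, `"q"`.
#' @return A ggplot object.
#' @export
plot_f1_vs_parameter <- function(sweep, parameter = c("k", "rho", "w", "q")) {
  .need_ggplot()
  parameter <- match.arg(parameter)
  df <- sweep$summary[!is.na(sweep$summary[[parameter]]), ]
  if (nrow(df) == 0L) stop("no rows vary over ", parameter, call. = FALSE)
  df$measure[is.na(df$measure)] <- "(none)"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[parameter]], y = .data$mean_F1,
    colour = .data$measure, linetype = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "mean F1") +
    ggplot2::theme_minimal()
}

#' Plot same-peak versus different-peak score distributions
#'
#' Density view of [score_distributions()]: how well a similarity
#' measure separates true peak pairs from cross pairs.
#'
#' @param dist A list with `same` and `different` score vectors.
#' @param measure Label for the plot title.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(dist, measure = "") {
  .need_ggplot()
  df <- data.frame(
    score = c(dist$same, dist$different),
    group = rep(c("same peaks", "different peaks"),
                c(length(dist$same), length(dist$different))))
  df <- df[is.finite(df$score), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(title = measure) +
    ggplot2::theme_minimal()
}
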