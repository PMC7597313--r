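#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: the down-state probability of a two-level trajectory, the
#' mean-evidence curves of the four lattice models, the measured vs
#' unmeasured confidence distributions of an interference analysis, and the
#' log-likelihood profile of a weight fit.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name openwalk-plots
NULL

#' @rdname openwalk-plots
#' @export
autoplot.walk_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$p_down)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "p(down state)",
                  title = "Two-level open-system trajectory") +
    ggplot2::ylim(0, 1)
}

#' @rdname openwalk-plots
#' @export
autoplot.evidence_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$time, y = .data$mean_evidence,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$invariant_mean, linetype = 2) +
    ggplot2::labs(x = "time", y = "mean evidence",
                  title = "Mean evidence across time",
                  subtitle = "dashed: Markov invariant mean")
}

#' @rdname openwalk-plots
#' @export
autoplot.interference <- function(object, ...) {
  d <- tidyr::pivot_longer(object$distributions,
                           cols = c("p_measured", "p_unmeasured"),
                           names_to = "condition", values_to = "probability")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$confidence, y = .data$probability,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = sprintf("Interference statistic = %.4g",
                                  object$statistic),
                  x = "confidence outcome") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname openwalk-plots
#' @export
autoplot.weight_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$w, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$w_hat, linetype = 2) +
    ggplot2::labs(x = "mixing weight w", y = "log likelihood",
                  title = sprintf("w_hat = %.3f", object$w_hat))
}
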