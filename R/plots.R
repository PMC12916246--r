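#' Plot a capnometry trace with detected end-tidal values
#'
#' @param trace A [capno_trace()].
#' @param et Optional [etco2_series()] of detected breaths to overlay.
#' @param paradigm Optional [paradigm_spec()]; CO2 blocks are shaded.
#' @return A ggplot object.
#' @export
plot_capno_trace <- function(trace, et = NULL, paradigm = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$co2))
  if (!is.null(paradigm)) {
    co2 <- paradigm[paradigm$gas == "co2", ]
    p <- p + ggplot2::geom_rect(
      data = as_tibble(co2),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey85", alpha = 0.6
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3, colour = "steelblue")
  if (!is.null(et)) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(et),
      ggplot2::aes(x = .data$time, y = .data$etco2),
      colour = "firebrick", size = 1
    )
  }
  p + ggplot2::labs(x = "Time (s)", y = expression(CO[2] ~ "(mmHg)"),
                    title = "Capnometry trace")
}

#' @export
autoplot.cvr_fit <- function(object, ...) {
  d <- tibble(
    time = object$model$model$drift1 %||% seq_len(object$n),
    observed = object$model$model$y,
    fitted = stats::fitted(object$model)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Time (standardized)", y = "BOLD signal",
                  title = sprintf("CVR GLM fit (CVR = %.3f %%/mmHg)",
                                  cvr_from_fit(object)))
}

#' Forest plot of an association suite
#'
#' Betas with 95% confidence intervals per outcome, faceted by metric
#' family; filled points mark raw p < 0.05.
#'
#' @param object A `cvr_assoc_suite` from [run_association_suite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvr_assoc_suite <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(
      label = ifelse(is.na(.data$tract), .data$outcome, .data$tract),
      family = ifelse(is.na(.data$family), .data$domain, .data$family),
      significant = .data$p < 0.05
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::labs(x = expression(beta ~ "per (%/mmHg)"), y = NULL,
                  title = sprintf("CVR associations (%s)",
                                  unique(d$design)))
}
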