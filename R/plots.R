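# ggplot2 views of the reliability and density tradeoffs. Plotting is
# optional: ggplot2 is a suggested dependency.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

#' Plot decoder error probability versus strand length
#'
#' Log decoder error probability against strand length, one line per
#' curve (rows from one or more [system_error_curve()] calls can be
#' stacked; a `label` column distinguishes them). A horizontal reference
#' line marks a hard-drive-class reliability of 1e-14.
#'
#' @param curves Data frame from [system_error_curve()], optionally with
#'   a `label` column.
#' @param reference Reference reliability for the dashed line (default
#'   1e-14; NULL to omit).
#' @return A ggplot object.
#' @export
plot_error_curves <- function(curves, reference = 1e-14) {
  need_ggplot()
  if (is.null(curves$label)) {
    curves$label <- sprintf("c=%d, p_error=%g", curves$copies,
                            curves$p_error)
  }
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = length,
                                    y = log10_decoder_error,
                                    colour = label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "strand length (nt)",
                  y = "log10 decoder error probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_hline(yintercept = log10(reference),
                                 linetype = "dashed")
  }
  p
}

#' Plot a density sweep
#'
#' Two standard views of a [density_sweep()]: `"breakage"` draws density
#' against the per-nt breakage probability (log x axis, one line per
#' strand length); `"length"` draws density against strand length (one
#' line per breakage rate).
#'
#' @param sweep A [density_sweep()] result.
#' @param by `"breakage"` or `"length"`.
#' @return A ggplot object.
#' @export
plot_density_sweep <- function(sweep, by = c("breakage", "length")) {
  need_ggplot()
  by <- match.arg(by)
  df <- sweep[sweep$feasible, , drop = FALSE]
  if (by == "breakage") {
    ggplot2::ggplot(df, ggplot2::aes(x = breakage,
                                     y = density_bits_per_nt,
                                     colour = factor(length))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "strand breakage probability per nt",
                    y = "information density (bits/nt)",
                    colour = "length (nt)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = length,
                                     y = density_bits_per_nt,
                                     colour = factor(breakage))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "strand length (nt)",
                    y = "information density (bits/nt)",
                    colour = "breakage/nt") +
      ggplot2::theme_minimal()
  }
}
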