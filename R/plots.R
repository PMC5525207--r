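# ggplot2 views of the result tables. Values at integer positions are
# discrete; connecting lines are illustrative only.

#' Plot a positional profile
#'
#' One line per residue class over the inside(-) to outside(+) position
#' axis, optionally with horizontal background and flank-average guides.
#'
#' @param profile A long profile tibble (`residue`, `position`, `value`).
#' @param background Optional output of [background_level()] drawn as
#'   dashed guides.
#' @param flank_averages Optional output of [flank_average()] drawn as
#'   thick bars over the flank windows.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, background = NULL, flank_averages = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$position, y = .data$value, colour = .data$residue
  )) +
    ggplot2::geom_line(alpha = 0.9) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::labs(
      x = "position (negative = cytoplasmic side)",
      y = unique(profile$kind)[1], colour = "residue"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(background)) {
    p <- p + ggplot2::geom_hline(
      data = background,
      ggplot2::aes(yintercept = .data$background, colour = .data$residue),
      linetype = "dashed", alpha = 0.6
    )
  }
  if (!is.null(flank_averages)) {
    seg <- bind_rows(
      mutate(flank_averages, x = -20, xend = -10,
             value = .data$inside_avg),
      mutate(flank_averages, x = 10, xend = 20,
             value = .data$outside_avg)
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$value,
                   yend = .data$value, colour = .data$residue),
      linewidth = 1.6, alpha = 0.8
    )
  }
  p
}

#' Plot a per-position net charge profile
#'
#' @param profile Output of [net_charge_profile()], optionally with a
#'   `pass_class` column for colour.
#' @return A ggplot object.
#' @export
plot_net_charge <- function(profile) {
  aes <- if ("pass_class" %in% names(profile)) {
    ggplot2::aes(x = .data$position, y = .data$value,
                 colour = .data$pass_class)
  } else {
    ggplot2::aes(x = .data$position, y = .data$value)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (negative = cytoplasmic side)",
                  y = "mean net charge per helix") +
    ggplot2::theme_minimal()
}

#' Plot hydrophobicity curves stratified by helix count
#'
#' @param profile Output of [hydrophobicity_profile()] with
#'   `stratify_by_count = TRUE`.
#' @return A ggplot object.
#' @export
plot_hydrophobicity <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$position, y = .data$value,
    colour = if ("tmh_class" %in% names(profile)) .data$tmh_class else NULL
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (negative = cytoplasmic side)",
                  y = "windowed hydrophobicity",
                  colour = "helices per protein") +
    ggplot2::theme_minimal()
}

#' Residue-by-position heatmap of an aligned segment set
#'
#' @param object An [aligned_set()].
#' @param normalisation `"q_rel"` or `"p_abs"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aligned_set <- function(object, normalisation = c("q_rel", "p_abs"),
                                 ...) {
  normalisation <- match.arg(normalisation)
  prof <- if (normalisation == "q_rel") {
    relative_percentage(object)
  } else {
    absolute_relative_occurrence(object)
  }
  kd <- sort(hydro_scale("kyte_doolittle"), decreasing = TRUE)
  prof$residue <- factor(prof$residue, levels = rev(names(kd)))
  ggplot2::ggplot(prof, ggplot2::aes(
    x = .data$position, y = .data$residue, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred",
                                  midpoint = max(prof$value, na.rm = TRUE) / 2) +
    ggplot2::labs(x = "position (negative = cytoplasmic side)",
                  y = "residue (by decreasing hydrophobicity)",
                  fill = normalisation) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
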