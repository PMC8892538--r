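#' Plot a compartment profile
#'
#' Bar-style eigenvector track: positive (A) bins up, negative (B) bins
#' down, masked bins absent.
#'
#' @param object An `eigen_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eigen_profile
#' @export
autoplot.eigen_profile <- function(object, ...) {
  td <- tidy(object) |> filter(is.finite(.data$value))
  ggplot2::ggplot(td, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$value,
                                   fill = .data$compartment)) +
    ggplot2::geom_col(width = (td$end - td$start) / 1e6) +
    ggplot2::scale_fill_manual(values = c(A = "#b2182b", B = "#2166ac"),
                               na.value = "grey70") +
    ggplot2::labs(x = "position (Mb)", y = "eigenvector",
                  title = object$scaffold) +
    ggplot2::theme_minimal()
}

#' Plot a Hi-C contact matrix
#'
#' Log-colour heatmap of the raw counts. For display only, counts are capped
#' at `cap` (default 1000); computation never uses the cap.
#'
#' @param object A `contact_matrix`.
#' @param cap Display cap on counts (default 1000).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, cap = 1000, ...) {
  m <- pmin(object$counts, cap)
  df <- tibble(i = rep(seq_len(nrow(m)), times = ncol(m)),
               j = rep(seq_len(ncol(m)), each = nrow(m)),
               count = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = log10(1 + .data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#67000d") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = object$scaffold,
                  fill = "log10 count") +
    ggplot2::theme_minimal()
}

#' Ideogram-style synteny track
#'
#' Draws the homologous synteny blocks of one or more species along the
#' reference chromosomes, orientation-coloured in the style of comparative
#' chromosome browsers (same orientation as the reference vs inverted).
#'
#' @param hsbs HSB tibble, optionally with a `species` column.
#' @return A ggplot object.
#' @export
plot_synteny <- function(hsbs) {
  df <- as_tibble(hsbs)
  if (!"species" %in% names(df)) df$species <- "target"
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$ref_start / 1e6,
                                    xmax = .data$ref_end / 1e6,
                                    ymin = 0, ymax = 1,
                                    fill = .data$orientation)) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$ref_start + .data$ref_end) / 2e6,
                                    y = 0.5, label = .data$tgt_scaffold),
                       size = 2.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$species),
                        cols = ggplot2::vars(.data$ref_chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`+` = "#74a9cf", `-` = "#f1b6da"),
                               labels = c(`+` = "same", `-` = "inverted")) +
    ggplot2::labs(x = "reference position (Mb)", y = NULL,
                  fill = "orientation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Compare reference and lifted compartment profiles
#'
#' Overlaid eigenvector tracks on reference coordinates, one panel per
#' reference chromosome, with compartment shifts highlighted when supplied.
#'
#' @param ref_profile Per-bin reference tibble (`ref_chrom`, `start`, `end`,
#'   `value`).
#' @param lifted_profile Lifted target tibble from [liftover_profile()].
#' @param shifts Optional shift tibble from [call_compartment_shifts()].
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(ref_profile, lifted_profile,
                                    shifts = NULL) {
  both <- bind_rows(
    mutate(as_tibble(ref_profile), track = "reference"),
    mutate(select(as_tibble(lifted_profile), "ref_chrom", "start", "end",
                  "value"), track = "target")) |>
    filter(is.finite(.data$value))
  p <- ggplot2::ggplot(both,
                       ggplot2::aes((.data$start + .data$end) / 2e6,
                                    .data$value, colour = .data$track)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ref_chrom), scales = "free_x") +
    ggplot2::labs(x = "reference position (Mb)", y = "eigenvector") +
    ggplot2::theme_minimal()
  if (!is.null(shifts) && nrow(shifts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(shifts), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$ref_start / 1e6, xmax = .data$ref_end / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "gold", alpha = 0.25)
  }
  p
}
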