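#' Plot scanned acceptor sites
#'
#' Lollipop plot of candidate acceptor scores by position relative to the
#' canonical exon-intron junction (negative = intronic, positive = exonic).
#'
#' @param object An `acceptor_sites` tibble from [scan_acceptors()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot acceptor_sites
#' @export
autoplot.acceptor_sites <- function(object, ...) {
  d <- mutate(object,
              pos = ifelse(.data$location == "intron",
                           -.data$retained, .data$exon_g_index),
              label = ifelse(.data$provenance == "canonical",
                             "canonical", .data$location))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$score,
                                  colour = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "AG position relative to canonical junction (nt)",
                  y = "acceptor score (0-100)", colour = NULL,
                  title = attr(object, "variant")) +
    ggplot2::theme_minimal()
}

#' Plot a predicted RT-PCR band table as a schematic gel
#'
#' One lane per isoform, bands drawn at their product sizes on a log scale,
#' the way a minigene readout is inspected.
#'
#' @param object An `rtpcr_bands` tibble from [rtpcr_size()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rtpcr_bands
#' @export
autoplot.rtpcr_bands <- function(object, ...) {
  d <- mutate(object, lane = ifelse(.data$isoform_kind == "normal", "WT", "MT"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lane, y = .data$size_bp)) +
    ggplot2::geom_tile(width = 0.6, height = 4, fill = "grey20") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%s: %d bp",
                                                    .data$band_label,
                                                    .data$size_bp)),
                       hjust = -0.25, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "product size (bp)",
                  title = "predicted RT-PCR products") +
    ggplot2::theme_minimal()
}

#' Plot a splice report
#'
#' Combines the band schematic with isoform annotations; the quickest visual
#' summary of what the variant does to splicing.
#'
#' @param object A `splice_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot splice_report
#' @export
autoplot.splice_report <- function(object, ...) {
  if (is.null(object$bands)) {
    abort("report has no band table (not an acceptor variant)")
  }
  lab <- tidy(object)
  d <- mutate(object$bands,
              lane = ifelse(.data$isoform_kind == "normal", "WT", "MT"))
  d <- left_join(d, select(lab, "kind", "nt_delta", "hgvs_p"),
                 by = c(isoform_kind = "kind", nt_delta = "nt_delta"))
  d$hgvs_p[is.na(d$hgvs_p)] <- ""
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lane, y = .data$size_bp)) +
    ggplot2::geom_tile(width = 0.6, height = 4, fill = "grey20") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%s %d bp %s",
                                                    .data$band_label,
                                                    .data$size_bp,
                                                    .data$hgvs_p)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::expand_limits(x = 3) +
    ggplot2::labs(x = NULL, y = "product size (bp)",
                  title = object$variant$hgvs) +
    ggplot2::theme_minimal()
}
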