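#' Plot runs of homozygosity along the genome
#'
#' One horizontal track per sample and chromosome, runs drawn as
#' segments; seeded truth regions can be overlaid for comparison.
#'
#' @param runs Run tibble from [detect_roh()] (several samples may be
#'   stacked).
#' @param truth Optional tibble `chrom`, `start`, `end` of known
#'   autozygous tracts.
#' @return A ggplot object.
#' @export
plot_roh <- function(runs, truth = NULL) {
  p <- ggplot2::ggplot(runs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$sample, yend = .data$sample),
      linewidth = 3, colour = "steelblue"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Runs of homozygosity")
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_rect(
      data = truth,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "firebrick"
    )
  }
  p
}

#' Plot a triage funnel
#'
#' @param funnel A `triage_funnel` (or a list of them).
#' @return A ggplot object with per-stage surviving-variant counts.
#' @export
plot_funnel <- function(funnel) {
  tbl <- if (inherits(funnel, "triage_funnel")) tidy(funnel)
         else bind_rows(purrr::map(funnel, tidy))
  tbl$stage <- factor(tbl$stage, levels = unique(tbl$stage))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$stage, y = .data$n,
                                    fill = .data$branch)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::labs(x = NULL, y = "surviving variants",
                  title = "Private-variant triage funnel") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot wild-type vs truncated protein with domains
#'
#' @param annotation One row of [annotate_variants()] output for a
#'   truncating call.
#' @param domains Domain tibble for the same transcript.
#' @return A ggplot object.
#' @export
plot_protein <- function(annotation, domains) {
  stopifnot(nrow(annotation) == 1)
  dom <- domains[domains$transcript_id == annotation$transcript_id, ]
  bars <- tibble(
    protein = c("wild-type", "mutant"),
    len = c(annotation$wt_length, annotation$mutant_length)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = bars,
      ggplot2::aes(x = 0, xend = .data$len, y = .data$protein,
                   yend = .data$protein),
      linewidth = 4, colour = "grey60"
    ) +
    ggplot2::geom_rect(
      data = dom,
      ggplot2::aes(xmin = .data$aa_start, xmax = .data$aa_end,
                   ymin = 2 - 0.2, ymax = 2 + 0.2, fill = .data$domain),
      alpha = 0.9
    ) +
    ggplot2::labs(x = "amino acid", y = NULL,
                  title = annotation$protein_hgvs %||% "truncation")
}
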