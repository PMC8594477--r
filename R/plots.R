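#' Plot AUC against expression with significance thresholds
#'
#' Reproduces the method's diagnostic scatter: one point per terminal exon,
#' AUC on the y axis against log10(mean CPM) on the x axis, with the
#' smoothed per-bin thresholds drawn as step lines and APA-attributed calls
#' highlighted. Points above the upper line are exons with shorter 3' UTRs
#' in group A.
#'
#' @param object An \code{apa_fit} object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot apa_fit
#' @export
autoplot.apa_fit <- function(object, ...) {
  auc <- object$auc
  auc$status <- "not significant"
  sig <- object$calls
  auc$status[auc$te_id %in% sig$te_id] <- "significant"
  auc$status[auc$te_id %in% sig$te_id[sig$passed_span_filter]] <- "APA"
  thr <- object$thresholds
  step <- tibble::tibble(
    x = c(thr$bin_lo_edge, thr$bin_hi_edge[nrow(thr)]),
    lo = c(thr$lo, thr$lo[nrow(thr)]),
    hi = c(thr$hi, thr$hi[nrow(thr)])
  )
  ggplot2::ggplot(auc, ggplot2::aes(x = .data$log10_mean_cpm, y = .data$auc)) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$status), size = 0.6, alpha = 0.6
    ) +
    ggplot2::geom_step(
      data = step, ggplot2::aes(x = .data$x, y = .data$lo),
      colour = "red", direction = "hv"
    ) +
    ggplot2::geom_step(
      data = step, ggplot2::aes(x = .data$x, y = .data$hi),
      colour = "red", direction = "hv"
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "not significant" = "grey60", "significant" = "orange",
      "APA" = "forestgreen"
    )) +
    ggplot2::labs(
      x = expression(log[10] * "(mean CPM)"), y = "AUC", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Cumulative-coverage curve of one terminal exon
#'
#' Draws the ROC-like curve behind a single exon's AUC: the fraction of
#' group-A reads (x) against the fraction of group-B reads (y) accumulated
#' walking from the exon 3' end (0,0) to its 5' end (1,1). A curve above the
#' diagonal indicates denser distal coverage in group B, i.e. 3' UTR
#' shortening in group A.
#'
#' @param reads Grouped read tibble.
#' @param te_id The terminal exon to plot.
#' @return A ggplot object, with the AUC in the subtitle.
#' @export
plot_te_curve <- function(reads, te_id) {
  r <- reads[reads$te_id == te_id, ]
  if (nrow(r) == 0L) abort(sprintf("no reads for terminal exon '%s'", te_id))
  da <- r$dist[r$group == "A"]
  db <- r$dist[r$group == "B"]
  if (length(da) == 0L || length(db) == 0L) {
    abort(sprintf("terminal exon '%s' lacks reads in one group", te_id))
  }
  d <- sort(unique(c(da, db)))
  curve <- tibble::tibble(
    frac_a = c(0, findInterval(d, sort(da)) / length(da)),
    frac_b = c(0, findInterval(d, sort(db)) / length(db))
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$frac_a, y = .data$frac_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "cumulative fraction of group A reads (3' to 5')",
      y = "cumulative fraction of group B reads (3' to 5')",
      title = te_id,
      subtitle = sprintf("AUC = %.3f", compute_auc(da, db))
    ) +
    ggplot2::theme_minimal()
}
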