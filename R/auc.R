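#' Normalized reverse-cumulative 3'-end coverage of a terminal exon
#'
#' Distances are measured from the terminal-exon 3' end, so the cumulative
#' fraction is accumulated walking from the 3' end towards the 5' end of the
#' exon: \code{F(d)} is the fraction of the group's reads whose 3' end lies
#' within \code{d} nucleotides of the exon end. \code{F} is a step function
#' that jumps only at observed distances, in multiples of \code{1/n}.
#'
#' @param distances Numeric vector of read 3'-end distances (nt, >= 0).
#' @return Tibble with one row per distinct distance: \code{dist},
#'   \code{count} and the cumulative fraction \code{cum_frac}.
#' @export
reverse_cumulative <- function(distances) {
  if (length(distances) == 0L) {
    abort("reverse_cumulative() needs at least one read")
  }
  tab <- table(distances)
  tibble::tibble(
    dist = as.numeric(names(tab)),
    count = as.integer(tab),
    cum_frac = cumsum(as.integer(tab)) / length(distances)
  )
}

#' AUC statistic for a 3' UTR length difference between two read groups
#'
#' The two groups' reverse-cumulative coverage fractions trace a curve in the
#' unit square, from (0,0) at the terminal-exon 3' end to (1,1) at its 5'
#' end, with group A on the x axis and group B on the y axis. Simultaneous
#' jumps (reads of both groups at the same distance) are connected linearly,
#' which makes the area under this curve exactly the Mann-Whitney
#' probability \eqn{P(d_B < d_A) + P(d_B = d_A)/2}. An AUC of 0.5 means
#' identical positional coverage; values above 0.5 mean group B's 3' ends
#' concentrate nearer the exon 3' end (the distal region), i.e. 3' UTRs are
#' shorter in group A.
#'
#' @param dist_a,dist_b Numeric vectors of 3'-end distances for groups A
#'   (test, x axis) and B (reference, y axis). Both must be nonempty.
#' @return The AUC, a number in \code{[0, 1]}.
#' @export
compute_auc <- function(dist_a, dist_b) {
  if (length(dist_a) == 0L || length(dist_b) == 0L) {
    abort("compute_auc() requires nonempty read groups")
  }
  d <- sort(unique(c(dist_a, dist_b)))
  # findInterval on a sorted vector counts elements <= d.
  x <- c(0, findInterval(d, sort(dist_a)) / length(dist_a))
  y <- c(0, findInterval(d, sort(dist_b)) / length(dist_b))
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Counts per million
#'
#' @param count Per-exon read count(s).
#' @param group_total The group's total number of terminal-exon-assigned
#'   reads (the CPM denominator).
#' @return \code{count * 1e6 / group_total}.
#' @export
compute_cpm <- function(count, group_total) {
  if (length(group_total) != 1L || is.na(group_total) || group_total <= 0) {
    abort("compute_cpm(): group_total must be a single positive number")
  }
  count * 1e6 / group_total
}

#' Span of the union of the two groups' interquartile intervals
#'
#' Per group, the closed interval between the first and third quartile of
#' the 3'-end distances (linear-interpolation quantiles) summarises where
#' the bulk of that group's 3' ends fall. The effect size of a positional
#' shift is the distance spanned by the union of the two intervals — from
#' the smallest to the largest quartile (default, \code{method = "span"}).
#' A clean switch between two well-separated polyadenylation sites yields
#' two narrow, far-apart intervals: a large span, as an APA event should be.
#' \code{method = "union"} instead measures the total \emph{length} of the
#' merged set union (disjoint intervals contribute the sum of their
#' lengths), which penalises exactly those clean switches and is kept only
#' for comparison.
#'
#' @param dist_a,dist_b Distance vectors for the two groups (nonempty).
#' @param method \code{"span"} (default, overall extent of the union) or
#'   \code{"union"} (merged-union length).
#' @return Span in nucleotides.
#' @export
iqr_union_span <- function(dist_a, dist_b, method = c("span", "union")) {
  method <- match.arg(method)
  qa <- stats::quantile(dist_a, c(0.25, 0.75), names = FALSE, type = 7)
  qb <- stats::quantile(dist_b, c(0.25, 0.75), names = FALSE, type = 7)
  if (method == "span") {
    return(max(qa[2], qb[2]) - min(qa[1], qb[1]))
  }
  lo <- c(qa[1], qb[1])
  hi <- c(qa[2], qb[2])
  ord <- order(lo)
  lo <- lo[ord]
  hi <- hi[ord]
  if (lo[2] <= hi[1]) { # overlap or touch: merge
    max(hi) - lo[1]
  } else {
    (hi[1] - lo[1]) + (hi[2] - lo[2])
  }
}

#' Per-terminal-exon AUC table for a grouped read set
#'
#' Summarises a grouped 3'-end read set into one row per terminal exon with
#' reads in both groups: read counts, CPM (normalized by each group's total
#' of terminal-exon-assigned reads, or by supplied totals such as all-mapped
#' counts), the AUC statistic and the interquartile-range union span.
#'
#' @param reads Tibble of grouped read 3' ends with columns \code{te_id},
#'   \code{dist} and \code{group} (values \code{"A"}/\code{"B"}); a
#'   \code{gene_name} column is carried through if present.
#' @param totals Optional named numeric vector \code{c(A = ..., B = ...)}
#'   overriding the CPM denominators.
#' @param span_method Passed to [iqr_union_span()].
#' @return Tibble with columns \code{te_id}, \code{gene_name}, \code{n_A},
#'   \code{n_B}, \code{cpm_A}, \code{cpm_B}, \code{mean_cpm},
#'   \code{log10_mean_cpm}, \code{auc}, \code{iqr_union_span}.
#' @export
auc_table <- function(reads, totals = NULL, span_method = "span") {
  stopifnot(all(c("te_id", "dist", "group") %in% names(reads)))
  if (!all(reads$group %in% c("A", "B"))) {
    abort("auc_table(): reads$group must be 'A' or 'B'; see assign_read_groups()")
  }
  if (is.null(totals)) {
    totals <- c(
      A = sum(reads$group == "A"),
      B = sum(reads$group == "B")
    )
  }
  if (any(totals <= 0)) {
    abort(sprintf(
      "group '%s' has no terminal-exon-assigned reads",
      names(totals)[which(totals <= 0)[1L]]
    ))
  }
  has_gene <- "gene_name" %in% names(reads)
  out <- reads %>%
    dplyr::group_by(.data$te_id) %>%
    dplyr::summarise(
      gene_name = if (has_gene) .data$gene_name[1L] else NA_character_,
      n_A = sum(.data$group == "A"),
      n_B = sum(.data$group == "B"),
      auc = if (n_A > 0 && n_B > 0) {
        compute_auc(.data$dist[.data$group == "A"],
                    .data$dist[.data$group == "B"])
      } else {
        NA_real_
      },
      iqr_union_span = if (n_A > 0 && n_B > 0) {
        iqr_union_span(.data$dist[.data$group == "A"],
                       .data$dist[.data$group == "B"],
                       method = span_method)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  one_sided <- out$n_A == 0L | out$n_B == 0L
  log_count(sum(one_sided), "terminal exons with reads in only one group")
  out <- out[!one_sided, ]
  out$cpm_A <- compute_cpm(out$n_A, totals[["A"]])
  out$cpm_B <- compute_cpm(out$n_B, totals[["B"]])
  out$mean_cpm <- (out$cpm_A + out$cpm_B) / 2
  out$log10_mean_cpm <- log10(out$mean_cpm)
  dplyr::select(
    out, "te_id", "gene_name", "n_A", "n_B", "cpm_A", "cpm_B",
    "mean_cpm", "log10_mean_cpm", "auc", "iqr_union_span"
  )
}

#' Expected AUC for a two-polyadenylation-site usage mixture
#'
#' When each group's reads come from just two polyadenylation sites — a
#' distal one at the terminal-exon end and a proximal one further upstream —
#' with proximal-usage fractions \code{f_a} and \code{f_b}, the AUC has the
#' closed form \deqn{f_A (1 - f_B) + \frac{1}{2}\left[f_A f_B +
#' (1 - f_A)(1 - f_B)\right],} i.e. the probability that a group-B read lies
#' distal of a group-A read, with half credit for reads from the same site.
#' Positional jitter that is identically distributed around each site in the
#' two groups leaves the value unchanged.
#'
#' @param f_a,f_b Proximal-usage fractions in groups A and B, in [0, 1].
#' @return The expected AUC.
#' @export
expected_auc_mixture <- function(f_a, f_b) {
  f_a * (1 - f_b) + 0.5 * (f_a * f_b + (1 - f_a) * (1 - f_b))
}
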