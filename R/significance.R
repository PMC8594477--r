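#' Randomize cell-group labels within each terminal exon
#'
#' Builds the background read set used to calibrate the AUC statistic: within
#' each terminal exon independently, the group labels are permuted uniformly
#' at random over that exon's reads. This preserves per-exon depth in each
#' group (and therefore CPM) and the exact multiset of 3'-end distances,
#' while destroying any association between label and position — exactly the
#' null under which AUC deviations reflect sampling noise alone.
#'
#' @param reads Grouped read tibble (columns \code{te_id}, \code{dist},
#'   \code{group}, ...).
#' @param seed Integer seed; the permutation is deterministic given the seed.
#' @return The read tibble with permuted \code{group} labels.
#' @export
randomize_labels <- function(reads, seed) {
  withr::with_seed(seed, {
    reads %>%
      dplyr::group_by(.data$te_id) %>%
      dplyr::mutate(group = sample(.data$group)) %>%
      dplyr::ungroup()
  })
}

running_median <- function(x, window = 5L) {
  if (length(x) == 0L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Expression-binned significance thresholds from the randomized background
#'
#' The spread of null AUC values shrinks with read depth, so a single cutoff
#' would be miscalibrated. Terminal exons are binned into \code{n_bins}
#' equal-width bins of \code{log10(mean CPM)} spanning the observed range;
#' within each bin the empirical \code{alpha} and \code{1 - alpha} quantiles
#' of the background AUC values form the lower and upper thresholds
#' (two-tailed; Weibull plotting-position estimator, \code{type = 6}, which
#' keeps the realized two-tailed call rate near \code{2 * alpha} at the
#' ~100-values-per-bin sizes a single randomization yields — the mode-based
#' default estimator is anti-conservative that far in the tails). Each
#' threshold series is then smoothed by a running median
#' over \code{window} bins, the window shrinking symmetrically at the edges.
#' Bins holding fewer than \code{min_bin_n} background values borrow the
#' thresholds of the nearest populated bin (with a warning) before smoothing.
#'
#' @param auc_tbl Observed AUC table (defines the binning range); normally
#'   pre-filtered to CPM-passing exons.
#' @param background AUC table computed from [randomize_labels()] output.
#' @param n_bins Number of expression bins (default 20).
#' @param alpha Per-tail quantile level (default 0.01: 1st and 99th
#'   percentiles).
#' @param window Running-median window in bins (default 5).
#' @param min_bin_n Minimum background values per bin before borrowing.
#' @return Tibble with one row per bin: \code{bin}, \code{bin_lo_edge},
#'   \code{bin_hi_edge}, \code{n_bg}, \code{lo}, \code{hi}; the bin edges,
#'   \code{alpha} and \code{window} are carried as attributes.
#' @export
build_thresholds <- function(auc_tbl, background, n_bins = 20L,
                             alpha = 0.01, window = 5L, min_bin_n = 10L) {
  if (nrow(auc_tbl) == 0L || nrow(background) == 0L) {
    abort("build_thresholds(): empty AUC table or background")
  }
  rng <- range(auc_tbl$log10_mean_cpm)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bg_bin <- pmin(pmax(findInterval(
    background$log10_mean_cpm, edges,
    rightmost.closed = TRUE
  ), 1L), n_bins)
  lo <- hi <- rep(NA_real_, n_bins)
  n_bg <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    v <- background$auc[bg_bin == b]
    n_bg[b] <- length(v)
    if (length(v) >= min_bin_n) {
      lo[b] <- stats::quantile(v, alpha, names = FALSE, type = 6)
      hi[b] <- stats::quantile(v, 1 - alpha, names = FALSE, type = 6)
    }
  }
  if (anyNA(lo)) {
    warn(sprintf(
      "%d of %d expression bins hold fewer than %d background values; borrowing thresholds from the nearest populated bin",
      sum(is.na(lo)), n_bins, min_bin_n
    ))
    filled <- which(!is.na(lo))
    if (length(filled) == 0L) {
      abort("build_thresholds(): no expression bin has enough background values")
    }
    for (b in which(is.na(lo))) {
      nearest <- filled[which.min(abs(filled - b))]
      lo[b] <- lo[nearest]
      hi[b] <- hi[nearest]
    }
  }
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_lo_edge = edges[-length(edges)],
    bin_hi_edge = edges[-1L],
    n_bg = n_bg,
    lo = running_median(lo, window),
    hi = running_median(hi, window)
  )
  attr(out, "edges") <- edges
  attr(out, "alpha") <- alpha
  attr(out, "window") <- window
  out
}

threshold_bin <- function(log10_mean_cpm, thresholds) {
  edges <- attr(thresholds, "edges")
  # Exons whose expression falls outside all bins are assigned to the
  # nearest edge bin.
  pmin(pmax(
    findInterval(log10_mean_cpm, edges, rightmost.closed = TRUE), 1L
  ), nrow(thresholds))
}

#' Call terminal exons with significant 3' UTR length changes
#'
#' A terminal exon is called significant when it is expressed at
#' \code{min_cpm} or more in both groups and its AUC falls outside the
#' two-tailed thresholds of its expression bin: above the upper threshold
#' means 3' UTRs are shorter in group A (\code{shortened_in_A}), below the
#' lower one longer (\code{lengthened_in_A}). A significant exon is
#' attributed to alternative polyadenylation only if its read 3' ends span
#' enough of the exon — interquartile-range union span of at least
#' \code{min_span} nucleotides — since tighter shifts are unlikely to
#' reflect a change of polyadenylation site.
#'
#' @param auc_tbl AUC table from [auc_table()].
#' @param thresholds Threshold table from [build_thresholds()].
#' @param min_cpm Minimum CPM required in both groups (default 2, roughly
#'   one read per group at typical depths).
#' @param min_span Minimum IQR-union span in nt (default 200).
#' @return Tibble of significant exons with columns \code{te_id},
#'   \code{gene_name}, \code{auc}, \code{direction}, \code{mean_cpm},
#'   \code{log10_mean_cpm}, \code{iqr_union_span}, \code{lo}, \code{hi},
#'   \code{passed_span_filter}. Rows with \code{passed_span_filter = TRUE}
#'   are the APA calls.
#' @export
call_apa <- function(auc_tbl, thresholds, min_cpm = 2, min_span = 200) {
  tested <- dplyr::filter(
    auc_tbl, .data$cpm_A >= min_cpm, .data$cpm_B >= min_cpm
  )
  if (nrow(tested) == 0L) {
    return(tibble::tibble(
      te_id = character(), gene_name = character(), auc = numeric(),
      direction = character(), mean_cpm = numeric(),
      log10_mean_cpm = numeric(), iqr_union_span = numeric(),
      lo = numeric(), hi = numeric(), passed_span_filter = logical()
    ))
  }
  bin <- threshold_bin(tested$log10_mean_cpm, thresholds)
  tested$lo <- thresholds$lo[bin]
  tested$hi <- thresholds$hi[bin]
  sig <- tested$auc < tested$lo | tested$auc > tested$hi
  out <- tested[sig, ]
  out$direction <- ifelse(out$auc > out$hi, "shortened_in_A", "lengthened_in_A")
  out$passed_span_filter <- out$iqr_union_span >= min_span
  dplyr::select(
    out, "te_id", "gene_name", "auc", "direction", "mean_cpm",
    "log10_mean_cpm", "iqr_union_span", "lo", "hi", "passed_span_filter"
  )
}

#' Hypergeometric overlap between two gene sets
#'
#' Assesses whether two sets of affected genes (e.g. shortened terminal
#' exons from two data sets) overlap more than expected by chance within a
#' common universe (the genes testable in both comparisons). The p-value is
#' the hypergeometric upper tail \eqn{P(X \ge k)} for an overlap of size
#' \eqn{k}; the odds ratio comes from the 2x2 contingency table:
#' \eqn{k (N - K - n + k) / [(K - k)(n - k)]}.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe Character vector containing both sets.
#' @return One-row tibble: \code{n_universe}, \code{n_a}, \code{n_b},
#'   \code{n_overlap}, \code{odds_ratio}, \code{p_value}.
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  stray <- setdiff(c(set_a, set_b), universe)
  if (length(stray) > 0L) {
    abort(sprintf(
      "overlap_stats(): %d genes are not in the universe (e.g. %s)",
      length(stray), paste(utils::head(stray, 3), collapse = ", ")
    ))
  }
  N <- length(universe)
  K <- length(set_a)
  n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  odds <- if (K == k || n == k) {
    if (k == 0) 0 else Inf
  } else {
    k * (N - K - n + k) / ((K - k) * (n - k))
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(
    n_universe = N, n_a = K, n_b = n, n_overlap = k,
    odds_ratio = odds, p_value = p
  )
}
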