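#' Test for 3' UTR length differences between two groups of cells
#'
#' Runs the statistics core of the method on a grouped read set: computes
#' the per-terminal-exon AUC table, builds the label-randomization
#' background (one randomization, as depth-preserving permutation makes
#' even a single pass a valid per-bin null sample), derives expression-binned
#' two-tailed thresholds, and calls exons whose AUC cannot be explained by
#' sampling noise, attributing span-passing ones to alternative
#' polyadenylation.
#'
#' @param reads Grouped read tibble (columns \code{te_id}, \code{dist},
#'   \code{group} in \code{"A"}/\code{"B"}; see [assign_read_groups()] or
#'   [simulate_apa()]).
#' @param seed Seed for the label randomization.
#' @param n_bins,alpha,window Passed to [build_thresholds()].
#' @param min_cpm,min_span Passed to [call_apa()].
#' @param n_permutations Number of label randomizations pooled into the
#'   background (default 1).
#' @param totals,span_method Passed to [auc_table()].
#' @return An object of class \code{apa_fit}: list with \code{auc} (full AUC
#'   table), \code{background}, \code{thresholds}, \code{calls} (the
#'   significant exons; `tidy()` returns them) and \code{params}.
#' @seealso [tidy.apa_fit()], [glance.apa_fit()], [autoplot.apa_fit()]
#' @export
apa_test <- function(reads, seed = 1L, n_bins = 20L, alpha = 0.01,
                     window = 5L, min_cpm = 2, min_span = 200,
                     n_permutations = 1L, totals = NULL,
                     span_method = "span") {
  auc_obs <- auc_table(reads, totals = totals, span_method = span_method)
  bg <- purrr::map_dfr(seq_len(n_permutations), function(i) {
    auc_table(
      randomize_labels(reads, seed = seed + i - 1L),
      totals = totals, span_method = span_method
    )
  })
  pass <- auc_obs$cpm_A >= min_cpm & auc_obs$cpm_B >= min_cpm
  bg_pass <- bg$cpm_A >= min_cpm & bg$cpm_B >= min_cpm
  thresholds <- build_thresholds(
    auc_obs[pass, ], bg[bg_pass, ],
    n_bins = n_bins, alpha = alpha, window = window
  )
  calls <- call_apa(auc_obs, thresholds, min_cpm = min_cpm,
                    min_span = min_span)
  structure(
    list(
      auc = auc_obs, background = bg, thresholds = thresholds, calls = calls,
      params = list(
        seed = seed, n_bins = n_bins, alpha = alpha, window = window,
        min_cpm = min_cpm, min_span = min_span,
        n_permutations = n_permutations, span_method = span_method,
        n_tested = sum(pass)
      )
    ),
    class = "apa_fit"
  )
}

#' @export
print.apa_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0(
      "<apa_fit> %d terminal exons, %d tested (CPM >= %g in both groups)\n",
      "  significant: %d | APA-attributed: %d ",
      "(%d shortened, %d lengthened in group A; %.0f%% shortened)\n"
    ),
    g$n_te, g$n_tested, x$params$min_cpm, g$n_significant, g$n_apa,
    g$n_shortened, g$n_lengthened, 100 * g$frac_shortened
  ))
  invisible(x)
}

#' Tidy the significant terminal exons of an APA fit
#'
#' @param x An \code{apa_fit} object.
#' @param apa_only If \code{TRUE} (default), return only exons passing the
#'   IQR-union span filter, i.e. the calls attributed to APA.
#' @param ... Unused.
#' @return The calls tibble (see [call_apa()]).
#' @importFrom generics tidy
#' @method tidy apa_fit
#' @export
tidy.apa_fit <- function(x, apa_only = TRUE, ...) {
  if (apa_only) x$calls[x$calls$passed_span_filter, ] else x$calls
}

#' One-row summary of an APA fit
#'
#' @param x An \code{apa_fit} object.
#' @param ... Unused.
#' @return Tibble with exon counts at each stage and the fraction of
#'   APA-attributed calls that are shortenings in group A.
#' @importFrom generics glance
#' @method glance apa_fit
#' @export
glance.apa_fit <- function(x, ...) {
  apa <- x$calls[x$calls$passed_span_filter, ]
  tibble::tibble(
    n_te = nrow(x$auc),
    n_tested = x$params$n_tested,
    n_significant = nrow(x$calls),
    n_apa = nrow(apa),
    n_shortened = sum(apa$direction == "shortened_in_A"),
    n_lengthened = sum(apa$direction == "lengthened_in_A"),
    frac_shortened = if (nrow(apa) > 0) {
      mean(apa$direction == "shortened_in_A")
    } else {
      NA_real_
    },
    seed = x$params$seed
  )
}

#' @export
generics::tidy

#' @export
generics::glance
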