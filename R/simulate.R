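#' Simulate two-group read 3'-end data with planted APA
#'
#' Generates a fully synthetic data set with known ground truth, emulating
#' what 3'-biased single-cell RNA-seq looks like at the level this method
#' consumes: a set of terminal exons and, per exon, sparse read 3' ends from
#' two cell groups. Each exon carries two polyadenylation sites — a distal
#' one at the exon 3' end (distance 0) and a proximal one \code{delta} nt
#' upstream — and each group uses the proximal site with its own fraction.
#' Planted exons use \code{f_a} vs \code{f_b}; null exons share a common
#' proximal-usage fraction drawn uniformly, so group label and position are
#' independent. Read 3' ends scatter upstream of their site by a half-normal
#' jitter (reads end at or before the cleavage site in 3'-end protocols) and
#' are clipped to the exon. Depth per exon and group is Poisson (sparse), or
#' fixed when \code{reads_per_group} is given.
#'
#' @param n_te Number of terminal exons.
#' @param frac_planted Fraction of exons with a planted usage difference.
#' @param delta Proximal-to-distal site separation in nt (default 500).
#' @param f_a,f_b Proximal-usage fractions of planted exons in groups A and
#'   B (defaults 0.8 / 0.2: strong shortening in A).
#' @param depth_mean Poisson mean reads per exon per group (default 30).
#' @param reads_per_group If non-NULL, a fixed read count per exon per group
#'   instead of Poisson depth.
#' @param jitter_sd Standard deviation of the half-normal positional jitter
#'   in nt (default 25; 0 disables jitter).
#' @param te_length_range Terminal-exon lengths are drawn uniformly from
#'   this range (default 1500-3000 nt, typical of mammalian terminal exons).
#' @param n_cells_per_group Cell barcodes per group (default 100).
#' @param seed Integer seed; the whole data set is deterministic given it.
#' @return An object of class \code{apa_sim}: a list with tibbles
#'   \code{tes} (BED-ready terminal exons), \code{reads} (grouped 3'-end
#'   table with \code{te_id}, \code{chrom}, \code{pos}, \code{dist},
#'   \code{strand}, \code{group}, \code{barcode}, \code{umi}),
#'   \code{truth} (per exon: planted \code{direction}, \code{delta},
#'   \code{f_a}, \code{f_b}, \code{expected_auc} from the closed form) and
#'   the \code{config}.
#' @export
simulate_apa <- function(n_te = 2000L, frac_planted = 0, delta = 500L,
                         f_a = 0.8, f_b = 0.2, depth_mean = 30,
                         reads_per_group = NULL, jitter_sd = 25,
                         te_length_range = c(1500L, 3000L),
                         n_cells_per_group = 100L, seed = 1L) {
  if (delta >= te_length_range[1]) {
    abort("simulate_apa(): delta must be smaller than the shortest exon")
  }
  config <- list(
    n_te = n_te, frac_planted = frac_planted, delta = delta,
    f_a = f_a, f_b = f_b, depth_mean = depth_mean,
    reads_per_group = reads_per_group, jitter_sd = jitter_sd,
    te_length_range = te_length_range,
    n_cells_per_group = n_cells_per_group, seed = seed
  )
  withr::with_seed(seed, {
    te_id <- sprintf("te%05d", seq_len(n_te))
    len <- sample(te_length_range[1]:te_length_range[2], n_te, replace = TRUE)
    strand <- sample(c("+", "-"), n_te, replace = TRUE)
    # Lay exons along one synthetic chromosome with 1-kb gaps.
    start <- cumsum(c(1000L, utils::head(len, -1L) + 1000L))
    tes <- tibble::tibble(
      chrom = "1", start = start, end = start + len,
      strand = strand, te_id = te_id, gene_name = te_id
    )

    n_planted <- round(frac_planted * n_te)
    planted <- seq_len(n_te) <= n_planted # deterministic layout
    fa_te <- ifelse(planted, f_a, stats::runif(n_te))
    fb_te <- ifelse(planted, f_b, fa_te)
    truth <- tibble::tibble(
      te_id = te_id,
      direction = dplyr::case_when(
        fa_te > fb_te ~ "shortened_in_A",
        fa_te < fb_te ~ "lengthened_in_A",
        TRUE ~ "null"
      ),
      delta = delta, f_a = fa_te, f_b = fb_te,
      expected_auc = expected_auc_mixture(fa_te, fb_te)
    )

    barcodes <- list(
      A = sprintf("CELLA%04d", seq_len(n_cells_per_group)),
      B = sprintf("CELLB%04d", seq_len(n_cells_per_group))
    )
    draw_group <- function(group_label, f) {
      n <- if (is.null(reads_per_group)) {
        stats::rpois(n_te, depth_mean)
      } else {
        rep(as.integer(reads_per_group), n_te)
      }
      idx <- rep.int(seq_len(n_te), n)
      total <- length(idx)
      pas <- ifelse(stats::runif(total) < f[idx], delta, 0L)
      jit <- if (jitter_sd > 0) round(abs(stats::rnorm(total, 0, jitter_sd))) else 0
      dist <- as.integer(pmin(pas + jit, len[idx] - 1L))
      read_strand <- strand[idx]
      pos <- as.integer(ifelse(read_strand == "+",
        tes$end[idx] - 1L - dist, tes$start[idx] + dist
      ))
      tibble::tibble(
        te_id = te_id[idx],
        chrom = "1",
        dist = dist,
        strand = read_strand,
        pos = pos,
        group = group_label,
        barcode = sample(barcodes[[group_label]], total, replace = TRUE)
      )
    }
    reads <- dplyr::bind_rows(draw_group("A", fa_te), draw_group("B", fb_te))
    reads$umi <- sprintf("UMI%07d", seq_len(nrow(reads)))
    reads <- dplyr::select(
      reads, "te_id", "chrom", "pos", "dist", "strand", "group",
      "barcode", "umi"
    )
    structure(
      list(tes = tes, reads = reads, truth = truth, config = config),
      class = "apa_sim"
    )
  })
}

#' @export
print.apa_sim <- function(x, ...) {
  cat(sprintf(
    "<apa_sim> %d terminal exons (%d planted), %d reads, seed %d\n",
    nrow(x$tes), sum(x$truth$direction != "null"), nrow(x$reads),
    x$config$seed
  ))
  invisible(x)
}

#' Cell-barcode table of a simulated data set
#'
#' @param sim An \code{apa_sim} object.
#' @param group_a,group_b Labels to expose for the two simulated groups.
#' @return Tibble with columns \code{barcode}, \code{group},
#'   \code{condition} usable by [assign_read_groups()] in either mode.
#' @export
sim_cell_table <- function(sim, group_a = "groupA", group_b = "groupB") {
  n <- sim$config$n_cells_per_group
  tibble::tibble(
    barcode = c(
      sprintf("CELLA%04d", seq_len(n)), sprintf("CELLB%04d", seq_len(n))
    ),
    group = rep(c(group_a, group_b), each = n),
    condition = rep(c(group_a, group_b), each = n)
  )
}

#' Write a simulated data set as a minimal SAM file
#'
#' Encodes every simulated read as a single-base alignment (CIGAR \code{1M})
#' at its 3'-end position, with CB/UB/GX tags, so the full read-processing
#' path can be exercised end-to-end on synthetic data. Coordinate-sorted.
#'
#' @param sim An \code{apa_sim} object.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(sim, path) {
  chrom_len <- max(sim$tes$end) + 1000L
  reads <- dplyr::arrange(sim$reads, .data$pos)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:1\tLN:%d", chrom_len)
  )
  records <- sprintf(
    "r%07d\t%d\t1\t%d\t60\t1M\t*\t0\t0\tA\tI\tCB:Z:%s\tUB:Z:%s\tGX:Z:%s",
    seq_len(nrow(reads)),
    ifelse(reads$strand == "+", 0L, 16L),
    reads$pos + 1L, # SAM is 1-based
    reads$barcode, reads$umi, reads$te_id
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Score APA calls against the simulated truth
#'
#' @param calls APA-call tibble from [call_apa()] (rows failing the span
#'   filter are not counted as calls).
#' @param truth Truth tibble from [simulate_apa()].
#' @return One-row tibble: \code{n_planted}, \code{n_null},
#'   \code{sensitivity} (planted exons called with the planted direction),
#'   \code{specificity} (null exons not called), \code{direction_accuracy}
#'   (correct direction among calls on planted exons) and
#'   \code{null_call_rate}.
#' @export
score_calls <- function(calls, truth) {
  calls <- calls[calls$passed_span_filter, ]
  unknown <- setdiff(calls$te_id, truth$te_id)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "score_calls(): %d called exon(s) absent from the truth table (e.g. %s)",
      length(unknown), unknown[1L]
    ))
  }
  called_dir <- calls$direction[match(truth$te_id, calls$te_id)]
  planted <- truth$direction != "null"
  n_planted <- sum(planted)
  n_null <- sum(!planted)
  correct <- !is.na(called_dir) & called_dir == truth$direction
  tibble::tibble(
    n_planted = n_planted,
    n_null = n_null,
    sensitivity = if (n_planted > 0) sum(correct & planted) / n_planted else NA_real_,
    specificity = if (n_null > 0) sum(is.na(called_dir[!planted])) / n_null else NA_real_,
    direction_accuracy = {
      on_planted <- planted & !is.na(called_dir)
      if (any(on_planted)) mean(correct[on_planted]) else NA_real_
    },
    null_call_rate = if (n_null > 0) {
      sum(!is.na(called_dir[!planted])) / n_null
    } else {
      NA_real_
    }
  )
}
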