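#' Read a flat key=value run configuration file
#'
#' @param path Path to a text file of \code{key = value} lines (\code{#}
#'   comments allowed). Numeric-looking values are converted.
#' @return Named list suitable for [run_apa_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(
    kv, function(x) paste(x[-1L], collapse = "="), ""
  ))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

default_run_config <- function() {
  list(
    mode = "two_group", min_mapq = 30, min_cpm = 2, n_bins = 20,
    alpha = 0.01, smooth_window = 5, min_span = 200, seed = 1
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full 3' UTR length comparison pipeline
#'
#' Orchestrates the four stages on file inputs: terminal-exon extraction
#' (\code{extract-te}), read filtering/deduplication/3'-end assignment
#' (\code{prepare-reads}), the per-exon AUC table (\code{auc}) and the
#' significance calls (\code{call-apa}). Any stage error aborts with the
#' stage name. All stage outputs are plain files under \code{out_dir}, so a
#' run can also be entered mid-pipeline by supplying \code{te_bed} instead
#' of \code{gff}, or \code{reads_tsv} instead of \code{bam}.
#'
#' @param config Named list or path to a key=value file. Recognised keys:
#'   \code{gff}, \code{assembly_report}, \code{gene_map}, \code{te_bed},
#'   \code{bam}, \code{reads_tsv}, \code{cells} (barcode table TSV),
#'   \code{group_a}, \code{group_b}, \code{mode} (\code{two_group} or
#'   \code{quasi_bulk}), \code{out_dir}, and the tunables \code{min_mapq}
#'   (30), \code{min_cpm} (2), \code{n_bins} (20), \code{alpha} (0.01),
#'   \code{smooth_window} (5), \code{min_span} (200), \code{seed} (1).
#' @return The \code{apa_fit} object, invisibly; output files
#'   (\code{terminal_exons.bed}, \code{read_ends.tsv}, \code{auc.tsv},
#'   \code{thresholds.tsv}, \code{apa_calls.tsv}, \code{summary.txt},
#'   \code{manifest.json}) are written under \code{out_dir}.
#' @export
run_apa_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_run_config(), config)
  if (is.null(config$out_dir)) abort("config must set 'out_dir'")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  path <- function(f) file.path(config$out_dir, f)

  tes <- run_stage("extract-te", {
    if (!is.null(config$te_bed)) {
      read_te_bed(config$te_bed)
    } else {
      if (is.null(config$gff)) abort("config must set 'gff' or 'te_bed'")
      cm <- if (!is.null(config$assembly_report)) {
        read_chrom_map(config$assembly_report)
      }
      te <- cluster_terminal_exons(extract_terminal_exons(config$gff, cm))
      if (!is.null(config$gene_map)) te <- add_gene_names(te, config$gene_map)
      te
    }
  })
  write_te_bed(tes, path("terminal_exons.bed"))
  counts$terminal_exons <- nrow(tes)

  reads <- run_stage("prepare-reads", {
    raw <- if (!is.null(config$reads_tsv)) {
      read_read_ends(config$reads_tsv)
    } else {
      if (is.null(config$bam)) abort("config must set 'bam' or 'reads_tsv'")
      extract_read_ends(config$bam, tes, min_mapq = config$min_mapq)
    }
    if ("group" %in% names(raw) && all(raw$group %in% c("A", "B"))) {
      raw # already grouped (e.g. simulated input)
    } else {
      if (is.null(config$cells)) abort("config must set 'cells'")
      cells <- readr::read_tsv(config$cells, col_types = readr::cols())
      assign_read_groups(
        raw, cells, config$group_a, config$group_b, mode = config$mode
      )
    }
  })
  write_read_ends(reads, path("read_ends.tsv"))
  counts$read_ends <- nrow(reads)
  counts$reads_group_a <- sum(reads$group == "A")
  counts$reads_group_b <- sum(reads$group == "B")

  fit <- run_stage("auc", {
    apa_test(
      reads,
      seed = as.integer(config$seed), n_bins = as.integer(config$n_bins),
      alpha = config$alpha, window = as.integer(config$smooth_window),
      min_cpm = config$min_cpm, min_span = config$min_span
    )
  })
  g <- run_stage("call-apa", {
    readr::write_tsv(fit$auc, path("auc.tsv"))
    readr::write_tsv(fit$thresholds, path("thresholds.tsv"))
    readr::write_tsv(fit$calls, path("apa_calls.tsv"))
    writeLines(utils::capture.output(print(fit)), path("summary.txt"))
    glance(fit)
  })
  counts$significant <- g$n_significant
  counts$apa_calls <- g$n_apa

  manifest <- list(
    package = "utrdiff",
    version = as.character(utils::packageVersion("utrdiff")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = config[c(
      "mode", "min_mapq", "min_cpm", "n_bins", "alpha", "smooth_window",
      "min_span", "seed"
    )],
    counts = counts
  )
  jsonlite::write_json(manifest, path("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(fit)
}
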