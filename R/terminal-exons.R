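#' Read a chromosome name mapping from an assembly report
#'
#' Sequencing-consortium annotations name chromosomes by accession
#' (e.g. \code{NC_000001.11}) while most downstream tools use plain
#' ENSEMBL-style names (\code{1}, \code{X}, \code{MT}). NCBI assembly
#' reports pair the two. Only autosomes, allosomes and the mitochondrial
#' chromosome are retained; unplaced scaffolds, patches and alternative
#' loci are dropped (with a logged count).
#'
#' @param path Path to an NCBI \code{assembly_report.txt}-style file
#'   (tab-separated, \code{#}-comment header) or a plain two-column TSV of
#'   (source accession, target name) pairs.
#' @return A tibble with columns \code{source} and \code{target}, one row per
#'   retained chromosome. The mapping is injective on the target names; a
#'   duplicated target is an error.
#' @export
read_chrom_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn("empty assembly report: chromosome map is empty")
    return(tibble::tibble(source = character(), target = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (all(ncol >= 7L)) {
    # NCBI assembly_report layout: Sequence-Name, Sequence-Role,
    # Assigned-Molecule, Location/Type, GenBank-Accn, Relationship, RefSeq-Accn
    map <- tibble::tibble(
      role = vapply(fields, `[`, "", 2L),
      target = vapply(fields, `[`, "", 3L),
      source = vapply(fields, `[`, "", 7L)
    )
    map <- dplyr::filter(map, .data$role == "assembled-molecule")
  } else if (all(ncol == 2L)) {
    map <- tibble::tibble(
      source = vapply(fields, `[`, "", 1L),
      target = vapply(fields, `[`, "", 2L)
    )
  } else {
    abort(sprintf(
      "assembly report '%s' is neither an NCBI report nor a 2-column TSV",
      path
    ))
  }
  keep <- is_allowed_chrom(map$target) & map$source != "na" & nzchar(map$source)
  log_count(sum(!keep), "sequences outside autosomes/allosomes/MT")
  map <- map[keep, c("source", "target")]
  if (anyDuplicated(map$target)) {
    abort(sprintf(
      "duplicate target chromosome names in assembly report: %s",
      paste(unique(map$target[duplicated(map$target)]), collapse = ", ")
    ))
  }
  map <- map[!duplicated(map$source), ]
  map
}

# Light GFF3 shape validation so that a truncated or non-GFF line fails with
# its line number instead of an opaque parser error downstream.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(body)) abort(sprintf("no feature lines in GFF3 '%s'", path))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9L]
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed GFF3 line %d in '%s': expected 9 tab-separated fields",
      bad[1L], path
    ))
  }
  invisible(TRUE)
}

transcript_kept <- function(accession, biotype, type) {
  # Gnomon model predictions are always excluded.
  model <- grepl("^X[MRP]_", accession)
  allowed_bio <- c(
    "protein_coding", "lncRNA", "lnc_RNA", "lincRNA",
    "long_noncoding", "antisense"
  )
  has_bio <- !is.na(biotype)
  by_bio <- has_bio & biotype %in% allowed_bio
  by_acc <- !has_bio & grepl("^N[MR]_", accession)
  # No biotype attribute and no RefSeq-style accession: fall back to the
  # feature type (toy or third-party GFFs).
  by_type <- !has_bio & !grepl("^[NX][MRP]_", accession) &
    type %in% c("mRNA", "lnc_RNA", "transcript")
  !model & (by_bio | by_acc | by_type)
}

#' Extract terminal exons from a GFF3 annotation
#'
#' For every retained transcript (protein-coding and long noncoding;
#' Gnomon model predictions with accession prefixes \code{XM_}, \code{XR_},
#' \code{XP_} are discarded) the 3'-most exon is taken: the exon with the
#' largest end on the plus strand, the smallest start on the minus strand.
#' Identical intervals arising from transcripts that share a terminal exon
#' are collapsed to a single record. Coordinates are converted from 1-based
#' inclusive GFF3 to 0-based half-open; all downstream code uses the latter.
#'
#' @param gff Path to a GFF3 file with a transcript/exon hierarchy.
#' @param chrom_map Tibble from [read_chrom_map()]; exons on chromosomes
#'   absent from the map are dropped with a logged count. \code{NULL} keeps
#'   chromosome names as-is.
#' @return Tibble of candidate terminal exons with columns \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{te_id}, \code{gene_name},
#'   not yet clustered (see [cluster_terminal_exons()]).
#' @export
extract_terminal_exons <- function(gff, chrom_map = NULL) {
  validate_gff3_lines(gff)
  gr <- rtracklayer::import(gff, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  get_attr <- function(name) {
    if (name %in% names(meta)) {
      v <- meta[[name]]
      if (is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) {
          if (length(x) == 0) NA_character_ else as.character(x[[1L]])
        }, character(1))
      }
      as.character(v)
    } else {
      rep(NA_character_, length(gr))
    }
  }
  type <- as.character(meta$type)
  id <- get_attr("ID")
  parent <- get_attr("Parent")
  is_exon <- type == "exon"
  if (!any(is_exon)) abort(sprintf("no exon features in '%s'", gff))

  # Transcript-level features are those that exons point at via Parent.
  tx_idx <- which(!is_exon & !is.na(id) & id %in% parent[is_exon])
  tx <- tibble::tibble(
    tx_id = id[tx_idx],
    type = type[tx_idx],
    accession = dplyr::coalesce(
      get_attr("transcript_id")[tx_idx], id[tx_idx]
    ),
    biotype = dplyr::coalesce(
      get_attr("transcript_biotype")[tx_idx],
      get_attr("gene_biotype")[tx_idx]
    ),
    gene_name = get_attr("gene")[tx_idx]
  )
  no_exon_tx <- setdiff(
    id[!is_exon & type %in% c("mRNA", "lnc_RNA", "transcript")], parent[is_exon]
  )
  log_count(length(no_exon_tx), "transcripts with no exon features")

  keep_tx <- tx[transcript_kept(tx$accession, tx$biotype, tx$type), ]

  ex <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr)[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    tx_id = parent[is_exon]
  )
  ex <- dplyr::inner_join(ex, keep_tx, by = "tx_id")

  if (!is.null(chrom_map)) {
    mapped <- match(ex$chrom, chrom_map$source)
    log_count(sum(is.na(mapped)), "exons on unmappable chromosomes")
    ex <- ex[!is.na(mapped), ]
    ex$chrom <- chrom_map$target[mapped[!is.na(mapped)]]
  }
  if (any(!ex$strand %in% c("+", "-"))) {
    abort("exon with undefined strand: cannot orient terminal exon")
  }

  # 3'-most exon per transcript: largest end on +, smallest start on -.
  te <- ex %>%
    dplyr::group_by(.data$tx_id) %>%
    dplyr::arrange(
      dplyr::desc(ifelse(.data$strand == "+", .data$end, -.data$start)),
      .by_group = TRUE
    ) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()

  # Collapse transcripts sharing an identical terminal exon; the id is the
  # lexicographically smallest accession so output is input-order invariant.
  te %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand) %>%
    dplyr::summarise(
      te_id = min(.data$accession),
      gene_name = if (all(is.na(.data$gene_name))) {
        NA_character_
      } else {
        min(.data$gene_name, na.rm = TRUE)
      },
      .groups = "drop"
    ) %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$start, .data$end) %>%
    dplyr::select(
      "chrom", "start", "end", "strand", "te_id", "gene_name"
    )
}

#' Cluster overlapping terminal exons and keep the longest
#'
#' Terminal exons that overlap on the same chromosome strand are grouped
#' transitively and each cluster is represented by its longest exon, so that
#' the final set is non-overlapping per strand and every read 3' end has at
#' most one owner. A length tie is broken deterministically in favour of the
#' smaller start. Exons on opposite strands never cluster together.
#'
#' @param tes Tibble of terminal exons as from [extract_terminal_exons()].
#' @return Tibble with the same columns, one row per cluster, sorted by
#'   chromosome then start.
#' @export
cluster_terminal_exons <- function(tes) {
  if (nrow(tes) == 0L) return(tes)
  gr <- GenomicRanges::GRanges(
    tes$chrom,
    IRanges::IRanges(tes$start + 1L, tes$end),
    strand = tes$strand
  )
  # min.gapwidth = 0 merges only genuinely overlapping ranges (abutting
  # exons stay separate); reduce() is strand-aware.
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, clusters)
  tes$cluster <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  tes %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::arrange(
      dplyr::desc(.data$end - .data$start), .data$start, .data$te_id,
      .by_group = TRUE
    ) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"cluster") %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$start, .data$end)
}

#' Attach gene symbols to terminal exons from a two-column table
#'
#' @param tes Terminal-exon tibble.
#' @param gene_map Path to a two-column TSV (te_id, symbol) or an equivalent
#'   data frame. Symbols mapping to more than one terminal exon are dropped
#'   with a logged count, so gene names stay unique.
#' @return `tes` with its \code{gene_name} column filled from the map.
#' @export
add_gene_names <- function(tes, gene_map) {
  if (is.character(gene_map)) {
    gene_map <- readr::read_tsv(
      gene_map,
      col_names = c("te_id", "symbol"), col_types = "cc"
    )
  } else {
    gene_map <- tibble::as_tibble(gene_map)
    names(gene_map)[1:2] <- c("te_id", "symbol")
  }
  dup <- gene_map$symbol[duplicated(gene_map$symbol)]
  log_count(
    sum(gene_map$symbol %in% dup), "gene-map rows with duplicated symbols"
  )
  gene_map <- gene_map[!gene_map$symbol %in% dup, ]
  tes$gene_name <- gene_map$symbol[match(tes$te_id, gene_map$te_id)]
  tes
}

#' Write / read terminal exons as BED6
#'
#' The BED file is 0-based half-open, sorted by chromosome then start, with
#' \code{te_id} in the name column and 0 in the score column. Reading is
#' strict: malformed lines, invalid intervals or an unsorted file are errors,
#' so a round trip is the identity.
#'
#' @param tes Terminal-exon tibble.
#' @param path Output (input) file path.
#' @return \code{write_te_bed} returns `path` invisibly; \code{read_te_bed}
#'   returns the terminal-exon tibble (with \code{gene_name} set to `NA`).
#' @export
write_te_bed <- function(tes, path) {
  tes <- dplyr::arrange(tes, chrom_rank(.data$chrom), .data$start, .data$end)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    tes$chrom, tes$start, tes$end, tes$te_id, tes$strand
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_te_bed
#' @export
read_te_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), te_id = character(), gene_name = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d in '%s'", bad[1L], path))
  }
  tes <- tibble::tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
    te_id = vapply(fields, `[`, "", 4L),
    strand = vapply(fields, `[`, "", 6L),
    gene_name = NA_character_
  )
  if (anyNA(tes$start) || anyNA(tes$end) || any(tes$start >= tes$end)) {
    abort(sprintf("invalid interval in BED file '%s'", path))
  }
  if (any(!tes$strand %in% c("+", "-"))) {
    abort(sprintf("invalid strand in BED file '%s'", path))
  }
  ord <- order(chrom_rank(tes$chrom), tes$start, tes$end)
  if (!identical(ord, seq_len(nrow(tes)))) {
    abort(sprintf("BED file '%s' is not sorted by chromosome and start", path))
  }
  dplyr::select(
    tes, "chrom", "start", "end", "strand", "te_id", "gene_name"
  )
}
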