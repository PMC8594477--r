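#' Extract deduplicated, terminal-exon-assigned read 3' ends from a BAM/SAM
#'
#' Implements the read-processing contract of the method in one pass:
#' \enumerate{
#'   \item keep mapped, primary, non-supplementary alignments with mapping
#'     quality strictly greater than \code{min_mapq} and a cell-barcode tag;
#'   \item collapse PCR/optical duplicates to one alignment per
#'     (cell barcode, UMI, gene) key — reads lacking a gene tag are keyed by
#'     (cell barcode, UMI, owning terminal exon) instead; the representative
#'     is the highest-MAPQ alignment, ties broken by leftmost position;
#'   \item take each alignment's 3'-most \emph{aligned} reference base
#'     (soft-clipped bases excluded): the rightmost base on the plus strand,
#'     the leftmost on the minus strand;
#'   \item assign the 3' end to the unique same-strand terminal exon whose
#'     half-open interval contains it; 3' ends falling in no exon are
#'     discarded.
#' }
#' Every filter logs the number of records it removes.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM, or to a SAM file
#'   (converted and indexed on the fly).
#' @param tes Terminal-exon tibble (non-overlapping per strand, as from
#'   [cluster_terminal_exons()] or [read_te_bed()]).
#' @param min_mapq Keep alignments with MAPQ strictly greater than this
#'   (default 30).
#' @param cb_tag,umi_tag,gene_tag BAM tag names for cell barcode, UMI and
#'   gene (10x conventions: CB, UB, GX).
#' @return Tibble of read 3' ends: \code{te_id}, \code{chrom}, \code{pos}
#'   (0-based genomic position of the 3'-most aligned base), \code{dist}
#'   (nt from the exon 3' end), \code{strand}, \code{barcode}, \code{umi}.
#' @export
extract_read_ends <- function(bam, tes, min_mapq = 30,
                              cb_tag = "CB", umi_tag = "UB",
                              gene_tag = "GX") {
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(
      bam, tempfile(), overwrite = TRUE, indexDestination = TRUE
    )
  } else if (!file.exists(paste0(bam, ".bai")) &&
    !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort(sprintf("BAM index not found for '%s'", bam))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("mapq"),
    tag = c(cb_tag, umi_tag, gene_tag),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(aln) == 0L) {
    warn(sprintf("no usable alignments in '%s'", bam))
  }
  meta <- S4Vectors::mcols(aln)
  rd <- tibble::tibble(
    chrom = as.character(GenomicAlignments::seqnames(aln)),
    # GAlignments start/end cover aligned reference bases only, so soft
    # clips are already excluded; convert to 0-based.
    start = GenomicAlignments::start(aln) - 1L,
    end = GenomicAlignments::end(aln), # 0-based half-open
    strand = as.character(GenomicAlignments::strand(aln)),
    mapq = meta$mapq,
    barcode = as.character(meta[[cb_tag]]),
    umi = as.character(meta[[umi_tag]]),
    gene = as.character(meta[[gene_tag]])
  )

  low_q <- is.na(rd$mapq) | rd$mapq <= min_mapq
  log_count(sum(low_q), sprintf("alignments with MAPQ <= %d", min_mapq))
  rd <- rd[!low_q, ]
  no_cb <- is.na(rd$barcode)
  log_count(sum(no_cb), "alignments without a cell barcode tag")
  rd <- rd[!no_cb, ]
  no_umi <- is.na(rd$umi)
  log_count(sum(no_umi), "alignments without a UMI tag")
  rd <- rd[!no_umi, ]

  # 3'-most aligned reference base, 0-based.
  rd$pos <- ifelse(rd$strand == "+", rd$end - 1L, rd$start)

  # Deduplicate gene-tagged reads before exon assignment; untagged reads are
  # deduplicated afterwards, keyed by their owning exon.
  has_gene <- !is.na(rd$gene)
  rd_gene <- dedup_reads(rd[has_gene, ], c("barcode", "umi", "gene"))
  rd <- dplyr::bind_rows(rd_gene, rd[!has_gene, ])

  rd <- assign_te(rd, tes)
  rd <- dplyr::bind_rows(
    rd[!is.na(rd$gene), ],
    dedup_reads(rd[is.na(rd$gene), ], c("barcode", "umi", "te_id"))
  )
  rd %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos, .data$barcode,
                   .data$umi) %>%
    dplyr::select(
      "te_id", "chrom", "pos", "dist", "strand", "barcode", "umi"
    )
}

dedup_reads <- function(rd, key) {
  if (nrow(rd) == 0L) return(rd)
  before <- nrow(rd)
  rd <- rd %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::arrange(dplyr::desc(.data$mapq), .data$pos, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
  log_count(before - nrow(rd), "duplicate reads (same barcode/UMI key)")
  rd
}

assign_te <- function(rd, tes) {
  if (nrow(rd) == 0L) {
    rd$te_id <- character(0)
    rd$dist <- integer(0)
    return(rd)
  }
  ends <- GenomicRanges::GRanges(
    rd$chrom, IRanges::IRanges(rd$pos + 1L, width = 1L), strand = rd$strand
  )
  te_gr <- GenomicRanges::GRanges(
    tes$chrom, IRanges::IRanges(tes$start + 1L, tes$end), strand = tes$strand
  )
  hits <- GenomicRanges::findOverlaps(ends, te_gr)
  rd$te_id <- NA_character_
  rd$te_id[S4Vectors::queryHits(hits)] <- tes$te_id[S4Vectors::subjectHits(hits)]
  outside <- is.na(rd$te_id)
  log_count(sum(outside), "reads whose 3' end falls in no terminal exon")
  rd <- rd[!outside, ]
  i <- match(rd$te_id, tes$te_id)
  rd$dist <- ifelse(
    rd$strand == "+", tes$end[i] - 1L - rd$pos, rd$pos - tes$start[i]
  )
  rd
}

#' Assign read 3' ends to the two cell groups being compared
#'
#' Labels each read \code{"A"} (test group, x axis of the AUC curve) or
#' \code{"B"} (reference group, y axis) via its cell barcode. In
#' \code{two_group} mode the \code{group} column of the cell table is
#' matched against the two declared labels; in \code{quasi_bulk} mode the
#' \code{condition} column is used instead, pooling all barcodes of each
#' condition regardless of cell type to emulate a bulk comparison. Barcodes
#' absent from the table (or carrying other labels) are dropped with a
#' logged count.
#'
#' @param reads Read 3'-end tibble from [extract_read_ends()] (or the
#'   synthetic generator).
#' @param cells Tibble with a \code{barcode} column plus \code{group}
#'   (two_group mode) and/or \code{condition} (quasi_bulk mode); each
#'   barcode may appear at most once.
#' @param group_a,group_b The two labels to compare; an AUC above 0.5 will
#'   mean shorter 3' UTRs in \code{group_a}.
#' @param mode \code{"two_group"} (default) or \code{"quasi_bulk"}.
#' @return The read tibble with a \code{group} column of \code{"A"}/\code{"B"};
#'   the original labels are kept as attributes \code{group_a}/\code{group_b}.
#' @export
assign_read_groups <- function(reads, cells, group_a, group_b,
                               mode = c("two_group", "quasi_bulk")) {
  mode <- match.arg(mode)
  label_col <- if (mode == "two_group") "group" else "condition"
  if (!label_col %in% names(cells)) {
    abort(sprintf("cell table lacks a '%s' column (mode '%s')", label_col, mode))
  }
  if (anyDuplicated(cells$barcode)) {
    abort("cell table assigns some barcodes to more than one group")
  }
  lab <- cells[[label_col]][match(reads$barcode, cells$barcode)]
  keep <- !is.na(lab) & lab %in% c(group_a, group_b)
  log_count(sum(!keep), "reads from unannotated or out-of-comparison barcodes")
  reads <- reads[keep, ]
  reads$group <- ifelse(lab[keep] == group_a, "A", "B")
  for (g in c("A", "B")) {
    if (!any(reads$group == g)) {
      abort(sprintf(
        "group '%s' (%s) has zero reads after barcode assignment",
        g, if (g == "A") group_a else group_b
      ))
    }
  }
  attr(reads, "group_a") <- group_a
  attr(reads, "group_b") <- group_b
  reads
}

#' Read / write a grouped 3'-end table
#'
#' Plain-TSV serialization of the grouped read set so the statistics stage
#' can be entered mid-pipeline.
#'
#' @param reads Grouped read tibble.
#' @param path File path.
#' @return `read_read_ends` returns the tibble; `write_read_ends` the path,
#'   invisibly.
#' @export
write_read_ends <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' @rdname write_read_ends
#' @export
read_read_ends <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    te_id = "c", chrom = "c", pos = "i", dist = "i", strand = "c",
    .default = "c"
  ))
}
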