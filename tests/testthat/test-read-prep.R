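# Alignment filtering, UMI deduplication and 3'-end assignment on a
# hand-written SAM against the two exons of test_tes():
#   te1 = [100, 600) on +, te2 = [1000, 1500) on -.

test_that("alignment filters: MAPQ, cell barcode, secondary, UMI", {
  sam <- write_test_sam(list(
    sam_read("keep31", 0, 596, 31, "5M", cb = "C1", ub = "U1", gx = "g1"),
    sam_read("mapq30", 0, 596, 30, "5M", cb = "C2", ub = "U2", gx = "g1"),
    sam_read("no_cb", 0, 596, 60, "5M", cb = NULL, ub = "U3", gx = "g1"),
    sam_read("secondary", 256, 596, 60, "5M", cb = "C4", ub = "U4", gx = "g1"),
    sam_read("no_umi", 0, 596, 60, "5M", cb = "C5", ub = NULL, gx = "g1")
  ))
  ends <- suppressMessages(extract_read_ends(sam, test_tes()))
  expect_equal(ends$barcode, "C1")
  expect_equal(ends$te_id, "te1")
  expect_equal(ends$pos, 599L) # 3'-most aligned base, 0-based
  expect_equal(ends$dist, 0L)
})

test_that("3' ends respect strand, soft clips and half-open containment", {
  sam <- write_test_sam(list(
    # + read whose alignment ends at 0-based 599: dist 0
    sam_read("r_end", 0, 596, 60, "5M", cb = "C1", ub = "U1", gx = "g1"),
    # + read near the exon start: 3' end 0-based 104, dist 495
    sam_read("r_start", 0, 101, 60, "5M", cb = "C1", ub = "U2", gx = "g1"),
    # soft clip excluded: aligned part is 101..105 (1-based), 3' end 104
    sam_read("r_clip", 0, 101, 60, "3S5M4S", cb = "C1", ub = "U3", gx = "g1"),
    # one base past the exon end (0-based 600): discarded
    sam_read("r_out", 0, 598, 60, "4M", cb = "C1", ub = "U4", gx = "g1"),
    # - strand: 3' end is the LEFTMOST aligned base; te2 start 1000 -> dist 0
    sam_read("r_minus", 16, 1001, 60, "8M", cb = "C1", ub = "U5", gx = "g2"),
    # - strand inside te2: 3' end 0-based 1200 -> dist 200
    sam_read("r_minus2", 16, 1201, 60, "10M", cb = "C1", ub = "U6", gx = "g2")
  ))
  ends <- suppressMessages(extract_read_ends(sam, test_tes()))
  ends <- ends[order(ends$umi), ]
  expect_false("U4" %in% ends$umi)
  expect_equal(ends$umi, c("U1", "U2", "U3", "U5", "U6"))
  expect_equal(ends$pos, c(599L, 104L, 104L, 1000L, 1200L))
  expect_equal(ends$dist, c(0L, 495L, 495L, 0L, 200L))
  # stored dist always reproducible from (pos, exon, strand)
  tes <- test_tes()
  i <- match(ends$te_id, tes$te_id)
  expect_equal(
    ends$dist,
    ifelse(ends$strand == "+", tes$end[i] - 1L - ends$pos, ends$pos - tes$start[i])
  )
})

test_that("deduplication keys on (barcode, UMI, gene) and is idempotent", {
  sam <- write_test_sam(list(
    # same CB+UMI+gene at different positions: only one survives
    sam_read("dupA", 0, 580, 60, "5M", cb = "C1", ub = "U1", gx = "g1"),
    sam_read("dupB", 0, 590, 50, "5M", cb = "C1", ub = "U1", gx = "g1"),
    # same CB+UMI but different gene: both kept
    sam_read("gene1", 0, 560, 60, "5M", cb = "C2", ub = "U2", gx = "g1"),
    sam_read("gene2", 16, 1101, 60, "5M", cb = "C2", ub = "U2", gx = "g2"),
    # unique keys: untouched
    sam_read("solo", 0, 300, 60, "5M", cb = "C3", ub = "U3", gx = "g1"),
    # no gene tag: keyed by owning exon after assignment
    sam_read("ng1", 0, 400, 60, "5M", cb = "C4", ub = "U4"),
    sam_read("ng2", 0, 410, 60, "5M", cb = "C4", ub = "U4")
  ))
  ends <- suppressMessages(extract_read_ends(sam, test_tes()))
  # dup pair: highest MAPQ representative
  expect_equal(sum(ends$barcode == "C1"), 1L)
  expect_equal(ends$pos[ends$barcode == "C1"], 583L)
  expect_equal(sum(ends$barcode == "C2"), 2L)
  expect_equal(sum(ends$barcode == "C4"), 1L)
  expect_equal(nrow(ends), 5L)

  # idempotence: rebuilding a SAM from the deduplicated reads and running
  # the extraction again changes nothing
  sam2 <- write_test_sam(purrr::pmap(
    list(ends$pos, ends$strand, ends$barcode, ends$umi, ends$te_id,
      seq_len(nrow(ends))),
    function(pos, strand, cb, ub, te, i) {
      sam_read(sprintf("redo%d", i), ifelse(strand == "+", 0, 16),
        pos + 1L, 60, "1M",
        cb = cb, ub = ub, gx = te
      )
    }
  ))
  ends2 <- suppressMessages(extract_read_ends(sam2, test_tes()))
  expect_equal(nrow(ends2), nrow(ends))
  expect_setequal(paste(ends2$te_id, ends2$dist, ends2$barcode), paste(ends$te_id, ends$dist, ends$barcode))
})

test_that("missing BAM index is a hard error", {
  sim <- simulate_apa(n_te = 5, seed = 1)
  sam <- tempfile(fileext = ".sam")
  write_sim_sam(sim, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  expect_error(extract_read_ends(bam, sim$tes), "index")
})

test_that("group assignment maps labels, drops unknown barcodes, supports quasi-bulk", {
  reads <- tibble::tibble(
    te_id = "t1", chrom = "1", pos = 0L, dist = 0L, strand = "+",
    barcode = c("b1", "b2", "b3", "b4", "b5"),
    umi = paste0("u", 1:5)
  )
  cells <- tibble::tibble(
    barcode = c("b1", "b2", "b3", "b4"),
    group = c("tumor_Tcell", "control_Tcell", "tumor_myeloid", "control_Tcell"),
    condition = c("tumor", "control", "tumor", "control")
  )
  out <- suppressMessages(
    assign_read_groups(reads, cells, "tumor_Tcell", "control_Tcell")
  )
  # b3 (other cell type) and b5 (unannotated) are dropped
  expect_equal(out$barcode, c("b1", "b2", "b4"))
  expect_equal(out$group, c("A", "B", "B"))

  qb <- suppressMessages(
    assign_read_groups(reads, cells, "tumor", "control", mode = "quasi_bulk")
  )
  expect_equal(qb$group, c("A", "B", "A", "B"))

  expect_error(
    suppressMessages(
      assign_read_groups(reads, cells, "tumor_Tcell", "no_such_label")
    ),
    "zero reads"
  )
  cells_dup <- dplyr::bind_rows(cells, cells[1, ])
  expect_error(
    assign_read_groups(reads, cells_dup, "tumor_Tcell", "control_Tcell"),
    "more than one group"
  )
})

test_that("grouped read table survives a TSV round trip", {
  sim <- simulate_apa(n_te = 10, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_read_ends(sim$reads, path)
  back <- read_read_ends(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$reads))
})
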