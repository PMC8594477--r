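test_that("chromosome map keeps only autosomes, allosomes and MT", {
  path <- write_toy_assembly_report()
  map <- suppressMessages(read_chrom_map(path))
  expect_equal(map$target[map$source == "NC_TEST.1"], "1")
  expect_equal(map$target[map$source == "NC_MT.1"], "MT")
  expect_false("NW_SCAF.1" %in% map$source)

  # plain two-column form
  p2 <- tempfile()
  writeLines(c("NC_000001.11\t1", "NT_1877.1\tKI27", "NC_000023.11\tX"), p2)
  m2 <- suppressMessages(read_chrom_map(p2))
  expect_equal(m2$target, c("1", "X"))

  # duplicated target is a hard error
  p3 <- tempfile()
  writeLines(c("NC_A\t1", "NC_B\t1"), p3)
  expect_error(suppressMessages(read_chrom_map(p3)), "duplicate")

  # empty file: empty map with a warning
  p4 <- tempfile()
  writeLines(character(0), p4)
  expect_warning(m4 <- read_chrom_map(p4), "empty")
  expect_equal(nrow(m4), 0L)
})

test_that("terminal exon extraction applies strand, model and biotype rules", {
  gff <- write_toy_gff()
  map <- suppressMessages(read_chrom_map(write_toy_assembly_report()))
  tes <- suppressMessages(extract_terminal_exons(gff, map))

  # model transcript and off-map scaffold are gone
  expect_false(any(grepl("^XM_", tes$te_id)))
  expect_false("NM_007" %in% tes$te_id)
  # identical terminal exons collapse to one record (smallest accession wins)
  expect_true("NM_001" %in% tes$te_id)
  expect_false("NM_002" %in% tes$te_id)
  # minus strand: the smallest-start exon is the 3'-most one
  nm004 <- tes[tes$te_id == "NM_004", ]
  expect_equal(c(nm004$start, nm004$end), c(1000L, 1100L))
  # lncRNA retained; GFF 1-based inclusive -> 0-based half-open
  nr <- tes[tes$te_id == "NR_001", ]
  expect_equal(c(nr$start, nr$end), c(3000L, 3200L))
  expect_equal(nrow(tes), 9L) # hand-counted pre-clustering set
})

test_that("malformed GFF3 fails with its line number", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tsrc\texon\t1\t100"), bad)
  expect_error(extract_terminal_exons(bad), "line 2")
})

test_that("clustering keeps the longest exon per overlap group", {
  gff <- write_toy_gff()
  map <- suppressMessages(read_chrom_map(write_toy_assembly_report()))
  tes <- suppressMessages(cluster_terminal_exons(extract_terminal_exons(gff, map)))
  expect_equal(
    dplyr::select(tes, -"gene_name"),
    toy_expected_tes()
  )
})

test_that("clustering is strand-aware with a deterministic length tie-break", {
  tes <- tibble::tibble(
    chrom = "1",
    start = c(100L, 150L, 100L),
    end = c(600L, 650L, 600L),
    strand = c("+", "+", "-"),
    te_id = c("a", "b", "c"),
    gene_name = NA_character_
  )
  out <- cluster_terminal_exons(tes)
  # equal lengths on +: smaller start kept; the - exon is untouched
  expect_setequal(out$te_id, c("a", "c"))

  # abutting exons do not cluster
  ab <- tibble::tibble(
    chrom = "1", start = c(100L, 200L), end = c(200L, 300L),
    strand = "+", te_id = c("x", "y"), gene_name = NA_character_
  )
  expect_equal(nrow(cluster_terminal_exons(ab)), 2L)
})

test_that("clustered terminal exons are pairwise disjoint per strand and input-order invariant", {
  gff <- write_toy_gff()
  map <- suppressMessages(read_chrom_map(write_toy_assembly_report()))
  pre <- suppressMessages(extract_terminal_exons(gff, map))
  post <- cluster_terminal_exons(pre)

  # sweep check for disjointness within (chrom, strand)
  by_cs <- split(post, paste(post$chrom, post$strand))
  for (grp in by_cs) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1L) {
      expect_true(all(grp$start[-1L] >= grp$end[-nrow(grp)]))
    }
  }
  # every output exon existed before clustering
  expect_true(all(post$te_id %in% pre$te_id))
  # permuting the input changes nothing
  for (seed in 1:3) {
    perm <- withr::with_seed(seed, pre[sample(nrow(pre)), ])
    expect_equal(cluster_terminal_exons(perm), post)
  }
})

test_that("BED6 round-trip is the identity and malformed BED errors", {
  tes <- toy_expected_tes()
  tes$gene_name <- NA_character_
  path <- tempfile(fileext = ".bed")
  write_te_bed(tes, path)
  expect_equal(
    readLines(path)[1L],
    "1\t500\t900\tNM_003\t0\t+"
  )
  expect_equal(read_te_bed(path), tes)

  # empty set -> empty file -> empty tibble
  p0 <- tempfile()
  write_te_bed(tes[0, ], p0)
  expect_equal(nrow(read_te_bed(p0)), 0L)

  unsorted <- tempfile()
  writeLines(c("1\t500\t900\ta\t0\t+", "1\t100\t200\tb\t0\t+"), unsorted)
  expect_error(read_te_bed(unsorted), "not sorted")

  bad <- tempfile()
  writeLines("1\t100\t200", bad)
  expect_error(read_te_bed(bad), "malformed")

  inverted <- tempfile()
  writeLines("1\t500\t400\ta\t0\t+", inverted)
  expect_error(read_te_bed(inverted), "invalid interval")
})

test_that("gene-name map drops duplicated symbols", {
  tes <- toy_expected_tes()
  tes$gene_name <- NA_character_
  gm <- tempfile()
  writeLines(c("NM_003\tFoo", "NM_008\tBar", "NM_010\tBar"), gm)
  out <- suppressMessages(add_gene_names(tes, gm))
  expect_equal(out$gene_name[out$te_id == "NM_003"], "Foo")
  expect_true(all(is.na(out$gene_name[out$te_id %in% c("NM_008", "NM_010")])))
})
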