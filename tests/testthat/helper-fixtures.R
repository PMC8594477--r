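# Fixtures are built in code at test time; nothing binary is stored.

# Toy GFF3: 12 transcripts exercising every extraction rule.
#   NM_001/NM_002 (gene G1, +): identical terminal exon [300,600) -> dedup
#   NM_003 (G2, +): TE [500,900), overlaps the above, longer -> kept
#   NM_004 (G3, -): two exons, TE is the *smallest-start* exon [1000,1100)
#   NM_005 (G4, -): TE [1049,1150), overlaps NM_004 on -, longer -> kept
#   NM_006 (G5, +): TE [1000,1100), overlaps NM_004 on the OPPOSITE strand
#   XM_0123 (G6, +): Gnomon model -> excluded
#   NR_001 (G7, lncRNA, -): TE [3000,3200)
#   NM_007 (G8, +): on an unplaced scaffold -> dropped by the chromosome map
#   NM_008 (G9, +): single-exon transcript, TE [4000,4600)
#   NM_009/NM_010 (G10, +): TEs [6200,6700) / [6200,6800), overlap -> longer kept
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  tx <- function(chrom, id, gene, strand, biotype, type, exons) {
    c(
      sprintf(
        "%s\tRefSeq\t%s\t%d\t%d\t.\t%s\t.\tID=rna-%s;transcript_id=%s;gene=%s;gene_biotype=%s",
        chrom, type, min(vapply(exons, `[`, 0, 1L)),
        max(vapply(exons, `[`, 0, 2L)), strand, id, id, gene, biotype
      ),
      vapply(exons, function(e) {
        sprintf(
          "%s\tRefSeq\texon\t%d\t%d\t.\t%s\t.\tParent=rna-%s",
          chrom, e[1L], e[2L], strand, id
        )
      }, character(1))
    )
  }
  pc <- "protein_coding"
  lines <- c(
    "##gff-version 3",
    tx("NC_TEST.1", "NM_001", "G1", "+", pc, "mRNA", list(c(101, 200), c(301, 600))),
    tx("NC_TEST.1", "NM_002", "G1", "+", pc, "mRNA", list(c(121, 200), c(301, 600))),
    tx("NC_TEST.1", "NM_003", "G2", "+", pc, "mRNA", list(c(501, 900))),
    tx("NC_TEST.1", "NM_004", "G3", "-", pc, "mRNA", list(c(1001, 1100), c(1201, 1300))),
    tx("NC_TEST.1", "NM_005", "G4", "-", pc, "mRNA", list(c(1050, 1150), c(1251, 1350))),
    tx("NC_TEST.1", "NM_006", "G5", "+", pc, "mRNA", list(c(1001, 1100))),
    tx("NC_TEST.1", "XM_0123", "G6", "+", pc, "mRNA", list(c(2001, 2500))),
    tx("NC_TEST.1", "NR_001", "G7", "-", "lncRNA", "lnc_RNA", list(c(3001, 3200), c(3401, 3600))),
    tx("NW_SCAF.1", "NM_007", "G8", "+", pc, "mRNA", list(c(5001, 5400))),
    tx("NC_TEST.1", "NM_008", "G9", "+", pc, "mRNA", list(c(4001, 4600))),
    tx("NC_TEST.1", "NM_009", "G10", "+", pc, "mRNA", list(c(6001, 6100), c(6201, 6700))),
    tx("NC_TEST.1", "NM_010", "G10", "+", pc, "mRNA", list(c(6001, 6100), c(6201, 6800)))
  )
  writeLines(lines, path)
  path
}

# The hand-counted terminal exon set for the toy GFF after clustering.
toy_expected_tes <- function() {
  tibble::tibble(
    chrom = "1",
    start = c(500L, 1000L, 1049L, 3000L, 4000L, 6200L),
    end = c(900L, 1100L, 1150L, 3200L, 4600L, 6800L),
    strand = c("+", "+", "-", "-", "+", "+"),
    te_id = c("NM_003", "NM_006", "NM_005", "NR_001", "NM_008", "NM_010")
  )
}

write_toy_assembly_report <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "# Assembly name: TOY1.0",
    "# Sequence-Name\tSequence-Role\tAssigned-Molecule\tAssigned-Molecule-Location/Type\tGenBank-Accn\tRelationship\tRefSeq-Accn\tAssembly-Unit\tSequence-Length\tUCSC-style-name",
    "1\tassembled-molecule\t1\tChromosome\tCM0001.1\t=\tNC_TEST.1\tPrimary Assembly\t10000\tchr1",
    "MT\tassembled-molecule\tMT\tMitochondrion\tAY0001.1\t=\tNC_MT.1\tnon-nuclear\t16299\tchrM",
    "Scaf1\tunplaced-scaffold\tna\tna\tKB0001.1\t=\tNW_SCAF.1\tPrimary Assembly\t5000\tna"
  ), path)
  path
}

# Minimal SAM writer for read-prep tests. Each record is a list/vector of
# (qname, flag, pos1, mapq, cigar, tags...).
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           chrom = "1", chrom_len = 10000L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(records, function(r) {
    paste(c(
      r$qname, r$flag, chrom, r$pos1, r$mapq, r$cigar,
      "*", 0, 0, "*", "*", r$tags
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

sam_read <- function(qname, flag, pos1, mapq, cigar, cb = "ACGT-1",
                     ub = "UMI1", gx = NULL) {
  tags <- c(
    if (!is.null(cb)) sprintf("CB:Z:%s", cb),
    if (!is.null(ub)) sprintf("UB:Z:%s", ub),
    if (!is.null(gx)) sprintf("GX:Z:%s", gx)
  )
  list(qname = qname, flag = flag, pos1 = pos1, mapq = mapq, cigar = cigar, tags = tags)
}

# Two disjoint terminal exons used by the read-prep tests.
test_tes <- function() {
  tibble::tibble(
    chrom = "1", start = c(100L, 1000L), end = c(600L, 1500L),
    strand = c("+", "-"), te_id = c("te1", "te2"),
    gene_name = c("g1", "g2")
  )
}

# Independent pairwise (Mann-Whitney half-credit) oracle for the AUC.
auc_pairwise_oracle <- function(dist_a, dist_b) {
  cmp <- outer(dist_b, dist_a, function(b, a) (b < a) + 0.5 * (b == a))
  mean(cmp)
}
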