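test_that("read_fasta reads single and multi-line records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "MSTLV",
               ">g2", "MSTL", "VKVA"), f)
  rec <- read_fasta(f, molecule = "protein")
  expect_equal(rec$id, c("g1", "g2"))
  expect_equal(rec$molecule, c("protein", "protein"))
  expect_equal(rec$residues, c("MSTLV", "MSTLVKVA"))
})

test_that("read_fasta upper-cases and auto-detects molecule type", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dna1", "acgtacgt", ">prot1", "mstlv"), f)
  rec <- read_fasta(f)
  expect_equal(rec$residues, c("ACGTACGT", "MSTLV"))
  expect_equal(rec$molecule, c("cds", "protein"))
})

test_that("read_fasta rejects duplicate ids and illegal residues", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "MST", ">g1", "MST"), f)
  expect_error(read_fasta(f), "duplicate FASTA id: g1")
  writeLines(c(">g1", "MSTZ"), f)
  expect_error(read_fasta(f, molecule = "protein"), "illegal protein.*g1")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  expect_error(read_fasta(file.path(tempdir(), "no_such.fa")), "not found")
})

test_that("FASTA write/read round trip is the identity on records", {
  recs <- data.frame(id = c("a", "b"),
                     residues = c(strrep("MKLV", 40), "M"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f, molecule = "protein")
  expect_equal(back$id, recs$id)
  expect_equal(back$residues, recs$residues)
})

test_that("read_gff3 parses genes and links CDS directly and via mRNA", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\tCDS\t1000\t1500\t.\t+\t0\tID=gA.c1;Parent=gA.t1",
    "chr2\tsrc\tgene\t50\t80\t.\t-\t.\tID=gB",
    "chr2\tsrc\tCDS\t50\t80\t.\t-\t0\tID=gB.c1;Parent=gB"), f)
  gm <- read_gff3(f)
  gm <- gm[order(gm$gene_id), ]
  expect_equal(gm$gene_id, c("gA", "gB"))
  expect_equal(gm$start, c(1000L, 50L))
  expect_equal(gm$end, c(2000L, 80L))
  expect_equal(gm$strand, c("+", "-"))
  expect_equal(gm$cds_ids[[1]], "gA.c1")
  expect_equal(gm$cds_ids[[2]], "gB.c1")
})

test_that("read_gff3 flags malformed input with the line number", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t10\t20\t.\t+\t."), f)
  expect_error(read_gff3(f), "line 2.*expected 9 columns")
  writeLines("chr1\tsrc\tgene\t30\t20\t.\t+\t.\tID=g1", f)
  expect_error(read_gff3(f), "invalid coordinates on GFF3 line 1")
  writeLines("chr1\tsrc\tgene\t10\t20\t.\t?\t.\tID=g1", f)
  expect_error(read_gff3(f), "unknown strand")
})

test_that("read_gff3 warns about genes without CDS children", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tgene\t10\t20\t.\t+\t.\tID=lonely", f)
  expect_warning(gm <- read_gff3(f), "without CDS children: lonely")
  expect_equal(length(gm$cds_ids[[1]]), 0L)
})

test_that("read_collinearity_blocks groups anchors and rejects self-pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("b1\tg1\tg2", "b2\tg5\tg6", "b1\tg3\tg4"), f)
  blocks <- read_collinearity_blocks(f)
  expect_equal(blocks$block_id, c("b1", "b1", "b2"))
  expect_equal(blocks$gene_a[blocks$block_id == "b1"], c("g1", "g3"))
  writeLines(character(0), f)
  expect_equal(nrow(read_collinearity_blocks(f)), 0L)
  writeLines("b1\tg1\tg1", f)
  expect_error(read_collinearity_blocks(f), "self-pair")
})

test_that("fixture tables match the printed values", {
  tabs <- load_fixture_tables()
  expect_equal(nrow(tabs$table1), 17L)
  expect_equal(nrow(tabs$table2), 10L)
  expect_equal(nrow(tabs$table3), 16L)
  gm <- tabs$table1[tabs$table1$species == "Glycine max", ]
  expect_equal(gm$predicted_loci, 56044)
  expect_equal(gm$aux_iaa_count, 63)
  pa <- tabs$table2[tabs$table2$species == "Picea abies", ]
  expect_equal(pa$ka, 4.3721)
  expect_equal(pa$ks, 2.6149)
  expect_equal(pa$ka_ks, 1.6720)
  expect_equal(pa$duplication_type, "tandem")
  pp <- tabs$table3[tabs$table3$species == "Physcomitrella patens", ]
  expect_equal(pp$sv40_intact, 2L)
})

test_that("consensus motif fixtures hold the five patterns", {
  tab <- load_consensus_motifs()
  expect_equal(tab$motif_id, paste0("m", 1:5))
  expect_equal(tab$pattern[tab$motif_id == "m3"], "VGWPPV")
  expect_equal(tab$pattern[tab$motif_id == "m5"], "LxLxLx")
})
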