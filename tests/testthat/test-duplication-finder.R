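.toy_models <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chromosome = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 12000L, 200000L, 5000L),
    end = c(2000L, 13000L, 201000L, 6000L),
    strand = "+", stringsAsFactors = FALSE)
}

.toy_proteins <- function() {
  base <- strrep("MKLVEQWPHD", 5)
  variant <- paste0(substr(base, 1, 45), "AAAAA")  # 90% identical
  unrelated <- strrep("CYFNSTCYFN", 5)
  c(g1 = base, g2 = variant, g3 = base, g4 = base)
}

test_that("tandem pairs respect the distance and identity thresholds", {
  pairs <- find_tandem_pairs(.toy_models(), .toy_proteins())
  # g1-g2: 10 kb apart, 90% identity -> tandem; g3 is 187 kb away; g4 is on
  # another chromosome
  expect_equal(nrow(pairs), 1L)
  expect_equal(c(pairs$gene_a, pairs$gene_b), c("g1", "g2"))
  expect_equal(pairs$distance_bp, 10000L)
  expect_gt(pairs$identity_pct, 50)
  expect_equal(pairs$classification, "tandem")
})

test_that("the distance cap is inclusive and identity strictly above", {
  gm <- .toy_models()[1:2, ]
  gm$start <- c(1000L, 52000L)
  gm$end <- c(2000L, 53000L)  # nearest-boundary distance exactly 50000
  prots <- .toy_proteins()[1:2]
  expect_equal(nrow(find_tandem_pairs(gm, prots)), 1L)
  gm$start[2] <- 52001L  # distance 50001: over the cap
  expect_equal(nrow(find_tandem_pairs(gm, prots)), 0L)
  # identical coordinates but unrelated proteins: identity below threshold
  gm$start[2] <- 3000L
  gm$end[2] <- 4000L
  prots[2] <- strrep("CYFNSTCYFN", 5)
  expect_equal(nrow(find_tandem_pairs(gm, prots)), 0L)
})

test_that("overlapping genes have distance zero", {
  gm <- .toy_models()[1:2, ]
  gm$start <- c(1000L, 1500L)
  gm$end <- c(2000L, 2500L)
  pairs <- find_tandem_pairs(gm, .toy_proteins()[1:2])
  expect_equal(pairs$distance_bp, 0L)
})

test_that("a missing protein sequence is an error", {
  expect_error(find_tandem_pairs(.toy_models(), .toy_proteins()[1:3]),
               "without a protein sequence: g4")
})

test_that("assign_segmental overlays block anchors onto tandem calls", {
  tandem <- data.frame(gene_a = c("g1", "g5"), gene_b = c("g2", "g6"),
                       identity_pct = c(90, 80), distance_bp = c(100L, 5L),
                       classification = "tandem", stringsAsFactors = FALSE)
  blocks <- data.frame(block_id = c("b1", "b1"),
                       gene_a = c("g1", "g7"), gene_b = c("g2", "g8"),
                       stringsAsFactors = FALSE)
  out <- assign_segmental(tandem, blocks)
  cls <- setNames(out$classification, paste(out$gene_a, out$gene_b))
  expect_equal(unname(cls["g1 g2"]), "both")
  expect_equal(unname(cls["g5 g6"]), "tandem")
  expect_equal(unname(cls["g7 g8"]), "segmental")
  # anchor order within a pair is irrelevant
  rev_blocks <- data.frame(block_id = "b2", gene_a = "g2", gene_b = "g1",
                           stringsAsFactors = FALSE)
  out2 <- assign_segmental(tandem, rev_blocks)
  expect_equal(out2$classification[out2$gene_a == "g1"], "both")
})

test_that("pairs matching no rule become unlinked, empty inputs work", {
  universe <- data.frame(gene_a = "gX", gene_b = "gY",
                         stringsAsFactors = FALSE)
  out <- assign_segmental(universe, data.frame(block_id = character(),
                                               gene_a = character(),
                                               gene_b = character()))
  expect_equal(out$classification, "unlinked")
  out0 <- assign_segmental(NULL, data.frame(block_id = "b", gene_a = "p",
                                            gene_b = "q"))
  expect_equal(out0$classification, "segmental")
})

test_that("duplication_summary reports gene-level counts and 2-dp percents", {
  pairs <- data.frame(
    gene_a = c("a1", "a3", "a1"),
    gene_b = c("a2", "a4", "a3"),
    classification = c("tandem", "segmental", "both"),
    stringsAsFactors = FALSE)
  universe <- paste0("a", 1:5)
  species_of <- setNames(rep("sp1", 5), universe)
  s <- duplication_summary(pairs, universe, species_of)
  # segmental-or-both genes: a3, a4, a1; tandem-or-both: a1, a2, a3
  expect_equal(s$seg, 3L)
  expect_equal(s$tan, 3L)
  expect_equal(s$seg_and_tan, 2L)
  expect_equal(s$seg_pct, 60)
  expect_equal(s$seg_and_tan_pct, 40)
  expect_error(duplication_summary(pairs, c(universe, "zz"), species_of),
               "not mapped")
})
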