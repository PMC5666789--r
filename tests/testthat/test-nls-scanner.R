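test_that("match_nls distinguishes intact, degenerated and lack", {
  pats <- nls_patterns()
  p2 <- pats$bipartite_part2  # RxxRK, basic positions 1, 4, 5
  expect_equal(match_nls("AARQQRKAA", p2)$status, "intact")
  expect_equal(match_nls("AARQQRKAA", p2)$window_start, 3L)
  expect_equal(match_nls("AARQQRKAA", p2)$matched, "RQQRK")
  # one basic-position substitution -> degenerated
  expect_equal(match_nls("AACQQRKAA", p2)$status, "degenerated")
  # substitution at a non-basic position only is not a placement at all
  # (wildcards make non-basic positions free, so craft two basic misses)
  expect_equal(match_nls("AACQQRCAA", p2)$status, "lack")
  expect_equal(match_nls("", p2)$status, "lack")
  expect_equal(match_nls("RK", p2)$status, "lack")
})

test_that("intact placements take precedence and ties go leftmost", {
  p1 <- nls_patterns()$bipartite_part1  # KR
  r <- match_nls("AKAKRA", p1)
  expect_equal(r$status, "intact")
  expect_equal(r$window_start, 4L)
  # no intact anywhere: leftmost degenerated wins
  r2 <- match_nls("AKAKGA", p1, window_offset = 10L)
  expect_equal(r2$status, "degenerated")
  expect_equal(r2$window_start, 11L)
})

test_that("SV40 pattern requires exactly one basic substitution", {
  sv <- nls_patterns()$sv40  # KRxRxxK, basic 1, 2, 4, 7
  expect_equal(match_nls("KRARAAK", sv)$status, "intact")
  expect_equal(match_nls("KRARAAQ", sv)$status, "degenerated")
  expect_equal(match_nls("KAARAAQ", sv)$status, "lack")
})

test_that("search windows anchor on motifs and fall back to thirds", {
  prot <- paste0("LALALA", strrep("S", 10), "VGWPPV", strrep("S", 10),
                 "VKVAM", strrep("S", 10), "KRARAAK", strrep("S", 10),
                 "GDVPW")
  prof <- call_presence(prot)
  w <- locate_search_windows(prot, prof)
  # Part 1 sits strictly between motif 5 and motif 3
  expect_equal(w$bipartite_part1$start, 7L)
  expect_equal(w$bipartite_part1$end, 16L)
  expect_equal(w$bipartite_part1$window, strrep("S", 10))
  # Part 2 is motif 3 +/- 10
  expect_equal(w$bipartite_part2$start, 17L - 10L)
  expect_equal(w$bipartite_part2$end, 22L + 10L)
  # fallbacks: a motif-free protein splits into thirds
  bare <- strrep("S", 30)
  wb <- locate_search_windows(bare, call_presence(bare))
  expect_equal(c(wb$bipartite_part1$start, wb$bipartite_part1$end), c(1L, 10L))
  expect_equal(c(wb$bipartite_part2$start, wb$bipartite_part2$end), c(11L, 20L))
  expect_equal(c(wb$sv40$start, wb$sv40$end), c(21L, 30L))
})

test_that("species variant tagging detects the primordial forms", {
  expect_equal(detect_species_variants("AAQTTRKAA")$variant_tag, "QxxRK")
  expect_equal(detect_species_variants("AKAANKAA")$variant_tag, "KxxNK")
  expect_true(is.na(detect_species_variants("AAAAA")$variant_tag))
  expect_equal(detect_species_variants("AQTTRK", "moss")$species, "moss")
})

test_that("scan_nls reports all three categories for a planted protein", {
  plan <- data.frame(id = "p1", m1 = TRUE, m2 = TRUE, m3 = TRUE, m4 = TRUE,
                     m5 = TRUE, part1 = "intact", part2 = "degenerated",
                     sv40 = "intact", stringsAsFactors = FALSE)
  prot <- plant_motifs_and_nls(plan, seed = 21)$residues
  rep <- scan_nls(prot, sequence_id = "p1")
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$status[rep$category == "bipartite_part1"], "intact")
  expect_equal(rep$status[rep$category == "bipartite_part2"], "degenerated")
  expect_equal(rep$status[rep$category == "sv40"], "intact")
  expect_true(all(rep$sequence_id == "p1"))
})

test_that("aggregate_species conserves counts and rejects unmapped ids", {
  plan <- data.frame(
    id = c("a1", "a2", "b1"),
    m1 = TRUE, m2 = TRUE, m3 = TRUE, m4 = c(TRUE, FALSE, TRUE), m5 = TRUE,
    part1 = c("intact", "lack", "degenerated"),
    part2 = c("intact", "intact", "lack"),
    sv40 = c("intact", "lack", "degenerated"),
    stringsAsFactors = FALSE)
  prots <- plant_motifs_and_nls(plan, seed = 31)
  reports <- do.call(rbind, lapply(seq_len(nrow(prots)), function(i) {
    scan_nls(prots$residues[i], sequence_id = prots$id[i])
  }))
  species_of <- c(a1 = "spA", a2 = "spA", b1 = "spB")
  agg <- aggregate_species(reports, species_of)
  expect_true(all(agg$summary$intact + agg$summary$degenerated +
                    agg$summary$lack == agg$summary$n))
  spA_p1 <- agg$summary[agg$summary$species == "spA" &
                          agg$summary$category == "bipartite_part1", ]
  expect_equal(spA_p1$intact, 1L)
  expect_equal(spA_p1$lack, 1L)
  expect_equal(agg$overall$pct_intact + agg$overall$pct_degenerated +
                 agg$overall$pct_lack, rep(100, 3))
  expect_error(aggregate_species(reports, c(a1 = "spA")), "not mapped")
})
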