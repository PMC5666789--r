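test_that("consensus scanning finds exact and one-mismatch hits", {
  m3 <- consensus_pattern("m3", "VGWPPV")
  hits <- scan_motif("AAAVGWPPVAAA", m3)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 4L)
  expect_equal(hits$matched, "VGWPPV")
  expect_equal(hits$score, 6)
  # one substitution still matches, with a lower score
  one <- scan_motif("AAAVGWPAVAAA", m3)
  expect_equal(one$score, 5)
  # two substitutions do not
  expect_equal(nrow(scan_motif("AAAVGAPAVAAA", m3)), 0L)
})

test_that("wildcard positions are free and never scored", {
  m5 <- consensus_pattern("m5", "LxLxLx")
  hits <- scan_motif("LALALA", m5)
  expect_equal(hits$score[1], 3)
  # mismatch at a non-wildcard position plus wildcards: still a hit
  expect_equal(nrow(scan_motif("AALALA", m5)) >= 1, TRUE)
})

test_that("scanning a protein shorter than the model is empty", {
  expect_equal(nrow(scan_motif("VG", consensus_pattern("m3", "VGWPPV"))), 0L)
})

test_that("consensus scanning agrees with a brute-force window check", {
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pat <- "KRxRxxK"
  model <- consensus_pattern("m4", pat)
  p <- strsplit(pat, "")[[1]]
  fixed <- which(p != "x")
  for (rep in 1:20) {
    prot <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    chars <- strsplit(prot, "")[[1]]
    expected <- which(vapply(seq_len(40 - 7 + 1), function(s) {
      sum(chars[s + fixed - 1] != p[fixed]) <= 1
    }, logical(1)))
    expect_equal(scan_motif(prot, model)$start, expected)
  }
})

test_that("call_presence keeps the best hit per motif", {
  prot <- paste0("LALALA", strrep("S", 10), "VGWPPV", strrep("S", 10),
                 "VKVAM", strrep("S", 10), "KRARAAK", strrep("S", 10),
                 "GDVPW")
  prof <- call_presence(prot, sequence_id = "p1")
  expect_s3_class(prof, "motif_profile")
  expect_true(all(prof$present))
  expect_equal(prof$hits$m3$matched, "VGWPPV")
  expect_equal(prof$sequence_id, "p1")
  none <- call_presence(strrep("S", 60))
  expect_false(any(none$present))
  expect_error(call_presence("AAAA", models = list()), "all five motifs")
})

test_that("PWM scanning thresholds on the fraction of the maximum score", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg <- setNames(rep(1 / 20, 20), aa)
  mat <- matrix(0.01 / 19, nrow = 3, ncol = 20, dimnames = list(NULL, aa))
  mat[1, "W"] <- 0.99
  mat[2, "P"] <- 0.99
  mat[3, "W"] <- 0.99
  mat[, setdiff(aa, c("W", "P"))] <-
    (1 - rowSums(mat[, c("W", "P")])) / 18
  pwm <- structure(list(motif_id = "mx", width = 3L, mat = mat, bg = bg),
                   class = "pwm")
  hits <- scan_motif("AAWPWAA", pwm, threshold_fraction = 0.9)
  expect_equal(hits$start, 3L)
  expect_equal(hits$matched, "WPW")
  # a weaker window passes only at a lower threshold
  expect_equal(nrow(scan_motif("AAWPAAA", pwm, threshold_fraction = 0.9)), 0L)
  expect_gt(nrow(scan_motif("AAWPAAA", pwm, threshold_fraction = 0.15)), 0L)
  expect_error(scan_motif("AAA", pwm, threshold_fraction = 0), "threshold_fraction")
})

test_that("ZOOPS discovery recovers a planted motif and is deterministic", {
  set.seed(1)
  sterile <- strsplit("ACEFHINQSTY", "")[[1]]
  planted <- "WGWDMG"
  prots <- vapply(1:8, function(i) {
    left <- paste(sample(sterile, 15, replace = TRUE), collapse = "")
    right <- paste(sample(sterile, 15, replace = TRUE), collapse = "")
    paste0(left, planted, right)
  }, character(1))
  fit1 <- discover_motifs_zoops(prots, n_motifs = 1, width_min = 6,
                                width_max = 6, seed = 4)
  expect_equal(length(fit1), 1L)
  expect_equal(fit1[[1]]$consensus, planted)
  expect_gt(fit1[[1]]$gamma, 0.9)
  expect_equal(rowSums(fit1[[1]]$mat), rep(1, 6), tolerance = 1e-9)
  fit2 <- discover_motifs_zoops(prots, n_motifs = 1, width_min = 6,
                                width_max = 6, seed = 4)
  expect_identical(fit1[[1]]$mat, fit2[[1]]$mat)
})

test_that("ZOOPS discovery masks found sites before the next motif", {
  set.seed(2)
  sterile <- strsplit("ACEFHINQSTY", "")[[1]]
  m_a <- "WWGGWW"
  m_b <- "DMDKDM"
  prots <- vapply(1:8, function(i) {
    paste0(paste(sample(sterile, 12, replace = TRUE), collapse = ""), m_a,
           paste(sample(sterile, 12, replace = TRUE), collapse = ""), m_b,
           paste(sample(sterile, 12, replace = TRUE), collapse = ""))
  }, character(1))
  fits <- discover_motifs_zoops(prots, n_motifs = 2, width_min = 6,
                                width_max = 6, seed = 9)
  expect_equal(length(fits), 2L)
  # EM may lock onto a planted site shifted by a couple of positions, so
  # require each planted motif to dominate a different discovered
  # consensus (>= 4 of 6 aligned letters at some small offset): masking
  # must prevent the second round from rediscovering the first motif
  overlap <- function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    max(vapply(-3:3, function(off) {
      ia <- seq_along(ca)
      ib <- ia + off
      ok <- ib >= 1 & ib <= length(cb)
      sum(ca[ia[ok]] == cb[ib[ok]])
    }, numeric(1)))
  }
  found <- vapply(fits, `[[`, character(1), "consensus")
  claimed <- vapply(c(m_a, m_b), function(m) {
    which.max(vapply(found, overlap, numeric(1), b = m))
  }, integer(1))
  expect_setequal(claimed, 1:2)
  for (m in c(m_a, m_b)) {
    expect_gte(max(vapply(found, overlap, numeric(1), b = m)), 4)
  }
})

test_that("discovery validates its inputs", {
  expect_error(discover_motifs_zoops(c("AAA", "CCC")), "at least 5")
  expect_error(discover_motifs_zoops(rep("ACE", 6), width_min = 6),
               "shorter than width_min")
})

test_that("package randomness does not disturb the global RNG", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(discover_motifs_zoops(
    vapply(1:6, function(i) strrep("ACEFHINQSTY", 2), character(1)),
    n_motifs = 1, width_min = 6, width_max = 6, seed = 7))
  expect_identical(runif(3), expected)
})
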