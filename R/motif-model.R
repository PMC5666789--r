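# Motif discovery and scanning.
#
# Two motif representations are supported: consensus patterns with an 'x'
# wildcard (the packaged anchors for the five family motifs) and position
# weight matrices fitted by a ZOOPS (zero-or-one-occurrence-per-sequence)
# expectation-maximization, a deliberately compact re-implementation of the
# classic EM motif-discovery scheme.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a consensus pattern model
#'
#' @param motif_id Identifier (e.g. `"m3"`).
#' @param pattern String over amino-acid letters plus the wildcard `x`
#'   (length >= 2).
#' @return An object of class `consensus_pattern`.
#' @export
consensus_pattern <- function(motif_id, pattern) {
  if (nchar(pattern) < 2L) stop("consensus pattern must have length >= 2")
  structure(list(motif_id = motif_id, pattern = pattern),
            class = "consensus_pattern")
}

#' The packaged consensus models for motifs 1-5
#'
#' @return Named list of [consensus_pattern] objects (`m1`..`m5`).
#' @export
consensus_models <- function() {
  tab <- load_consensus_motifs()
  models <- lapply(seq_len(nrow(tab)), function(i) {
    consensus_pattern(tab$motif_id[i], tab$pattern[i])
  })
  names(models) <- tab$motif_id
  models
}

.model_width <- function(model) {
  if (inherits(model, "consensus_pattern")) nchar(model$pattern)
  else if (inherits(model, "pwm")) model$width
  else stop("model must be a consensus_pattern or pwm")
}

#' Scan a protein with a motif model
#'
#' For a [consensus_pattern], every window matching the pattern with at most
#' one mismatch at non-wildcard positions is a hit (score = number of
#' matching non-wildcard positions). For a PWM, every window whose log-odds
#' score (bits, against the PWM's background) reaches
#' `threshold_fraction` times the maximum attainable score is a hit.
#' Proteins shorter than the model width yield an empty hit list.
#'
#' @param protein A protein string.
#' @param model A `consensus_pattern` or `pwm`.
#' @param threshold_fraction Fraction of the maximum attainable PWM score
#'   required for a hit, in (0, 1]. Ignored for consensus patterns.
#' @param sequence_id Optional id recorded in the hit table.
#' @return data.frame with columns `sequence_id`, `motif_id`, `start`
#'   (1-based), `matched`, `score`, sorted by position.
#' @export
scan_motif <- function(protein, model, threshold_fraction = 0.6,
                       sequence_id = NA_character_) {
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]")
  }
  protein <- toupper(protein)
  w <- .model_width(model)
  empty <- data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), matched = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  L <- nchar(protein)
  if (L < w) return(empty)
  chars <- strsplit(protein, "")[[1]]
  starts <- seq_len(L - w + 1L)

  if (inherits(model, "consensus_pattern")) {
    pat <- strsplit(model$pattern, "")[[1]]
    fixed <- which(pat != "x")
    score <- vapply(starts, function(s) {
      sum(chars[s + fixed - 1L] == pat[fixed])
    }, numeric(1))
    hit <- score >= length(fixed) - 1L
  } else {
    lo <- log2(model$mat / rep(model$bg[colnames(model$mat)],
                               each = nrow(model$mat)))
    idx <- match(chars, colnames(model$mat))
    score <- vapply(starts, function(s) {
      cols <- idx[s:(s + w - 1L)]
      if (anyNA(cols)) return(-Inf)
      sum(lo[cbind(seq_len(w), cols)])
    }, numeric(1))
    hit <- score >= threshold_fraction * sum(apply(lo, 1, max))
  }
  if (!any(hit)) return(empty)
  s <- starts[hit]
  data.frame(sequence_id = sequence_id, motif_id = model$motif_id,
             start = s, matched = substring(protein, s, s + w - 1L),
             score = score[hit], stringsAsFactors = FALSE)
}

#' Per-protein motif presence profile
#'
#' Scans a protein with models for all five motifs and records, per motif,
#' whether at least one hit exists; the best-scoring hit (leftmost on ties)
#' is kept as the representative occurrence.
#'
#' @param protein Protein string.
#' @param models Named list of models covering `m1`..`m5`; defaults to the
#'   packaged consensus patterns.
#' @param threshold_fraction Passed to [scan_motif()] for PWM models.
#' @param sequence_id Optional id.
#' @return Object of class `motif_profile`: list with `sequence_id`,
#'   `present` (named logical, `m1`..`m5`) and `hits` (named list of
#'   one-row hit data.frames or `NULL`).
#' @export
call_presence <- function(protein, models = consensus_models(),
                          threshold_fraction = 0.6,
                          sequence_id = NA_character_) {
  motif_ids <- paste0("m", 1:5)
  if (!all(motif_ids %in% names(models))) {
    stop("models must cover all five motifs m1..m5")
  }
  hits <- lapply(motif_ids, function(m) {
    h <- scan_motif(protein, models[[m]], threshold_fraction, sequence_id)
    if (nrow(h) == 0L) NULL else h[which.max(h$score), , drop = FALSE]
  })
  names(hits) <- motif_ids
  structure(list(
    sequence_id = sequence_id,
    present = vapply(hits, Negate(is.null), logical(1)),
    hits = hits
  ), class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("motif profile", if (!is.na(x$sequence_id)) x$sequence_id else "",
      ":", paste(names(x$present)[x$present], collapse = " "), "\n")
  invisible(x)
}

# ---- ZOOPS EM discovery -------------------------------------------------

.as_protein_vector <- function(proteins) {
  if (is.data.frame(proteins)) {
    setNames(proteins$residues, proteins$id)
  } else {
    p <- as.character(proteins)
    names(p) <- names(proteins)
    if (is.null(names(p))) names(p) <- paste0("seq", seq_along(p))
    p
  }
}

#' Discover motifs by ZOOPS expectation-maximization
#'
#' Fits up to `n_motifs` position weight matrices to a protein set under a
#' zero-or-one-occurrence-per-sequence model: each sequence carries a motif
#' site with probability `gamma` at a uniform position. Candidate widths
#' are scanned on a grid and the width maximizing (information content per
#' column) x (expected number of sites) is kept. EM is seeded from actual
#' subsequences of the input (a deterministic sample controlled by `seed`),
#' run until the log-likelihood gain drops below `tol` (at most `max_iter`
#' iterations; the likelihood is asserted to be non-decreasing), and the
#' best site per sequence is masked before the next motif is sought.
#'
#' @param proteins Character vector (optionally named) or a data.frame from
#'   [read_fasta()]; at least 5 sequences, each at least `width_min` long.
#' @param n_motifs Maximum number of motifs to extract.
#' @param width_min,width_max Width bounds (the grid steps by `width_step`).
#' @param seed Integer seed; discovery is deterministic given the seed.
#' @param width_step Grid step for candidate widths.
#' @param pseudocount Flat pseudocount added to PWM counts.
#' @param n_seeds Number of seed subsequences tried per width.
#' @param max_iter,tol EM stopping controls.
#' @return List of `pwm` objects (elements: `motif_id`, `width`, `mat`
#'   (width x 20 probability matrix), `pseudocount`, `bg`, `gamma`,
#'   `consensus`, `loglik`).
#' @export
discover_motifs_zoops <- function(proteins, n_motifs = 5L, width_min = 6L,
                                  width_max = 50L, seed = 1L,
                                  width_step = 2L, pseudocount = 0.01,
                                  n_seeds = 20L, max_iter = 200L,
                                  tol = 1e-6) {
  prots <- .as_protein_vector(proteins)
  if (length(prots) < 5L) stop("ZOOPS discovery needs at least 5 sequences")
  if (all(nchar(prots) < width_min)) {
    stop("all sequences are shorter than width_min (", width_min, ")")
  }
  seqs <- lapply(strsplit(toupper(prots), ""), function(ch) {
    match(ch, .AA20) # NA for X / unknowns: excluded from windows and counts
  })
  res_counts <- table(factor(unlist(lapply(seqs, function(s) s[!is.na(s)])),
                             levels = seq_along(.AA20)))
  bg <- setNames(as.numeric(res_counts + 1) / sum(res_counts + 1), .AA20)

  rng <- .new_rng(seed)
  widths <- seq(width_min, min(width_max, max(nchar(prots))), by = width_step)
  out <- list()
  for (k in seq_len(n_motifs)) {
    best <- NULL
    for (w in widths) {
      fit <- .zoops_em_fit(seqs, w, bg, pseudocount, n_seeds, max_iter, tol, rng)
      if (is.null(fit)) next
      ic <- .pwm_information(fit$mat, bg)
      fit$objective <- ic * fit$gamma * length(seqs)
      if (is.null(best) || fit$objective > best$objective) best <- fit
    }
    if (is.null(best)) break
    best$motif_id <- paste0("m", k)
    best$pseudocount <- pseudocount
    best$bg <- bg
    best$consensus <- paste(.AA20[apply(best$mat, 1, which.max)], collapse = "")
    class(best) <- "pwm"
    out[[k]] <- best
    # mask the best site of every sequence the model believes has one
    for (i in seq_along(seqs)) {
      z <- best$site_posterior[[i]]
      if (length(z) > 0 && sum(z) > 0.5) {
        j <- as.integer(names(z)[which.max(z)])
        seqs[[i]][j:(j + best$width - 1L)] <- NA_integer_
      }
    }
    best$site_posterior <- NULL
    out[[k]] <- best
  }
  out
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM ", x$motif_id, ": width ", x$width, ", consensus ", x$consensus,
      ", gamma ", round(x$gamma, 3), "\n", sep = "")
  invisible(x)
}

# Counter-based deterministic RNG wrapper: keeps package functions from
# touching the global .Random.seed.
.new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- as.integer(seed)
  env
}

.with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$state)
  out <- force(expr)
  rng$state <- as.integer((as.numeric(rng$state) * 69069 + 12345) %% 2147483647)
  out
}

.zoops_em_fit <- function(seqs, w, bg, pseudocount, n_seeds, max_iter, tol, rng) {
  valid_windows <- lapply(seqs, function(s) {
    m <- length(s) - w + 1L
    if (m < 1L) return(integer(0))
    ok <- vapply(seq_len(m), function(j) !anyNA(s[j:(j + w - 1L)]), logical(1))
    which(ok)
  })
  usable <- which(lengths(valid_windows) > 0L)
  if (length(usable) < 2L) return(NULL)

  # seed candidates: actual windows drawn deterministically
  cand <- do.call(rbind, lapply(usable, function(i) {
    cbind(i, valid_windows[[i]])
  }))
  pick <- .with_rng(rng, sample(nrow(cand), min(n_seeds, nrow(cand))))
  lbg <- log(bg)

  run_em <- function(theta, iters, full = FALSE) {
    gamma <- 0.5
    ll_old <- -Inf
    ll_trace <- numeric(0)
    zs <- NULL
    for (it in seq_len(iters)) {
      ltheta <- log(theta)
      zs <- vector("list", length(seqs))
      ll <- 0
      counts <- matrix(0, nrow = w, ncol = length(.AA20))
      gamma_acc <- 0
      for (i in seq_along(seqs)) {
        win <- valid_windows[[i]]
        s <- seqs[[i]]
        if (length(win) == 0L) { zs[[i]] <- numeric(0); next }
        m <- length(win)
        llr <- vapply(win, function(j) {
          idx <- s[j:(j + w - 1L)]
          sum(ltheta[cbind(seq_len(w), idx)] - lbg[idx])
        }, numeric(1))
        # guard against overflow
        mx <- max(llr, 0)
        denom <- (1 - gamma) * exp(-mx) + (gamma / m) * sum(exp(llr - mx))
        ll <- ll + mx + log(denom)
        z <- (gamma / m) * exp(llr - mx) / denom
        zvec <- setNames(z, win)
        zs[[i]] <- zvec
        gamma_acc <- gamma_acc + sum(z)
        for (jj in seq_along(win)) {
          j <- win[jj]
          idx <- s[j:(j + w - 1L)]
          counts[cbind(seq_len(w), idx)] <- counts[cbind(seq_len(w), idx)] + z[jj]
        }
      }
      ll_trace <- c(ll_trace, ll)
      if (it > 1L && ll < ll_old - 1e-8) {
        stop("internal error: ZOOPS EM log-likelihood decreased")
      }
      if (it > 1L && ll - ll_old < tol) { ll_old <- ll; break }
      ll_old <- ll
      theta <- (counts + pseudocount) / (rowSums(counts) + pseudocount * length(.AA20))
      gamma <- min(max(gamma_acc / length(usable), 1e-3), 1 - 1e-3)
    }
    list(theta = theta, gamma = gamma, ll = ll_old, z = zs, trace = ll_trace)
  }

  seed_theta <- function(i, j) {
    idx <- seqs[[i]][j:(j + w - 1L)]
    th <- matrix((1 - 0.5) / (length(.AA20) - 1), nrow = w, ncol = length(.AA20))
    th[cbind(seq_len(w), idx)] <- 0.5
    th
  }
  short <- lapply(pick, function(p) {
    run_em(seed_theta(cand[p, 1], cand[p, 2]), iters = 2L)
  })
  best0 <- short[[which.max(vapply(short, `[[`, numeric(1), "ll"))]]
  fit <- run_em(best0$theta, iters = max_iter)
  mat <- fit$theta
  dimnames(mat) <- list(NULL, .AA20)
  list(width = w, mat = mat, gamma = fit$gamma, loglik = fit$ll,
       site_posterior = fit$z)
}

# mean per-column information content (bits) relative to the background
.pwm_information <- function(mat, bg) {
  mean(vapply(seq_len(nrow(mat)), function(k) {
    p <- mat[k, ]
    sum(p * log2(p / bg[colnames(mat)]))
  }, numeric(1)))
}
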