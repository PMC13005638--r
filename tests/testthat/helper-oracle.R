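# Independent brute-force classifier: a direct, per-sequence transcription of
# the published gap/dose-count rules, sharing no code with the package engine.
# Used as the oracle in the exhaustive and randomized equivalence tests.

oracle_classify <- function(dates, biologic, followup = 365) {
  dates <- sort(unique(dates))
  n <- length(dates)
  gaps <- if (n > 1) dates[-1] - dates[-n] else numeric()
  terminal <- followup - dates[n]

  if (biologic == "benralizumab") {
    # Q4W for first 3 doses then Q8W.
    # prolonged: gap >= 56 (doses 1->2), >= 84 (2->3), >= 112 (after dose 3)
    prolonged <- FALSE
    for (i in seq_along(gaps)) {
      lim <- if (i == 1) 56 else if (i == 2) 84 else 112
      if (gaps[i] >= lim) prolonged <- TRUE
    }
    # discontinuation: end-of-12-months gap >= 112 (between doses 1 and 2),
    # >= 140 (between doses 2 and 3), >= 168 (after dose 3)
    dlim <- if (n == 1) 112 else if (n == 2) 140 else 168
    if (terminal >= dlim) return("discontinuation")
    if (!prolonged && n > 4) return("adherent")
    if (prolonged && n <= 4) return("minimally_adherent")
    return("partially_adherent")
  }

  if (biologic == "omalizumab") {
    schedule <- if (n >= 2 && median(gaps) < 21) "q2w" else "q4w"
    if (schedule == "q2w") {
      gap_lim <- 28; min_doses <- 13; dlim <- 42
    } else {
      gap_lim <- 56; min_doses <- 7; dlim <- 84
    }
  } else if (biologic == "dupilumab") {
    gap_lim <- 28; min_doses <- 13; dlim <- 42
  } else if (biologic %in% c("mepolizumab", "tezepelumab")) {
    gap_lim <- 56; min_doses <- 7; dlim <- 84
  } else {
    stop("unknown biologic: ", biologic)
  }

  if (terminal >= dlim) return("discontinuation")
  prolonged <- any(gaps >= gap_lim)
  if (!prolonged && n >= min_doses) return("adherent")
  if (prolonged && n < min_doses) return("minimally_adherent")
  "partially_adherent"
}

# all k-element subsets of 1..n as rows, lexicographic, vectorized expansion
grid_combos <- function(n, k) {
  if (k == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  res <- matrix(seq_len(n - k + 1L), ncol = 1)
  if (k >= 2) {
    for (j in 2:k) {
      last <- res[, j - 1L]
      room <- (n - (k - j)) - last
      keep <- room > 0L
      res <- res[keep, , drop = FALSE]
      room <- room[keep]
      idx <- rep.int(seq_len(nrow(res)), room)
      res <- cbind(res[idx, , drop = FALSE],
                   rep.int(res[, j - 1L], room)[] + sequence(room))
    }
  }
  unname(res)
}

# row-wise median for up to 5 columns via min/max networks (exact)
row_median_small <- function(G) {
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  m <- ncol(G)
  if (m == 1) return(G[, 1])
  if (m == 2) return((G[, 1] + G[, 2]) / 2)
  if (m == 3) return(med3(G[, 1], G[, 2], G[, 3]))
  if (m == 4) {
    s <- G[, 1] + G[, 2] + G[, 3] + G[, 4]
    lo <- pmin(G[, 1], G[, 2], G[, 3], G[, 4])
    hi <- pmax(G[, 1], G[, 2], G[, 3], G[, 4])
    return((s - lo - hi) / 2)
  }
  if (m == 5) {
    f <- pmax(pmin(G[, 1], G[, 2]), pmin(G[, 3], G[, 4]))
    g <- pmin(pmax(G[, 1], G[, 2]), pmax(G[, 3], G[, 4]))
    return(med3(f, g, G[, 5]))
  }
  apply(G, 1, median)
}

# Vectorized transcription of the same published rules for equal-length
# sequences (rows of `dates`). Written directly from the rule table with
# per-column literal thresholds; independent of the package kernel.
oracle_classify_matrix <- function(dates, biologic, followup = 365) {
  k <- ncol(dates)
  n_seq <- nrow(dates)
  gaps <- if (k > 1) dates[, -1, drop = FALSE] - dates[, -k, drop = FALSE]
  terminal <- followup - dates[, k]

  if (biologic == "benralizumab") {
    prolonged <- rep(FALSE, n_seq)
    if (k > 1) prolonged <- prolonged | (gaps[, 1] >= 56)
    if (k > 2) prolonged <- prolonged | (gaps[, 2] >= 84)
    if (k > 3) {
      for (j in 3:(k - 1)) prolonged <- prolonged | (gaps[, j] >= 112)
    }
    dlim <- if (k == 1) 112 else if (k == 2) 140 else 168
    out <- ifelse(terminal >= dlim, "discontinuation",
           ifelse(!prolonged & k > 4, "adherent",
           ifelse(prolonged & k <= 4, "minimally_adherent",
                  "partially_adherent")))
    return(out)
  }

  if (biologic == "omalizumab") {
    q2w <- if (k == 1) rep(FALSE, n_seq) else
      row_median_small(gaps) < 21
    gap_lim <- ifelse(q2w, 28, 56)
    min_doses <- ifelse(q2w, 13, 7)
    dlim <- ifelse(q2w, 42, 84)
  } else if (biologic == "dupilumab") {
    gap_lim <- 28; min_doses <- 13; dlim <- 42
  } else if (biologic %in% c("mepolizumab", "tezepelumab")) {
    gap_lim <- 56; min_doses <- 7; dlim <- 84
  } else stop("unknown biologic")

  prolonged <- if (k == 1) rep(FALSE, n_seq) else rowSums(gaps >= gap_lim) > 0
  ifelse(terminal >= dlim, "discontinuation",
  ifelse(!prolonged & k >= min_doses, "adherent",
  ifelse(prolonged & k < min_doses, "minimally_adherent",
         "partially_adherent")))
}
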