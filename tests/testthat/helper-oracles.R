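# Independent brute-force oracles used to validate the fast paths.

# Three-state Gotoh local alignment, plain loops; gap of length L costs
# gap_open + (L-1) * gap_extend.
oracle_affine_local_score <- function(a, b, params) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  s <- function(x, y) {
    if (x == "N" || y == "N" || x != y) params$mismatch else params$match
  }
  M <- matrix(-Inf, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (consumes a)
  Iy <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consumes b)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      prev <- max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                  Iy[i - 1L, j - 1L], 0)
      M[i, j] <- prev + s(A[i - 1L], B[j - 1L])
      Ix[i, j] <- max(M[i - 1L, j] + params$gap_open,
                      Ix[i - 1L, j] + params$gap_extend,
                      Iy[i - 1L, j] + params$gap_open)
      Iy[i, j] <- max(M[i, j - 1L] + params$gap_open,
                      Iy[i, j - 1L] + params$gap_extend,
                      Ix[i, j - 1L] + params$gap_open)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exact sum-of-pairs optimum for exactly three short sequences under the
# package's SP scoring (linear gap cost = gap_extend, double gap 0).
oracle_msa3_sp_optimum <- function(seqs, params) {
  stopifnot(length(seqs) == 3L)
  S <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  n <- vapply(S, length, integer(1))
  sub <- function(x, y) {
    if (x == "-" || y == "-") {
      if (x == "-" && y == "-") 0 else params$gap_extend
    } else if (x == y && x != "N") params$match else params$mismatch
  }
  col_score <- function(c1, c2, c3) {
    sub(c1, c2) + sub(c1, c3) + sub(c2, c3)
  }
  D <- array(-Inf, dim = n + 1L)
  D[1, 1, 1] <- 0
  moves <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, , drop = FALSE]
  for (i in 0:n[1]) for (j in 0:n[2]) for (k in 0:n[3]) {
    cur <- D[i + 1L, j + 1L, k + 1L]
    if (!is.finite(cur)) next
    for (mv in seq_len(nrow(moves))) {
      d <- moves[mv, ]
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii > n[1] || jj > n[2] || kk > n[3]) next
      c1 <- if (d[1] == 1) S[[1]][ii] else "-"
      c2 <- if (d[2] == 1) S[[2]][jj] else "-"
      c3 <- if (d[3] == 1) S[[3]][kk] else "-"
      val <- cur + col_score(c1, c2, c3)
      if (val > D[ii + 1L, jj + 1L, kk + 1L]) {
        D[ii + 1L, jj + 1L, kk + 1L] <- val
      }
    }
  }
  D[n[1] + 1L, n[2] + 1L, n[3] + 1L]
}

# Best consensus word by total Hamming distance to its closest match in
# each sequence (candidates: all width-mers of the input, both strands).
oracle_best_word <- function(seqs, width) {
  words <- unique(unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < width) return(character(0))
    substring(s, 1:(L - width + 1L), width:(L))
  })))
  words <- unique(c(words, vapply(words, comotif::revcomp, character(1))))
  hamming <- function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  best_in_seq <- function(word, s) {
    L <- nchar(s)
    subs <- substring(s, 1:(L - width + 1L), width:(L))
    min(c(vapply(subs, hamming, numeric(1), y = word),
          vapply(subs, hamming, numeric(1),
                 y = comotif::revcomp(word))))
  }
  tot <- vapply(words, function(w) {
    sum(vapply(seqs, function(s) best_in_seq(w, s), numeric(1)))
  }, numeric(1))
  words[which.min(tot)]
}

# Exact tail probability of the per-window log-odds score by full
# enumeration of all 4^width words (widths <= 8).
oracle_scan_tail <- function(pwm_obj, threshold, background) {
  W <- pwm_obj$width
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  llr <- log(pwm_obj$mat) - log(background)
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    idx <- cbind(words[r, ], seq_len(W))
    scores[r] <- sum(llr[idx])
    probs[r] <- prod(background[words[r, ]])
  }
  sum(probs[scores >= threshold])
}

# Direct mismatch-count scan of a plain word (forward strand only).
oracle_scan_word <- function(word, sequence, budget) {
  W <- nchar(word)
  L <- nchar(sequence)
  if (L < W) return(integer(0))
  wc <- strsplit(word, "")[[1]]
  hits <- integer(0)
  for (off in 0:(L - W)) {
    sc <- strsplit(substr(sequence, off + 1L, off + W), "")[[1]]
    mm <- sum(sc != wc | sc == "N")
    if (mm <= budget) hits <- c(hits, off)
  }
  hits
}

# small helpers for building occurrence matrices in tests
make_occurrence <- function(patterns, vars = NULL) {
  m <- do.call(rbind, patterns)
  if (is.null(vars)) vars <- LETTERS[seq_len(ncol(m))]
  colnames(m) <- vars
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  m
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}
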