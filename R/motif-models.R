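#' Position weight matrices and de novo motif discovery
#'
#' Motifs are discovered with an EM algorithm under the ZOOPS assumption
#' (zero or one occurrence per sequence): each sequence either contains a
#' single motif site at an unknown position (and, optionally, on either
#' strand) or is pure background. EM is started deterministically from
#' seeds built out of the width-mers present in the input, so discovery is
#' reproducible without a random seed.
#'
#' @name motif-models
NULL

DNA <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#' @param x nucleotide string over ACGTN (brackets of degenerate consensi
#'   are handled by [revcomp_consensus()]).
#' @return reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Reverse complement of a (possibly bracketed) consensus
#' @param x consensus string, possibly containing `[...]` degenerate groups.
#' @return reverse complement with groups preserved.
#' @export
revcomp_consensus <- function(x) {
  toks <- consensus_tokens(x)
  toks <- rev(vapply(toks, function(t) {
    chartr("ACGTN", "TGCAN", t)
  }, character(1)))
  paste(vapply(toks, function(t) {
    if (nchar(t) > 1L) paste0("[", t, "]") else t
  }, character(1)), collapse = "")
}

# Split a bracketed consensus into per-position letter sets.
consensus_tokens <- function(x) {
  out <- character(0)
  chars <- strsplit(x, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      while (chars[j] != "]") j <- j + 1L
      out <- c(out, paste(chars[seq.int(i + 1L, j - 1L)], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  out
}

#' Construct a position weight matrix
#'
#' @param mat 4 x width numeric matrix of column probabilities, rows in
#'   A,C,G,T order; each column must sum to 1.
#' @param background length-4 background distribution (default uniform).
#' @param pseudocount pseudocount used when the PWM was estimated.
#' @return a `pwm` object.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.25) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L, all(mat >= 0),
            all(abs(colSums(mat) - 1) < 1e-9))
  rownames(mat) <- DNA
  background <- background / sum(background)
  names(background) <- DNA
  structure(list(width = ncol(mat), mat = mat, background = background,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", x$width, pwm_consensus(x)))
  invisible(x)
}

#' Majority consensus of a PWM
#' @param pwm a [pwm()] object.
#' @return consensus string (per-column argmax; ties broken in A,C,G,T
#'   order).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Degenerate (bracketed) consensus of a PWM
#'
#' Letters with column probability at least `include_threshold` are listed
#' in decreasing-probability order (ties in A,C,G,T order); a single
#' qualifying letter is emitted bare, several are bracketed.
#'
#' @param pwm a [pwm()] object.
#' @param include_threshold inclusion threshold (default 0.2).
#' @return bracketed consensus string.
#' @export
ambiguous_consensus <- function(pwm, include_threshold = 0.2) {
  cols <- apply(pwm$mat, 2L, function(p) {
    qual <- which(p >= include_threshold)
    qual <- qual[order(-p[qual], qual)]
    if (length(qual) == 0L) qual <- which.max(p)
    if (length(qual) == 1L) DNA[qual]
    else paste0("[", paste(DNA[qual], collapse = ""), "]")
  })
  paste(cols, collapse = "")
}

# Reverse-complement a PWM (reverse columns, swap A<->T, C<->G rows).
revcomp_pwm <- function(p) {
  m <- p$mat[c("T", "G", "C", "A"), rev(seq_len(p$width)), drop = FALSE]
  rownames(m) <- DNA
  pwm(m, p$background, p$pseudocount)
}

# integer-encode a sequence: 1..4 for ACGT, NA for N
encode_seq <- function(s) {
  v <- match(strsplit(s, "")[[1]], DNA)
  v
}

# log-probabilities of every width-window of x under a 4 x W log matrix;
# windows containing NA (i.e. N) get -Inf.
window_logprobs <- function(x, logmat) {
  W <- ncol(logmat)
  L <- length(x)
  m <- L - W + 1L
  if (m < 1L) return(numeric(0))
  out <- numeric(m)
  idx <- outer(seq_len(m) - 1L, seq_len(W), `+`)   # m x W positions
  base <- matrix(x[idx], nrow = m)
  lp <- matrix(logmat[cbind(as.vector(base), rep(seq_len(W), each = m))],
               nrow = m)
  out <- rowSums(lp)
  out[apply(is.na(base), 1L, any)] <- -Inf
  out
}

# One ZOOPS E-step + log-likelihood bracket for a model; returns per-seq
# posteriors and sufficient statistics for the M-step.
zoops_estep <- function(enc, enc_rc, mat, background, gamma, revcomp) {
  logmat <- log(mat)
  logbg <- log(background)
  W <- ncol(mat)
  n <- length(enc)
  stats <- matrix(0, 4L, W)
  site_post <- numeric(n)
  loglik <- 0
  details <- vector("list", n)
  for (s in seq_len(n)) {
    x <- enc[[s]]
    lp_f <- window_logprobs(x, logmat)
    lb_f <- window_logprobs(x, matrix(logbg, 4L, W))
    r_f <- exp(lp_f - lb_f)
    r_f[!is.finite(r_f)] <- 0
    if (revcomp) {
      xr <- enc_rc[[s]]
      lp_r <- window_logprobs(xr, logmat)
      lb_r <- window_logprobs(xr, matrix(logbg, 4L, W))
      r_r <- exp(lp_r - lb_r)
      r_r[!is.finite(r_r)] <- 0
    } else {
      r_r <- numeric(0)
    }
    m_eff <- sum(is.finite(lb_f)) + if (revcomp) sum(is.finite(lb_f)) else 0L
    if (m_eff == 0L) {
      details[[s]] <- list(z_f = r_f * 0, z_r = r_r * 0)
      loglik <- loglik + log1p(-gamma)
      next
    }
    pri <- gamma / m_eff
    denom <- (1 - gamma) + pri * (sum(r_f) + sum(r_r))
    z_f <- pri * r_f / denom
    z_r <- if (revcomp) pri * r_r / denom else numeric(0)
    site_post[s] <- sum(z_f) + sum(z_r)
    loglik <- loglik + log(denom)
    # accumulate weighted base counts
    add_counts <- function(x, z) {
      mw <- length(z)
      if (mw == 0L) return()
      nz <- which(z > 1e-12)
      for (j in nz) {
        b <- x[seq.int(j, j + W - 1L)]
        ok <- !is.na(b)
        stats[cbind(b[ok], which(ok))] <<- stats[cbind(b[ok], which(ok))] +
          z[j]
      }
    }
    add_counts(x, z_f)
    if (revcomp) add_counts(enc_rc[[s]], z_r)
    details[[s]] <- list(z_f = z_f, z_r = z_r)
  }
  list(stats = stats, site_post = site_post, loglik = loglik,
       details = details)
}

#' Discover a single motif by ZOOPS EM
#'
#' EM is seeded deterministically: every distinct width-mer occurring in
#' the input (and, with `revcomp`, its reverse complement) defines a
#' candidate start; starts are screened with one EM step, the best
#' `n_keep` are run to convergence, and the converged model with the
#' highest log-likelihood-ratio score wins, ties broken lexicographically
#' by consensus. With `revcomp` the final model is canonically oriented to
#' the lexicographically smaller of consensus and reverse-complement
#' consensus.
#'
#' @param sequences character vector (>= 2 sequences, each at least
#'   `width` long).
#' @param width motif width.
#' @param revcomp also model sites on the minus strand (default TRUE).
#' @param seq_ids sequence identifiers (default `seq1`, `seq2`, ...).
#' @param background length-4 background distribution over A,C,G,T;
#'   estimated from the input when `NULL`.
#' @param pseudocount per-letter pseudocount in the M-step (default 0.25).
#' @param n_keep number of screened seeds run to full convergence
#'   (default 10).
#' @param n_screen cap on the number of seed words entering the
#'   screening stage; on inputs with more distinct width-mers, the words
#'   present in the most sequences are kept (default 200).
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` or `max_iter` iterations.
#' @return a `motif_model` with fields `motif_id`, `pwm`, `consensus`,
#'   `ambiguous_consensus`, `sites` (data.frame seq_id, offset (0-based),
#'   strand), `score` (ZOOPS log-likelihood ratio vs background) and
#'   `is_mafb` (FALSE).
#' @export
discover_motif_zoops <- function(sequences, width, revcomp = TRUE,
                                 seq_ids = NULL, background = NULL,
                                 pseudocount = 0.25, n_keep = 10L,
                                 n_screen = 200L, max_iter = 200L,
                                 tol = 1e-6) {
  stopifnot(length(sequences) >= 2L)
  width <- as.integer(width)
  if (any(nchar(sequences) < width)) {
    stop("width ", width, " exceeds the shortest sequence")
  }
  sequences <- toupper(sequences)
  if (is.null(seq_ids)) seq_ids <- paste0("seq", seq_along(sequences))
  enc <- lapply(sequences, encode_seq)
  enc_rc <- lapply(sequences, function(s) encode_seq(revcomp(s)))
  if (is.null(background)) {
    tab <- table(factor(unlist(lapply(enc, stats::na.omit)),
                        levels = 1:4))
    background <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  }
  names(background) <- DNA

  # --- deterministic seeds: distinct clean width-mers in the input; on
  # large inputs only the n_screen words with the widest sequence support
  # (ties lexicographic) enter the screening stage
  per_seq_words <- lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < width) return(character(0))
    w <- substring(s, seq_len(L - width + 1L),
                   seq_len(L - width + 1L) + width - 1L)
    unique(w[!grepl("N", w, fixed = TRUE)])
  })
  words <- sort(unique(unlist(per_seq_words)))
  if (length(words) == 0L) stop("no N-free width-", width, " words in input")
  if (length(words) > n_screen) {
    support <- table(unlist(per_seq_words))
    ord <- order(-as.vector(support[words]), words)
    words <- sort(words[ord[seq_len(n_screen)]])
  }

  seed_pwm <- function(word) {
    m <- matrix(0.1, 4L, width, dimnames = list(DNA, NULL))
    idx <- match(strsplit(word, "")[[1]], DNA)
    m[cbind(idx, seq_len(width))] <- 0.7
    m
  }

  run_em <- function(mat, gamma, iters) {
    # with a Dirichlet(pseudocount) M-step, EM is monotone in the
    # penalized objective loglik + pc * sum(log pwm), not the raw loglik
    ll_prev <- -Inf
    pen_prev <- -Inf
    est <- NULL
    for (it in seq_len(iters)) {
      est <- zoops_estep(enc, enc_rc, mat, background, gamma, revcomp)
      pen <- est$loglik + pseudocount * sum(log(mat))
      if (pen < pen_prev - 1e-6 * (abs(pen_prev) + 1)) {
        stop("EM penalized objective decreased (", pen_prev, " -> ",
             pen, ")")
      }
      pen_prev <- pen
      counts <- est$stats + pseudocount
      mat <- sweep(counts, 2L, colSums(counts), "/")
      gamma <- min(max(mean(est$site_post), 1e-6), 1 - 1e-6)
      if (is.finite(ll_prev) &&
          abs(est$loglik - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
        ll_prev <- est$loglik
        break
      }
      ll_prev <- est$loglik
    }
    list(mat = mat, gamma = gamma, loglik = ll_prev, est = est)
  }

  # screen every seed with a single EM step
  screened <- lapply(words, function(w) {
    r <- run_em(seed_pwm(w), 0.5, 1L)
    list(word = w, loglik = r$loglik)
  })
  ll <- vapply(screened, `[[`, numeric(1), "loglik")
  ord <- order(-ll, words)
  keep <- words[ord[seq_len(min(n_keep, length(words)))]]

  best <- NULL
  for (w in keep) {
    r <- run_em(seed_pwm(w), 0.5, max_iter)
    cand_cons <- paste(DNA[apply(r$mat, 2L, which.max)], collapse = "")
    if (is.null(best) || r$loglik > best$loglik + 1e-9 ||
        (abs(r$loglik - best$loglik) <= 1e-9 &&
         cand_cons < best$consensus)) {
      best <- r
      best$consensus <- cand_cons
    }
  }

  p <- pwm(best$mat, background, pseudocount)
  # canonical orientation
  if (revcomp) {
    cons <- pwm_consensus(p)
    rc <- revcomp_pwm(p)
    if (pwm_consensus(rc) < cons) {
      p <- rc
      flip <- TRUE
    } else flip <- FALSE
  } else flip <- FALSE

  # final E-step (on the oriented model) to call sites: zero or one per seq
  est <- zoops_estep(enc, enc_rc, p$mat, background, best$gamma, revcomp)
  sites <- do.call(rbind, lapply(seq_along(sequences), function(s) {
    d <- est$details[[s]]
    tot <- sum(d$z_f) + sum(d$z_r)
    if (tot < 0.5) return(NULL)
    cand <- c(d$z_f, d$z_r)
    j <- which.max(cand)
    L <- nchar(sequences[s])
    if (j <= length(d$z_f)) {
      data.frame(seq_id = seq_ids[s], offset = j - 1L, strand = "+",
                 stringsAsFactors = FALSE)
    } else {
      jr <- j - length(d$z_f)          # offset on the reverse strand
      data.frame(seq_id = seq_ids[s], offset = L - (jr - 1L) - width,
                 strand = "-", stringsAsFactors = FALSE)
    }
  }))
  if (is.null(sites)) {
    sites <- data.frame(seq_id = character(0), offset = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  }
  if (flip && nrow(sites) > 0L) {
    sites$strand <- ifelse(sites$strand == "+", "-", "+")
  }

  # LLR score: model loglik minus background-only loglik (bg terms cancel,
  # background-only corresponds to gamma = 0 i.e. bracket = 1 per seq)
  score <- est$loglik

  structure(list(motif_id = as.character(width), pwm = p,
                 consensus = pwm_consensus(p),
                 ambiguous_consensus = ambiguous_consensus(p),
                 sites = sites, score = score, is_mafb = FALSE),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: %s (%s), %d sites, score %.2f\n",
              x$motif_id, x$consensus, x$ambiguous_consensus,
              nrow(x$sites), x$score))
  invisible(x)
}

#' Discover a ranked set of motifs across several widths
#'
#' Per width, motifs are discovered one at a time; after each discovery
#' the called sites are masked with `N` and discovery repeats. The
#' per-width models are then ranked by their log-likelihood-ratio score
#' (ids `"width-rank"`, rank 1 written as the bare width).
#'
#' @param sequences character vector of sequences.
#' @param widths motif widths to scan (default `c(6, 8, 10, 12, 14, 16, 18)`).
#' @param per_width motifs per width (default 10).
#' @param ... passed to [discover_motif_zoops()].
#' @return list of `motif_model`s (at most `per_width * length(widths)`).
#' @export
discover_motif_set <- function(sequences,
                               widths = c(6L, 8L, 10L, 12L, 14L, 16L, 18L),
                               per_width = 10L, ...) {
  out <- list()
  seq_ids <- if (is.null(names(sequences))) {
    paste0("seq", seq_along(sequences))
  } else names(sequences)
  for (W in widths) {
    work <- unname(sequences)
    found <- list()
    for (r in seq_len(per_width)) {
      mm <- tryCatch(discover_motif_zoops(work, W, seq_ids = seq_ids, ...),
                     error = function(e) NULL)
      if (is.null(mm)) break
      found[[length(found) + 1L]] <- mm
      if (nrow(mm$sites) == 0L) break
      # mask called sites so the next round finds something else
      for (i in seq_len(nrow(mm$sites))) {
        s <- match(mm$sites$seq_id[i], seq_ids)
        off <- mm$sites$offset[i]
        substr(work[s], off + 1L, off + W) <-
          paste(rep("N", W), collapse = "")
      }
    }
    # rank by significance (log-likelihood-ratio score), not discovery
    # order; ties broken by consensus for determinism
    ord <- order(-vapply(found, `[[`, numeric(1), "score"),
                 vapply(found, `[[`, character(1), "consensus"))
    found <- found[ord]
    for (r in seq_along(found)) {
      found[[r]]$motif_id <- if (r == 1L) as.character(W) else
        paste0(W, "-", r)
    }
    out <- c(out, found)
  }
  out
}

#' The bundled MafB binding sequences
#'
#' Nine short sequences experimentally confirmed to bind MafB, bundled as
#' a FASTA fixture; used to derive the MafB motif models.
#'
#' @return named character vector of 9 sequences (upper case).
#' @export
mafb_binding_sequences <- function() {
  path <- system.file("extdata", "mafb_binding_sequences.fasta",
                      package = "comotif")
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Derive MafB motif models from the binding sequences
#'
#' Runs ZOOPS discovery at each requested width over the MafB binding
#' sequences. The AT-rich extension sits about three nucleotides upstream
#' of the 6-bp MARE core, which motivates widths 8 through 11. The
#' resulting models are tagged `is_mafb = TRUE` so downstream merging
#' rules can exempt them.
#'
#' @param binding_sequences character vector of binding sites (default:
#'   the bundled nine).
#' @param widths motif widths (default 8:11).
#' @param ... passed to [discover_motif_zoops()].
#' @return list of `motif_model`s, ids equal to their widths.
#' @export
extract_mafb_motifs <- function(binding_sequences = mafb_binding_sequences(),
                                widths = 8:11, ...) {
  lapply(widths, function(W) {
    mm <- discover_motif_zoops(unname(binding_sequences), W, ...)
    mm$motif_id <- as.character(W)
    mm$is_mafb <- TRUE
    mm
  })
}

#' Write motif models to a plain-text motif file
#'
#' One block per motif: a `>id width score is_mafb` line, the consensus,
#' the degenerate consensus, then four tab-separated probability rows in
#' A,C,G,T order.
#'
#' @param motifs list of `motif_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    cat(sprintf(">%s %d %.6g %d\n", m$motif_id, m$pwm$width, m$score,
                as.integer(m$is_mafb)), file = con)
    cat(m$consensus, "\n", sep = "", file = con)
    cat(m$ambiguous_consensus, "\n", sep = "", file = con)
    for (b in DNA) {
      cat(paste(sprintf("%.6f", m$pwm$mat[b, ]), collapse = "\t"), "\n",
          sep = "", file = con)
    }
  }
  invisible(path)
}

#' Read motif models from a motif file written by [write_motifs()]
#' @param path motif file path.
#' @return list of `motif_model`s (without site lists).
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  lapply(starts, function(i) {
    hdr <- strsplit(sub("^>", "", lines[i]), " ")[[1]]
    mat <- do.call(rbind, lapply(lines[(i + 3L):(i + 6L)], function(l) {
      as.numeric(strsplit(l, "\t")[[1]])
    }))
    mat <- sweep(mat, 2L, colSums(mat), "/")
    p <- pwm(mat)
    structure(list(motif_id = hdr[1], pwm = p, consensus = lines[i + 1L],
                   ambiguous_consensus = lines[i + 2L],
                   sites = data.frame(seq_id = character(0),
                                      offset = integer(0),
                                      strand = character(0)),
                   score = as.numeric(hdr[3]),
                   is_mafb = as.integer(hdr[4]) == 1L),
              class = "motif_model")
  })
}
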