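#' Motif scanning
#'
#' Two complementary locators: PWM log-odds scanning with a per-sequence
#' best-hit p-value from the exact null score distribution (computed by
#' dynamic programming on a discretized score lattice), and degenerate
#' string matching under a width-dependent substitution budget.
#'
#' @name motif-scan
NULL

# Exact null distribution of the per-window log-odds score under the
# background model, discretized to `delta`-wide bins. Returns bin scores
# and probabilities.
pwm_null_distribution <- function(pwm, background = pwm$background,
                                  delta = 1e-3) {
  llr <- log(pwm$mat) - log(background)       # 4 x W
  bins <- round(llr / delta)                  # integer bin per cell
  lo <- sum(apply(bins, 2L, min))
  hi <- sum(apply(bins, 2L, max))
  dist <- numeric(hi - lo + 1L)               # index = bin - lo + 1
  # start: the empty prefix has score 0 at running offset cur_lo = 0
  dist0 <- 1
  cur <- c(dist0)
  cur_lo <- 0L
  for (w in seq_len(pwm$width)) {
    b <- bins[, w]
    new_lo <- cur_lo + min(b)
    new_hi <- cur_lo + length(cur) - 1L + max(b)
    new <- numeric(new_hi - new_lo + 1L)
    for (base in 1:4) {
      sh <- cur_lo + b[base] - new_lo         # left padding
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * background[base]
    }
    cur <- new
    cur_lo <- new_lo
  }
  list(bin_lo = cur_lo, prob = cur, delta = delta)
}

# P(null window score >= s), conservative at bin resolution.
null_tail_prob <- function(null, s) {
  bin <- floor(s / null$delta + 1e-9)
  idx <- bin - null$bin_lo + 1L
  if (idx <= 1L) return(1)
  if (idx > length(null$prob)) return(0)
  sum(null$prob[idx:length(null$prob)])
}

#' Scan sequences with a PWM and compute best-hit E-values
#'
#' For each sequence the best log-odds score over all positions (both
#' strands) is found; its p-value is the exact-null tail probability of
#' that score, corrected for the `m` scanned windows as
#' `1 - (1 - p1)^m`; the E-value multiplies the p-value by the number of
#' sequences scanned. Windows overlapping `N` are skipped; a sequence
#' with no scannable window gets p-value 1.
#'
#' @param pwm a [pwm()] object.
#' @param sequences named character vector (names are sequence/gene ids).
#' @param background length-4 background over A,C,G,T (default: the
#'   PWM's own background).
#' @param both_strands scan the minus strand too (default TRUE).
#' @param delta score-lattice bin width for the exact null (default 1e-3).
#' @return a `scan_result`: data.frame with `seq_id`, `best_score`,
#'   `best_pos` (0-based forward-strand offset), `strand`, `p_value`,
#'   `e_value`.
#' @export
pwm_scan_evalue <- function(pwm, sequences, background = NULL,
                            both_strands = TRUE, delta = 1e-3) {
  if (is.null(background)) background <- pwm$background
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  W <- pwm$width
  if (all(nchar(sequences) < W)) stop("PWM width exceeds every sequence")
  if (any(nchar(sequences) < W)) {
    warning(sum(nchar(sequences) < W),
            " sequence(s) shorter than the PWM width skipped")
  }
  null <- pwm_null_distribution(pwm, background, delta)
  llr <- log(pwm$mat) - log(background)
  n_seq <- sum(nchar(sequences) >= W)
  rows <- lapply(names(sequences), function(id) {
    s <- toupper(sequences[[id]])
    L <- nchar(s)
    if (L < W) return(NULL)
    score_strand <- function(seqstr) {
      x <- encode_seq(seqstr)
      sc <- window_logprobs(x, llr)  # llr "log-matrix": sums give log-odds
      sc
    }
    sc_f <- score_strand(s)
    sc <- sc_f
    strands <- rep("+", length(sc_f))
    pos <- seq_along(sc_f) - 1L
    if (both_strands) {
      sc_r <- score_strand(revcomp(s))
      sc <- c(sc, sc_r)
      strands <- c(strands, rep("-", length(sc_r)))
      pos <- c(pos, L - seq_along(sc_r) + 1L - W)
    }
    ok <- is.finite(sc)
    m <- sum(ok)
    if (m == 0L) {
      return(data.frame(seq_id = id, best_score = NA_real_,
                        best_pos = NA_integer_, strand = NA_character_,
                        p_value = 1, e_value = n_seq,
                        stringsAsFactors = FALSE))
    }
    j <- which(ok)[which.max(sc[ok])]
    p1 <- null_tail_prob(null, sc[j])
    p <- 1 - (1 - p1)^m
    data.frame(seq_id = id, best_score = sc[j], best_pos = pos[j],
               strand = strands[j], p_value = p, e_value = p * n_seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", class(out))
  out
}

#' Substitution budget for a motif width
#'
#' Listed schedule: widths 6 and 8 allow 1 substitution, 10 and 12 allow
#' 2, 14 and 16 allow 3, 18 allows 4. Unlisted widths inherit the budget
#' of the nearest lower listed width; widths below 6 get 0.
#'
#' @param width motif width (>= 1).
#' @return integer substitution budget.
#' @export
substitution_budget <- function(width) {
  stopifnot(width >= 1)
  vapply(width, function(w) {
    if (w < 6) 0L
    else if (w < 10) 1L
    else if (w < 14) 2L
    else if (w < 18) 3L
    else 4L
  }, integer(1))
}

# mismatch counts of a token list (per-position allowed sets) against
# every offset of a sequence; N in the sequence never matches.
mismatch_profile <- function(tokens, seq_chars) {
  W <- length(tokens)
  L <- length(seq_chars)
  m <- L - W + 1L
  if (m < 1L) return(integer(0))
  mm <- integer(m)
  for (w in seq_len(W)) {
    allowed <- strsplit(tokens[w], "")[[1]]
    allowed <- setdiff(allowed, "N")
    bad <- !(seq_chars %in% allowed)
    mm <- mm + bad[w:(m + w - 1L)]
  }
  mm
}

#' Locate a (possibly degenerate) motif allowing substitutions
#'
#' Reports a hit at every offset, on either strand, where the number of
#' motif positions not matched by the sequence (bracketed positions match
#' any listed letter; `N` in the sequence matches nothing) is at most
#' `budget`. Overlapping hits are all reported; minus-strand hits are
#' given in forward coordinates.
#'
#' @param motif consensus string, possibly bracketed.
#' @param sequence nucleotide string.
#' @param budget maximum substitutions (default: [substitution_budget()]
#'   of the motif width).
#' @param both_strands also scan the minus strand (default TRUE).
#' @return data.frame with `position` (0-based forward-strand start),
#'   `strand`, `mismatches`, sorted by position.
#' @export
locate_with_substitutions <- function(motif, sequence, budget = NULL,
                                      both_strands = TRUE) {
  tokens <- consensus_tokens(toupper(motif))
  W <- length(tokens)
  if (is.null(budget)) budget <- substitution_budget(W)
  s <- toupper(sequence)
  if (nchar(s) < W) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  seq_chars <- strsplit(s, "")[[1]]
  hits <- list()
  mm_f <- mismatch_profile(tokens, seq_chars)
  hf <- which(mm_f <= budget)
  if (length(hf)) {
    hits[[1]] <- data.frame(position = hf - 1L, strand = "+",
                            mismatches = mm_f[hf],
                            stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rc_tokens <- consensus_tokens(
      revcomp_consensus(paste(vapply(tokens, function(t) {
        if (nchar(t) > 1L) paste0("[", t, "]") else t
      }, character(1)), collapse = ""))
    )
    mm_r <- mismatch_profile(rc_tokens, seq_chars)
    hr <- which(mm_r <= budget)
    if (length(hr)) {
      hits[[length(hits) + 1L]] <-
        data.frame(position = hr - 1L, strand = "-",
                   mismatches = mm_r[hr], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Write motif hits as BED-like TSV
#'
#' Columns: seq_id, start, end (0-based half-open), motif_id, score (the
#' mismatch count or PWM score), strand.
#'
#' @param hits data.frame with `seq_id`, `position`, `width`, `motif_id`,
#'   `value`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(seq_id = hits$seq_id, start = hits$position,
                    end = hits$position + hits$width,
                    motif_id = hits$motif_id, score = hits$value,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select the MafB binding gene set
#'
#' A gene is kept when (i) the smallest E-value over the MafB motif
#' models in the reference species falls strictly below `e_threshold`,
#' and (ii) every required species carries a MafB motif hit (its own
#' minimum E-value below the threshold) in its conserved promoter.
#'
#' @param scans nested list: species name -> list of `scan_result`s (one
#'   per MafB motif model) whose `seq_id`s are gene ids.
#' @param conserved_species species that must all carry the motif
#'   (default mouse and human; the first is the reference).
#' @param e_threshold strict E-value cut-off (default 21).
#' @return character vector of gene ids.
#' @export
select_mafb_binding_genes <- function(scans,
                                      conserved_species = c("mouse", "human"),
                                      e_threshold = 21) {
  missing_sp <- setdiff(conserved_species, names(scans))
  if (length(missing_sp)) {
    stop("no scans for required species: ",
         paste(missing_sp, collapse = ", "))
  }
  reference <- conserved_species[1]
  min_e <- function(species) {
    per_motif <- scans[[species]]
    ids <- unique(unlist(lapply(per_motif, function(sr) sr$seq_id)))
    vapply(ids, function(g) {
      evs <- vapply(per_motif, function(sr) {
        row <- sr[sr$seq_id == g, , drop = FALSE]
        if (nrow(row) == 0L) {
          stop("missing ", species, " scan for gene ", g)
        }
        row$e_value[1]
      }, numeric(1))
      min(evs)
    }, numeric(1))
  }
  ref_e <- min_e(reference)
  keep <- names(ref_e)[ref_e < e_threshold]
  for (sp in setdiff(conserved_species, reference)) {
    sp_e <- min_e(sp)
    present <- names(sp_e)[sp_e < e_threshold]
    keep <- keep[keep %in% present]
  }
  keep
}
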