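#' Alignment parameters
#'
#' Affine gap convention: the first position of a gap costs `gap_open`,
#' every further position `gap_extend` (both non-positive). Defaults follow
#' the common EMBOSS-water-style nucleotide scheme.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0). `N` mismatches everything,
#'   including `N`.
#' @param gap_open cost of the first gap position (<= `gap_extend`).
#' @param gap_extend cost of each additional gap position (<= 0).
#' @return an `alignment_params` object.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap_open = -10,
                             gap_extend = -0.5) {
  stopifnot(match > 0, mismatch <= 0, gap_extend <= 0,
            gap_open <= gap_extend)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

# ACGTN substitution matrix under these params; N never matches anything.
substitution_matrix <- function(params) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- params$match
  m["N", "N"] <- params$mismatch
  m
}

# Map our affine convention onto Biostrings' (gap of length L costs
# gapOpening + L * gapExtension, passed as positive costs).
biostrings_gap_costs <- function(params) {
  list(opening = -(params$gap_open - params$gap_extend),
       extension = -params$gap_extend)
}

#' Smith-Waterman-Gotoh local alignment
#'
#' Optimal local alignment under affine gap penalties. The score of the
#' empty alignment is 0, so the result is always non-negative.
#'
#' @param a,b nucleotide strings (non-empty; `N` mismatches everything).
#' @param params an [alignment_params()].
#' @return a `pairwise_alignment` with `score`, gapped `aligned_a` /
#'   `aligned_b` of equal length, 1-based `start_a`/`end_a`/`start_b`/`end_b`
#'   coordinates of the aligned substrings, and `consensus_length` (number
#'   of alignment columns).
#' @export
sw_gotoh <- function(a, b, params = alignment_params()) {
  stopifnot(nzchar(a), nzchar(b))
  gaps <- biostrings_gap_costs(params)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = gaps$opening, gapExtension = gaps$extension
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(score = 0, aligned_a = "", aligned_b = "",
                          start_a = NA_integer_, end_a = NA_integer_,
                          start_b = NA_integer_, end_b = NA_integer_,
                          consensus_length = 0L),
                     class = "pairwise_alignment"))
  }
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  aligned_a <- as.character(pat)
  structure(list(score = sc,
                 aligned_a = aligned_a,
                 aligned_b = as.character(sub),
                 start_a = Biostrings::start(pat), end_a = Biostrings::end(pat),
                 start_b = Biostrings::start(sub), end_b = Biostrings::end(sub),
                 consensus_length = nchar(aligned_a)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f over %d columns\n",
              x$score, x$consensus_length))
  invisible(x)
}

#' Select species aligning well to the reference promoter
#'
#' A species is retained when its local alignment to the reference scores
#' strictly more than `min_score` and spans between `min_len` and `max_len`
#' alignment columns (inclusive). The reference itself is always retained.
#'
#' @param group an `orthologue_group` (see [orthologue_groups()]).
#' @param params an [alignment_params()].
#' @param reference reference species name.
#' @param min_score score threshold (strict; default 200).
#' @param min_len,max_len inclusive bounds on the alignment span
#'   (defaults 500 and 1000).
#' @return character vector of retained species, reference first.
#' @export
filter_species <- function(group, params = alignment_params(),
                           reference = "mouse", min_score = 200,
                           min_len = 500L, max_len = 1000L) {
  if (!reference %in% names(group$members)) {
    stop("group ", group$gene_id, " lacks reference species '",
         reference, "'")
  }
  ref_seq <- group$members[[reference]]$sequence
  others <- setdiff(names(group$members), reference)
  keep <- vapply(others, function(sp) {
    al <- sw_gotoh(ref_seq, group$members[[sp]]$sequence, params)
    al$score > min_score &&
      al$consensus_length >= min_len && al$consensus_length <= max_len
  }, logical(1))
  c(reference, others[keep])
}

# Global affine alignment of two strings, returning the gapped pair.
global_align <- function(a, b, params) {
  gaps <- biostrings_gap_costs(params)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = gaps$opening, gapExtension = gaps$extension
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# Merge a new pairwise (reference, seq) alignment into rows already gapped
# against the reference: classic "once a gap, always a gap".
merge_into_star <- function(ref_gapped_old, rows_old, ref_gapped_new,
                            new_row) {
  o <- strsplit(ref_gapped_old, "")[[1]]
  n <- strsplit(ref_gapped_new, "")[[1]]
  rows_old_c <- lapply(rows_old, function(r) strsplit(r, "")[[1]])
  new_c <- strsplit(new_row, "")[[1]]
  i <- 1L; j <- 1L
  merged_old <- lapply(rows_old_c, function(r) character(0))
  merged_ref <- character(0)
  merged_new <- character(0)
  take <- function(lst, idx) vapply(lst, `[`, character(1), idx)
  while (i <= length(o) || j <= length(n)) {
    oi <- if (i <= length(o)) o[i] else ""
    nj <- if (j <= length(n)) n[j] else ""
    if (i <= length(o) && j <= length(n) && oi != "-" && nj != "-") {
      # both consume a reference base (must be the same base)
      merged_ref <- c(merged_ref, oi)
      for (k in seq_along(merged_old)) {
        merged_old[[k]] <- c(merged_old[[k]], rows_old_c[[k]][i])
      }
      merged_new <- c(merged_new, new_c[j])
      i <- i + 1L; j <- j + 1L
    } else if (i <= length(o) && oi == "-") {
      merged_ref <- c(merged_ref, "-")
      for (k in seq_along(merged_old)) {
        merged_old[[k]] <- c(merged_old[[k]], rows_old_c[[k]][i])
      }
      merged_new <- c(merged_new, "-")
      i <- i + 1L
    } else {
      merged_ref <- c(merged_ref, "-")
      for (k in seq_along(merged_old)) {
        merged_old[[k]] <- c(merged_old[[k]], "-")
      }
      merged_new <- c(merged_new, new_c[j])
      j <- j + 1L
    }
  }
  list(ref = paste(merged_ref, collapse = ""),
       rows = vapply(merged_old, paste, character(1), collapse = ""),
       new = paste(merged_new, collapse = ""))
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Columns where both rows carry a base score match/mismatch; columns where
#' exactly one row has a gap score `gap_extend` (linear gap cost — affine
#' penalties are not projected onto pairs); double-gap columns score 0.
#' `N` against anything scores as a mismatch.
#'
#' @param msa a `multiple_alignment`.
#' @param params an [alignment_params()].
#' @return numeric score.
#' @export
sp_score <- function(msa, params = alignment_params()) {
  rows <- lapply(msa$rows, function(r) strsplit(r, "")[[1]])
  k <- length(rows)
  if (k < 2L) return(0)
  total <- 0
  for (p in seq_len(k - 1L)) {
    for (q in seq.int(p + 1L, k)) {
      a <- rows[[p]]; b <- rows[[q]]
      both <- a != "-" & b != "-"
      one <- xor(a == "-", b == "-")
      matchv <- both & a == b & a != "N"
      total <- total + sum(matchv) * params$match +
        sum(both & !matchv) * params$mismatch +
        sum(one) * params$gap_extend
    }
  }
  total
}

new_multiple_alignment <- function(species, rows, params) {
  rows <- drop_all_gap_columns(rows)
  msa <- structure(list(species = species, rows = rows, sp = NA_real_),
                   class = "multiple_alignment")
  msa$sp <- sp_score(msa, params)
  msa
}

drop_all_gap_columns <- function(rows) {
  if (length(rows) == 0L) return(rows)
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(mat != "-") > 0L
  apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns (SP %.1f)\n",
              length(x$rows), nchar(x$rows[1]), x$sp))
  invisible(x)
}

#' Reference-centred progressive multiple alignment
#'
#' Star alignment: each retained species is globally aligned to the
#' reference promoter and the pairwise alignments are merged under the
#' "once a gap, always a gap" rule. A single retained species yields the
#' trivial one-row alignment.
#'
#' @param group an `orthologue_group`.
#' @param retained species to include (reference must be among them).
#' @param params an [alignment_params()].
#' @param reference reference species name.
#' @return a `multiple_alignment` with `species` (reference first), gapped
#'   `rows` of equal length, and sum-of-pairs score `sp`.
#' @export
progressive_msa <- function(group, retained = names(group$members),
                            params = alignment_params(),
                            reference = "mouse") {
  stopifnot(reference %in% retained)
  ref_seq <- group$members[[reference]]$sequence
  others <- setdiff(retained, reference)
  ref_gapped <- ref_seq
  rows <- character(0)
  for (sp in others) {
    al <- global_align(ref_seq, group$members[[sp]]$sequence, params)
    m <- merge_into_star(ref_gapped, rows, al$a, al$b)
    ref_gapped <- m$ref
    rows <- c(m$rows, m$new)
  }
  new_multiple_alignment(c(reference, others), c(ref_gapped, rows), params)
}

# Majority consensus over non-gap characters per column ('N' allowed to
# win only if nothing else is present); all-gap columns must have been
# dropped beforehand.
column_consensus <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    tab["N"] <- tab["N"] - 0.5  # prefer a real base over N on ties
    names(tab)[which.max(tab)]
  })
}

#' Iteratively refine a multiple alignment
#'
#' Leave-one-out refinement: each row in turn is removed, the remaining
#' rows' majority consensus is formed, the removed sequence is re-aligned
#' globally against it and merged back. A candidate re-alignment is kept
#' only if the sum-of-pairs score improves, so the SP score is
#' non-decreasing; iteration stops at a fixed point or after `max_rounds`.
#'
#' @param msa a `multiple_alignment`.
#' @param params an [alignment_params()].
#' @param max_rounds maximum full passes over the rows (default 10).
#' @return refined `multiple_alignment`.
#' @export
refine_msa <- function(msa, params = alignment_params(), max_rounds = 10L) {
  if (length(msa$rows) < 2L) return(msa)
  current <- msa
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (i in seq_along(current$rows)) {
      others <- current$rows[-i]
      others <- drop_all_gap_columns(others)
      cons <- paste(column_consensus(others), collapse = "")
      seq_i <- gsub("-", "", current$rows[i], fixed = TRUE)
      al <- global_align(cons, seq_i, params)
      m <- merge_into_star(cons, others, al$a, al$b)
      cand_rows <- append(m$rows, m$new, after = i - 1L)
      cand <- new_multiple_alignment(current$species, cand_rows, params)
      if (cand$sp > current$sp + 1e-9) {
        current <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  current
}

#' Mask non-conserved reference positions with N
#'
#' Walks the reference row of the alignment (skipping its gap columns, so
#' the output has exactly the reference promoter's length). A position is
#' conserved when, among the non-reference rows without a gap in that
#' column, the fraction matching the reference base is at least
#' `min_agree_frac` (`N` never counts as agreement; a column where every
#' other row is gapped counts as non-conserved). Conserved runs shorter
#' than `min_run` are masked as well.
#'
#' @param msa a `multiple_alignment`.
#' @param reference reference species name (must be a row).
#' @param min_agree_frac minimum agreeing fraction (default 0.5).
#' @param min_run minimum length of a retained conserved run (default 6).
#' @return a `masked_consensus` with fields `sequence` (reference sequence
#'   with `N` at masked positions), `retained_species`, and
#'   `fraction_masked`.
#' @export
mask_nonconserved <- function(msa, reference = "mouse",
                              min_agree_frac = 0.5, min_run = 6L) {
  idx <- match(reference, msa$species)
  if (is.na(idx)) stop("reference species '", reference, "' not in alignment")
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  ref_row <- mat[idx, ]
  ref_cols <- which(ref_row != "-")
  n_pos <- length(ref_cols)
  if (nrow(mat) < 2L) {
    warning("single-row alignment: nothing to compare, no masking applied")
    return(structure(list(sequence = paste(ref_row[ref_cols], collapse = ""),
                          retained_species = msa$species,
                          fraction_masked = 0),
                     class = "masked_consensus"))
  }
  conserved <- logical(n_pos)
  for (p in seq_len(n_pos)) {
    col <- mat[-idx, ref_cols[p]]
    base <- ref_row[ref_cols[p]]
    col <- col[col != "-"]
    if (length(col) == 0L || base == "N") {
      conserved[p] <- FALSE
    } else {
      conserved[p] <- mean(col == base & col != "N") >= min_agree_frac
    }
  }
  # wipe conserved runs shorter than min_run
  r <- rle(conserved)
  r$values[r$values & r$lengths < min_run] <- FALSE
  conserved <- inverse.rle(r)
  out <- ref_row[ref_cols]
  out[!conserved] <- "N"
  structure(list(sequence = paste(out, collapse = ""),
                 retained_species = msa$species,
                 fraction_masked = mean(!conserved)),
            class = "masked_consensus")
}

#' @export
print.masked_consensus <- function(x, ...) {
  cat(sprintf("<masked_consensus> %d nt, %.1f%% masked (%d species)\n",
              nchar(x$sequence), 100 * x$fraction_masked,
              length(x$retained_species)))
  invisible(x)
}
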