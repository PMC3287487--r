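#' Over-representation scoring and the binary occurrence matrix
#'
#' The Over-Representation Index (ORI) compares a motif's occurrence rate
#' between the down-regulated and non-regulated promoter groups and
#' weights it by how evenly the motif is spread over the down-regulated
#' promoters:
#'
#' \deqn{ORI = \frac{Patt_p / S_p}{\max(Patt_{np}, 1) / S_{np}} \cdot
#'   \frac{N_p}{N_{promoter}}}
#'
#' where `Patt_p` / `Patt_np` are total motif occurrences in the
#' down-regulated / non-regulated promoters, `S_p` / `S_np` the number of
#' promoters scanned in each group, `N_p` the number of down-regulated
#' promoters containing at least one occurrence, and `N_promoter` the
#' total number of down-regulated promoters. A score above 1 indicates
#' over-representation; a high score indicates even presence across the
#' down-regulated promoters.
#'
#' @name enrichment
NULL

#' Count motif occurrences in a promoter group
#'
#' @param motif a `motif_model` (its degenerate consensus is scanned) or
#'   a plain consensus string.
#' @param promoters named character vector of (masked) promoter
#'   sequences.
#' @param budget substitution budget; default derived from the motif
#'   width via [substitution_budget()].
#' @return list with `patt` (total hits over both strands) and `n_with`
#'   (promoters with at least one hit), plus the per-promoter hit counts.
#' @export
count_occurrences <- function(motif, promoters, budget = NULL) {
  stopifnot(length(promoters) > 0L)
  cons <- if (inherits(motif, "motif_model")) motif$ambiguous_consensus
          else motif
  W <- length(consensus_tokens(cons))
  if (is.null(budget)) budget <- substitution_budget(W)
  per <- vapply(promoters, function(s) {
    nrow(locate_with_substitutions(cons, s, budget))
  }, integer(1))
  list(patt = sum(per), n_with = sum(per > 0L), per_promoter = per)
}

#' Compute the Over-Representation Index
#'
#' The occurrence-rate ratio between groups times the evenness fraction;
#' see [enrichment]. `max(patt_np, 1)` guards the zero-count denominator;
#' `smoothing = "add1"` uses `(patt_np + 1)` instead.
#'
#' @param patt_p total occurrences in down-regulated promoters.
#' @param patt_np total occurrences in non-regulated promoters.
#' @param n_p down-regulated promoters containing >= 1 occurrence.
#' @param n_promoter total down-regulated promoters.
#' @param s_p number of down-regulated promoters scanned (defaults to
#'   `n_promoter`).
#' @param s_np number of non-regulated promoters scanned.
#' @param smoothing `"max1"` (default) or `"add1"` handling of
#'   `patt_np = 0`.
#' @return non-negative finite ORI score.
#' @export
compute_ori <- function(patt_p, patt_np, n_p, n_promoter,
                        s_p = n_promoter, s_np,
                        smoothing = c("max1", "add1")) {
  smoothing <- match.arg(smoothing)
  stopifnot(s_p > 0, s_np > 0, n_promoter > 0, n_p >= 0,
            n_p <= n_promoter, patt_p >= 0, patt_np >= 0)
  denom_patt <- if (smoothing == "max1") max(patt_np, 1) else patt_np + 1
  (patt_p / s_p) / (denom_patt / s_np) * (n_p / n_promoter)
}

#' Score a motif set and rank functional motif candidates
#'
#' @param motifs list of `motif_model`s.
#' @param down_promoters,nonreg_promoters named character vectors of
#'   masked promoter sequences for the two groups.
#' @param smoothing passed to [compute_ori()].
#' @return data.frame (one row per motif) with `motif_id`, `consensus`,
#'   `width`, `is_mafb`, `patt_p`, `patt_np`, `n_p`, `n_promoter`, `ori`.
#' @export
score_motifs_ori <- function(motifs, down_promoters, nonreg_promoters,
                             smoothing = "max1") {
  rows <- lapply(motifs, function(m) {
    cd <- count_occurrences(m, down_promoters)
    cn <- count_occurrences(m, nonreg_promoters)
    data.frame(motif_id = m$motif_id, consensus = m$consensus,
               width = m$pwm$width, is_mafb = m$is_mafb,
               patt_p = cd$patt, patt_np = cn$patt, n_p = cd$n_with,
               n_promoter = length(down_promoters),
               ori = compute_ori(cd$patt, cn$patt, cd$n_with,
                                 length(down_promoters),
                                 length(down_promoters),
                                 length(nonreg_promoters),
                                 smoothing = smoothing),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank the top motif candidates by ORI
#'
#' @param ori_table output of [score_motifs_ori()].
#' @param top_k number of candidates (default 10).
#' @return the top rows, ordered by descending ORI; ties broken by
#'   ascending width then lexicographic motif id (a message notes ties).
#' @export
rank_candidates <- function(ori_table, top_k = 10L) {
  if (top_k > nrow(ori_table)) {
    warning("top_k = ", top_k, " exceeds the ", nrow(ori_table),
            " scored motifs; returning all")
    top_k <- nrow(ori_table)
  }
  ord <- order(-ori_table$ori, ori_table$width, ori_table$motif_id)
  out <- ori_table[ord, , drop = FALSE]
  cut <- out$ori[top_k]
  if (sum(out$ori == cut) > 1L &&
      any(out$ori[-seq_len(top_k)] == cut)) {
    message("ORI tie at the selection boundary (score ", signif(cut, 6),
            "); ties broken by width then motif id")
  }
  out[seq_len(top_k), , drop = FALSE]
}

#' Build the binary occurrence matrix
#'
#' Entries use the 1/2 coding: 2 when the motif has at least one hit in
#' the gene's promoter, 1 otherwise.
#'
#' @param candidates list of `motif_model`s (or consensus strings named
#'   by motif id).
#' @param promoters named character vector of promoters over all genes.
#' @param groups named character vector mapping gene id -> group label
#'   (`"down"` or `"nonreg"`).
#' @return an `occurrence_matrix`: integer matrix (genes x motifs) of
#'   1/2 values with a `groups` attribute.
#' @export
build_occurrence_matrix <- function(candidates, promoters, groups) {
  ids <- vapply(candidates, function(m) {
    if (inherits(m, "motif_model")) m$motif_id else NA_character_
  }, character(1))
  if (anyNA(ids)) ids <- names(candidates)
  mat <- sapply(candidates, function(m) {
    co <- count_occurrences(m, promoters)
    ifelse(co$per_promoter > 0L, 2L, 1L)
  })
  mat <- matrix(as.integer(mat), nrow = length(promoters),
                dimnames = list(names(promoters), ids))
  structure(mat, groups = groups[rownames(mat)],
            is_mafb = vapply(candidates, function(m) {
                        inherits(m, "motif_model") && isTRUE(m$is_mafb)
                      }, logical(1)),
            consensus = vapply(candidates, function(m) {
                          if (inherits(m, "motif_model")) m$consensus else m
                        }, character(1)),
            class = c("occurrence_matrix", "matrix", "array"))
}

#' Merge equivalent motif columns of an occurrence matrix
#'
#' Two columns are merged when their occurrence vectors are identical and
#' their consensi are reverse complements, or one consensus is a
#' substring of the other or of its reverse complement. Columns flagged
#' as MafB motifs are never merged.
#'
#' @param matrix an `occurrence_matrix` from [build_occurrence_matrix()].
#' @return list with `matrix` (merged columns; representative keeps its
#'   id) and `merge_map` (named list representative -> member ids).
#' @export
merge_equivalent_motifs <- function(matrix) {
  cons <- attr(matrix, "consensus")
  mafb <- attr(matrix, "is_mafb")
  k <- ncol(matrix)
  related <- function(a, b) {
    ra <- revcomp(a); rb <- revcomp(b)
    a == rb || grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE) ||
      grepl(a, rb, fixed = TRUE) || grepl(b, ra, fixed = TRUE)
  }
  rep_of <- seq_len(k)
  for (i in seq_len(k - 1L)) {
    if (mafb[i]) next
    for (j in seq.int(i + 1L, k)) {
      if (mafb[j] || rep_of[j] != j) next
      if (identical(matrix[, i], matrix[, j]) && related(cons[i], cons[j])) {
        rep_of[j] <- rep_of[i]
      }
    }
  }
  keep <- which(rep_of == seq_len(k))
  merge_map <- lapply(keep, function(i) colnames(matrix)[rep_of == i])
  names(merge_map) <- colnames(matrix)[keep]
  out <- matrix[, keep, drop = FALSE]
  attr(out, "groups") <- attr(matrix, "groups")
  attr(out, "is_mafb") <- mafb[keep]
  attr(out, "consensus") <- cons[keep]
  class(out) <- class(matrix)
  list(matrix = out, merge_map = merge_map)
}

#' Write an occurrence matrix as TSV (1/2 coding plus a group column)
#' @param matrix an `occurrence_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), group = attr(matrix, "groups"),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
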