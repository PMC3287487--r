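#' Promoter sequence and expression-table input/output
#'
#' Sequences are exchanged as FASTA with a `gene|species|tss` header dialect:
#' the record id encodes the gene id, the species and the 0-based index of
#' the transcription start site within the stored sequence, separated by
#' `|`. A missing third field falls back to `tss_index = 2000`, matching
#' promoters stored as a -2000/+300 window around the TSS.
#'
#' @name promoter-io
NULL

#' Construct a promoter record
#'
#' @param gene_id gene identifier.
#' @param species species label (e.g. `"mouse"`).
#' @param sequence nucleotide string; case-folded to upper and any character
#'   outside `A,C,G,T,N` replaced by `N`.
#' @param tss_index 0-based position of the transcription start site within
#'   `sequence`.
#' @return an object of class `promoter_record`.
#' @export
promoter_record <- function(gene_id, species, sequence, tss_index = 2000L) {
  sequence <- normalize_sequence(sequence)$sequence
  tss_index <- as.integer(tss_index)
  if (!nzchar(sequence)) stop("sequence must be non-empty for gene ", gene_id)
  if (tss_index < 0L || tss_index >= nchar(sequence)) {
    stop("tss_index ", tss_index, " outside sequence of length ",
         nchar(sequence), " for gene ", gene_id)
  }
  structure(
    list(gene_id = as.character(gene_id), species = as.character(species),
         sequence = sequence, tss_index = tss_index),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s [%s] %d nt, TSS at %d\n",
              x$gene_id, x$species, nchar(x$sequence), x$tss_index))
  invisible(x)
}

# Upper-case and restrict to the ACGTN alphabet; returns the number of
# substituted characters so callers can log them.
normalize_sequence <- function(sequence) {
  s <- toupper(as.character(sequence))
  bad <- gregexpr("[^ACGTN]", s)[[1]]
  n_sub <- if (bad[1] == -1L) 0L else length(bad)
  if (n_sub > 0L) s <- gsub("[^ACGTN]", "N", s)
  list(sequence = s, n_substituted = n_sub)
}

#' Read promoter records from FASTA
#'
#' Headers must follow the `gene|species|tss` dialect (see
#' [promoter-io]); the tss field may be omitted (default 2000). Sequences
#' are upper-cased and non-ACGTN characters are replaced by `N`; the number
#' of substitutions is reported via a message.
#'
#' @param path FASTA file path.
#' @return a list of [promoter_record()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0L) return(list())
  ids <- names(set)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1L])
  }
  total_sub <- 0L
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    fields <- strsplit(ids[i], "|", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 2L || !nzchar(fields[1]) || !nzchar(fields[2])) {
      stop("malformed FASTA header (expected gene|species[|tss]): ", ids[i])
    }
    tss <- if (length(fields) >= 3L) {
      t <- suppressWarnings(as.integer(fields[3]))
      if (is.na(t)) stop("malformed tss field in FASTA header: ", ids[i])
      t
    } else 2000L
    norm <- normalize_sequence(as.character(set[[i]]))
    total_sub <- total_sub + norm$n_substituted
    records[[i]] <- promoter_record(fields[1], fields[2], norm$sequence, tss)
  }
  if (total_sub > 0L) {
    message(total_sub, " non-ACGTN character(s) replaced by N in ", path)
  }
  records
}

#' Write promoter records to FASTA
#'
#' Inverse of [read_fasta()]: emits the `gene|species|tss` header dialect.
#'
#' @param records list of [promoter_record()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  names(seqs) <- vapply(
    records,
    function(r) paste(r$gene_id, r$species, r$tss_index, sep = "|"),
    character(1)
  )
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Extract the promoter window around the TSS
#'
#' Returns the half-open window `[tss - upstream, tss + downstream)`,
#' clipped to the sequence bounds; a full-length result has
#' `upstream + downstream` nucleotides.
#'
#' @param record a [promoter_record()].
#' @param upstream bases upstream of the TSS (default 2000).
#' @param downstream bases downstream of (and including) the TSS
#'   (default 300).
#' @return nucleotide string (possibly empty after clipping).
#' @export
extract_promoter_window <- function(record, upstream = 2000L,
                                    downstream = 300L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  len <- nchar(record$sequence)
  from <- max(0L, record$tss_index - as.integer(upstream))
  to <- min(len, record$tss_index + as.integer(downstream))  # exclusive
  if (from >= to) return("")
  substr(record$sequence, from + 1L, to)
}

#' Read an expression table
#'
#' Tab-separated with columns `gene_id`, `wt_signal`, `ko_signal` (a header
#' line is required). `wt_signal` is the wild-type processed signal,
#' `ko_signal` the knockout signal.
#'
#' @param path TSV file path.
#' @return data.frame with the three columns.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "wt_signal", "ko_signal")
  if (!all(need %in% names(df))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Write an expression table
#' @param df data.frame with `gene_id`, `wt_signal`, `ko_signal`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify genes into down-regulated and non-regulated sets
#'
#' A gene is down-regulated when its knockout/wild-type signal ratio falls
#' below `down_threshold` (default: less than half the wild-type level);
#' it is non-regulated when the ratio lies within `nonreg_tol` of
#' `nonreg_value` (default: exactly 1). Genes failing both criteria belong
#' to neither set. Genes with `wt_signal == 0` are excluded with a warning.
#'
#' @param expression data.frame with `gene_id`, `wt_signal`, `ko_signal`.
#' @param down_threshold ratio below which a gene is down-regulated.
#' @param nonreg_value target ratio of the non-regulated class.
#' @param nonreg_tol tolerance around `nonreg_value`.
#' @param force_down character vector of gene ids forced into the
#'   down-regulated set (manual-addition hook for genes missed upstream).
#' @return list with character vectors `down` and `nonreg` (disjoint).
#' @export
classify_genes <- function(expression, down_threshold = 0.5,
                           nonreg_value = 1.0, nonreg_tol = 0.0,
                           force_down = character(0)) {
  zero <- expression$wt_signal <= 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with non-positive wt_signal excluded: ",
            paste(utils::head(expression$gene_id[zero], 5), collapse = ", "))
    expression <- expression[!zero, , drop = FALSE]
  }
  ratio <- expression$ko_signal / expression$wt_signal
  down <- expression$gene_id[ratio < down_threshold]
  nonreg <- expression$gene_id[abs(ratio - nonreg_value) <= nonreg_tol]
  down <- union(down, force_down)
  nonreg <- setdiff(nonreg, down)
  list(down = down, nonreg = nonreg)
}

#' Read an orthologue table and assemble orthologue groups
#'
#' The orthologue table is tab-separated with columns `gene_id`, `species`,
#' `fasta_id`, mapping each (gene, species) pair to a FASTA record id in
#' the accompanying promoter FASTA.
#'
#' @param path TSV file path.
#' @return data.frame with the three columns.
#' @export
read_orthologue_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "fasta_id")
  if (!all(need %in% names(df))) {
    stop("orthologue table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Build orthologue groups from promoter records
#'
#' @param records list of [promoter_record()]s (one per species per gene,
#'   with headers already carrying gene and species).
#' @param reference reference species that every group must contain
#'   (default `"mouse"`).
#' @return named list of `orthologue_group` objects; each holds
#'   `gene_id` and `members`, a species-named list of promoter records.
#' @export
orthologue_groups <- function(records, reference = "mouse") {
  genes <- vapply(records, function(r) r$gene_id, character(1))
  out <- list()
  for (g in unique(genes)) {
    members <- records[genes == g]
    sp <- vapply(members, function(r) r$species, character(1))
    if (anyDuplicated(sp)) {
      stop("gene ", g, " has more than one record for species ",
           sp[duplicated(sp)][1L])
    }
    names(members) <- sp
    if (!reference %in% sp) {
      stop("gene ", g, " lacks the reference species '", reference, "'")
    }
    out[[g]] <- structure(list(gene_id = g, members = members),
                          class = "orthologue_group")
  }
  out
}

#' @export
print.orthologue_group <- function(x, ...) {
  cat(sprintf("<orthologue_group> %s: %s\n", x$gene_id,
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}
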