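#' Full-pipeline orchestration
#'
#' [run_full()] chains the analysis end to end: gene classification,
#' conservation masking, MafB motif extraction and the MafB-binding gene
#' set, de novo motif discovery, ORI ranking, the binary occurrence
#' matrix, log-linear model selection, motif combinations and the star
#' table. All stage parameters live in a [pipeline_config()]; every
#' intermediate is written to the output directory as plain text.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param promoters_fasta FASTA of promoters (header dialect
#'   `gene|species|tss`).
#' @param orthologue_tsv orthologue table TSV (`gene_id`, `species`,
#'   `fasta_id`).
#' @param expression_tsv expression table TSV (`gene_id`, `wt_signal`,
#'   `ko_signal`).
#' @param out_dir output directory for artifacts.
#' @param reference reference species (default `"mouse"`).
#' @param conserved_species species that must share a MafB motif
#'   (default mouse + human).
#' @param upstream,downstream promoter window around the TSS
#'   (defaults 2000 / 300).
#' @param down_threshold,nonreg_tol gene classification knobs.
#' @param min_score,min_len,max_len species-filter thresholds (defaults
#'   200, 500, 1000).
#' @param min_agree_frac,min_run conservation-masking knobs.
#' @param refine_rounds refinement passes over each alignment
#'   (default 2).
#' @param mafb_widths widths of the MafB motif models (default 8:11).
#' @param e_threshold MAST-style E-value cut-off (default 21).
#' @param widths,per_width de novo discovery widths and motifs per width
#'   (defaults 6,8,...,18 and 10).
#' @param top_k functional motif candidates kept by ORI (default 10).
#' @param ori_smoothing `"max1"` or `"add1"` (see [compute_ori()]).
#' @param alpha backward-elimination stopping threshold (default 0.001).
#' @param full full model for elimination (`"saturated"` or
#'   `"all_two_way"`).
#' @param force_down gene ids forced into the down-regulated set.
#' @param seed seed recorded in the report.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(promoters_fasta, orthologue_tsv,
                            expression_tsv, out_dir,
                            reference = "mouse",
                            conserved_species = c("mouse", "human"),
                            upstream = 2000L, downstream = 300L,
                            down_threshold = 0.5, nonreg_tol = 0.0,
                            min_score = 200, min_len = 500L,
                            max_len = 1000L, min_agree_frac = 0.5,
                            min_run = 6L, refine_rounds = 2L,
                            mafb_widths = 8:11, e_threshold = 21,
                            widths = c(6L, 8L, 10L, 12L, 14L, 16L, 18L),
                            per_width = 10L, top_k = 10L,
                            ori_smoothing = "max1", alpha = 0.001,
                            full = "saturated",
                            force_down = character(0), seed = 1L) {
  stopifnot(min_score > 0, min_len > 0, max_len >= min_len,
            e_threshold > 0, alpha > 0, top_k >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

mask_gene_group <- function(groups, config, params) {
  masked <- character(0)
  for (g in names(groups)) {
    grp <- groups[[g]]
    retained <- filter_species(grp, params, config$reference,
                               config$min_score, config$min_len,
                               config$max_len)
    msa <- progressive_msa(grp, retained, params, config$reference)
    if (length(msa$rows) > 1L && config$refine_rounds > 0L) {
      msa <- refine_msa(msa, params, config$refine_rounds)
    }
    mc <- suppressWarnings(
      mask_nonconserved(msa, config$reference, config$min_agree_frac,
                        config$min_run))
    masked[g] <- mc$sequence
  }
  masked
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @param params an [alignment_params()].
#' @return a `run_report` (stage counts, candidates, the `lgm_selection`
#'   and the star table); artifacts are written under `config$out_dir`.
#' @export
run_full <- function(config, params = alignment_params()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  report <- list(seed = config$seed)

  # --- classification
  expr <- read_expression_table(config$expression_tsv)
  cls <- classify_genes(expr, config$down_threshold, 1.0,
                        config$nonreg_tol, config$force_down)
  report$n_down <- length(cls$down)
  report$n_nonreg <- length(cls$nonreg)
  if (report$n_down == 0L) stop("stage classify: no down-regulated genes")

  # --- promoter windows and conservation masking
  records <- read_fasta(config$promoters_fasta)
  for (i in seq_along(records)) {
    r <- records[[i]]
    win <- extract_promoter_window(r, config$upstream, config$downstream)
    records[[i]] <- promoter_record(r$gene_id, r$species, win,
                                    min(r$tss_index, config$upstream))
  }
  groups <- orthologue_groups(records, config$reference)
  missing <- setdiff(c(cls$down, cls$nonreg), names(groups))
  if (length(missing)) {
    warning("stage mask: ", length(missing),
            " classified gene(s) without promoters dropped")
    cls$down <- intersect(cls$down, names(groups))
    cls$nonreg <- intersect(cls$nonreg, names(groups))
  }
  masked_down <- mask_gene_group(groups[cls$down], config, params)
  masked_nonreg <- mask_gene_group(groups[cls$nonreg], config, params)
  write_fasta(mapply(function(s, g) {
    promoter_record(g, config$reference, s,
                    min(config$upstream, nchar(s) - 1L))
  }, masked_down, names(masked_down), SIMPLIFY = FALSE),
  art("masked_down.fasta"))
  report$n_masked <- length(masked_down) + length(masked_nonreg)

  # --- MafB motifs and the MafB binding gene set
  mafb <- extract_mafb_motifs(widths = config$mafb_widths)
  write_motifs(mafb, art("mafb_motifs.txt"))
  scans <- list()
  for (sp in config$conserved_species) {
    seqs <- if (sp == config$reference) masked_down else {
      has <- vapply(groups[cls$down], function(g) sp %in% names(g$members),
                    logical(1))
      vapply(groups[cls$down][has],
             function(g) g$members[[sp]]$sequence, character(1))
    }
    scans[[sp]] <- lapply(mafb, function(m) {
      sr <- pwm_scan_evalue(m$pwm, seqs)
      absent <- setdiff(cls$down, sr$seq_id)
      if (length(absent)) {
        sr <- rbind(sr, data.frame(seq_id = absent, best_score = NA_real_,
                                   best_pos = NA_integer_,
                                   strand = NA_character_, p_value = 1,
                                   e_value = Inf))
      }
      sr
    })
  }
  binding_set <- select_mafb_binding_genes(scans, config$conserved_species,
                                           config$e_threshold)
  report$n_binding_set <- length(binding_set)
  if (length(binding_set) < 2L) {
    stop("stage mafb-select: fewer than 2 MafB binding genes")
  }
  writeLines(binding_set, art("mafb_binding_genes.txt"))

  # --- de novo discovery on the binding set
  found <- discover_motif_set(masked_down[binding_set],
                              widths = config$widths,
                              per_width = config$per_width)
  report$n_discovered <- length(found)
  all_motifs <- c(found, mafb)
  write_motifs(all_motifs, art("motifs.txt"))

  # --- ORI scoring and candidate ranking
  ori <- score_motifs_ori(all_motifs, masked_down[binding_set],
                          masked_nonreg, config$ori_smoothing)
  utils::write.table(ori, art("ori_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cand_tab <- rank_candidates(ori, config$top_k)
  report$n_candidates <- nrow(cand_tab)
  candidates <- all_motifs[match(cand_tab$motif_id,
                                 vapply(all_motifs, `[[`, character(1),
                                        "motif_id"))]

  # --- occurrence matrix over both groups, merged
  promoters <- c(masked_down[binding_set], masked_nonreg)
  grp_label <- stats::setNames(rep(c("down", "nonreg"),
                                   c(length(binding_set),
                                     length(masked_nonreg))),
                               names(promoters))
  occ <- build_occurrence_matrix(candidates, promoters, grp_label)
  merged <- merge_equivalent_motifs(occ)
  write_occurrence_matrix(merged$matrix, art("occurrence_matrix.tsv"))
  report$n_matrix_columns <- ncol(merged$matrix)

  # --- log-linear model selection
  tab <- tabulate_patterns(merged$matrix)
  sel <- backward_eliminate(tab, config$alpha, config$full)
  utils::write.table(sel$trace, art("elimination_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_graph_json(sel, art("independence_graph.json"))
  write_graph_dot(sel, art("independence_graph.dot"))
  combos <- extract_combinations(sel)
  report$n_combinations <- nrow(combos$pairs)

  # --- star table over the down-regulated genes
  stars <- star_table(merged$matrix, combos)
  star_df <- data.frame(gene = rownames(stars),
                        ifelse(stars, "*", ""), check.names = FALSE)
  utils::write.table(star_df, art("star_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report$selection <- sel
  report$combinations <- combos
  report$star_table <- stars
  report$candidates <- cand_tab
  report$binding_set <- binding_set
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  down-regulated genes:      %d\n", x$n_down))
  cat(sprintf("  non-regulated genes:       %d\n", x$n_nonreg))
  cat(sprintf("  masked promoters:          %d\n", x$n_masked))
  cat(sprintf("  MafB binding gene set:     %d\n", x$n_binding_set))
  cat(sprintf("  discovered motifs:         %d\n", x$n_discovered))
  cat(sprintf("  functional candidates:     %d\n", x$n_candidates))
  cat(sprintf("  occurrence-matrix columns: %d\n", x$n_matrix_columns))
  cat(sprintf("  retained combinations:     %d\n", x$n_combinations))
  invisible(x)
}

#' Count genes for a motif in a bundled or user star table
#'
#' Thin wrapper over [read_star_table()] + [count_genes_with_motif()];
#' prints and returns the count.
#'
#' @param fixture_path star-table TSV (default: the packaged star matrix
#'   of the 18 MafB binding genes).
#' @param motif motif display name, e.g. `"GATA-1"`.
#' @return integer count, invisibly.
#' @export
cmd_table5_check <- function(fixture_path = system.file(
                               "extdata", "star_table_mafb.tsv",
                               package = "comotif"),
                             motif = "GATA-1") {
  if (!nzchar(fixture_path) || !file.exists(fixture_path)) {
    stop("star-table fixture not found: ", fixture_path)
  }
  star <- read_star_table(fixture_path)
  n <- count_genes_with_motif(star, motif)
  cat(sprintf("%d genes carry a starred combination involving %s\n",
              n, motif))
  invisible(n)
}

#' Generate a synthetic run directory (wrapper)
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
cmd_simulate <- function(config, dir) {
  end_to_end_fixture(config, dir)
}
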