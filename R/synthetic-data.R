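#' Synthetic promoter and expression data with known truth
#'
#' Generates fully specified inputs for the pipeline: per-gene motif
#' presence/absence patterns drawn exactly from a log-linear joint
#' distribution (enumerated over the 2^k states, no MCMC), multi-species
#' promoters with a conserved core carrying the planted motif sites, and
#' a wild-type/knockout expression table whose classification recovers
#' the generated groups. Every operation is reproducible bit-for-bit for
#' a fixed seed.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults mirror the study conditions of the motivating analysis: 18
#' down-regulated (MafB-binding) genes, 211 non-regulated genes, 4
#' species, promoters spanning a -2000/+300 window (2300 nt).
#'
#' @param seed integer seed controlling all randomness.
#' @param k_motifs number of planted motifs (<= 12, exact enumeration).
#' @param planted_edges data.frame with columns `i`, `j`, `coef`
#'   (pairwise interaction coefficients, natural-log scale), or NULL.
#' @param main_effects per-motif main-effect coefficients (recycled).
#' @param n_down,n_nonreg group sizes (defaults 18 and 211).
#' @param n_species number of species including the mouse reference
#'   (default 4).
#' @param promoter_length promoter length in nt (default 2300,
#'   the -2000/+300 window).
#' @param conserved_core_length conserved core length (default 600,
#'   inside the 500-1000 nt consensus band used for species filtering).
#' @param gc_fraction background GC content (default 0.5).
#' @param site_mutation_prob per-position mutation probability of a
#'   planted site when copied to another species (default 0.05).
#' @param species_substitution_prob per-site substitution probability
#'   outside the conserved core in non-reference species (default 0.3).
#' @param nonreg_presence_prob independent per-motif presence probability
#'   in the non-regulated group (default 0.3).
#' @param motif_width width of planted motifs (default 10).
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, k_motifs = 10L,
                              planted_edges = NULL,
                              main_effects = 0,
                              n_down = 18L, n_nonreg = 211L,
                              n_species = 4L, promoter_length = 2300L,
                              conserved_core_length = 600L,
                              gc_fraction = 0.5,
                              site_mutation_prob = 0.05,
                              species_substitution_prob = 0.3,
                              nonreg_presence_prob = 0.3,
                              motif_width = 10L) {
  stopifnot(k_motifs >= 1L, k_motifs <= 12L,
            conserved_core_length <= promoter_length,
            gc_fraction > 0, gc_fraction < 1,
            site_mutation_prob >= 0, site_mutation_prob <= 1,
            species_substitution_prob >= 0,
            species_substitution_prob <= 1)
  if (is.null(planted_edges)) {
    planted_edges <- data.frame(i = integer(0), j = integer(0),
                                coef = numeric(0))
  }
  stopifnot(all(planted_edges$i >= 1), all(planted_edges$j <= k_motifs),
            all(planted_edges$i < planted_edges$j),
            all(is.finite(planted_edges$coef)))
  structure(list(seed = as.integer(seed), k_motifs = as.integer(k_motifs),
                 planted_edges = planted_edges,
                 main_effects = rep_len(main_effects, k_motifs),
                 n_down = as.integer(n_down),
                 n_nonreg = as.integer(n_nonreg),
                 n_species = as.integer(n_species),
                 promoter_length = as.integer(promoter_length),
                 conserved_core_length = as.integer(conserved_core_length),
                 gc_fraction = gc_fraction,
                 site_mutation_prob = site_mutation_prob,
                 species_substitution_prob = species_substitution_prob,
                 nonreg_presence_prob = nonreg_presence_prob,
                 motif_width = as.integer(motif_width)),
            class = "sim_config")
}

SIM_SPECIES <- c("mouse", "human", "rat", "cow", "dog", "chimp", "macaque")

#' Exact cell probabilities of the planted log-linear model
#'
#' `P(x) \%prop\% exp(sum_i main_i x_i + sum_(i,j) coef_ij x_i x_j)` over
#' all 2^k binary states, variable 1 fastest in the linear order.
#'
#' @param config a [simulation_config()].
#' @return list with `states` (2^k x k 0/1 matrix) and `prob`.
#' @export
enumerate_pattern_distribution <- function(config) {
  k <- config$k_motifs
  states <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(states) <- paste0("m", seq_len(k))
  eta <- states %*% config$main_effects
  if (nrow(config$planted_edges) > 0L) {
    for (r in seq_len(nrow(config$planted_edges))) {
      e <- config$planted_edges[r, ]
      eta <- eta + e$coef * states[, e$i] * states[, e$j]
    }
  }
  w <- exp(eta - max(eta))
  list(states = states, prob = as.vector(w / sum(w)))
}

#' Sample motif presence patterns for the down-regulated group
#'
#' Draws `n_down` patterns exactly from the enumerated joint
#' distribution.
#'
#' @param config a [simulation_config()].
#' @param n number of genes (default `config$n_down`).
#' @return 0/1 matrix genes x motifs.
#' @export
sample_presence_patterns <- function(config, n = config$n_down) {
  set.seed(config$seed)
  d <- enumerate_pattern_distribution(config)
  rows <- sample.int(nrow(d$states), n, replace = TRUE, prob = d$prob)
  out <- d$states[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sharp planted PWMs around random consensus words
#'
#' @param config a [simulation_config()] (`k_motifs`, `motif_width`,
#'   `seed` are used).
#' @param major probability of the consensus letter per column
#'   (default 0.91; the rest is spread evenly).
#' @return list of [pwm()] objects named `m1`, `m2`, ...
#' @export
planted_pwms <- function(config, major = 0.91) {
  set.seed(config$seed + 7L)
  lapply(stats::setNames(seq_len(config$k_motifs),
                         paste0("m", seq_len(config$k_motifs))),
         function(i) {
    word <- sample(DNA, config$motif_width, replace = TRUE)
    m <- matrix((1 - major) / 3, 4L, config$motif_width,
                dimnames = list(DNA, NULL))
    m[cbind(match(word, DNA), seq_len(config$motif_width))] <- major
    pwm(m)
  })
}

random_background <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

sample_site <- function(p) {
  paste(apply(p$mat, 2L, function(col) sample(DNA, 1L, prob = col)),
        collapse = "")
}

mutate_string <- function(s, prob) {
  if (prob <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(chars)) < prob
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Plant motif sites into multi-species synthetic promoters
#'
#' Per gene: an i.i.d. background promoter is drawn; each present motif
#' gets one site sampled from its PWM, placed at a random non-overlapping
#' offset inside the conserved core (on a random strand). Orthologues
#' copy the reference: positions outside the core are substituted with
#' `species_substitution_prob`, core positions with
#' `site_mutation_prob`. The TSS sits `downstream` bases before the 3'
#' end (2000 for the default 2300-nt window).
#'
#' @param presence 0/1 matrix genes x motifs (columns named as the pwms).
#' @param pwms list of [pwm()] objects, one per presence column.
#' @param config a [simulation_config()].
#' @param gene_ids gene identifiers (default `g001`, ...).
#' @return list with `records` (list of [promoter_record()]s for every
#'   gene and species) and `truth` (presence matrix, placements
#'   data.frame, planted edges, consensi).
#' @export
plant_motifs <- function(presence, pwms, config, gene_ids = NULL) {
  set.seed(config$seed + 1L)
  k <- ncol(presence)
  stopifnot(length(pwms) == k)
  if (is.null(colnames(presence))) {
    colnames(presence) <- names(pwms)
  }
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%03d", seq_len(nrow(presence)))
  }
  L <- config$promoter_length
  core_len <- config$conserved_core_length
  core_start <- (L - core_len) %/% 2L           # 0-based
  W <- config$motif_width
  max_sites <- core_len %/% (W + 2L)
  species <- SIM_SPECIES[seq_len(config$n_species)]
  tss <- max(L - 300L, 0L)
  records <- list()
  placements <- list()
  for (gi in seq_len(nrow(presence))) {
    seq_ref <- random_background(L, config$gc_fraction)
    idx_present <- which(presence[gi, ] == 1L)
    if (length(idx_present) > max_sites) {
      stop("conserved core too small for ", length(idx_present),
           " sites of width ", W)
    }
    # non-overlapping slots inside the core
    slots <- sample.int(max_sites, length(idx_present))
    for (s in seq_along(idx_present)) {
      m <- idx_present[s]
      site <- sample_site(pwms[[m]])
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") site <- revcomp(site)
      off <- core_start + (slots[s] - 1L) * (W + 2L)   # 0-based
      substr(seq_ref, off + 1L, off + W) <- site
      placements[[length(placements) + 1L]] <-
        data.frame(gene_id = gene_ids[gi],
                   motif = colnames(presence)[m],
                   offset = off, strand = strand,
                   stringsAsFactors = FALSE)
    }
    for (sp in species) {
      if (sp == species[1L]) {
        seq_sp <- seq_ref
      } else {
        pre <- substr(seq_ref, 1L, core_start)
        core <- substr(seq_ref, core_start + 1L, core_start + core_len)
        post <- substr(seq_ref, core_start + core_len + 1L, L)
        seq_sp <- paste0(
          mutate_string(pre, config$species_substitution_prob),
          mutate_string(core, config$site_mutation_prob),
          mutate_string(post, config$species_substitution_prob))
      }
      records[[length(records) + 1L]] <-
        promoter_record(gene_ids[gi], sp, seq_sp, tss)
    }
  }
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(gene_id = character(0), motif = character(0),
               offset = integer(0), strand = character(0))
  rownames(presence) <- gene_ids
  list(records = records,
       truth = list(presence = presence, placements = placements,
                    edges = config$planted_edges,
                    consensi = vapply(pwms, pwm_consensus, character(1)),
                    core = c(start = core_start, length = core_len)))
}

#' Generate a synthetic wild-type/knockout expression table
#'
#' Down-regulated genes get knockout/wild-type ratios uniform in
#' (0.05, 0.5); non-regulated genes get a ratio of exactly 1. Wild-type
#' signals are drawn log-uniformly inside the observed intensity band of
#' the study (roughly 5e2 to 2e5).
#'
#' @param config a [simulation_config()].
#' @param gene_ids optional gene ids (down genes first); default
#'   `g001`, ...
#' @return data.frame `gene_id`, `wt_signal`, `ko_signal`, `group`.
#' @export
generate_expression_table <- function(config, gene_ids = NULL) {
  set.seed(config$seed + 2L)
  n <- config$n_down + config$n_nonreg
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  wt <- 10^stats::runif(n, log10(500), log10(2e5))
  ratio <- c(stats::runif(config$n_down, 0.05, 0.5),
             rep(1, config$n_nonreg))
  data.frame(gene_id = gene_ids, wt_signal = wt, ko_signal = wt * ratio,
             group = rep(c("down", "nonreg"),
                         c(config$n_down, config$n_nonreg)),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic run directory
#'
#' Emits `promoters.fasta` (all species), `orthologues.tsv`,
#' `expression.tsv` and `truth.json` so the full pipeline can be run on
#' self-contained files. Down-regulated genes receive presence patterns
#' from the planted log-linear model; non-regulated genes from
#' independent Bernoulli draws with `nonreg_presence_prob`.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly, with the truth bundle attached as the
#'   `"truth"` attribute.
#' @export
end_to_end_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pwms <- planted_pwms(config)
  pres_down <- sample_presence_patterns(config)
  set.seed(config$seed + 3L)
  pres_nonreg <- matrix(
    stats::rbinom(config$n_nonreg * config$k_motifs, 1L,
                  config$nonreg_presence_prob),
    nrow = config$n_nonreg)
  colnames(pres_down) <- colnames(pres_nonreg) <- names(pwms)
  presence <- rbind(pres_down, pres_nonreg)
  planted <- plant_motifs(presence, pwms, config)
  write_fasta(planted$records, file.path(dir, "promoters.fasta"))
  ortho <- do.call(rbind, lapply(planted$records, function(r) {
    data.frame(gene_id = r$gene_id, species = r$species,
               fasta_id = paste(r$gene_id, r$species, r$tss_index,
                                sep = "|"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ortho, file.path(dir, "orthologues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- generate_expression_table(config)
  write_expression_table(expr[c("gene_id", "wt_signal", "ko_signal")],
                         file.path(dir, "expression.tsv"))
  truth <- planted$truth
  truth$groups <- stats::setNames(expr$group, expr$gene_id)
  jsonlite::write_json(
    list(presence = as.data.frame(truth$presence),
         gene_id = rownames(truth$presence),
         placements = truth$placements,
         edges = truth$edges,
         consensi = as.list(truth$consensi),
         core = as.list(truth$core),
         seed = config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  attr(dir, "truth") <- truth
  invisible(dir)
}
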