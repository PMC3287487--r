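#' Log-linear graphical models for binary motif occurrence tables
#'
#' The joint distribution of motif presence/absence across promoters is
#' modelled by hierarchical log-linear models whose interaction structure
#' is an undirected conditional-independence graph. Models are fitted by
#' iterative proportional fitting (IPF); edges are removed by backward
#' elimination using likelihood-ratio (deviance, G-squared) tests against
#' the chi-square reference distribution, until every remaining edge is
#' significant at `alpha`.
#'
#' @name lgm
NULL

#' Tabulate an occurrence matrix into a 2^k contingency table
#'
#' @param matrix an `occurrence_matrix` (1/2 coded) or any integer/logical
#'   genes-x-motifs matrix (2 or `TRUE` = present).
#' @return a `binary_table`: list with `counts` (k-dimensional array, 2
#'   levels per variable, variable 1 fastest in the linear cell order),
#'   `vars` and `n`.
#' @export
tabulate_patterns <- function(matrix) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("empty occurrence matrix")
  }
  k <- ncol(matrix)
  if (k > 16L) stop("more than 16 variables (2^k enumeration bound)")
  present <- if (is.logical(matrix)) matrix else matrix == 2L
  idx <- as.integer(present %*% 2^(seq_len(k) - 1L))  # bit i = variable i
  counts <- tabulate(idx + 1L, nbins = 2^k)
  arr <- array(counts, dim = rep(2L, k),
               dimnames = stats::setNames(
                 rep(list(c("absent", "present")), k), colnames(matrix)))
  structure(list(counts = arr, vars = colnames(matrix),
                 n = nrow(matrix)), class = "binary_table")
}

#' @export
print.binary_table <- function(x, ...) {
  cat(sprintf("<binary_table> %d variables, n = %d, %d non-empty cells\n",
              length(x$vars), x$n, sum(x$counts > 0)))
  invisible(x)
}

# number of identifiable parameters beyond the intercept: with effects
# (+/-1) coding over the full 2^k grid the columns for distinct non-empty
# variable subsets are mutually orthogonal, so the design-matrix rank is
# the size of the downward closure of the generating class.
model_rank <- function(generators, vars) {
  masks <- integer(0)
  for (g in generators) {
    idx <- match(g, vars)
    if (anyNA(idx)) stop("generator names unknown: ",
                         paste(g[is.na(idx)], collapse = ", "))
    bits <- 2^(idx - 1L)
    sub <- 0L
    # enumerate all non-empty subsets of the generator
    all_subsets <- unlist(lapply(seq_len(2^length(bits) - 1L), function(m) {
      sum(bits[bitwAnd(m, 2^(seq_along(bits) - 1L)) > 0L])
    }))
    masks <- union(masks, all_subsets)
  }
  length(masks)
}

normalize_generators <- function(generators, vars) {
  gens <- lapply(generators, function(g) {
    g <- as.character(g)
    if (!all(g %in% vars)) stop("unknown variable in generator: ",
                                paste(setdiff(g, vars), collapse = ", "))
    sort(g)
  })
  # drop generators contained in another
  keep <- vapply(seq_along(gens), function(i) {
    !any(vapply(seq_along(gens), function(j) {
      j != i && all(gens[[i]] %in% gens[[j]]) &&
        (length(gens[[j]]) > length(gens[[i]]) || j < i)
    }, logical(1)))
  }, logical(1))
  gens[keep]
}

#' Fit a hierarchical log-linear model by iterative proportional fitting
#'
#' Cycles over the generating class, scaling the fitted table so each
#' generator's fitted margin matches the observed margin, until the
#' largest absolute margin discrepancy falls below `tol`.
#'
#' @param table a [tabulate_patterns()] `binary_table`.
#' @param generators generating class: list of character vectors of
#'   variable names (maximal interaction terms).
#' @param tol convergence tolerance on margin discrepancies
#'   (default 1e-8).
#' @param max_iter maximum IPF cycles (default 2000).
#' @return an `lgm_fit` with the generating class, fitted cell means,
#'   `deviance` (G-squared vs the data), `df` (cells minus one minus the
#'   model rank), `converged`, `iterations`.
#' @export
ipf_fit <- function(table, generators, tol = 1e-8, max_iter = 2000L) {
  stopifnot(inherits(table, "binary_table"))
  vars <- table$vars
  gens <- normalize_generators(generators, vars)
  if (length(gens) == 0L) stop("empty generating class")
  obs <- table$counts
  k <- length(vars)
  fitted <- array(table$n / 2^k, dim = dim(obs), dimnames = dimnames(obs))
  gi <- lapply(gens, function(g) match(g, vars))
  obs_marg <- lapply(gi, function(ix) apply(obs, ix, sum))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (j in seq_along(gi)) {
      fm <- apply(fitted, gi[[j]], sum)
      ratio <- obs_marg[[j]] / fm
      ratio[!is.finite(ratio)] <- 0
      fitted <- sweep(fitted, gi[[j]], ratio, "*")
    }
    disc <- max(vapply(seq_along(gi), function(j) {
      max(abs(apply(fitted, gi[[j]], sum) - obs_marg[[j]]))
    }, numeric(1)))
    if (disc < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("IPF did not converge in ", max_iter, " cycles")
  }
  pos <- obs > 0
  g2 <- 2 * sum(obs[pos] * log(obs[pos] / fitted[pos]))
  rank <- model_rank(gens, vars)
  structure(list(generators = gens, fitted = fitted, observed = obs,
                 vars = vars, n = table$n, deviance = max(g2, 0),
                 df = (2^k - 1L) - rank, converged = converged,
                 iterations = it),
            class = "lgm_fit")
}

#' @export
print.lgm_fit <- function(x, ...) {
  gen <- paste(vapply(x$generators, paste, character(1), collapse = ","),
               collapse = " | ")
  cat(sprintf("<lgm_fit> [%s]\n  deviance %.4f on %d df (n = %d, %s)\n",
              gen, x$deviance, x$df, x$n,
              if (x$converged) paste0(x$iterations, " IPF cycles")
              else "NOT converged"))
  invisible(x)
}

#' @export
summary.lgm_fit <- function(object, ...) {
  cat("Hierarchical log-linear model fitted by IPF\n")
  print(object)
  p <- stats::pchisq(object$deviance, object$df, lower.tail = FALSE)
  cat(sprintf("  goodness of fit vs saturated: p = %.4f\n",
              if (object$df > 0) p else 1))
  invisible(object)
}

#' @export
fitted.lgm_fit <- function(object, ...) object$fitted

#' @export
residuals.lgm_fit <- function(object, type = c("pearson", "deviance"),
                              ...) {
  type <- match.arg(type)
  o <- object$observed
  f <- object$fitted
  if (type == "pearson") {
    r <- (o - f) / sqrt(pmax(f, .Machine$double.eps))
  } else {
    r <- sign(o - f) *
      sqrt(pmax(2 * (ifelse(o > 0, o * log(o / pmax(f, 1e-300)), 0) -
                       (o - f)), 0))
  }
  r
}

#' @export
coef.lgm_fit <- function(object, ...) {
  # effects-coded u-terms of the fitted log-linear expansion
  k <- length(object$vars)
  lf <- log(pmax(object$fitted, 1e-300))
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  v <- as.vector(lf)
  terms <- unlist(lapply(object$generators, function(g) {
    idx <- match(g, object$vars)
    lapply(seq_len(2^length(idx) - 1L), function(m) {
      idx[bitwAnd(m, 2^(seq_along(idx) - 1L)) > 0L]
    })
  }), recursive = FALSE)
  terms <- unique(lapply(terms, sort))
  out <- vapply(terms, function(t) {
    mean(v * apply(grid[, t, drop = FALSE], 1L, prod))
  }, numeric(1))
  names(out) <- vapply(terms, function(t) {
    paste(object$vars[t], collapse = ":")
  }, character(1))
  c("(intercept)" = mean(v), out)
}

#' @export
simulate.lgm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prob <- as.vector(object$fitted) / sum(object$fitted)
  k <- length(object$vars)
  lapply(seq_len(nsim), function(i) {
    cells <- sample.int(2^k, object$n, replace = TRUE, prob = prob)
    bits <- t(vapply(cells - 1L, function(c) {
      as.integer(bitwAnd(c, 2^(seq_len(k) - 1L)) > 0L)
    }, integer(k)))
    colnames(bits) <- object$vars
    bits + 1L   # 1/2 coding
  })
}

#' Likelihood-ratio (deviance) test between nested log-linear models
#'
#' @param rm the reduced model (`lgm_fit`).
#' @param fm the full model (`lgm_fit`); every generator of `rm` must be
#'   contained in a generator of `fm`.
#' @return list with `delta_g2`, `delta_df` and the upper-tail chi-square
#'   `p` value.
#' @export
deviance_test <- function(rm, fm) {
  nested <- all(vapply(rm$generators, function(g) {
    any(vapply(fm$generators, function(h) all(g %in% h), logical(1)))
  }, logical(1)))
  if (!nested) stop("models are not nested")
  delta_g2 <- max(rm$deviance - fm$deviance, 0)
  delta_df <- rm$df - fm$df
  p <- if (delta_df <= 0L) 1 else
    stats::pchisq(delta_g2, delta_df, lower.tail = FALSE)
  list(delta_g2 = delta_g2, delta_df = delta_df, p = p)
}

# maximal cliques of an undirected graph given as a logical adjacency
# matrix (Bron-Kerbosch); isolated vertices come back as singletons.
maximal_cliques <- function(adj) {
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) return(list(R))
    out <- list()
    for (v in P) {
      Nv <- which(adj[v, ])
      out <- c(out, bk(c(R, v), intersect(P, Nv), intersect(X, Nv)))
      P <- setdiff(P, v)
      X <- union(X, v)
    }
    out
  }
  bk(integer(0), seq_len(nrow(adj)), integer(0))
}

graph_generators <- function(adj, vars) {
  lapply(maximal_cliques(adj), function(cl) vars[sort(cl)])
}

#' Backward edge elimination of a log-linear graphical model
#'
#' Starts from the full model (saturated, i.e. the complete graph, or all
#' two-way interactions) and repeatedly removes the edge whose single-edge
#' deviance test against the current model has the largest p-value, as
#' long as that p-value is at least `alpha`. Each candidate is the
#' graphical model generated by the maximal cliques of the graph without
#' that edge.
#'
#' @param table a `binary_table`.
#' @param alpha stopping threshold: elimination stops when every
#'   remaining edge's removal tests at p < `alpha` (default 0.001).
#' @param full `"saturated"` (default) or `"all_two_way"` starting model.
#' @param tol,max_iter passed to [ipf_fit()].
#' @return an `lgm_selection` with the final `graph` (nodes, edge
#'   data.frame), the elimination `trace` (per step: removed edge,
#'   deviance and df change, p-value, plus the cumulative test vs the
#'   full model), the final and full fits, and the final-vs-full test.
#' @export
backward_eliminate <- function(table, alpha = 0.001,
                               full = c("saturated", "all_two_way"),
                               tol = 1e-8, max_iter = 2000L) {
  full <- match.arg(full)
  vars <- table$vars
  k <- length(vars)
  adj <- matrix(TRUE, k, k, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  fm_gens <- if (full == "saturated") list(vars) else {
    pairs <- utils::combn(vars, 2L, simplify = FALSE)
    if (k == 1L) list(vars) else pairs
  }
  fm_fit <- ipf_fit(table, fm_gens, tol, max_iter)
  current_fit <- fm_fit
  trace <- data.frame(edge_a = character(0), edge_b = character(0),
                      delta_g2 = numeric(0), delta_df = integer(0),
                      p = numeric(0), cum_g2 = numeric(0),
                      cum_df = integer(0), cum_p = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (nrow(edges) == 0L) break
    best <- NULL
    for (e in seq_len(nrow(edges))) {
      cand_adj <- adj
      cand_adj[edges[e, 1L], edges[e, 2L]] <- FALSE
      cand_adj[edges[e, 2L], edges[e, 1L]] <- FALSE
      cand_fit <- tryCatch(
        ipf_fit(table, graph_generators(cand_adj, vars), tol, max_iter),
        error = function(err) NULL)
      if (is.null(cand_fit)) next
      if (!cand_fit$converged) {
        warning("skipping non-convergent candidate without edge ",
                vars[edges[e, 1L]], "-", vars[edges[e, 2L]])
        next
      }
      tst <- deviance_test(cand_fit, current_fit)
      if (is.null(best) || tst$p > best$p) {
        best <- list(e = e, fit = cand_fit, adj = cand_adj, p = tst$p,
                     delta_g2 = tst$delta_g2, delta_df = tst$delta_df)
      }
    }
    if (is.null(best) || best$p < alpha) break
    cum <- deviance_test(best$fit, fm_fit)
    trace <- rbind(trace, data.frame(
      edge_a = vars[edges[best$e, 1L]], edge_b = vars[edges[best$e, 2L]],
      delta_g2 = best$delta_g2, delta_df = best$delta_df, p = best$p,
      cum_g2 = cum$delta_g2, cum_df = cum$delta_df, cum_p = cum$p,
      stringsAsFactors = FALSE))
    adj <- best$adj
    current_fit <- best$fit
  }
  final_edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  graph <- list(nodes = vars,
                edges = data.frame(a = vars[final_edges[, 1L]],
                                   b = vars[final_edges[, 2L]],
                                   stringsAsFactors = FALSE))
  structure(list(graph = graph, trace = trace, final_fit = current_fit,
                 fm_fit = fm_fit, alpha = alpha, full = full,
                 final_vs_full = deviance_test(current_fit, fm_fit)),
            class = "lgm_selection")
}

#' @export
print.lgm_selection <- function(x, ...) {
  tst <- x$final_vs_full
  cat(sprintf(paste0("<lgm_selection> %d nodes, %d edges retained ",
                     "(alpha %.3g, %s full model)\n",
                     "  final vs full: deviance %.3f on %d df, p = %.3f\n"),
              length(x$graph$nodes), nrow(x$graph$edges), x$alpha, x$full,
              tst$delta_g2, tst$delta_df, tst$p))
  invisible(x)
}

#' @export
summary.lgm_selection <- function(object, ...) {
  print(object)
  if (nrow(object$trace) > 0L) {
    cat("Elimination trace:\n")
    print(object$trace, digits = 4)
  }
  if (nrow(object$graph$edges) > 0L) {
    cat("Retained edges:\n")
    for (i in seq_len(nrow(object$graph$edges))) {
      cat("  ", object$graph$edges$a[i], "--",
          object$graph$edges$b[i], "\n")
    }
  }
  invisible(object)
}

#' @export
plot.lgm_selection <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting the independence graph requires the igraph package")
  }
  g <- igraph::graph_from_data_frame(x$graph$edges, directed = FALSE,
                                     vertices = x$graph$nodes)
  plot(g, ...)
  invisible(x)
}

#' Extract motif combinations from an independence graph
#'
#' One combination per retained edge; per node, its neighbours are
#' reported as the "linked motifs".
#'
#' @param selection an `lgm_selection` (or a graph list with `nodes` and
#'   `edges`).
#' @return list with `pairs` (data.frame `motif_a`, `motif_b`) and
#'   `linked` (named list node -> neighbour character vector).
#' @export
extract_combinations <- function(selection) {
  graph <- if (inherits(selection, "lgm_selection")) selection$graph
           else selection
  edges <- graph$edges
  linked <- stats::setNames(lapply(graph$nodes, function(v) {
    sort(unique(c(edges$b[edges$a == v], edges$a[edges$b == v])))
  }), graph$nodes)
  list(pairs = data.frame(motif_a = edges$a, motif_b = edges$b,
                          stringsAsFactors = FALSE),
       linked = linked)
}

#' Gene-by-combination star table
#'
#' A star marks a gene whose promoter carries both motifs of a
#' combination (both coded 2 in the occurrence matrix). Rows are
#' restricted to the down-regulated genes.
#'
#' @param matrix an `occurrence_matrix`.
#' @param combinations data.frame with `motif_a`, `motif_b` columns (or
#'   the output of [extract_combinations()]).
#' @return logical matrix genes x combinations; column names
#'   `"motif_a|motif_b"`.
#' @export
star_table <- function(matrix, combinations) {
  if (is.list(combinations) && !is.data.frame(combinations)) {
    combinations <- combinations$pairs
  }
  unknown <- setdiff(c(combinations$motif_a, combinations$motif_b),
                     colnames(matrix))
  if (length(unknown)) {
    stop("combination motif(s) not in occurrence matrix: ",
         paste(unknown, collapse = ", "))
  }
  groups <- attr(matrix, "groups")
  rows <- if (is.null(groups)) rownames(matrix) else
    rownames(matrix)[groups == "down"]
  out <- matrix(FALSE, length(rows), nrow(combinations),
                dimnames = list(rows, paste(combinations$motif_a,
                                            combinations$motif_b,
                                            sep = "|")))
  for (j in seq_len(nrow(combinations))) {
    out[, j] <- matrix[rows, combinations$motif_a[j]] == 2L &
      matrix[rows, combinations$motif_b[j]] == 2L
  }
  out
}

#' Read a star-table TSV
#'
#' Expects a `gene` column followed by combination columns named
#' `"motif|linked1;linked2;..."` (or `"motif_a|motif_b"`), with `*`
#' marking a star.
#'
#' @param path TSV path. The packaged star matrix of the 18 MafB binding
#'   genes is at `system.file("extdata", "star_table_mafb.tsv",
#'   package = "comotif")`.
#' @return logical matrix genes x combinations.
#' @export
read_star_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = NULL)
  if (nrow(df) == 0L) {
    return(matrix(FALSE, 0L, max(ncol(df) - 1L, 0L),
                  dimnames = list(NULL, setdiff(names(df), "gene"))))
  }
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE]) == "*"
  m[is.na(m)] <- FALSE
  rownames(m) <- genes
  m
}

#' Count genes carrying a motif within a starred combination
#'
#' Counts the genes with at least one star in any combination column
#' whose motif or linked-motif set includes `motif`; column names are
#' parsed on `|` and `;`.
#'
#' @param star logical star matrix ([star_table()] or
#'   [read_star_table()]).
#' @param motif motif display name, e.g. `"GATA-1"`.
#' @return integer gene count.
#' @export
count_genes_with_motif <- function(star, motif) {
  if (ncol(star) == 0L || nrow(star) == 0L) {
    if (ncol(star) > 0L) return(0L)
    return(0L)
  }
  col_sets <- lapply(colnames(star), function(nm) {
    unlist(strsplit(nm, "[|;]"))
  })
  if (!motif %in% unlist(col_sets)) {
    stop("motif '", motif, "' appears in no combination column")
  }
  cols <- which(vapply(col_sets, function(s) motif %in% s, logical(1)))
  sum(rowSums(star[, cols, drop = FALSE]) > 0L)
}

#' Write an independence graph as JSON
#' @param selection an `lgm_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(selection, path) {
  tst <- selection$final_vs_full
  obj <- list(nodes = selection$graph$nodes,
              edges = selection$graph$edges,
              alpha = selection$alpha,
              final_deviance_vs_full = tst$delta_g2,
              final_df_vs_full = tst$delta_df,
              final_p_vs_full = tst$p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an independence graph in DOT format
#' @param selection an `lgm_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(selection, path) {
  lines <- c("graph independence {",
             paste0("  \"", selection$graph$nodes, "\";"),
             if (nrow(selection$graph$edges) > 0L) {
               paste0("  \"", selection$graph$edges$a, "\" -- \"",
                      selection$graph$edges$b, "\";")
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}
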