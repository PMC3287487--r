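mk_patterns <- function(pat, n) {
  matrix(rep(pat, n), ncol = length(pat), byrow = TRUE)
}

test_that("pattern tabulation counts cells and conserves the total", {
  m <- rbind(c(2, 2), c(2, 2), c(1, 2), c(1, 1))
  colnames(m) <- c("A", "B")
  tab <- tabulate_patterns(m)
  expect_equal(tab$n, 4L)
  expect_equal(tab$counts["absent", "absent"], 1L)   # pattern (1,1)
  expect_equal(tab$counts["absent", "present"], 1L)  # pattern (1,2)
  expect_equal(tab$counts["present", "absent"], 0L)
  expect_equal(tab$counts["present", "present"], 2L)
  expect_equal(sum(tab$counts), nrow(m))
  expect_error(tabulate_patterns(m[0, , drop = FALSE]), "empty")
  wide <- matrix(1L, 2, 17,
                 dimnames = list(NULL, paste0("v", 1:17)))
  expect_error(tabulate_patterns(wide), "16")
})

test_that("IPF reproduces closed forms exactly", {
  # saturated: fitted = observed, deviance 0, df 0
  occ <- rbind(mk_patterns(c(1, 1), 40), mk_patterns(c(2, 1), 10),
               mk_patterns(c(1, 2), 40), mk_patterns(c(2, 2), 10))
  colnames(occ) <- c("A", "B")
  tab <- tabulate_patterns(occ)
  sat <- ipf_fit(tab, list(c("A", "B")))
  expect_lt(abs(sat$deviance), 1e-9)
  expect_equal(sat$df, 0L)
  expect_equal(as.vector(sat$fitted), as.vector(tab$counts))

  # independence on independent data: fitted = row x col / n
  ind <- ipf_fit(tab, list("A", "B"))
  expect_equal(as.vector(ind$fitted), c(40, 10, 40, 10),
               tolerance = 1e-8)
  expect_lt(abs(ind$deviance), 1e-9)
  expect_equal(ind$df, 1L)

  # decomposable {AB},{BC}: fitted = n(ab) n(bc) / n(b)
  set.seed(701)
  m3 <- cbind(A = sample(1:2, 80, TRUE), B = sample(1:2, 80, TRUE),
              C = sample(1:2, 80, TRUE))
  t3 <- tabulate_patterns(m3)
  fit3 <- ipf_fit(t3, list(c("A", "B"), c("B", "C")))
  nab <- apply(t3$counts, c(1, 2), sum)
  nbc <- apply(t3$counts, c(2, 3), sum)
  nb <- apply(t3$counts, 2, sum)
  closed <- array(0, dim = rep(2, 3))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    closed[a, b, cc] <- nab[a, b] * nbc[b, cc] / nb[b]
  }
  expect_lt(max(abs(fit3$fitted - closed)), 1e-6)
})

test_that("IPF margins match observations and agree with stats::loglin", {
  set.seed(702)
  for (rep in 1:5) {
    k <- sample(3:4, 1)
    m <- matrix(sample(1:2, 60 * k, TRUE), ncol = k,
                dimnames = list(NULL, LETTERS[1:k]))
    tab <- tabulate_patterns(m)
    gens <- list(LETTERS[1:2], LETTERS[2:3],
                 if (k == 4) LETTERS[3:4] else LETTERS[c(1, 3)])
    fit <- ipf_fit(tab, gens, tol = 1e-10)
    # fitted margins equal observed margins on every generator
    for (g in gens) {
      ix <- match(g, tab$vars)
      expect_lt(max(abs(apply(fit$fitted, ix, sum) -
                          apply(tab$counts, ix, sum))), 1e-6)
    }
    expect_equal(sum(fit$fitted), tab$n, tolerance = 1e-8)
    # independent implementation: stats::loglin
    ref <- stats::loglin(tab$counts, lapply(gens, match, tab$vars),
                         print = FALSE)
    expect_lt(abs(fit$deviance - ref$lrt), 1e-5)
    expect_equal(fit$df, ref$df)
  }
})

test_that("deviance tests reproduce closed forms and chi-square tails", {
  occ <- rbind(mk_patterns(c(1, 1), 30), mk_patterns(c(2, 1), 10),
               mk_patterns(c(1, 2), 10), mk_patterns(c(2, 2), 30))
  colnames(occ) <- c("A", "B")
  tab <- tabulate_patterns(occ)
  rm <- ipf_fit(tab, list("A", "B"))
  fm <- ipf_fit(tab, list(c("A", "B")))
  tst <- deviance_test(rm, fm)
  expect_equal(tst$delta_g2, 2 * (60 * log(1.5) - 20 * log(2)),
               tolerance = 1e-8)
  expect_equal(tst$delta_df, 1L)
  expect_lt(tst$p, 0.001)
  # identical models
  same <- deviance_test(fm, fm)
  expect_equal(same$delta_g2, 0)
  expect_equal(same$p, 1)
  expect_error(deviance_test(fm, rm), "not nested")
  # p-value equals numerical integration of the chi-square density
  # (integrate the finite lower tail; the upper bound is improper)
  for (case in list(c(20.93, 1), c(122.806, 1001), c(5, 3))) {
    p_int <- 1 - stats::integrate(stats::dchisq, 0, case[1],
                                  df = case[2], rel.tol = 1e-12)$value
    expect_lt(abs(stats::pchisq(case[1], case[2], lower.tail = FALSE) -
                    p_int), 1e-6)
  }
})

test_that("backward elimination keeps real edges and drops absent ones", {
  ind <- rbind(mk_patterns(c(1, 1), 40), mk_patterns(c(2, 1), 10),
               mk_patterns(c(1, 2), 40), mk_patterns(c(2, 2), 10))
  colnames(ind) <- c("A", "B")
  sel <- backward_eliminate(tabulate_patterns(ind), 0.001)
  expect_equal(nrow(sel$graph$edges), 0L)

  dep <- rbind(mk_patterns(c(1, 1), 30), mk_patterns(c(2, 1), 10),
               mk_patterns(c(1, 2), 10), mk_patterns(c(2, 2), 30))
  colnames(dep) <- c("A", "B")
  sel2 <- backward_eliminate(tabulate_patterns(dep), 0.001)
  expect_equal(nrow(sel2$graph$edges), 1L)
  # deviance vs full model never decreases along the trace
  expect_true(all(diff(c(0, sel2$trace$cum_g2)) >= -1e-9))
})

test_that("the modelling methods behave like a classed fit", {
  set.seed(703)
  m <- cbind(A = sample(1:2, 50, TRUE), B = sample(1:2, 50, TRUE))
  tab <- tabulate_patterns(m)
  fit <- ipf_fit(tab, list("A", "B"))
  expect_s3_class(fit, "lgm_fit")
  expect_equal(dim(fitted(fit)), c(2L, 2L))
  expect_equal(sum(residuals(fit) * sqrt(fitted(fit))), 0,
               tolerance = 1e-6)
  cf <- coef(fit)
  expect_true(all(c("(intercept)", "A", "B") %in% names(cf)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), c(50L, 2L))
  expect_true(all(sims[[1]] %in% 1:2))
  expect_output(print(fit), "deviance")
})

test_that("combinations enumerate edges and neighbour sets", {
  empty <- extract_combinations(list(nodes = c("A", "B"),
                                     edges = data.frame(a = character(0),
                                                        b = character(0))))
  expect_equal(nrow(empty$pairs), 0L)
  tri <- extract_combinations(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"))))
  expect_equal(nrow(tri$pairs), 3L)
  expect_setequal(tri$linked$A, c("B", "C"))
})

test_that("the star table marks pairwise co-occurrence in down genes", {
  occ <- rbind(g1 = c(2, 2, 2), g2 = c(1, 1, 1), g3 = c(2, 1, 2),
               g4 = c(2, 2, 2))
  colnames(occ) <- c("A", "B", "C")
  occ <- structure(occ, groups = c(g1 = "down", g2 = "down",
                                   g3 = "down", g4 = "nonreg"),
                   class = c("occurrence_matrix", "matrix", "array"))
  combos <- data.frame(motif_a = c("A", "B"), motif_b = c("B", "C"))
  stars <- star_table(occ, combos)
  expect_equal(rownames(stars), c("g1", "g2", "g3"))  # down genes only
  expect_true(all(stars["g1", ]))
  expect_false(any(stars["g2", ]))
  expect_equal(unname(stars["g3", ]), c(FALSE, FALSE))
  expect_error(star_table(occ, data.frame(motif_a = "A", motif_b = "Z")),
               "not in occurrence matrix")
})

test_that("gene counting over star columns matches hand counts", {
  path <- system.file("extdata", "star_table_mafb.tsv",
                      package = "comotif")
  star <- read_star_table(path)
  expect_equal(dim(star), c(18L, 10L))
  expect_equal(count_genes_with_motif(star, "GATA-1"), 15L)
  expect_equal(count_genes_with_motif(star, "AP2"), 9L)
  expect_error(count_genes_with_motif(star, "NOSUCH"), "no combination")
  # fully starred table: every gene counts
  full <- matrix(TRUE, 4, 2,
                 dimnames = list(paste0("g", 1:4), c("A|B", "B|C")))
  expect_equal(count_genes_with_motif(full, "B"), 4L)
  # empty table
  empty <- full[0, , drop = FALSE]
  expect_equal(count_genes_with_motif(empty, "B"), 0L)
})

test_that("graph artifacts serialize to JSON and DOT", {
  dep <- rbind(mk_patterns(c(1, 1), 30), mk_patterns(c(2, 1), 10),
               mk_patterns(c(1, 2), 10), mk_patterns(c(2, 2), 30))
  colnames(dep) <- c("A", "B")
  sel <- backward_eliminate(tabulate_patterns(dep), 0.001)
  jf <- withr::local_tempfile(fileext = ".json")
  df <- withr::local_tempfile(fileext = ".dot")
  write_graph_json(sel, jf)
  write_graph_dot(sel, df)
  parsed <- jsonlite::read_json(jf)
  expect_equal(length(parsed$nodes), 2L)
  expect_match(paste(readLines(df), collapse = " "), "\"A\" -- \"B\"")
})
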