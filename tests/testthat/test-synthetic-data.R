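test_that("pattern sampling matches the enumerated joint distribution", {
  # uniform model: marginals 0.5
  cfg0 <- simulation_config(seed = 801, k_motifs = 3)
  d0 <- enumerate_pattern_distribution(cfg0)
  expect_equal(d0$prob, rep(1 / 8, 8))
  pats <- sample_presence_patterns(cfg0, n = 20000)
  expect_equal(unname(colMeans(pats)), rep(0.5, 3), tolerance = 0.02)

  # near-infinite coupling locks the pair together
  cfg_lock <- simulation_config(seed = 802, k_motifs = 2,
                                planted_edges = data.frame(i = 1, j = 2,
                                                           coef = 20))
  locked <- sample_presence_patterns(cfg_lock, n = 2000)
  expect_true(all(locked[, 1] == locked[, 2]))

  # k = 3, one edge coef 1.5: empirical cells within 3 SE of enumeration
  cfg <- simulation_config(seed = 803, k_motifs = 3,
                           planted_edges = data.frame(i = 1, j = 2,
                                                      coef = 1.5))
  d <- enumerate_pattern_distribution(cfg)
  n <- 50000
  pats <- sample_presence_patterns(cfg, n = n)
  cell <- pats %*% 2^(0:2)
  emp <- tabulate(cell + 1, nbins = 8) / n
  se <- sqrt(d$prob * (1 - d$prob) / n)
  expect_true(all(abs(emp - d$prob) <= 3 * se + 1e-12))
  # goodness of fit of the whole sample
  gof <- chisq.test(tabulate(cell + 1, nbins = 8), p = d$prob)
  expect_gt(gof$p.value, 0.01)
})

test_that("sampling is reproducible bit-for-bit per seed", {
  cfg <- simulation_config(seed = 804, k_motifs = 4)
  expect_identical(sample_presence_patterns(cfg),
                   sample_presence_patterns(cfg))
  expect_identical(generate_expression_table(cfg),
                   generate_expression_table(cfg))
  cfg2 <- simulation_config(seed = 805, k_motifs = 4)
  expect_false(identical(sample_presence_patterns(cfg),
                         sample_presence_patterns(cfg2)))
})

test_that("noise-free planting writes exact consensus sites everywhere", {
  cfg <- simulation_config(seed = 806, k_motifs = 2, n_down = 4,
                           n_species = 3, promoter_length = 200,
                           conserved_core_length = 80,
                           site_mutation_prob = 0,
                           species_substitution_prob = 0)
  pwms <- planted_pwms(cfg, major = 1)  # point-mass PWMs
  presence <- matrix(1L, 4, 2, dimnames = list(NULL, names(pwms)))
  planted <- plant_motifs(presence, pwms, cfg)
  cons <- planted$truth$consensi
  for (r in planted$records) {
    for (m in names(pwms)) {
      hits <- locate_with_substitutions(cons[[m]], r$sequence, 0)
      expect_gte(nrow(hits), 1L)
    }
  }
  # all-absent row yields background only
  pres0 <- matrix(0L, 2, 2, dimnames = list(NULL, names(pwms)))
  bg_only <- plant_motifs(pres0, pwms, cfg)
  expect_equal(nrow(bg_only$truth$placements), 0L)
})

test_that("planted sites are recovered by scanning at the stated budget", {
  cfg <- simulation_config(seed = 807, k_motifs = 3, n_down = 30,
                           n_species = 2, promoter_length = 300,
                           conserved_core_length = 150,
                           site_mutation_prob = 0.05)
  pwms <- planted_pwms(cfg, major = 1)
  set.seed(807)
  presence <- matrix(rbinom(30 * 3, 1, 0.6), 30, 3,
                     dimnames = list(NULL, names(pwms)))
  planted <- plant_motifs(presence, pwms, cfg)
  cons <- planted$truth$consensi
  pl <- planted$truth$placements
  # scan the orthologue copy, whose core carries the 0.05 mutation rate
  human <- Filter(function(r) r$species == "human", planted$records)
  seqs <- vapply(human, function(r) r$sequence, character(1))
  names(seqs) <- vapply(human, function(r) r$gene_id, character(1))
  budget <- substitution_budget(cfg$motif_width)
  found <- vapply(seq_len(nrow(pl)), function(i) {
    hits <- locate_with_substitutions(cons[[pl$motif[i]]],
                                      seqs[[pl$gene_id[i]]], budget)
    pl$offset[i] %in% hits$position
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("the expression table round-trips through classification", {
  cfg <- simulation_config(seed = 808)
  expr <- generate_expression_table(cfg)
  expect_equal(nrow(expr), 229L)   # 18 down + 211 non-regulated
  cls <- classify_genes(expr[c("gene_id", "wt_signal", "ko_signal")])
  expect_setequal(cls$down, expr$gene_id[expr$group == "down"])
  expect_setequal(cls$nonreg, expr$gene_id[expr$group == "nonreg"])
})

test_that("the end-to-end fixture is complete and schema-stable", {
  cfg <- simulation_config(seed = 809, k_motifs = 3, n_down = 6,
                           n_nonreg = 10, n_species = 2,
                           promoter_length = 150,
                           conserved_core_length = 80)
  dir <- withr::local_tempdir()
  end_to_end_fixture(cfg, dir)
  expect_setequal(list.files(dir),
                  c("promoters.fasta", "orthologues.tsv",
                    "expression.tsv", "truth.json"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$gene_id, 16L)
  expect_equal(truth$seed, 809L)
  recs <- read_fasta(file.path(dir, "promoters.fasta"))
  expect_length(recs, 16L * 2L)
  # every recorded placement exists in the emitted reference sequence
  pl <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)$placements
  mouse <- Filter(function(r) r$species == "mouse", recs)
  names(mouse) <- vapply(mouse, function(r) r$gene_id, character(1))
  if (length(pl) && nrow(pl) > 0) {
    cons <- unlist(jsonlite::read_json(file.path(dir, "truth.json"),
                                       simplifyVector = TRUE)$consensi)
    ok <- vapply(seq_len(nrow(pl)), function(i) {
      hits <- locate_with_substitutions(cons[[pl$motif[i]]],
                                        mouse[[pl$gene_id[i]]]$sequence,
                                        substitution_budget(cfg$motif_width))
      pl$offset[i] %in% hits$position
    }, logical(1))
    expect_gte(mean(ok), 0.9)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(k_motifs = 20), "k_motifs")
  expect_error(simulation_config(k_motifs = 4,
                                 planted_edges = data.frame(i = 2, j = 1,
                                                            coef = 1)))
})
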