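make_group <- function(gene_id, seqs) {
  members <- mapply(function(sp, s) promoter_record(gene_id, sp, s, 0),
                    names(seqs), seqs, SIMPLIFY = FALSE)
  structure(list(gene_id = gene_id, members = members),
            class = "orthologue_group")
}

test_that("identical sequences align gaplessly at match x length", {
  params <- alignment_params()
  s <- paste(rep(c("A", "C", "G", "T"), length.out = 10), collapse = "")
  al <- sw_gotoh(s, s, params)
  expect_equal(al$score, 5 * 10)
  expect_equal(al$aligned_a, al$aligned_b)
  expect_false(grepl("-", al$aligned_a))
})

test_that("dissimilar sequences floor at the empty local alignment", {
  al <- sw_gotoh("AAAAAAAA", "TTTTTTTT")
  expect_equal(al$score, 0)
  expect_equal(al$consensus_length, 0L)
})

test_that("sw_gotoh equals the brute-force affine DP oracle", {
  set.seed(401)
  params <- alignment_params()
  letters5 <- c("A", "C", "G", "T", "N")
  for (i in 1:200) {
    a <- paste(sample(letters5, sample(5:30, 1), replace = TRUE,
                      prob = c(rep(0.24, 4), 0.04)), collapse = "")
    b <- paste(sample(letters5, sample(5:30, 1), replace = TRUE,
                      prob = c(rep(0.24, 4), 0.04)), collapse = "")
    expect_equal(sw_gotoh(a, b, params)$score,
                 oracle_affine_local_score(a, b, params),
                 tolerance = 1e-9)
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(402)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    expect_equal(sw_gotoh(a, b)$score, sw_gotoh(b, a)$score)
  }
})

test_that("species filter applies strict score and inclusive span bounds", {
  s40 <- paste(rep("ACGT", 10), collapse = "")   # self-score exactly 200
  s41 <- paste0(s40, "A")                        # self-score 205
  g <- make_group("g1", c(mouse = s41, human = s41, rat = s40))
  kept <- filter_species(g, min_score = 200, min_len = 1, max_len = 100)
  expect_true("human" %in% kept)                 # 205 > 200
  expect_false("rat" %in% kept)                  # score 200 is not > 200
  expect_equal(kept[1], "mouse")                 # reference always first

  # span bound: consensus length 41 fails max_len 40
  kept2 <- filter_species(g, min_score = 100, min_len = 1, max_len = 40)
  expect_false("human" %in% kept2)
  expect_error(filter_species(make_group("g2", c(human = s40))),
               "reference")
})

test_that("star alignment of identical sequences is gapless", {
  s <- "ACGTACGTAC"
  g <- make_group("g1", c(mouse = s, human = s, rat = s))
  msa <- progressive_msa(g)
  expect_equal(msa$rows, rep(s, 3))
  expect_equal(msa$sp, 5 * 10 * 3)   # match * length * pairs
  single <- progressive_msa(make_group("g2", c(mouse = s)),
                            retained = "mouse")
  expect_equal(single$rows, s)
})

test_that("progressive SP never exceeds the exact 3-sequence optimum", {
  set.seed(403)
  params <- alignment_params()
  for (i in 1:10) {
    seqs <- random_dna(3, sample(5:8, 1))
    names(seqs) <- c("mouse", "human", "rat")
    g <- make_group("g", seqs)
    msa <- refine_msa(progressive_msa(g, params = params), params)
    opt <- oracle_msa3_sp_optimum(unname(seqs), params)
    expect_lte(msa$sp, opt + 1e-9)
  }
})

test_that("refinement is SP-monotone and repairs a misplaced gap", {
  params <- alignment_params()
  good <- "ACGTTACG"
  bad_msa <- structure(list(species = c("mouse", "human", "rat"),
                            rows = c("ACGTTACG-", "ACGTTACG-",
                                     "ACG-TTACG"),
                            sp = NA_real_),
                       class = "multiple_alignment")
  bad_msa$sp <- sp_score(bad_msa, params)
  refined <- refine_msa(bad_msa, params)
  expect_gte(refined$sp, bad_msa$sp)
  expect_equal(refined$sp,
               oracle_msa3_sp_optimum(rep(good, 3), params))

  set.seed(404)
  for (i in 1:5) {
    seqs <- random_dna(3, 12)
    names(seqs) <- c("mouse", "human", "rat")
    msa <- progressive_msa(make_group("g", seqs), params = params)
    expect_gte(refine_msa(msa, params)$sp, msa$sp)
  }
})

test_that("masking keeps exactly the conserved core", {
  rows <- c(mouse = "ACGTACGTAC", human = "ACGTACGTAC",
            rat = "ACGTACGTAC")
  msa <- progressive_msa(make_group("g", rows))
  mc <- mask_nonconserved(msa)
  expect_equal(mc$fraction_masked, 0)
  expect_equal(mc$sequence, unname(rows["mouse"]))

  # total disagreement: everything masked
  g2 <- make_group("g", c(mouse = "AAAAAAAAAA", human = "CCCCCCCCCC",
                          rat = "GGGGGGGGGG"))
  mc2 <- mask_nonconserved(progressive_msa(g2))
  expect_equal(mc2$sequence, paste(rep("N", 10), collapse = ""))

  # 10-column identical core flanked by divergence survives alone
  core <- "ACGTTGCAAC"
  m_row <- paste0("AAAAAAAA", core, "AAAAAAAA")
  h_row <- paste0("CCCCCCCC", core, "GGGGGGGG")
  r_row <- paste0("GGGGGGGG", core, "CCCCCCCC")
  msa3 <- structure(list(species = c("mouse", "human", "rat"),
                         rows = c(m_row, h_row, r_row), sp = 0),
                    class = "multiple_alignment")
  mc3 <- mask_nonconserved(msa3, min_agree_frac = 0.5, min_run = 6)
  expect_equal(mc3$sequence,
               paste0(strrep("N", 8), core, strrep("N", 8)))
  expect_equal(nchar(mc3$sequence), nchar(m_row))
})

test_that("masking is monotone in the agreement fraction", {
  set.seed(405)
  seqs <- random_dna(3, 40)
  names(seqs) <- c("mouse", "human", "rat")
  msa <- progressive_msa(make_group("g", seqs))
  masked_at <- function(frac) {
    which(strsplit(mask_nonconserved(msa, min_agree_frac = frac,
                                     min_run = 1)$sequence,
                   "")[[1]] == "N")
  }
  low <- masked_at(0.4)
  high <- masked_at(0.9)
  expect_true(all(low %in% high))
})
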