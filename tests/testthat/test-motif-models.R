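test_that("a planted exact word dominates ZOOPS discovery", {
  set.seed(501)
  word <- "TTTTGGGG"
  seqs <- vapply(1:5, function(i) {
    bg <- random_dna(1, 40)
    pos <- sample(1:30, 1)
    paste0(substr(bg, 1, pos), word, substr(bg, pos + 1, 40))
  }, character(1))
  mm <- discover_motif_zoops(seqs, 8)
  expect_true(mm$consensus %in% c(word, revcomp(word)))
  expect_equal(nrow(mm$sites), 5L)
})

test_that("mutated planted motifs are recovered near the enumeration oracle", {
  set.seed(502)
  word <- "GATTACAGGC"
  mutate1 <- function(s) {
    i <- sample(nchar(s), 1)
    substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, i, i)), 1)
    s
  }
  seqs <- vapply(1:20, function(i) {
    bg <- random_dna(1, 50)
    pos <- sample(1:40, 1)
    site <- if (runif(1) < 0.8) mutate1(word) else word
    paste0(substr(bg, 1, pos), site, substr(bg, pos + 1, 50))
  }, character(1))
  mm <- discover_motif_zoops(seqs, 10)
  oracle <- oracle_best_word(seqs, 10)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  d <- min(ham(mm$consensus, oracle), ham(revcomp(mm$consensus), oracle))
  expect_lte(d, 1)
  d_true <- min(ham(mm$consensus, word), ham(revcomp(mm$consensus), word))
  expect_lte(d_true, 1)
})

test_that("PWM columns are distributions and EM is order-invariant", {
  set.seed(503)
  seqs <- vapply(1:8, function(i) {
    bg <- random_dna(1, 30)
    paste0(substr(bg, 1, 10), "ACGTACGT", substr(bg, 11, 30))
  }, character(1))
  mm <- discover_motif_zoops(seqs, 8)
  expect_true(all(abs(colSums(mm$pwm$mat) - 1) < 1e-9))
  expect_true(all(mm$pwm$mat > 0))
  mm2 <- discover_motif_zoops(rev(seqs), 8)
  expect_equal(mm2$consensus, mm$consensus)
  expect_error(discover_motif_zoops(c("ACG", "ACGT"), 4), "shortest")
})

test_that("ambiguous consensus follows the threshold/ordering rule", {
  point <- pwm(matrix(c(1, 0, 0, 0), 4, 1) * 0.997 +
                 0.00075)  # near point mass on A
  expect_equal(ambiguous_consensus(point), "A")
  col <- pwm(matrix(c(0.0, 0.5, 0.2, 0.3), 4, 1))  # A,C,G,T order
  expect_equal(ambiguous_consensus(col), "[CTG]")
  unif <- pwm(matrix(0.25, 4, 1))
  expect_equal(ambiguous_consensus(unif), "[ACGT]")
})

test_that("motif sets respect widths, counts, ids and rank ordering", {
  set.seed(504)
  seqs <- random_dna(6, 40)
  ms <- discover_motif_set(seqs, widths = c(6L, 8L), per_width = 3L)
  expect_lte(length(ms), 6L)
  ids <- vapply(ms, `[[`, character(1), "motif_id")
  expect_false(anyDuplicated(ids) > 0)
  widths <- vapply(ms, function(m) m$pwm$width, integer(1))
  expect_true(all(widths %in% c(6L, 8L)))
  # scores fall with rank within each width (iterative masking)
  for (W in c(6L, 8L)) {
    sc <- vapply(ms[widths == W], `[[`, numeric(1), "score")
    expect_true(all(diff(sc) < 0))
  }
  # per_width 1 on one width reduces to single discovery
  one <- discover_motif_set(seqs, widths = 10L, per_width = 1L)
  expect_length(one, 1L)
  expect_equal(one[[1]]$consensus,
               discover_motif_zoops(seqs, 10L)$consensus)
})

test_that("the MafB motif models cover widths 8 through 11", {
  mafb <- extract_mafb_motifs()
  expect_length(mafb, 4L)
  expect_equal(vapply(mafb, function(m) m$pwm$width, integer(1)), 8:11)
  expect_true(all(vapply(mafb, `[[`, logical(1), "is_mafb")))
  expect_equal(vapply(mafb, `[[`, character(1), "motif_id"),
               as.character(8:11))
  one <- extract_mafb_motifs(widths = 8L)
  expect_length(one, 1L)
})

test_that("motif files round-trip", {
  set.seed(505)
  seqs <- random_dna(5, 30)
  ms <- discover_motif_set(seqs, widths = 8L, per_width = 2L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_motifs(ms, path)
  back <- read_motifs(path)
  expect_length(back, length(ms))
  for (i in seq_along(ms)) {
    expect_equal(back[[i]]$motif_id, ms[[i]]$motif_id)
    expect_equal(back[[i]]$consensus, ms[[i]]$consensus)
    expect_equal(back[[i]]$pwm$mat, ms[[i]]$pwm$mat, tolerance = 1e-5)
    expect_equal(back[[i]]$is_mafb, ms[[i]]$is_mafb)
  }
})

test_that("reverse complement handles plain and bracketed consensi", {
  expect_equal(revcomp("ACGTN"), "NACGT")
  expect_equal(revcomp_consensus("[CTG]TGCT[GC]AC"), "GT[CG]AGCA[GAC]")
  expect_equal(revcomp_consensus(revcomp_consensus("A[CG]T")), "A[CG]T")
})
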