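test_that("sequence normalization uppercases, maps T to U, rejects invalid symbols", {
  expect_equal(unclass(normalize_sequence("gcgc")), "GCGC")
  expect_equal(unclass(normalize_sequence("ACGT")), "ACGU")
  expect_equal(unclass(normalize_sequence("  a c\ngu\t")), "ACGU")
  expect_error(normalize_sequence("ACGN"), "position 3")
  expect_error(normalize_sequence("XACG"), "position 0")
  expect_error(normalize_sequence("   "), "empty")
})

test_that("default pair scores follow the Watson-Crick scheme and are symmetric", {
  sch <- scoring_scheme()
  expect_equal(beta(sch, "G", "C"), 1L)
  expect_equal(beta(sch, "A", "U"), 1L)
  expect_equal(beta(sch, "A", "A"), 0L)
  expect_equal(beta(sch, "G", "U"), 0L)  # wobble not scored by default
  for (a in c("A", "C", "G", "U")) for (b in c("A", "C", "G", "U"))
    expect_equal(beta(sch, a, b), beta(sch, b, a))
  expect_equal(sch$beta_max, 1L)
  expect_equal(sch$D, 2L)
})

test_that("custom schemes set beta_max and D, and reject bad input", {
  sch <- scoring_scheme(c(AU = 2, CG = 3, GU = 1))
  expect_equal(beta(sch, "G", "C"), 3L)
  expect_equal(beta(sch, "U", "G"), 1L)
  expect_equal(sch$beta_max, 3L)
  expect_equal(sch$D, 4L)
  expect_error(scoring_scheme(c(AU = -1)), "non-negative")
  expect_error(scoring_scheme(c(AU = 1.5)), "integer")
  expect_error(scoring_scheme(c(AX = 1)), "ACGU")
})

test_that("scoring schemes round-trip through the JSON config format", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"GC": 2, "AU": 1}', path)
  sch <- read_scoring_scheme(path)
  expect_equal(beta(sch, "C", "G"), 2L)
  expect_equal(beta(sch, "U", "A"), 1L)
  expect_equal(sch$D, 3L)
})

test_that("block size q follows floor(epsilon * log_D(n)) with clamping", {
  expect_equal(choose_q(256, 0.5, 2), 4L)
  expect_equal(choose_q(16, 0.25, 2), 1L)
  expect_equal(choose_q(4, 0.4, 2), 1L)   # clamps up to 1
  expect_equal(choose_q(2^30, 0.5, 2), 8L)  # capped by q_max
  expect_equal(choose_q(2^20, 0.5, 2, q_max = 12), 10L)
  expect_equal(choose_q(81, 0.5, 3), 2L)  # log base D
  expect_error(choose_q(100, 0), "epsilon")
  expect_error(choose_q(100, 0.6), "epsilon")
  expect_error(choose_q(100, -0.2), "epsilon")
})

test_that("solution-matrix columns are monotone and [0, beta_max]-discrete", {
  sch4 <- scoring_scheme(c(AU = 2, CG = 3, GU = 1))
  for (r in 1:6) {
    sq <- random_sequence(96, 400 + r)
    for (e in c("naive", "sp", "fr", "sfr")) {
      expect_column_discrete(ssf_fold(sq, engine = e), beta_max = 1)
    }
    expect_column_discrete(ssf_fold(sq, sch4, engine = "fr"), beta_max = 3)
  }
})

test_that("base cells are zero, sub-diagonal cells are the sentinel, L = max(Lp, Lc)", {
  res <- ssf_fold(random_sequence(24, 1))
  n <- res$n
  expect_true(all(diag(res$L) == 0))
  expect_true(all(res$L[cbind(1:n, 2:(n + 1))] == 0))
  expect_true(all(is.na(res$L[lower.tri(res$L)])))
  ij <- which(row(res$L) <= col(res$L) - 2, arr.ind = TRUE)  # gap >= 2
  expect_equal(res$L[ij], pmax(res$Lp[ij], res$Lc[ij]))
})

test_that("folding validation enforces bounds, occupancy and non-crossing", {
  expect_silent(rna_folding(rbind(c(0, 3), c(1, 2)), 4))
  expect_error(rna_folding(rbind(c(0, 2), c(1, 3)), 4), "crossing")
  expect_error(rna_folding(rbind(c(0, 2), c(2, 3)), 4), "more than one")
  expect_error(rna_folding(rbind(c(2, 2)), 4), "bounds")
  expect_error(rna_folding(rbind(c(0, 4)), 4), "bounds")
  expect_silent(rna_folding(NULL, 7))
})
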