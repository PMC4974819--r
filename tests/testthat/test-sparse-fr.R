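test_that("signature dot product is 1 iff the bitmasks intersect", {
  expect_equal(sig_dot(0x0A, 0x08), 1L)   # shared bit
  expect_equal(sig_dot(0x02, 0x08), 0L)   # disjoint
  expect_equal(sig_dot(0L, 0xFF), 0L)     # empty signature
  expect_equal(sig_dot(5L, 5L), 1L)
})

test_that("STEP/OCT signatures are a pure function of the solution matrices", {
  for (r in 1:5) {
    sq <- random_sequence(64, 800 + r)
    ref <- ssf_fold(sq, engine = "naive")
    res <- ssf_fold(sq, engine = "sfr")
    q <- res$q; n <- res$n
    # recompute strict sigOct from the baseline's OCT flags
    for (j in seq(2, n, by = 7)) {
      for (g in 0:((n %/% q))) {
        rows <- (q * g):(min(q * g + q - 1, n))
        rows <- rows[rows < j]
        m <- 0L
        for (x in seq_along(rows)) {
          if (isTRUE(ref$oct[rows[x] + 1, j + 1])) m <- bitwOr(m, bitwShiftL(1L, x - 1L))
        }
        expect_equal(res$sig_oct[g + 1, j + 1], m,
                     label = sprintf("sigOct g=%d j=%d", g, j))
      }
    }
  }
  # worked example: "GC" column 2 has its OCT cell at group offset 0
  res <- ssf_fold("GC", engine = "sfr", q = 2)
  expect_equal(bitwAnd(res$sig_oct[1, 3], 1L), 1L)
})

test_that("pair-free sequences produce all-zero strict signatures", {
  res <- ssf_fold(strrep("A", 24), engine = "sfr")
  expect_true(all(res$sig_oct == 0L))
  expect_true(all(res$sig_step == 0L))
})

test_that("sparse Four-Russians reproduces the baseline matrices exactly", {
  for (n in c(16, 64, 128)) {
    for (r in 1:10) {
      expect_same_matrix_as_naive(random_sequence(n, 7 * n + r),
                                  engines = "sfr")
    }
  }
})

test_that("disabling the signature gate changes counters but no matrix value", {
  for (r in 1:6) {
    sq <- random_sequence(96, 90 + r)
    gated <- ssf_fold(sq, engine = "sfr")
    open <- ssf_fold(sq, engine = "sfr", gated = FALSE)
    expect_identical(gated$L, open$L)
    expect_identical(gated$Lp, open$Lp)
    expect_lte(gated$counters[["mul_lookups"]] + gated$counters[["mul_builds"]],
               open$counters[["mul_lookups"]] + open$counters[["mul_builds"]])
    expect_lte(gated$total_ops, open$total_ops)
  }
})

test_that("G-table soundness assertions pass on gated runs", {
  for (r in 1:4) {
    res <- ssf_fold(random_sequence(128, 20 + r), engine = "sfr",
                    debug_checks = TRUE)
    expect_gt(res$counters[["g_builds"]], 0)
    expect_equal(res$g_entries, res$counters[["g_builds"]])
  }
})

test_that("combined engine never exceeds the cheaper of its two parents", {
  for (n in c(64, 128)) {
    for (r in 1:10) {
      sq <- random_sequence(n, 55 * n + r)
      sp <- ssf_fold(sq, engine = "sp")
      fr <- ssf_fold(sq, engine = "fr")
      sfr <- ssf_fold(sq, engine = "sfr")
      expect_lte(sfr$total_ops, min(fr$total_ops, sp$total_ops),
                 label = sprintf("n=%d r=%d", n, r))
    }
  }
})
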