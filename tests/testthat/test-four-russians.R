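test_that("delta encoding matches worked examples and plain-R packing", {
  dv <- delta_encode(c(5L, 4L, 4L, 3L))
  expect_equal(dv$x0, 5L)
  expect_equal(dv$delta, 5)      # digits 1,0,1 MSB-first
  expect_equal(delta_encode(c(3L, 3L, 3L, 3L))$delta, 0)
  expect_equal(delta_encode(c(2L, 1L, 0L, 0L))$delta, 6)  # digits 1,1,0
  for (t in 1:50) {
    D <- sample(2:4, 1)
    v <- rand_discrete_vec(sample(2:6, 1), D)
    expect_equal(delta_encode(v, D)$delta, oracle_delta_pack(v, D))
  }
})

test_that("encode/decode round-trips exhaustively (D=2) and randomized (D=3,4)", {
  for (q in 1:6) {
    for (delta in 0:(2^(q - 1) - 1)) {
      for (x0 in c(0L, 3L)) {
        v <- delta_decode(x0, delta = delta, q = q, D = 2L)
        enc <- delta_encode(v, 2L)
        expect_equal(enc$x0, x0)
        expect_equal(enc$delta, delta)
      }
    }
  }
  for (t in 1:200) {
    D <- sample(3:4, 1)
    v <- rand_discrete_vec(sample(2:5, 1), D)
    expect_equal(delta_decode(delta_encode(v, D)), v)
  }
})

test_that("encoding rejects out-of-range deltas and non-discrete vectors", {
  expect_error(delta_encode(c(5L, 2L), 2L), "discrete")
  expect_error(delta_encode(c(1L, 2L), 2L), "discrete")   # increase
  expect_error(delta_decode(0L, delta = 2^3, q = 4, D = 2), "range")
  expect_error(delta_decode(7L, delta = 2^(5 - 1), q = 5, D = 2), "range")
})

test_that("scalar shift moves x0 and leaves the difference digits alone", {
  dv <- delta_encode(c(5L, 4L, 4L, 3L))
  sh <- delta_shift(dv, 3L)
  expect_equal(sh$x0, 8L)
  expect_equal(sh$delta, dv$delta)
  expect_equal(delta_decode(sh), c(5L, 4L, 4L, 3L) + 3L)
})

test_that("block max-plus product equals the brute-force oracle", {
  B <- rbind(c(0L, 1L), c(0L, 0L))
  out <- block_mul(B, delta_encode(c(0L, 0L)))
  expect_equal(delta_decode(out), c(1L, 0L))
  for (q in 2:4) {
    for (t in 1:100) {
      D <- sample(2:3, 1)
      B <- rand_discrete_block(q, D)
      v <- rand_discrete_vec(q, D, x0 = 0L)
      got <- delta_decode(block_mul(B, delta_encode(v, D)))
      expect_equal(got, unname(oracle_max_plus(B, v)),
                   label = sprintf("q=%d t=%d", q, t))
    }
  }
})

test_that("delta_max equals the elementwise maximum oracle", {
  # Fact-3 shortcut branch: head gap exceeds what the diffs can recover
  v <- delta_encode(c(2L, 1L, 1L)); w <- delta_encode(c(6L, 5L, 4L))
  expect_equal(delta_decode(delta_max(v, w)), c(6L, 5L, 4L))
  v <- delta_encode(c(2L, 2L, 1L)); w <- delta_encode(c(3L, 2L, 2L))
  expect_equal(delta_decode(delta_max(v, w)), c(3L, 2L, 2L))
  expect_equal(delta_decode(delta_max(v, v)), delta_decode(v))  # idempotent

  # exhaustive over the q = 3, D = 2 input space (heads 0..4, all digit pairs)
  for (v0 in 0:4) for (w0 in 0:4) for (dv in 0:3) for (dw in 0:3) {
    a <- delta_decode(v0, delta = dv, q = 3, D = 2)
    b <- delta_decode(w0, delta = dw, q = 3, D = 2)
    got <- delta_decode(delta_max(delta_encode(a), delta_encode(b)))
    expect_equal(got, pmax(a, b))
  }
  # randomized D = 3 (wider dominance threshold (q-1)(D-1))
  for (t in 1:100) {
    q <- sample(2:5, 1)
    a <- rand_discrete_vec(q, 3); b <- rand_discrete_vec(q, 3)
    got <- delta_decode(delta_max(delta_encode(a, 3), delta_encode(b, 3)))
    expect_equal(got, pmax(a, b))
  }
})

test_that("Four-Russians engine reproduces the baseline matrices exactly", {
  for (n in c(16, 64, 128)) {
    for (r in 1:8) {
      expect_same_matrix_as_naive(random_sequence(n, 10 * n + r),
                                  engines = "fr")
    }
  }
  # explicit block sizes, including larger-than-chosen ones
  sq <- random_sequence(96, 77)
  ref <- ssf_fold(sq, engine = "naive")
  for (qq in c(1, 2, 3, 5, 8)) {
    expect_identical(ssf_fold(sq, engine = "fr", q = qq)$L, ref$L)
  }
})

test_that("q = 1 degenerates to per-cell traversal with table bookkeeping", {
  sq <- random_sequence(40, 5)
  res <- ssf_fold(sq, engine = "fr", q = 1)
  n <- res$n
  cells <- sum(outer(0:n, 0:n, function(i, j) j - i >= 2))
  # every cell pays exactly its mandatory k = i+1 comparison, and every
  # split point of the cubic traversal appears as one singleton-block MUL
  # access (the per-cell k = i+1 is covered both ways by construction)
  expect_equal(res$counters[["split_comparisons"]], cells)
  expect_equal(res$counters[["mul_lookups"]] + res$counters[["mul_builds"]],
               choose(n + 1, 3))
  expect_equal(res$counters[["mul_builds"]], res$mul_entries)
})

test_that("on-demand tables respect their size bounds and memoize", {
  for (r in 1:6) {
    res <- ssf_fold(random_sequence(128, 40 + r), engine = "fr")
    q <- res$q; D <- res$D
    expect_lte(res$mul_block_max, D^(q - 1))
    expect_lte(res$max_entries, D^(q - 1) * D^(q - 1) * ((q - 1) * (D - 1) + 1))
    # memoization: far fewer builds than accesses
    expect_lte(res$counters[["mul_builds"]], res$mul_entries + 0)
    expect_gt(res$counters[["mul_lookups"]], 0)
  }
})

test_that("Four-Russians total counted work beats the cubic baseline at n = 64", {
  for (r in 1:10) {
    res <- ssf_fold(random_sequence(64, 500 + r), engine = "fr")
    expect_lt(res$total_ops, 43680)
  }
})
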