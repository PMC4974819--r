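# Independent oracles and small generators used across the suite.
# None of these share code with the engine paths they check.

# base-D packing of consecutive differences, MSB first, in plain R arithmetic
oracle_delta_pack <- function(v, D) {
  digs <- -diff(v)
  if (length(digs) == 0) return(0)
  sum(digs * D^(rev(seq_along(digs)) - 1))
}

# plain max-plus product row-wise
oracle_max_plus <- function(B, v) {
  apply(B, 1, function(row) max(row + v))
}

# random D-discrete vector of length q (non-increasing, drops in [0, D-1])
rand_discrete_vec <- function(q, D, x0 = sample(0:6, 1)) {
  drops <- sample(0:(D - 1), q - 1, replace = TRUE)
  as.integer(c(x0, x0 - cumsum(drops)))
}

# random block whose rows are column-discrete top-down, mimicking a
# solution-matrix submatrix L[I_g', K_g]
rand_discrete_block <- function(q, D) {
  top <- sample(0:8, q, replace = TRUE)
  B <- matrix(0L, q, q)
  B[1, ] <- top
  if (q > 1) for (r in 2:q)
    B[r, ] <- B[r - 1, ] - sample(0:(D - 1), q, replace = TRUE)
  B
}

# engines checked against the naive baseline
ALT_ENGINES <- c("sp", "fr", "sfr", "parallel-sim")

expect_same_matrix_as_naive <- function(sq, engines = ALT_ENGINES, ...) {
  ref <- ssf_fold(sq, engine = "naive", ...)
  for (e in engines) {
    res <- ssf_fold(sq, engine = e, ...)
    expect_identical(res$L, ref$L,
                     label = sprintf("%s L matrix (n = %d)", e, ref$n))
    expect_identical(res$score, ref$score)
  }
  invisible(ref)
}

# column monotonicity and [0, beta_max] discreteness of every column of L
expect_column_discrete <- function(res, beta_max = 1) {
  L <- res$L
  n <- res$n
  for (j in seq_len(n)) {          # column j (0-based), rows 0..j
    col <- L[seq_len(j + 1), j + 1]
    d <- -diff(col)
    expect_true(all(d >= 0), label = sprintf("column %d monotone", j))
    expect_true(all(d <= beta_max),
                label = sprintf("column %d discreteness", j))
  }
  invisible(res)
}
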