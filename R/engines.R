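#' Fold an RNA sequence with a chosen engine
#'
#' All engines compute the same solution matrices for the non-crossing
#' base-pair maximization recurrence
#' \deqn{L[i,j] = \max(L^p[i,j], L^c[i,j]),\quad
#'       L^p[i,j] = \max_{k \in (i,j)} L[i,k] + L[k,j],\quad
#'       L^c[i,j] = L[i+1,j-1] + \beta(s_i, s_{j-1}),}
#' over the half-open substring convention `s[i,j)`, and differ only in how
#' many split points and lookup-table events they spend doing it:
#'
#' * `"naive"` -- every split point, cell by cell; exactly
#'   `choose(n+1, 3)` split comparisons.
#' * `"sp"` -- sparsified: only `k = i+1` plus split points `k` where
#'   `(i,k)` is STEP (`L[i,k] > L[i+1,k]`) and `(k,j)` is OCT
#'   (`L[k,j] = Lc[k,j] > Lp[k,j]`); some such `k` is always optimal.
#' * `"fr"` -- on-demand Four-Russians: the matrix is tiled into `q x q`
#'   blocks and q-subcolumns; full blocks are combined through delta-encoded
#'   vectors with memoized MUL (block max-plus product) and MAX (vector
#'   maximum) tables; partial groups are done per cell.
#' * `"sfr"` -- sparse Four-Russians: as `"fr"`, but a block's MUL access is
#'   gated by the bitwise STEP/OCT signature dot product (through the
#'   on-demand G table), and per-cell work uses the sparsified candidates.
#' * `"parallel-sim"` -- deterministic simulation of the wavefront variant:
#'   one logical process per column, synchronous rounds, per-column
#'   operation accounting, optional signature gating.
#'
#' @param seq An `rna_sequence` or character string.
#' @param scheme A [scoring_scheme()].
#' @param engine One of `"naive"`, `"sp"`, `"fr"`, `"sfr"`, `"parallel-sim"`.
#' @param epsilon Block-size factor for the Four-Russians family; the block
#'   size is `q = max(1, floor(epsilon * log_D(n)))` (see [choose_q()]).
#' @param q Explicit block size overriding `epsilon` (Four-Russians family).
#' @param min_loop Minimum number of unpaired positions inside a pair
#'   (default 0: adjacent positions may pair).
#' @param gated For `"sfr"`: set `FALSE` to disable the signature gate
#'   (debug; identical matrices, more counted operations).
#' @param sparsified For `"parallel-sim"`: gate block access by STEP/OCT
#'   signatures (default `TRUE`).
#' @param debug_checks Enable internal consistency assertions (G-table
#'   membership re-verification).
#' @return An `ssf_result`: list with `score` (the optimal folding score
#'   `L[0,n]`), `engine`, `n`, `q`, `counters` (named vector:
#'   `split_comparisons`, `mul_lookups`, `mul_builds`, `max_lookups`,
#'   `max_builds`, `g_builds`), `total_ops`, the DP matrices `L`, `Lp`, `Lc`
#'   (cells below the diagonal are `NA`, the -infinity sentinel), logical
#'   `oct`/`step` cell classifications, sparsity summaries (`Z`, per-column
#'   `step_count`/`oct_count`), lookup-table sizes, and STEP/OCT signature
#'   matrices. The parallel simulator adds `col_ops`, `col_rounds`,
#'   `total_rounds`.
#' @examples
#' r <- ssf_fold("GGGAAACCC")
#' r$score
#' ssf_fold("GGGAAACCC", engine = "sfr")$counters
#' @export
ssf_fold <- function(seq, scheme = scoring_scheme(),
                     engine = c("naive", "sp", "fr", "sfr", "parallel-sim"),
                     epsilon = 0.4, q = NULL, min_loop = 0L,
                     gated = TRUE, sparsified = TRUE, debug_checks = FALSE) {
  engine <- match.arg(engine)
  seq <- as_rna_sequence(seq)
  stopifnot(inherits(scheme, "scoring_scheme"))
  s <- seq_to_int(seq)
  n <- length(s)
  uses_blocks <- engine %in% c("fr", "sfr", "parallel-sim")
  if (uses_blocks) {
    if (is.null(q)) q <- if (n >= 1) choose_q(n, epsilon, scheme$D) else 1L
    q <- as.integer(q)
    if (q < 1L) stop("`q` must be >= 1")
  } else q <- 1L
  raw <- if (engine == "parallel-sim") {
    rs_solve_parallel(s, scheme$matrix, q, as.integer(min_loop),
                      isTRUE(sparsified), isTRUE(debug_checks))
  } else {
    mode <- match(engine, c("naive", "sp", "fr", "sfr")) - 1L
    rs_solve(s, scheme$matrix, mode, q, as.integer(min_loop),
             isTRUE(gated), isTRUE(debug_checks))
  }
  res <- raw
  res$engine <- engine
  res$n <- n
  res$seq <- seq
  res$scheme <- scheme
  res$epsilon <- if (uses_blocks) epsilon else NA_real_
  res$min_loop <- as.integer(min_loop)
  if (!uses_blocks) res$q <- NA_integer_
  res$total_ops <- .total_ops(res$counters)
  class(res) <- "ssf_result"
  res
}

# Fixed counting convention: split comparisons + table builds + gated (MUL)
# lookups. MAX-table hits and first-element shortcuts are O(1) resolutions
# that build no entry and examine no split point; they are reported in the
# counters but not totalled.
.total_ops <- function(counters) {
  sum(counters[c("split_comparisons", "mul_builds", "max_builds",
                 "g_builds", "mul_lookups")])
}

#' @rdname ssf_fold
#' @export
solve_naive <- function(seq, scheme = scoring_scheme(), min_loop = 0L)
  ssf_fold(seq, scheme, "naive", min_loop = min_loop)

#' @rdname ssf_fold
#' @export
solve_sparse <- function(seq, scheme = scoring_scheme(), min_loop = 0L)
  ssf_fold(seq, scheme, "sp", min_loop = min_loop)

#' @rdname ssf_fold
#' @export
solve_fr <- function(seq, scheme = scoring_scheme(), epsilon = 0.4,
                     q = NULL, min_loop = 0L)
  ssf_fold(seq, scheme, "fr", epsilon = epsilon, q = q, min_loop = min_loop)

#' @rdname ssf_fold
#' @export
solve_sfr <- function(seq, scheme = scoring_scheme(), epsilon = 0.4,
                      q = NULL, min_loop = 0L, gated = TRUE,
                      debug_checks = FALSE)
  ssf_fold(seq, scheme, "sfr", epsilon = epsilon, q = q, min_loop = min_loop,
           gated = gated, debug_checks = debug_checks)

#' @rdname ssf_fold
#' @export
solve_parallel_sim <- function(seq, scheme = scoring_scheme(), epsilon = 0.4,
                               q = NULL, min_loop = 0L, sparsified = TRUE)
  ssf_fold(seq, scheme, "parallel-sim", epsilon = epsilon, q = q,
           min_loop = min_loop, sparsified = sparsified)

#' Total counted operations of a solve
#'
#' The package's fixed counting convention: split-point comparisons, plus
#' every lookup-table build (MUL, MAX, G), plus gated MUL lookups, each
#' weighted 1. MAX-table hits and first-element shortcut resolutions are
#' reported in the counters but not totalled: they construct no table entry
#' and examine no split point.
#'
#' @param res An `ssf_result`.
#' @return Numeric scalar.
#' @export
total_ops <- function(res) {
  stopifnot(inherits(res, "ssf_result"))
  .total_ops(res$counters)
}

#' @export
print.ssf_result <- function(x, ...) {
  cat(sprintf("SSF solve: engine = %s, n = %d, optimal score L(s) = %d\n",
              x$engine, x$n, x$score))
  if (!is.na(x$q)) cat(sprintf("  block size q = %d, D = %d\n", x$q, x$D))
  cat(sprintf("  Z (OCT cells) = %d, total counted operations = %s\n",
              as.integer(x$Z), format(x$total_ops, big.mark = ",")))
  cnt <- x$counters
  cat("  counters:",
      paste(names(cnt), format(cnt, trim = TRUE), sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$total_rounds))
    cat(sprintf("  wavefront rounds = %d, makespan (max column ops) = %d\n",
                x$total_rounds, as.integer(max(x$col_ops))))
  invisible(x)
}
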