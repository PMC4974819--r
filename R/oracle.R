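#' Exhaustive folding score by explicit enumeration
#'
#' Independent oracle for the DP engines: recursively enumerates every valid
#' non-crossing folding (position i unpaired, or paired with each admissible
#' l) and returns the maximum score. Shares no code with the engines and
#' builds no matrices. Exponential: guarded to `n <= 16`.
#'
#' @param seq An `rna_sequence` or string, length at most 16.
#' @param scheme A [scoring_scheme()].
#' @param min_loop Minimum unpaired positions inside a pair (default 0).
#' @return Integer: the maximum folding score.
#' @examples
#' brute_force_score("ACGU")  # 2
#' @export
brute_force_score <- function(seq, scheme = scoring_scheme(), min_loop = 0L) {
  s <- strsplit(unclass(as_rna_sequence(seq)), "", fixed = TRUE)[[1L]]
  n <- length(s)
  if (n > 16L) stop("brute_force_score is limited to n <= 16")
  if (n < 2L) return(0L)
  bmat <- scheme$matrix
  rec <- function(i, j) {
    # substring s[i, j) half-open, 0-based
    if (j - i < 2L) return(0L)
    best <- rec(i + 1L, j)
    for (l in (i + 1L):(j - 1L)) {
      if (l - i - 1L < min_loop) next
      cand <- bmat[s[i + 1L], s[l + 1L]] + rec(i + 1L, l) + rec(l + 1L, j)
      if (cand > best) best <- cand
    }
    best
  }
  rec(0L, n)
}
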