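#' Delta-encode a D-discrete vector
#'
#' A length-q integer vector is D-discrete when each consecutive difference
#' `v[l] - v[l+1]` lies in `[0, D-1]`. Its delta-encoding is the pair
#' `(x0, delta)`: the first element, and the base-D integer whose digits are
#' the consecutive differences with the first difference most significant.
#' `0 <= delta < D^(q-1)`.
#'
#' @param v Integer vector (length >= 1).
#' @param D Difference base (>= 2).
#' @return A `delta_vector`: list with `x0`, `delta`, `q`, `D`.
#' @examples
#' delta_encode(c(5, 4, 4, 3))          # (5, 0b101 = 5)
#' delta_decode(delta_encode(c(2, 1, 0, 0)))
#' @export
delta_encode <- function(v, D = 2L) {
  stopifnot(length(v) >= 1L, D >= 2)
  dv <- rs_delta_encode(as.integer(v), as.integer(D))
  structure(dv, class = "delta_vector")
}

#' Decode a delta-encoded vector
#'
#' Inverse of [delta_encode()]: `delta_decode(delta_encode(v))` is `v` for
#' every D-discrete `v`.
#'
#' @param dv A `delta_vector`, or the first element `x0` when the remaining
#'   arguments are given explicitly.
#' @param delta,q,D Encoding components when `dv` is given as a bare `x0`.
#' @return Integer vector of length `q`.
#' @export
delta_decode <- function(dv, delta = NULL, q = NULL, D = 2L) {
  if (inherits(dv, "delta_vector") || (is.list(dv) && !is.null(dv$delta)))
    return(rs_delta_decode(dv$x0, dv$delta, dv$q, dv$D))
  rs_delta_decode(as.integer(dv), as.numeric(delta), as.integer(q),
                  as.integer(D))
}

#' @export
print.delta_vector <- function(x, ...) {
  cat(sprintf("delta_vector (x0 = %d, delta = %d, q = %d, D = %d): ",
              x$x0, x$delta, x$q, x$D))
  cat(delta_decode(x), "\n")
  invisible(x)
}

#' Max-plus product of a block with a delta-encoded vector
#'
#' Computes row-wise `max_c(B[r, c] + v[c])` where `v` decodes from `dv`,
#' returning the result delta-encoded. This is the direct O(q^2) computation
#' behind each on-demand MUL lookup-table entry; within the engines the
#' vector argument is normalized to `x0 = 0` and the subcolumn offset is
#' added back after lookup.
#'
#' @param B A q x q integer matrix whose rows are D-discrete top-down
#'   (consecutive row entries of a solution matrix).
#' @param dv A `delta_vector` of length q.
#' @return A `delta_vector` holding the product.
#' @export
block_mul <- function(B, dv) {
  stopifnot(is.matrix(B), inherits(dv, "delta_vector") || is.list(dv))
  out <- rs_block_mul(matrix(as.integer(B), nrow(B), ncol(B)),
                      dv$x0, dv$delta, dv$D)
  structure(out, class = "delta_vector")
}

#' Elementwise maximum of two delta-encoded vectors
#'
#' If the first elements differ by more than `q - 1` the larger vector
#' dominates everywhere (the diffs can never make up the gap) and is
#' returned unchanged; otherwise the maximum is taken elementwise on the
#' offset pair `((0, delta_v), (h, delta_w))` and shifted back -- the O(q)
#' computation behind each on-demand MAX lookup-table entry.
#'
#' @param v,w `delta_vector`s of equal length and base.
#' @return A `delta_vector` with `decode(out)[l] == max(decode(v)[l],
#'   decode(w)[l])`.
#' @export
delta_max <- function(v, w) {
  stopifnot(v$q == w$q, v$D == w$D)
  out <- rs_delta_max(v$x0, v$delta, w$x0, w$delta, v$q, v$D)
  structure(out, class = "delta_vector")
}

#' Shift a delta-encoded vector by a scalar
#'
#' Adding a constant to every element leaves all consecutive differences
#' unchanged, so only `x0` moves: `(x0, delta) + c = (x0 + c, delta)`.
#'
#' @param dv A `delta_vector`.
#' @param c Integer shift.
#' @return The shifted `delta_vector`.
#' @export
delta_shift <- function(dv, c) {
  dv$x0 <- dv$x0 + as.integer(c)
  dv
}

#' Signature dot product
#'
#' Boolean dot product of two q-bit signatures (bit x of an OCT signature
#' marks an OCT cell at group offset x; bit x of a STEP signature marks a
#' column of the block containing a STEP cell): 1 iff the bitwise AND is
#' nonzero. A nonzero product is the gate through which the sparse
#' Four-Russians engine admits a block-level MUL access.
#'
#' @param m,mp Non-negative integer signatures (< 2^q).
#' @return 0 or 1.
#' @examples
#' sig_dot(0x0A, 0x08)  # 1: shared bit
#' sig_dot(0x02, 0x08)  # 0: disjoint
#' @export
sig_dot <- function(m, mp) {
  as.integer(bitwAnd(as.integer(m), as.integer(mp)) != 0L)
}
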