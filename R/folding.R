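#' Folding objects
#'
#' A folding is a set of 0-based position pairs `(k, l)`, `0 <= k < l < n`,
#' non-crossing, each position in at most one pair. Represented as a
#' two-column integer matrix with attribute `n`.
#'
#' @param pairs Two-column integer matrix (or empty) of 0-based pairs.
#' @param n Sequence length the folding refers to.
#' @return An `rna_folding`.
#' @export
rna_folding <- function(pairs, n) {
  if (is.null(pairs) || length(pairs) == 0L)
    pairs <- matrix(integer(0), ncol = 2L)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("k", "l")))
  out <- structure(pairs, n = as.integer(n), class = "rna_folding")
  validate_folding(out)
  out
}

#' Validate a folding
#'
#' Checks bounds, single occupancy and the non-crossing property; errors on
#' violation.
#'
#' @param folding An `rna_folding`.
#' @return The folding, invisibly.
#' @export
validate_folding <- function(folding) {
  stopifnot(inherits(folding, "rna_folding"))
  n <- attr(folding, "n")
  p <- unclass(folding)
  if (!nrow(p)) return(invisible(folding))
  if (any(p[, 1L] >= p[, 2L]) || any(p[, 1L] < 0L) || any(p[, 2L] >= n))
    stop("invalid pair bounds: need 0 <= k < l < n")
  pos <- c(p[, 1L], p[, 2L])
  if (anyDuplicated(pos))
    stop("a position participates in more than one pair")
  o <- order(p[, 1L])
  p <- p[o, , drop = FALSE]
  for (a in seq_len(nrow(p))) {
    for (b in seq_len(nrow(p))) {
      if (a == b) next
      # crossing: k <= k' <= l <= l' with distinct pairs
      if (p[a, 1L] < p[b, 1L] && p[b, 1L] < p[a, 2L] && p[a, 2L] < p[b, 2L])
        stop(sprintf("crossing pairs (%d,%d) and (%d,%d)",
                     p[a, 1L], p[a, 2L], p[b, 1L], p[b, 2L]))
    }
  }
  invisible(folding)
}

#' Score of a folding
#'
#' @param folding An `rna_folding`.
#' @param seq The sequence it folds.
#' @param scheme A [scoring_scheme()].
#' @return Sum of `beta(s[k], s[l])` over the pairs.
#' @export
folding_score <- function(folding, seq, scheme = scoring_scheme()) {
  stopifnot(inherits(folding, "rna_folding"))
  s <- strsplit(unclass(as_rna_sequence(seq)), "", fixed = TRUE)[[1L]]
  p <- unclass(folding)
  if (!nrow(p)) return(0L)
  sum(vapply(seq_len(nrow(p)),
             function(r) scheme$matrix[s[p[r, 1L] + 1L], s[p[r, 2L] + 1L]],
             integer(1)))
}

#' @export
print.rna_folding <- function(x, ...) {
  p <- unclass(x)
  cat(sprintf("RNA folding: %d pair(s), n = %d\n", nrow(p), attr(x, "n")))
  if (nrow(p)) print(p)
  invisible(x)
}

#' Recover an optimal folding from a solve
#'
#' Standard backtrace over the solved matrices. Deterministic tie-breaks:
#' subproblems with `L[i,j] = 0` contribute no pairs; the co-terminus case
#' is preferred whenever it is optimal and the closing pair scores
#' positively; otherwise the smallest optimal split point is taken. Every
#' emitted pair therefore has `beta > 0`, and the folding's score always
#' equals `L[0,n]`.
#'
#' @param res An `ssf_result` from [ssf_fold()].
#' @return A validated `rna_folding` with `folding_score()` equal to
#'   `res$score`.
#' @examples
#' ssf_traceback(ssf_fold("ACGU"))  # pairs (0,3) and (1,2)
#' @export
ssf_traceback <- function(res) {
  stopifnot(inherits(res, "ssf_result"))
  n <- res$n
  L <- res$L
  Lc <- res$Lc
  s <- strsplit(unclass(res$seq), "", fixed = TRUE)[[1L]]
  bmat <- res$scheme$matrix
  pairs <- list()
  stack <- list(c(0L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i < 2L) next
    l <- L[i + 1L, j + 1L]
    if (l == 0L) next
    lc <- Lc[i + 1L, j + 1L]
    b <- bmat[s[i + 1L], s[j]]   # pair (i, j-1)
    if (!is.na(lc) && lc == l && b > 0L) {
      pairs[[length(pairs) + 1L]] <- c(i, j - 1L)
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      next
    }
    found <- FALSE
    for (k in (i + 1L):(j - 1L)) {
      if (L[i + 1L, k + 1L] + L[k + 1L, j + 1L] == l) {
        stack[[length(stack) + 1L]] <- c(i, k)
        stack[[length(stack) + 1L]] <- c(k, j)
        found <- TRUE
        break
      }
    }
    if (!found)
      stop(sprintf("solution matrices are inconsistent at cell (%d,%d)", i, j))
  }
  out <- rna_folding(do.call(rbind, pairs), n)
  sc <- folding_score(out, res$seq, res$scheme)
  if (sc != res$score)
    stop(sprintf("traceback score %d does not match L[0,n] = %d", sc, res$score))
  out
}

#' Dot-bracket notation
#'
#' @param seq The folded sequence.
#' @param folding An `rna_folding` for `seq`.
#' @return `format_dotbracket()` returns the structure string: `(` at pair
#'   openings, `)` at closings, `.` elsewhere.
#' @export
format_dotbracket <- function(seq, folding) {
  validate_folding(folding)
  n <- seq_length(seq)
  stopifnot(attr(folding, "n") == n)
  db <- rep(".", n)
  p <- unclass(folding)
  if (nrow(p)) {
    db[p[, 1L] + 1L] <- "("
    db[p[, 2L] + 1L] <- ")"
  }
  paste(db, collapse = "")
}

#' @rdname format_dotbracket
#' @param path Output file: two lines, the sequence then the structure.
#' @return `write_dotbracket()` invisibly returns `path`.
#' @export
write_dotbracket <- function(seq, folding, path) {
  txt <- c(unclass(as_rna_sequence(seq)), format_dotbracket(seq, folding))
  writeLines(txt, path)
  invisible(path)
}
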