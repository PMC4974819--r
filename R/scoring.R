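#' Pair scoring scheme
#'
#' A scoring scheme assigns a non-negative integer score `beta(a, b)` to each
#' unordered nucleotide pair. The default is the base-pair maximization
#' scheme: score 1 for the Watson-Crick pairs `{A:U, C:G}` and 0 otherwise.
#' Scores must be discrete (integers): each engine relies on the fact that
#' adding one nucleotide changes an optimal score by at most `beta_max`, so
#' consecutive entries of any solution-matrix column differ by a value in
#' `[0, beta_max]`. The difference alphabet size is `D = beta_max + 1`
#' (2 for the default scheme).
#'
#' @param pairs Named integer vector; names are two-letter pair strings over
#'   `{A,C,G,U}` (unordered: both orientations are implied), values are
#'   non-negative integer scores. Unlisted pairs score 0.
#' @return An object of class `scoring_scheme` with elements `matrix`
#'   (4x4 symmetric integer score matrix with ACGU dimnames), `beta_max`,
#'   and `D`.
#' @examples
#' scoring_scheme()                      # default: AU = CG = 1
#' scoring_scheme(c(AU = 2, CG = 3, GU = 1))
#' @export
scoring_scheme <- function(pairs = c(AU = 1L, CG = 1L)) {
  bases <- c("A", "C", "G", "U")
  m <- matrix(0L, 4, 4, dimnames = list(bases, bases))
  if (length(pairs)) {
    if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
      stop("`pairs` must be a named vector of two-letter pair strings")
    for (nm in names(pairs)) {
      v <- pairs[[nm]]
      if (is.na(v) || v < 0 || v != as.integer(v))
        stop(sprintf("score for pair '%s' must be a non-negative integer", nm))
      p <- strsplit(chartr("tT", "uU", toupper(nm)), "", fixed = TRUE)[[1L]]
      if (length(p) != 2L || any(!p %in% bases))
        stop(sprintf("invalid pair name '%s': expected two letters of ACGU", nm))
      m[p[1L], p[2L]] <- as.integer(v)
      m[p[2L], p[1L]] <- as.integer(v)
    }
  }
  beta_max <- max(m)
  structure(list(matrix = m, beta_max = beta_max, D = beta_max + 1L),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("Pair scoring scheme (beta_max = %d, D = %d)\n",
              x$beta_max, x$D))
  print(x$matrix)
  invisible(x)
}

#' Pair score beta(a, b)
#'
#' @param scheme A [scoring_scheme()].
#' @param a,b Single nucleotides in `{A,C,G,U}`.
#' @return The configured non-negative integer score; symmetric in `a`, `b`.
#' @examples
#' beta(scoring_scheme(), "G", "C")  # 1
#' beta(scoring_scheme(), "A", "A")  # 0
#' @export
beta <- function(scheme, a, b) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  bases <- c("A", "C", "G", "U")
  if (!a %in% bases || !b %in% bases)
    stop("nucleotides must be in {A,C,G,U}")
  scheme$matrix[a, b]
}

#' Read a scoring scheme from a JSON config
#'
#' The file holds a JSON object mapping two-letter pair strings to
#' non-negative integer scores, e.g. `{"GC": 1, "AU": 1}`. Pairs are
#' unordered; both orientations are implied.
#'
#' @param path Path to the JSON file.
#' @return A [scoring_scheme()].
#' @export
read_scoring_scheme <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!length(obj)) stop("scoring config contains no pairs")
  scoring_scheme(unlist(obj))
}

#' Four-Russians block size q
#'
#' `q = max(1, floor(epsilon * log_D(n)))`, capped at `q_max` to bound
#' lookup-table memory. The log base is the difference-alphabet size `D`
#' (2 for the default scheme).
#'
#' @param n Sequence length (>= 1).
#' @param epsilon Block-size factor in (0, 0.5].
#' @param D Difference alphabet size (>= 2).
#' @param q_max Upper cap on q (default 8).
#' @return Integer block size >= 1.
#' @examples
#' choose_q(256, 0.5, 2)  # 4
#' choose_q(16, 0.25, 2)  # 1
#' @export
choose_q <- function(n, epsilon = 0.4, D = 2L, q_max = 8L) {
  stopifnot(length(n) == 1L, n >= 1, length(epsilon) == 1L)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon > 0.5)
    stop("`epsilon` must lie in (0, 0.5]")
  if (D < 2) stop("`D` must be >= 2")
  q <- floor(epsilon * log(n, base = D))
  max(1L, min(as.integer(q), as.integer(q_max)))
}
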