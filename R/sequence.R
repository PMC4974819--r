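#' Normalize a raw nucleotide string into an RNA sequence
#'
#' Strips whitespace, uppercases, and applies the DNA-to-RNA convention
#' `T -> U`. Any character outside `A`, `C`, `G`, `U`, `T` (either case) is
#' rejected with a message naming the offending 0-based position.
#'
#' @param raw A length-1 character string.
#' @return An object of class `rna_sequence`: a validated string over
#'   `{A,U,C,G}`. Positions are 0-based throughout the package and the
#'   substring `s[i,j)` excludes position `j`.
#' @examples
#' normalize_sequence("gcgc")
#' normalize_sequence("ACGT")   # T becomes U
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("`raw` must be a single character string")
  x <- gsub("[[:space:]]", "", raw)
  if (!nzchar(x)) stop("sequence is empty after whitespace removal")
  x <- chartr("tT", "uU", x)
  x <- toupper(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% c("A", "C", "G", "U"))
  if (length(bad))
    stop(sprintf("invalid symbol '%s' at position %d", ch[bad[1L]], bad[1L] - 1L))
  structure(x, class = "rna_sequence")
}

#' Coerce to an RNA sequence
#'
#' @param x An `rna_sequence` or a raw character string (normalized on the
#'   fly via [normalize_sequence()]). The empty string is accepted here and
#'   yields the length-0 sequence.
#' @return An `rna_sequence`.
#' @export
as_rna_sequence <- function(x) {
  if (inherits(x, "rna_sequence")) return(x)
  if (is.character(x) && length(x) == 1L && !is.na(x) &&
      !nzchar(gsub("[[:space:]]", "", x)))
    return(structure("", class = "rna_sequence"))
  normalize_sequence(x)
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("RNA sequence, n = %d\n", nchar(unclass(x))))
  s <- unclass(x)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(s, "\n")
  invisible(x)
}

#' Number of residues in an RNA sequence
#' @param seq An `rna_sequence` (or coercible string).
#' @return Integer length `n`.
#' @export
seq_length <- function(seq) nchar(unclass(as_rna_sequence(seq)))

# 0-based integer encoding A=0, C=1, G=2, U=3 used by the C++ engines
seq_to_int <- function(seq) {
  s <- unclass(as_rna_sequence(seq))
  if (!nchar(s)) return(integer(0))
  match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "U")) - 1L
}

#' Seeded random RNA sequence
#'
#' Draws residues i.i.d. uniformly over `{A,U,C,G}` from a seeded generator,
#' without disturbing the caller's RNG state. Identical `(n, seed)` always
#' yields the identical sequence.
#'
#' @param n Sequence length (>= 0).
#' @param seed Integer seed.
#' @return An `rna_sequence` of length `n`.
#' @export
random_sequence <- function(n, seed) {
  stopifnot(length(n) == 1L, n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(structure("", class = "rna_sequence"))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  structure(paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                  collapse = ""),
            class = "rna_sequence")
}
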