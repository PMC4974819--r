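#' Read RNA sequences from a FASTA file
#'
#' Multi-record FASTA; every record is normalized via
#' [normalize_sequence()] (uppercased, `T -> U`, invalid residues rejected
#' with their position).
#'
#' @param path Path to a FASTA file.
#' @return Named list of `rna_sequence` objects (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (!length(nonblank))
    stop(sprintf("%s: empty FASTA file", path))
  if (!startsWith(trimws(first[nonblank[1L]]), ">"))
    stop(sprintf("%s: line %d: expected a '>' header", path, nonblank[1L]))
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (!length(recs)) stop(sprintf("%s: no records", path))
  out <- lapply(seq_along(recs), function(t) {
    str <- as.character(recs[[t]])[1L]
    if (!nzchar(gsub("[[:space:]]", "", str)))
      stop(sprintf("%s: record '%s' is empty", path,
                   attr(recs[[t]], "name")))
    tryCatch(normalize_sequence(str), error = function(e)
      stop(sprintf("%s: record '%s': %s", path, attr(recs[[t]], "name"),
                   conditionMessage(e)), call. = FALSE))
  })
  names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
  out
}
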