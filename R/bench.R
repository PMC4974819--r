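#' Operation-count benchmark across engines
#'
#' For each size, generates `reps` random sequences (i.i.d. uniform bases,
#' seeds derived deterministically from `seed`) and runs every requested
#' engine on the *same* sequences, recording the operation counters. Score
#' agreement across engines is asserted for every row. The naive engine's
#' split count is sequence-independent and equals `choose(n+1, 3)` per
#' sequence.
#'
#' @param sizes Integer vector of sequence lengths.
#' @param reps Replicates per size (default 20).
#' @param seed Master seed; identical arguments give a byte-identical report.
#' @param engines Subset of `c("naive", "sp", "fr", "sfr", "parallel-sim")`.
#' @param epsilon Block-size factor for the Four-Russians family.
#' @param scheme A [scoring_scheme()].
#' @return A data.frame of class `ssf_benchmark`: one row per
#'   (size, replicate, engine) with the seed, optimal score, every counter,
#'   and `total_ops`. Aggregate with [benchmark_totals()].
#' @examples
#' run_benchmark(sizes = 32, reps = 2, seed = 1, engines = c("naive", "sfr"))
#' @export
run_benchmark <- function(sizes, reps = 20L, seed = 1L,
                          engines = c("naive", "sp", "fr", "sfr"),
                          epsilon = 0.4, scheme = scoring_scheme()) {
  stopifnot(all(engines %in% ENGINES), length(sizes) >= 1L, reps >= 1L)
  rows <- list()
  for (n in as.integer(sizes)) {
    for (r in seq_len(reps)) {
      sseed <- (as.integer(seed) * 10007L + n * 131L + r) %% 2147483647L
      sq <- random_sequence(n, sseed)
      scores <- integer(0)
      for (eng in engines) {
        res <- ssf_fold(sq, scheme, engine = eng, epsilon = epsilon)
        scores <- c(scores, res$score)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, engine = eng, rep = r, seed = sseed, score = res$score,
          split_comparisons = res$counters[["split_comparisons"]],
          mul_lookups = res$counters[["mul_lookups"]],
          mul_builds = res$counters[["mul_builds"]],
          max_lookups = res$counters[["max_lookups"]],
          max_builds = res$counters[["max_builds"]],
          g_builds = res$counters[["g_builds"]],
          total_ops = res$total_ops,
          Z = res$Z,
          stringsAsFactors = FALSE)
      }
      if (length(unique(scores)) > 1L)
        stop(sprintf("engines disagree on n = %d seed = %d: %s",
                     n, sseed, paste(engines, scores, collapse = ", ")))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(sizes = as.integer(sizes),
                              reps = as.integer(reps),
                              seed = as.integer(seed), engines = engines,
                              epsilon = epsilon,
                              base_composition = "iid uniform A,C,G,U")
  class(out) <- c("ssf_benchmark", "data.frame")
  out
}

#' Aggregate benchmark totals per (size, engine)
#'
#' @param report An `ssf_benchmark` from [run_benchmark()].
#' @return data.frame with per-(n, engine) summed `total_ops` and
#'   `split_comparisons`, plus the per-sequence mean of each.
#' @export
benchmark_totals <- function(report) {
  stopifnot(inherits(report, "ssf_benchmark"))
  df <- as.data.frame(report)
  agg <- aggregate(cbind(total_ops, split_comparisons) ~ n + engine,
                   data = df, FUN = sum)
  m <- aggregate(cbind(total_ops, split_comparisons) ~ n + engine,
                 data = df, FUN = mean)
  names(m)[3:4] <- c("total_ops_per_seq", "split_comparisons_per_seq")
  out <- merge(agg, m, by = c("n", "engine"), sort = TRUE)
  out[order(out$n, match(out$engine, ENGINES)), , drop = FALSE]
}

#' Write a benchmark report as TSV
#'
#' A commented header records the generation parameters (sizes, replicate
#' count, master seed, engines, base composition) so a report is
#' reproducible from its own file.
#'
#' @param report An `ssf_benchmark`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(report, path) {
  stopifnot(inherits(report, "ssf_benchmark"))
  p <- attr(report, "params")
  hdr <- sprintf(
    "# rnassf benchmark: sizes=%s reps=%d seed=%d engines=%s epsilon=%g composition=%s",
    paste(p$sizes, collapse = ","), p$reps, p$seed,
    paste(p$engines, collapse = ","), p$epsilon, p$base_composition)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
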