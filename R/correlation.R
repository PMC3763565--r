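#' Correlation profiles of read-start signals
#'
#' A `correlation_profile` stores pair counts over lags `0 <= tau < W`:
#' either the same-strand autocorrelation (DSP definition: raw pair
#' counts, no mean centering, no variance normalization) or the
#' opposing-strand cross-correlation. Construct directly from a count
#' vector, or via [autocorrelation()] / [cross_correlation()].
#'
#' @param values non-negative numeric vector of length `max_lag`;
#'   `values[tau + 1]` is the count at lag `tau`.
#' @param kind `"auto"` or `"cross"`.
#' @param max_lag the window W in bp.
#' @param sample_id sample identifier.
#' @return A `correlation_profile` object.
#' @export
correlation_profile <- function(values, kind = c("auto", "cross"),
                                max_lag = length(values),
                                sample_id = "sample") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != max_lag)
    stop("values has length ", length(values), ", expected max_lag = ", max_lag)
  if (anyNA(values) || any(values < 0))
    stop("correlation counts must be non-negative and finite")
  structure(list(sample_id = sample_id, kind = kind, max_lag = as.integer(max_lag),
                 values = values),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile '%s' (%s): W = %d, total pairs = %.6g\n",
              x$sample_id, x$kind, x$max_lag, sum(x$values)))
  invisible(x)
}

#' Same-strand pair-count autocorrelation
#'
#' Counts, for every lag `0 <= tau < max_lag`, the ordered pairs of
#' deduplicated read starts on the same strand of the same chromosome
#' separated by exactly `tau` bp, summed over strands and chromosomes.
#' This is the autocorrelation of the 0/1 read-start indicator signal:
#' `values[0]` equals the number of occupied positions (self-pairs), and
#' pairs never cross chromosomes or strands. Computed per chromosome by a
#' sliding window over sorted positions, O(N k) with k the mean number of
#' neighbours within the window.
#'
#' @param starts a [stranded_read_starts()] object.
#' @param max_lag window W in bp (default 8192, the spectral feature
#'   length); must be >= 2.
#' @param strands `"both"` (sum of the two same-strand autocorrelations,
#'   the default) or `"plus"`.
#' @return A `correlation_profile` of kind `"auto"`.
#' @export
autocorrelation <- function(starts, max_lag = 8192L,
                            strands = c("both", "plus")) {
  stopifnot(inherits(starts, "stranded_read_starts"))
  strands <- match.arg(strands)
  max_lag <- as.integer(max_lag)
  if (max_lag < 2) stop("max_lag must be >= 2")
  if (n_reads(starts)[["total"]] == 0)
    warning("no reads: returning all-zero autocorrelation")
  values <- numeric(max_lag)
  for (ch in starts$chroms) {
    values <- values + .pair_lag_counts(ch$plus, max_lag)
    if (strands == "both")
      values <- values + .pair_lag_counts(ch$minus, max_lag)
  }
  correlation_profile(values, "auto", max_lag, starts$sample_id)
}

#' Opposing-strand cross-correlation
#'
#' Counts ordered pairs (plus-strand start `p`, minus-strand start `m`)
#' on the same chromosome with `m - p = tau` for `0 <= tau < max_lag`,
#' summed over chromosomes. Distances from a fragment's plus-strand read
#' to its minus-strand read equal fragment length minus one, so this
#' histogram carries the fragment-length information exploited by
#' [fragment_length_distribution()].
#'
#' @inheritParams autocorrelation
#' @return A `correlation_profile` of kind `"cross"` (raw counts; any
#'   multiplicative normalization cancels in downstream spectral ratios).
#' @export
cross_correlation <- function(starts, max_lag = 8192L) {
  stopifnot(inherits(starts, "stranded_read_starts"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 2) stop("max_lag must be >= 2")
  n <- n_reads(starts)
  if (n[["plus"]] == 0 || n[["minus"]] == 0)
    warning("one strand empty: returning all-zero cross-correlation")
  values <- numeric(max_lag)
  for (ch in starts$chroms)
    values <- values + .cross_lag_counts(ch$plus, ch$minus, max_lag)
  correlation_profile(values, "cross", max_lag, starts$sample_id)
}

#' Normalized display view of a correlation profile
#'
#' Raw pair counts divided by `N+ * N-` (cross) or `N * N` (auto). Purely
#' for display/comparison across depths; all spectral machinery consumes
#' raw counts, where constants cancel in deconvolution ratios.
#'
#' @param profile a `correlation_profile`.
#' @param starts the [stranded_read_starts()] the profile came from.
#' @return Numeric vector of normalized values.
#' @export
normalized_values <- function(profile, starts) {
  n <- n_reads(starts)
  denom <- if (profile$kind == "cross") n[["plus"]] * n[["minus"]]
           else n[["total"]]^2
  if (denom == 0) stop("cannot normalize: no reads")
  profile$values / denom
}

#' Write / read a correlation or Arpeggio profile TSV
#'
#' Two tab-separated columns (`lag_bp`, `value`) with `#key=value` header
#' lines (`sample_id`, `kind`, `max_lag`).
#'
#' @param profile a `correlation_profile` or `arpeggio_profile`.
#' @param path file path.
#' @return `write_profile_tsv` returns `path` invisibly;
#'   `read_profile_tsv` a `correlation_profile` (kind `auto`/`cross`) or
#'   plain numeric for kind `arpeggio`.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "arpeggio_profile")) {
    kind <- "arpeggio"; values <- profile$values
    id <- profile$sample_id; W <- length(values)
  } else {
    stopifnot(inherits(profile, "correlation_profile"))
    kind <- profile$kind; values <- profile$values
    id <- profile$sample_id; W <- profile$max_lag
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#sample_id=", id), paste0("#kind=", kind),
               paste0("#max_lag=", W), "lag_bp\tvalue"), con)
  writeLines(paste(seq_len(W) - 1L, format(values, digits = 17, trim = TRUE,
                                           scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- character(); con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  meta <- list(sample_id = "sample", kind = "auto", max_lag = NA)
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- data.table::fread(path, skip = length(hdr), header = TRUE, sep = "\t")
  values <- as.numeric(tab$value)
  if (meta$kind == "arpeggio") {
    structure(list(sample_id = meta$sample_id, control_id = NA_character_,
                   values = values, epsilon_rel = NA_real_,
                   flatness = NA_real_, n_guarded = NA_integer_),
              class = "arpeggio_profile")
  } else {
    correlation_profile(values, meta$kind, as.integer(meta$max_lag),
                        meta$sample_id)
  }
}
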