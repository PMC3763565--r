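#' Match a ChIP experiment to its best control
#'
#' Candidate controls are filtered to the sample's organism and
#' DNA-shearing technique, then ranked by Pearson correlation between
#' spectral magnitude vectors in the frequency domain (low-passed, DC bin
#' excluded — the DC component only reflects total read-count differences
#' and would otherwise dominate). The best candidate is returned iff its
#' correlation exceeds `rho_min`; correlation in the frequency domain does
#' not imply correlation in genomic coordinates, which is the point: the
#' match is spectral, not positional.
#'
#' @param sample_sd [spectral_density()] of the ChIP sample's
#'   autocorrelation.
#' @param candidates list of candidate controls, each a list with
#'   elements `sd` (a `spectral_density`) and `meta` (a one-row
#'   data.frame or list with `sample_id`, `organism`, `shearing`,
#'   `is_control`).
#' @param sample_meta metadata for the ChIP sample (same fields).
#' @param rho_min minimum Pearson correlation to accept a match
#'   (default 0.85).
#' @param cutoff_scale low-pass cutoff in bp applied before correlating
#'   (default 40).
#' @param log_magnitude correlate log1p magnitudes instead of raw
#'   magnitudes.
#' @return A `control_match`: `sample_id`, `control_id` (`NA` if no
#'   candidate passes), `rho`, and a `trace` data.frame recording every
#'   candidate's fate (`matched`, `rho_below_threshold`, `organism`,
#'   `shearing`, `not_control`).
#' @export
match_control <- function(sample_sd, candidates, sample_meta,
                          rho_min = 0.85, cutoff_scale = 40,
                          log_magnitude = FALSE) {
  stopifnot(inherits(sample_sd, "spectral_density"))
  feat <- function(sd) {
    m <- Mod(low_pass(sd, cutoff_scale)$values)[-1]  # drop DC
    if (log_magnitude) log1p(m) else m
  }
  x <- feat(sample_sd)
  ids <- vapply(candidates, function(cc) as.character(cc$meta$sample_id),
                character(1))
  status <- character(length(candidates))
  rhos <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    meta <- candidates[[i]]$meta
    if (!isTRUE(as.logical(meta$is_control))) {
      status[i] <- "not_control"; next
    }
    if (!identical(as.character(meta$organism),
                   as.character(sample_meta$organism))) {
      status[i] <- "organism"; next
    }
    cand_sh <- as.character(meta$shearing)
    samp_sh <- as.character(sample_meta$shearing)
    # "unknown" shearing is permissive: it matches anything
    if (cand_sh != samp_sh && cand_sh != "unknown" && samp_sh != "unknown") {
      status[i] <- "shearing"; next
    }
    y <- feat(candidates[[i]]$sd)
    if (length(y) != length(x)) stop("spectra of unequal length")
    rhos[i] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
               else stats::cor(x, y)
    status[i] <- "candidate"
  }
  eligible <- which(status == "candidate" & !is.na(rhos) & rhos > rho_min)
  if (length(eligible)) {
    # argmax; ties broken by candidate id lexicographic order
    best <- eligible[order(-rhos[eligible], ids[eligible])][1]
    status[best] <- "matched"
    status[setdiff(eligible, best)] <- "lower_rho"
    control_id <- ids[best]; rho <- rhos[best]
  } else {
    status[status == "candidate"] <- "rho_below_threshold"
    control_id <- NA_character_; rho <- NA_real_
  }
  structure(list(sample_id = sample_sd$sample_id, control_id = control_id,
                 rho = rho, rho_min = rho_min,
                 trace = data.frame(candidate_id = ids, status = status,
                                    rho = rhos)),
            class = "control_match")
}

#' @export
print.control_match <- function(x, ...) {
  if (is.na(x$control_id))
    cat(sprintf("control_match '%s': no control passed rho > %.2f (%d candidate(s))\n",
                x$sample_id, x$rho_min, nrow(x$trace)))
  else
    cat(sprintf("control_match '%s': matched '%s' with rho = %.4f\n",
                x$sample_id, x$control_id, x$rho))
  invisible(x)
}
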