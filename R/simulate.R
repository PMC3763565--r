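#' Configuration for a synthetic ChIP-seq experiment
#'
#' The simulator emulates the four broad protein-chromatin interaction
#' regimes seen in genome-aggregated ChIP-seq signatures: isolated
#' binding events (factor-like: sharp pulse with decaying tails), phased
#' nucleosome arrays with a fixed repeat length and tunable positional
#' jitter (histone-mark-like: damped oscillations), polymerase-like
#' signals spread along gene bodies with a 5' anchor, and background-only
#' controls. Reads are single-end: every sheared fragment emits one read,
#' on the plus strand at the fragment start or on the minus strand at the
#' fragment end - 1, each with probability 1/2. Background fragments are
#' drawn from piecewise-constant accessibility blocks that a matched
#' control shares, emulating common technical bias.
#'
#' @param regime one of `"isolated_factor"`, `"periodic_array"`,
#'   `"polymerase_spread"`, `"background_control"`.
#' @param genome_length simulated chromosome length in bp (default 2 Mb,
#'   large enough to hold hundreds of events at realistic density).
#' @param n_events number of binding events / arrays / genes.
#' @param repeat_length nucleosome repeat length in bp (default 190).
#' @param array_size nucleosomes per phased array (default 10).
#' @param positional_jitter_sd sd in bp of Gaussian jitter on each
#'   nucleosome position (default 5: strict phasing; ~60 emulates fluid
#'   spacing).
#' @param fragment_model list with `type` (`"fixed"`, `"lognormal"`,
#'   `"gamma"`, or `"mixture"`) and `mean`/`sd` in bp (for `"mixture"`:
#'   `lengths` and optional `weights`). Default lognormal(250, 30), the
#'   size-selection target of sonication protocols.
#' @param read_length sequenced read length in bp (default 36).
#' @param n_reads total reads to emit (one per fragment).
#' @param background_fraction fraction of reads from accessibility
#'   background rather than signal. Default is per regime: 0.7 for
#'   `isolated_factor` (point-source ChIP libraries are mostly
#'   background; fraction-of-reads-in-peaks near 0.3 is strong
#'   enrichment), 0.3 for `periodic_array` (broad histone-mark domains
#'   capture most of the library), 0.5 for `polymerase_spread`, and 1
#'   for `background_control` (always forced to 1).
#' @param accessibility_blocks `NULL` (generated from the seed) or a
#'   data.frame with `start`, `end`, `rate` covering enriched blocks;
#'   unlisted genome has rate 1.
#' @param n_blocks,block_length,block_contrast parameters of the
#'   generated accessibility blocks (defaults: 20 blocks of 4 kb at 3x
#'   the baseline sampling rate).
#' @param spread_length gene-body length for `polymerase_spread` bp
#'   (default 2000).
#' @param anchor_fraction for `polymerase_spread`, fraction of signal
#'   fragments anchored at the 5' end (default 0.3).
#' @param fragment_placement how signal fragments relate to their event:
#'   `"cover"` (start uniform over the f positions that cover the event
#'   — random shearing around a point source), `"centered"` (fragment
#'   midpoint at the event — nucleosome-protected fragments whose
#'   boundaries track the particle, as after MNase digestion of a
#'   phased array), or `"anchored"` (fragment 5' end exactly at the
#'   event — digestion-boundary-anchored libraries; the only geometry
#'   in which fragment start and length are independent, as required
#'   for full fragment-length-distribution recovery). Default
#'   `"centered"` for `periodic_array`, else `"cover"`.
#' @param shearing shearing tag carried into the read-start metadata
#'   (default `"sonication"`); matched controls inherit it.
#' @param sample_id sample identifier.
#' @param seed RNG seed; identical configs with identical seeds produce
#'   byte-identical experiments.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(regime = c("isolated_factor", "periodic_array",
                                         "polymerase_spread",
                                         "background_control"),
                              genome_length = 2e6, n_events = 500,
                              repeat_length = 190, array_size = 10,
                              positional_jitter_sd = 5,
                              fragment_model = list(type = "lognormal",
                                                    mean = 250, sd = 30),
                              read_length = 36, n_reads = 100000,
                              background_fraction = NULL,
                              accessibility_blocks = NULL,
                              n_blocks = 20, block_length = 4000,
                              block_contrast = 3,
                              spread_length = 2000, anchor_fraction = 0.3,
                              fragment_placement = NULL,
                              shearing = c("sonication", "mnase", "unknown"),
                              sample_id = "sim", seed = 1) {
  shearing <- match.arg(shearing)
  regime <- match.arg(regime)
  if (is.null(background_fraction))
    background_fraction <- switch(regime, isolated_factor = 0.7,
                                  periodic_array = 0.3,
                                  polymerase_spread = 0.5,
                                  background_control = 1)
  if (is.null(fragment_placement))
    fragment_placement <- if (regime == "periodic_array")
      "centered" else "cover"
  fragment_placement <- match.arg(fragment_placement,
                                  c("cover", "centered", "anchored"))
  stopifnot(genome_length >= 1, n_events >= 0, repeat_length >= 1,
            array_size >= 1, positional_jitter_sd >= 0, n_reads >= 0,
            background_fraction >= 0, background_fraction <= 1,
            fragment_model$type %in% c("fixed", "lognormal", "gamma",
                                       "mixture"))
  if (regime == "background_control") background_fraction <- 1
  structure(as.list(environment()), class = "simulation_config")
}

.fragment_lengths <- function(model, n) {
  if (n == 0) return(integer(0))
  f <- switch(model$type,
    fixed = rep(model$mean, n),
    lognormal = {
      sdlog <- sqrt(log(1 + (model$sd / model$mean)^2))
      rlnorm(n, log(model$mean) - sdlog^2 / 2, sdlog)
    },
    gamma = rgamma(n, shape = (model$mean / model$sd)^2,
                   rate = model$mean / model$sd^2),
    mixture = sample(model$lengths, n, replace = TRUE,
                     prob = model$weights %||% NULL))
  pmax(1L, as.integer(round(f)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_blocks <- function(cfg) {
  g <- cfg$genome_length
  starts <- sort(floor(runif(cfg$n_blocks, 0, max(1, g - cfg$block_length))))
  gr <- IRanges::reduce(IRanges::IRanges(starts + 1L,
                                         pmin(starts + cfg$block_length, g)))
  data.frame(start = IRanges::start(gr) - 1L, end = IRanges::end(gr),
             rate = cfg$block_contrast)
}

# Piecewise-constant sampler: blocks at their rate, rest of the genome at 1.
.sample_background <- function(blocks, genome_length, n) {
  if (n == 0) return(integer(0))
  if (is.null(blocks) || !nrow(blocks)) {
    return(floor(runif(n, 0, genome_length)))
  }
  bl_len <- blocks$end - blocks$start
  rest <- genome_length - sum(bl_len)
  w <- c(blocks$rate * bl_len, rest)
  piece <- sample.int(length(w), n, replace = TRUE, prob = w)
  pos <- integer(n)
  in_block <- piece <= nrow(blocks)
  if (any(in_block)) {
    b <- piece[in_block]
    pos[in_block] <- blocks$start[b] +
      floor(runif(sum(in_block)) * bl_len[b])
  }
  if (any(!in_block)) {
    # uniform over the complement via gap bookkeeping
    gaps_start <- c(0, blocks$end)
    gaps_end <- c(blocks$start, genome_length)
    glen <- pmax(0, gaps_end - gaps_start)
    gi <- sample.int(length(glen), sum(!in_block), replace = TRUE, prob = glen)
    pos[!in_block] <- gaps_start[gi] + floor(runif(sum(!in_block)) * glen[gi])
  }
  pos
}

.event_positions <- function(cfg) {
  g <- cfg$genome_length
  switch(cfg$regime,
    isolated_factor = floor(runif(cfg$n_events, 0, g)),
    periodic_array = {
      span <- (cfg$array_size - 1) * cfg$repeat_length
      anchors <- floor(runif(cfg$n_events, 0, max(1, g - span)))
      centers <- rep(anchors, each = cfg$array_size) +
        rep(seq_len(cfg$array_size) - 1L, cfg$n_events) * cfg$repeat_length +
        round(rnorm(cfg$n_events * cfg$array_size, 0,
                    cfg$positional_jitter_sd))
      pmax(0L, pmin(as.integer(centers), as.integer(g) - 1L))
    },
    polymerase_spread = floor(runif(cfg$n_events, 0,
                                    max(1, g - cfg$spread_length))),
    background_control = integer(0))
}

#' Simulate a synthetic ChIP-seq experiment
#'
#' Places events per the configured regime, samples fragments covering
#' them (fragment start uniform over the positions that cover the event)
#' plus accessibility-biased background fragments, and emits one
#' single-end read per fragment on a random strand. Read starts are then
#' deduplicated exactly as real input would be. Deterministic under a
#' fixed seed.
#'
#' @param config a [simulation_config()].
#' @return A `simulated_experiment`: `starts`
#'   ([stranded_read_starts()]), `fragments` (data.frame `start`, `end`,
#'   `length`, 0-based half-open — the paired-end oracle), `events`
#'   (event positions), `blocks` (accessibility blocks used), `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  g <- cfg$genome_length
  .with_seed(cfg$seed, {
    blocks <- cfg$accessibility_blocks
    if (is.null(blocks)) blocks <- .default_blocks(cfg)
    events <- .event_positions(cfg)
    n_bg <- round(cfg$n_reads * cfg$background_fraction)
    n_sig <- cfg$n_reads - n_bg
    if (!length(events)) { n_bg <- cfg$n_reads; n_sig <- 0 }

    f_sig <- .fragment_lengths(cfg$fragment_model, n_sig)
    start_sig <- integer(0)
    if (n_sig > 0) {
      if (cfg$regime == "polymerase_spread") {
        gene <- events[sample.int(length(events), n_sig, replace = TRUE)]
        anchored <- runif(n_sig) < cfg$anchor_fraction
        start_sig <- integer(n_sig)
        # 5'-anchored fragments cover the TSS; the rest lie along the body
        start_sig[anchored] <- gene[anchored] -
          floor(runif(sum(anchored)) * f_sig[anchored])
        nb <- !anchored
        start_sig[nb] <- gene[nb] + floor(runif(sum(nb)) *
          pmax(1, cfg$spread_length - f_sig[nb]))
      } else {
        ev <- events[sample.int(length(events), n_sig, replace = TRUE)]
        start_sig <- switch(cfg$fragment_placement,
          # start uniform over the f positions covering the event
          cover = ev - floor(runif(n_sig) * f_sig),
          # fragment midpoint at the event (nucleosome-protected)
          centered = ev - f_sig %/% 2L,
          # fragment 5' end at the event (boundary-anchored)
          anchored = ev)
      }
    }
    f_bg <- .fragment_lengths(cfg$fragment_model, n_bg)
    start_bg <- .sample_background(blocks, g, n_bg) -
      floor(runif(n_bg) * f_bg)

    fstart <- c(start_sig, start_bg)
    flen <- c(f_sig, f_bg)
    fstart <- pmax(0L, pmin(as.integer(fstart), as.integer(g) - flen))
    fend <- fstart + flen

    plus <- runif(length(fstart)) < 0.5
    pos <- ifelse(plus, fstart, fend - 1L)
    starts <- stranded_read_starts(
      list(chr1 = list(plus = pos[plus], minus = pos[!plus])),
      sample_id = cfg$sample_id, read_length = cfg$read_length,
      organism = "synthetic", shearing = cfg$shearing)
    structure(list(starts = starts,
                   fragments = data.frame(start = fstart, end = fend,
                                          length = flen),
                   events = events, blocks = blocks, config = cfg),
              class = "simulated_experiment")
  })
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("simulated_experiment '%s' (%s): %d fragments, %d event(s)\n",
              x$config$sample_id, x$config$regime, nrow(x$fragments),
              length(x$events)))
  invisible(x)
}

#' Simulate a ChIP experiment with its matched background control
#'
#' The ChIP sample is generated from `config`; the control is a
#' background-only experiment drawing from the *same* accessibility
#' blocks (independent fragments), emulating the shared technical bias
#' that control matching and deconvolution rely on.
#'
#' @param config a [simulation_config()] for the ChIP sample.
#' @param control_depth reads in the control (default: same as ChIP).
#' @return List with elements `chip` and `control`, both
#'   `simulated_experiment`s.
#' @export
simulate_matched_pair <- function(config, control_depth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$accessibility_blocks)) {
    config$accessibility_blocks <- .with_seed(config$seed,
                                              .default_blocks(config))
  }
  chip <- simulate_experiment(config)
  ctrl_cfg <- config
  ctrl_cfg$regime <- "background_control"
  ctrl_cfg$background_fraction <- 1
  ctrl_cfg$n_reads <- if (is.null(control_depth)) config$n_reads
                      else control_depth
  ctrl_cfg$sample_id <- paste0(config$sample_id, "_control")
  ctrl_cfg$seed <- config$seed + 1
  class(ctrl_cfg) <- "simulation_config"
  list(chip = chip, control = simulate_experiment(ctrl_cfg))
}

#' Write a simulated experiment to plain-text artifacts
#'
#' Reads as BED6 (score 0, name `read<i>`), true fragments as BED3, and
#' a JSON truth sidecar (config, event positions).
#'
#' @param sim a `simulated_experiment`.
#' @param prefix output path prefix; writes `<prefix>.reads.bed`,
#'   `<prefix>.fragments.bed`, `<prefix>.truth.json`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_simulated_experiment <- function(sim, prefix) {
  stopifnot(inherits(sim, "simulated_experiment"))
  ch <- sim$starts$chroms[["chr1"]]
  rl <- sim$config$read_length
  bed <- rbind(
    data.frame(chrom = "chr1", start = ch$plus, end = ch$plus + rl,
               strand = "+"),
    data.frame(chrom = "chr1", start = ch$minus - rl + 1L,
               end = ch$minus + 1L, strand = "-"))
  bed$start <- pmax(0L, bed$start)
  reads_path <- paste0(prefix, ".reads.bed")
  frag_path <- paste0(prefix, ".fragments.bed")
  truth_path <- paste0(prefix, ".truth.json")
  data.table::fwrite(
    data.frame(bed$chrom, bed$start, bed$end,
               paste0("read", seq_len(nrow(bed))), 0L, bed$strand),
    reads_path, sep = "\t", col.names = FALSE)
  data.table::fwrite(
    data.frame("chr1", sim$fragments$start, sim$fragments$end),
    frag_path, sep = "\t", col.names = FALSE)
  cfg <- sim$config
  cfg$accessibility_blocks <- sim$blocks
  jsonlite::write_json(
    list(config = unclass(cfg), events = sim$events),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(reads = reads_path, fragments = frag_path, truth = truth_path))
}
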