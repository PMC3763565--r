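#' Stranded read-start sets
#'
#' A `stranded_read_starts` object holds, per chromosome, the deduplicated
#' 5'-end positions of aligned single-end reads, split by strand. All
#' coordinates are 0-based half-open; the 5' end of a minus-strand read is
#' its rightmost aligned base (`end - 1`). Duplicated positions within a
#' (chromosome, strand) are collapsed to one, so each strand signal is a
#' 0/1 indicator of occupied positions.
#'
#' @param chroms named list; each element a list with sorted integer
#'   vectors `plus` and `minus` of 0-based 5'-end positions.
#' @param sample_id sample identifier.
#' @param read_length median observed read length in bp, or `NA`.
#' @param organism free-text organism tag used for control matching.
#' @param shearing one of `"sonication"`, `"mnase"`, `"unknown"`.
#' @return A `stranded_read_starts` object.
#' @export
stranded_read_starts <- function(chroms, sample_id = "sample",
                                 read_length = NA_real_,
                                 organism = "unknown",
                                 shearing = c("unknown", "sonication", "mnase")) {
  shearing <- match.arg(shearing)
  stopifnot(is.list(chroms))
  if (length(chroms) && is.null(names(chroms)))
    stop("chroms must be a named list (one element per chromosome)")
  chroms <- lapply(chroms, function(ch) {
    plus <- .clean_positions(ch$plus)
    minus <- .clean_positions(ch$minus)
    list(plus = plus, minus = minus)
  })
  structure(
    list(sample_id = sample_id, chroms = chroms, read_length = read_length,
         organism = organism, shearing = shearing),
    class = "stranded_read_starts"
  )
}

.clean_positions <- function(x) {
  if (is.null(x) || !length(x)) return(integer(0))
  x <- as.integer(x)
  if (anyNA(x)) stop("read-start positions must not be NA")
  if (any(x < 0)) stop("read-start positions must be non-negative")
  sort(unique(x))
}

#' @export
print.stranded_read_starts <- function(x, ...) {
  n <- n_reads(x)
  cat(sprintf(
    "stranded_read_starts '%s': %d chromosome(s), N+ = %d, N- = %d (deduplicated)\n",
    x$sample_id, length(x$chroms), n[["plus"]], n[["minus"]]))
  invisible(x)
}

#' Count deduplicated read starts per strand
#'
#' @param starts a [stranded_read_starts()] object.
#' @return Named numeric vector with elements `plus`, `minus`, `total`.
#' @export
n_reads <- function(starts) {
  stopifnot(inherits(starts, "stranded_read_starts"))
  np <- sum(vapply(starts$chroms, function(ch) length(ch$plus), integer(1)))
  nm <- sum(vapply(starts$chroms, function(ch) length(ch$minus), integer(1)))
  c(plus = np, minus = nm, total = np + nm)
}

#' Load stranded read starts from BAM, SAM or BED
#'
#' Extracts the deduplicated 5'-end position of every usable aligned read:
#' alignment start for plus-strand reads, rightmost aligned base
#' (`end - 1`, 0-based) for minus-strand reads. Unmapped and secondary
#' records are skipped; PCR duplicates collapse because positions are
#' deduplicated per (chromosome, strand). For paired-end input only the
#' first mate is used (a warning reports dropped mate-2 records).
#'
#' @param path path to the alignment/interval file.
#' @param format `"auto"` (by extension), `"bam"`, `"sam"` or `"bed"`.
#' @param min_mapq minimum mapping quality (BAM/SAM only); default 0 keeps
#'   everything, trusting upstream unique-alignment filtering.
#' @inheritParams stranded_read_starts
#' @return A [stranded_read_starts()] object. BED records without strand
#'   are rejected (an error if no stranded record survives).
#' @export
load_read_starts <- function(path, format = c("auto", "bam", "sam", "bed"),
                             sample_id = NULL, min_mapq = 0,
                             organism = "unknown",
                             shearing = c("unknown", "sonication", "mnase")) {
  format <- match.arg(format)
  shearing <- match.arg(shearing)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bam = "bam", sam = "sam", bed = "bed",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format="))
  }
  tab <- switch(format,
                bed = .starts_from_bed(path),
                sam = ,
                bam = .starts_from_bam(path, format, min_mapq))
  chroms <- list()
  if (nrow(tab)) {
    for (chr in unique(tab$chrom)) {
      sub <- tab[tab$chrom == chr, ]
      chroms[[chr]] <- list(plus = sub$pos[sub$strand == "+"],
                            minus = sub$pos[sub$strand == "-"])
    }
  }
  rl <- if (nrow(tab)) stats::median(tab$width) else NA_real_
  stranded_read_starts(chroms, sample_id = sample_id, read_length = rl,
                       organism = organism, shearing = shearing)
}

.starts_from_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), width = integer()))
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), width = integer()))
  str <- as.character(GenomicRanges::strand(gr))
  stranded <- str %in% c("+", "-")
  if (!any(stranded))
    stop("all ", length(gr), " BED records lack strand; strand is required")
  if (any(!stranded))
    warning(sum(!stranded), " strandless BED record(s) rejected")
  gr <- gr[stranded]
  str <- str[stranded]
  # rtracklayer returns 1-based starts; BED itself is 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)  # exclusive in 0-based
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = ifelse(str == "+", start0, end0 - 1L),
    strand = str,
    width = GenomicRanges::width(gr)
  )
}

.starts_from_bam <- function(path, format, min_mapq) {
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("flag", "mapq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  fl <- S4Vectors::mcols(ga)$flag
  paired <- bitwAnd(fl, 1L) > 0L
  mate2 <- paired & bitwAnd(fl, 128L) > 0L
  if (any(mate2)) {
    warning(sum(mate2), " mate-2 record(s) ignored (single-end semantics)")
    ga <- ga[!mate2]
  }
  mq <- S4Vectors::mcols(ga)$mapq
  keep <- is.na(mq) | mq >= min_mapq
  ga <- ga[keep]
  if (!length(ga))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), width = integer()))
  str <- as.character(GenomicAlignments::strand(ga))
  # GAlignments coordinates are 1-based closed; convert to 0-based
  data.frame(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    pos = ifelse(str == "+",
                 GenomicAlignments::start(ga) - 1L,
                 GenomicAlignments::end(ga) - 1L),
    strand = str,
    width = GenomicAlignments::qwidth(ga)
  )
}

#' Write / read the internal read-start TSV dump
#'
#' Three tab-separated columns (`chrom`, `strand`, `pos`) with `#key=value`
#' header lines carrying sample metadata; round trips exactly.
#'
#' @param starts a [stranded_read_starts()] object.
#' @param path output (input) file path.
#' @return `write_starts_tsv` returns `path` invisibly; `read_starts_tsv`
#'   returns a [stranded_read_starts()] object.
#' @export
write_starts_tsv <- function(starts, path) {
  stopifnot(inherits(starts, "stranded_read_starts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#sample_id=", starts$sample_id),
    paste0("#read_length=", starts$read_length),
    paste0("#organism=", starts$organism),
    paste0("#shearing=", starts$shearing),
    "chrom\tstrand\tpos"), con)
  for (chr in names(starts$chroms)) {
    ch <- starts$chroms[[chr]]
    if (length(ch$plus))
      writeLines(paste(chr, "+", ch$plus, sep = "\t"), con)
    if (length(ch$minus))
      writeLines(paste(chr, "-", ch$minus, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_starts_tsv
#' @export
read_starts_tsv <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  meta <- list(sample_id = "sample", read_length = NA_real_,
               organism = "unknown", shearing = "unknown")
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- data.table::fread(path, skip = length(hdr), header = TRUE,
                           sep = "\t",
                           colClasses = list(character = c("chrom", "strand"),
                                             integer = "pos"))
  chroms <- list()
  if (nrow(tab)) {
    for (chr in unique(tab$chrom)) {
      sub <- tab[tab$chrom == chr, ]
      chroms[[chr]] <- list(plus = sub$pos[sub$strand == "+"],
                            minus = sub$pos[sub$strand == "-"])
    }
  }
  stranded_read_starts(chroms, sample_id = meta$sample_id,
                       read_length = suppressWarnings(as.numeric(meta$read_length)),
                       organism = meta$organism,
                       shearing = match.arg(meta$shearing,
                                            c("unknown", "sonication", "mnase")))
}

#' Load a peak set from BED
#'
#' Reads a 3+ column BED file, drops malformed records (start >= end) with
#' a warning, and merges overlapping intervals so the returned set is
#' sorted and non-overlapping — the form assumed by
#' [jaccard_peak_distance()].
#'
#' @param path BED file path.
#' @param sample_id sample identifier; defaults to the file stem.
#' @return A `peak_set`: a list with `sample_id` and a `GRanges` of merged
#'   intervals (0-based half-open externally; GRanges 1-based internally).
#' @export
load_peaks <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]+$", "", basename(path))
  if (file.size(path) == 0)
    return(peak_set(GenomicRanges::GRanges(), sample_id))
  tab <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (!nrow(tab)) return(peak_set(GenomicRanges::GRanges(), sample_id))
  if (ncol(tab) < 3) stop("BED needs >= 3 columns")
  chrom <- as.character(tab[[1]])
  start0 <- as.integer(tab[[2]])
  end0 <- as.integer(tab[[3]])
  bad <- is.na(start0) | is.na(end0) | start0 >= end0
  if (any(bad)) warning(sum(bad), " malformed BED record(s) rejected")
  gr <- GenomicRanges::GRanges(chrom[!bad],
                               IRanges::IRanges(start0[!bad] + 1L, end0[!bad]))
  peak_set(gr, sample_id)
}

#' Construct a peak set from a GRanges
#'
#' @param gr a `GRanges` of peak intervals.
#' @param sample_id sample identifier.
#' @return A merged (`reduce`d), sorted `peak_set`.
#' @export
peak_set <- function(gr, sample_id = "peaks") {
  stopifnot(methods::is(gr, "GRanges"))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
  structure(list(sample_id = sample_id, intervals = gr), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d merged interval(s)\n",
              x$sample_id, length(x$intervals)))
  invisible(x)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `antibody_target`, `organism`,
#' `cell_line`, `study_id`, `cellular_mechanism`, `shearing`,
#' `replicate_group`, `is_control`. Each sample carries one and only one
#' label per class variable.
#'
#' @param path TSV file path.
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("sample_id", "organism", "shearing", "is_control")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in metadata")
  tab$is_control <- as.logical(tab$is_control)
  tab
}
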