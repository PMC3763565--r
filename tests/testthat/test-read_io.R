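write_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("duplicated BED reads collapse to one position per strand", {
  path <- write_bed(rep("chr1\t100\t136\tr\t0\t+", 3))
  starts <- load_read_starts(path, format = "bed")
  expect_identical(starts$chroms$chr1$plus, 100L)
  expect_identical(unname(n_reads(starts)[["plus"]]), 1L)
})

test_that("minus-strand 5' end is the rightmost aligned base", {
  path <- write_bed("chr1\t100\t136\tr\t0\t-")
  starts <- load_read_starts(path, format = "bed")
  expect_identical(starts$chroms$chr1$minus, 135L)
  expect_length(starts$chroms$chr1$plus, 0)
})

test_that("empty input yields an empty read-start set", {
  path <- withr::local_tempfile(fileext = ".bed")
  file.create(path)
  starts <- load_read_starts(path, format = "bed")
  expect_identical(unname(n_reads(starts)[["total"]]), 0L)
})

test_that("strandless BED records are rejected, fully strandless errors", {
  mixed <- write_bed(c("chr1\t10\t46\tr\t0\t+", "chr1\t50\t86\tr\t0\t."))
  expect_warning(starts <- load_read_starts(mixed, format = "bed"),
                 "strandless")
  expect_identical(unname(n_reads(starts)[["total"]]), 1L)
  bare <- write_bed("chr1\t10\t46")
  expect_error(load_read_starts(bare, format = "bed"), "strand")
})

test_that("SAM parsing skips unmapped/secondary and ignores mate 2", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    # plus-strand primary: pos 101 (1-based) -> 0-based start 100
    "r1\t0\tchr1\t101\t30\t36M\t*\t0\t0\t*\t*",
    # minus-strand primary: pos 201, span 36 -> end0 = 236, 5' = 235
    "r2\t16\tchr1\t201\t30\t36M\t*\t0\t0\t*\t*",
    # unmapped
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    # secondary alignment
    "r4\t256\tchr1\t301\t30\t36M\t*\t0\t0\t*\t*",
    # paired mate 2 (flag 1 + 128 + 0)
    "r5\t129\tchr1\t401\t30\t36M\t*\t0\t0\t*\t*"), sam)
  expect_warning(starts <- load_read_starts(sam, format = "sam"), "mate-2")
  expect_identical(starts$chroms$chr1$plus, 100L)
  expect_identical(starts$chroms$chr1$minus, 235L)
})

test_that("read-start TSV round trips exactly", {
  starts <- starts_of(plus = c(5L, 10L, 500L), minus = c(3L, 99L),
                      sample_id = "rt", organism = "fly",
                      shearing = "mnase")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_starts_tsv(starts, path)
  back <- read_starts_tsv(path)
  expect_identical(back$chroms, starts$chroms)
  expect_identical(back$sample_id, "rt")
  expect_identical(back$organism, "fly")
  expect_identical(back$shearing, "mnase")
})

test_that("loading a file concatenated with itself is idempotent", {
  lines <- c("chr1\t10\t46\ta\t0\t+", "chr2\t20\t56\tb\t0\t-",
             "chr1\t30\t66\tc\t0\t+")
  once <- load_read_starts(write_bed(lines), format = "bed")
  twice <- load_read_starts(write_bed(c(lines, lines)), format = "bed")
  expect_identical(once$chroms, twice$chroms)
})

test_that("peak sets merge overlaps and reject malformed records", {
  merged <- load_peaks(write_bed(c("chr1\t0\t100", "chr1\t50\t150")))
  expect_length(merged$intervals, 1)
  expect_identical(GenomicRanges::start(merged$intervals), 1L)
  expect_identical(GenomicRanges::end(merged$intervals), 150L)

  two <- load_peaks(write_bed(c("chr1\t0\t100", "chr2\t0\t100")))
  expect_length(two$intervals, 2)

  expect_warning(bad <- load_peaks(write_bed(c("chr1\t5\t5", "chr1\t0\t10"))),
                 "malformed")
  expect_length(bad$intervals, 1)

  empty_path <- withr::local_tempfile(fileext = ".bed")
  file.create(empty_path)
  expect_length(load_peaks(empty_path)$intervals, 0)
})

test_that("metadata loader enforces required columns and unique ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\torganism\tshearing\tis_control",
               "s1\thuman\tsonication\tFALSE",
               "s2\thuman\tsonication\tTRUE"), path)
  meta <- read_sample_metadata(path)
  expect_identical(meta$is_control, c(FALSE, TRUE))
  writeLines(c("sample_id\torganism", "s1\thuman"), path)
  expect_error(read_sample_metadata(path), "missing column")
})

test_that("constructor validates and sorts positions", {
  s <- starts_of(plus = c(30L, 10L, 10L))
  expect_identical(s$chroms$chr1$plus, c(10L, 30L))
  expect_error(starts_of(plus = -1L), "non-negative")
})
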