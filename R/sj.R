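# SJ coverage container: per-experiment raw (pre-mask) per-position counts
# for every junction and intron, cached so alignments are parsed only once.

SJ_VERSION <- 1L

#' Write an SJ coverage file
#'
#' Loss-free text container of per-position coverage for one experiment:
#' a versioned header, one row per edge with its position counts, and an
#' explicit end marker so truncation is detectable.
#'
#' @param coverage named list of `edge_coverage` objects (raw, pre-mask),
#'   keyed by `chrom:type:start:end`.
#' @param path output file.
#' @param experiment experiment identifier stored in the header.
#' @param read_length nominal read length used to compute the coverage.
#' @return `path`, invisibly.
#' @export
write_sj <- function(coverage, path, experiment, read_length = 100L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sj_version: %d", SJ_VERSION),
               sprintf("#experiment: %s", experiment),
               sprintf("#read_length: %d", read_length),
               paste("chrom", "type", "start", "end", "num_positions",
                     "counts", sep = "\t")), con)
  keys <- sort(names(coverage))
  for (k in keys) {
    cv <- coverage[[k]]
    writeLines(paste(cv$edge$chrom, cv$edge$type, cv$edge$start, cv$edge$end,
                     cv$num_positions,
                     paste(format(cv$position_counts, trim = TRUE,
                                  scientific = FALSE), collapse = ","),
                     sep = "\t"), con)
  }
  writeLines("#end", con)
  invisible(path)
}

#' Read an SJ coverage file
#'
#' @param path file written by [write_sj()].
#' @return list with `experiment`, `read_length` and `coverage` (named list
#'   of `edge_coverage`, keyed `chrom:type:start:end`).
#' @export
read_sj <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5)
    stop(sprintf("SJ file '%s' is truncated or empty", path))
  ver <- as.integer(sub("#sj_version: *", "", lines[1]))
  if (is.na(ver) || ver != SJ_VERSION)
    stop(sprintf("SJ version mismatch: file has '%s', reader expects %d",
                 lines[1], SJ_VERSION))
  if (lines[length(lines)] != "#end")
    stop(sprintf("SJ file '%s' is truncated (missing end marker)", path))
  experiment <- sub("#experiment: *", "", lines[2])
  read_length <- as.integer(sub("#read_length: *", "", lines[3]))
  body <- lines[seq(5, length(lines) - 1)]
  coverage <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    counts <- as.numeric(strsplit(f[6], ",", fixed = TRUE)[[1]])
    if (length(counts) != as.integer(f[5]))
      stop(sprintf("SJ file '%s': corrupt row for %s:%s-%s", path,
                   f[1], f[3], f[4]))
    cv <- edge_coverage(list(chrom = f[1], type = f[2],
                             start = as.integer(f[3]), end = as.integer(f[4])),
                        counts)
    coverage[[sprintf("%s:%s:%s:%s", f[1], f[2], f[3], f[4])]] <- cv
  }
  list(experiment = experiment, read_length = read_length,
       coverage = coverage)
}

sj_key <- function(chrom, type, start, end) {
  sprintf("%s:%s:%d:%d", chrom, type, start, end)
}
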