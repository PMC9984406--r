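# Per-position junction/intron coverage, outlier masking, bootstrap rates.

#' Per-position coverage container
#'
#' @param edge list with `type`, `start`, `end` (and optionally `chrom`).
#' @param position_counts non-negative counts, one per possible read
#'   placement.
#' @param mask logical vector, `TRUE` = position excluded downstream.
#' @return object of class `edge_coverage`.
#' @export
edge_coverage <- function(edge, position_counts,
                          mask = rep(FALSE, length(position_counts))) {
  stopifnot(length(mask) == length(position_counts),
            all(position_counts >= 0))
  structure(list(edge = edge, position_counts = as.numeric(position_counts),
                 num_positions = length(position_counts),
                 mask = as.logical(mask)),
            class = "edge_coverage")
}

#' @export
print.edge_coverage <- function(x, ...) {
  cat(sprintf("edge_coverage %s:%d-%d  %d positions, %d masked, total %.3g\n",
              x$edge$type, x$edge$start, x$edge$end, x$num_positions,
              sum(x$mask), sum(x$position_counts[!x$mask])))
  invisible(x)
}

#' Read split-aware alignments from SAM/BAM
#'
#' Plain-text SAM is converted to BAM on the fly.  All split gaps are
#' extracted in a single pass, so downstream per-edge coverage is a cheap
#' table subset.
#'
#' @param path SAM or BAM file.
#' @return object of class `alignments`: `reads` (one row per read: `chrom`,
#'   `pos` 1-based, `ref_end` 1-based inclusive, `cigar`) and `gaps` (one
#'   row per split: `read`, `chrom`, `start`, `end` 0-based half-open,
#'   `offset` = read bases before the split).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  aln <- GenomicAlignments::readGAlignments(bam)
  reads <- data.frame(
    chrom = as.character(GenomicAlignments::seqnames(aln)),
    pos = GenomicAlignments::start(aln),
    ref_end = GenomicAlignments::end(aln),
    cigar = GenomicAlignments::cigar(aln),
    stringsAsFactors = FALSE
  )
  structure(list(reads = reads, gaps = extract_gaps(reads)),
            class = "alignments")
}

# one row per N operation across all reads, with the read offset at the split
extract_gaps <- function(reads) {
  empty <- data.frame(read = integer(), chrom = character(),
                      start = integer(), end = integer(), offset = integer())
  has_n <- grepl("N", reads$cigar, fixed = TRUE)
  if (!any(has_n)) return(empty)
  idx <- which(has_n)
  ops_all <- GenomicAlignments::explodeCigarOps(reads$cigar[idx])
  lens_all <- GenomicAlignments::explodeCigarOpLengths(reads$cigar[idx])
  out <- vector("list", length(idx))
  for (t in seq_along(idx)) {
    ops <- ops_all[[t]]; lens <- lens_all[[t]]
    ref <- reads$pos[idx[t]] - 1L  # 0-based
    qoff <- 0L
    rows <- NULL
    for (i in seq_along(ops)) {
      op <- ops[i]; n <- lens[i]
      if (op == "N") {
        rows <- rbind(rows, data.frame(read = idx[t],
                                       chrom = reads$chrom[idx[t]],
                                       start = ref, end = ref + n,
                                       offset = qoff))
        ref <- ref + n
      } else if (op %in% c("M", "=", "X")) {
        ref <- ref + n; qoff <- qoff + n
      } else if (op == "D") {
        ref <- ref + n
      } else if (op %in% c("I", "S")) {
        qoff <- qoff + n
      }
    }
    out[[t]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

# accept a plain data.frame of reads for backward-compatible callers
as_alignments <- function(x) {
  if (inherits(x, "alignments")) return(x)
  reads <- as.data.frame(x)
  if (is.null(reads$ref_end)) {
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
    reads$ref_end <- reads$pos + w - 1L
  }
  structure(list(reads = reads, gaps = extract_gaps(reads)),
            class = "alignments")
}

#' Junction coverage from split alignments
#'
#' A read supports a junction when one of its alignment gaps matches the
#' junction's excised interval; the junction "position" of the read is the
#' read offset at which the split occurs (1 .. L-1).
#'
#' @param alignments data.frame from [read_alignments()].
#' @param junction list with `chrom`, `start`, `end` (0-based; `start` =
#'   first intronic base).
#' @param read_length nominal read length L; `num_positions = L - 1`.
#' @return an `edge_coverage` with `L - 1` positions.
#' @export
junction_coverage <- function(alignments, junction, read_length = 100L) {
  alignments <- as_alignments(alignments)
  np <- read_length - 1L
  counts <- numeric(np)
  g <- alignments$gaps
  hit <- g$chrom == junction$chrom & g$start == junction$start &
    g$end == junction$end
  p <- g$offset[hit]
  if (any(p > np)) {
    warning("read longer than nominal length; split offset clipped")
    p[p > np] <- np
  }
  p <- p[p >= 1]
  if (length(p)) counts <- tabulate(p, nbins = np)
  edge_coverage(list(chrom = junction$chrom, type = "junction",
                     start = junction$start, end = junction$end), counts)
}

#' Intron coverage from contiguous alignments
#'
#' The exon/intron boundary at the intron start is treated as a zero-length
#' junction, contributing `L - 1` junction-like raw positions; reads starting
#' inside the intron contribute one raw position per genomic offset
#' `1 .. intron_length`.  Raw positions are then aggregated into `L - 1`
#' contiguous bins of near-equal size (sizes differ by at most one), each
#' reduced bin carrying the mean of its raw member counts.
#'
#' @param alignments data.frame from [read_alignments()].
#' @param intron list with `chrom`, `start`, `end` (0-based half-open).
#' @param read_length nominal read length L.
#' @return an `edge_coverage` with `L - 1` reduced positions (or the raw
#'   positions unchanged when there are fewer raw positions than bins).
#' @export
intron_coverage <- function(alignments, intron, read_length = 100L) {
  alignments <- as_alignments(alignments)
  np <- read_length - 1L
  ilen <- intron$end - intron$start
  raw <- numeric(np + ilen)
  istart1 <- intron$start + 1L  # 1-based first intronic base
  r <- alignments$reads
  cand <- which(r$chrom == intron$chrom & r$ref_end >= istart1 &
                  r$pos <= intron$end)
  if (length(cand)) {
    # exclude reads with a split inside the intron
    g <- alignments$gaps
    gapped <- unique(g$read[g$chrom == intron$chrom & g$start < intron$end &
                              g$end > intron$start])
    cand <- setdiff(cand, gapped)
  }
  for (k in cand) {
    s <- r$pos[k]
    if (s < istart1) {
      # read contains the exon/intron boundary: junction-like position
      p <- istart1 - s
      if (p >= 1 && p <= np) raw[p] <- raw[p] + 1
    } else {
      off <- s - istart1 + 1L  # genomic offset 1..intron_length
      if (off >= 1 && off <= ilen) raw[np + off] <- raw[np + off] + 1
    }
  }
  reduce_intron_positions(raw, np, intron)
}

# aggregate raw intron positions into `np` near-equal contiguous bins
reduce_intron_positions <- function(raw, np, intron) {
  nraw <- length(raw)
  if (nraw < np) {
    return(edge_coverage(list(chrom = intron$chrom, type = "intron",
                              start = intron$start, end = intron$end), raw))
  }
  bins <- intron_bin_index(nraw, np)
  counts <- as.numeric(tapply(raw, bins, mean))
  edge_coverage(list(chrom = intron$chrom, type = "intron",
                     start = intron$start, end = intron$end), counts)
}

# partition 1..nraw into np contiguous bins with sizes differing by <= 1
intron_bin_index <- function(nraw, np) {
  base <- nraw %/% np
  extra <- nraw %% np
  sizes <- rep(base, np) + c(rep(1L, extra), rep(0L, np - extra))
  rep(seq_len(np), times = sizes)
}

#' Mask zero and outlier positions
#'
#' Zero-coverage positions are always masked.  For each nonzero position the
#' Poisson rate is estimated from the other nonzero positions; the position
#' is masked when its right-tail probability P(X >= count) falls below
#' `alpha`.  All tests use the original counts (one simultaneous pass).
#'
#' @param cov an `edge_coverage`.
#' @param alpha right-tail significance threshold (default 1e-7).
#' @return the `edge_coverage` with its mask updated.
#' @export
mask_outliers <- function(cov, alpha = 1e-7) {
  x <- cov$position_counts
  mask <- x == 0
  nz <- which(x > 0)
  if (length(nz) >= 2) {
    for (i in nz) {
      lambda <- mean(x[setdiff(nz, i)])
      p <- stats::ppois(x[i] - 1, lambda, lower.tail = FALSE)
      if (p < alpha) mask[i] <- TRUE
    }
  }
  cov$mask <- mask
  cov
}

#' Bootstrap replicates of an edge's total read rate
#'
#' Each replicate sums n draws with replacement from the n unmasked position
#' counts.  When the unmasked counts are underdispersed (unbiased sample
#' variance below the sample mean) the nonparametric draw is replaced by
#' Poisson sampling around the observed total rate.
#'
#' @param cov an `edge_coverage` with its mask applied.
#' @param M number of replicates (default 30).
#' @param seed integer seed; replicates are reproducible given the seed.
#'   `NULL` draws from the current RNG stream (callers that seed once for a
#'   whole pipeline).
#' @return object of class `bootstrap_coverage` with `replicates` (length M),
#'   `total_rate`, `n_positions` and the branch used.
#' @export
bootstrap_rates <- function(cov, M = 30L, seed = NULL) {
  x <- cov$position_counts[!cov$mask]
  n <- length(x)
  total <- sum(x)
  if (n == 0) {
    reps <- numeric(M)
    branch <- "empty"
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (n == 1 || var(x) < mean(x)) {
      reps <- stats::rpois(M, total)
      branch <- "poisson"
    } else {
      reps <- vapply(seq_len(M),
                     function(i) sum(sample(x, n, replace = TRUE)),
                     numeric(1))
      branch <- "nonparametric"
    }
  }
  structure(list(edge = cov$edge, replicates = reps, M = M, seed = seed,
                 total_rate = total, n_positions = n, branch = branch),
            class = "bootstrap_coverage")
}

#' @export
print.bootstrap_coverage <- function(x, ...) {
  cat(sprintf("bootstrap_coverage %s:%d-%d  M=%d (%s), total rate %.3g\n",
              x$edge$type, x$edge$start, x$edge$end, x$M, x$branch,
              x$total_rate))
  invisible(x)
}
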