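# Synthetic annotation and coverage generator with known ground truth.
#
# Coverage-level simulation: per-edge read totals are Poisson around
# depth x (relative isoform abundance of the edge), spread uniformly over
# read positions.  This exercises every downstream contract (builder,
# quantifiers, HET, modulizer) without an aligner; it does not emulate
# sequence-level effects (errors, positional bias, fragment lengths).

#' Define a toy gene
#'
#' A gene is a set of isoforms, each a matrix of exon intervals (0-based
#' half-open, one row per exon), with a relative abundance per isoform.  The
#' planted event composition records which AS event types the gene is built
#' to contain.
#'
#' @param gene_id,chrom,strand gene identity.
#' @param isoforms list of 2-column matrices (`start`, `end` per exon row).
#' @param abundance positive relative abundances, one per isoform.
#' @param planted named integer vector of planted AS event types.
#' @return object of class `toy_gene`.
#' @export
toy_gene <- function(gene_id, chrom, strand, isoforms, abundance,
                     planted = integer(0)) {
  stopifnot(length(isoforms) == length(abundance), all(abundance > 0))
  for (iso in isoforms) {
    stopifnot(ncol(iso) == 2, all(iso[, 1] < iso[, 2]))
    if (nrow(iso) > 1) stopifnot(all(iso[-nrow(iso), 2] < iso[-1, 1]))
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 isoforms = isoforms,
                 abundance = abundance / sum(abundance),
                 planted = planted),
            class = "toy_gene")
}

# ---------------------------------------------------------------------------
# Archetype genes.  Layouts use generous exon sizes so junction reads of
# length <= 150 fit comfortably.

exon_mat <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

#' Toy gene archetypes for each planted AS event type
#'
#' Each constructor returns a `toy_gene` whose parsed splicegraph contains
#' exactly the named AS event; `psi` sets the inclusion level of the
#' alternative path.
#'
#' @param gene_id,chrom,strand gene identity.
#' @param offset genomic offset added to all coordinates.
#' @param psi inclusion level of the alternative (inclusion) isoform.
#' @return a `toy_gene`.
#' @name toy_archetypes
NULL

#' @rdname toy_archetypes
#' @export
toy_gene_ce <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                        psi = 0.5) {
  e1 <- c(0, 400); e2 <- c(1000, 1400); e3 <- c(2000, 2400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(e1, e2, e3) + offset,
                           exon_mat(e1, e3) + offset),
           abundance = c(psi, 1 - psi),
           planted = c(CE = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_ir <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                        psi = 0.5) {
  e1 <- c(0, 400); e2 <- c(1000, 1400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(c(0, 1400)) + offset,   # retained
                           exon_mat(e1, e2) + offset),       # spliced
           abundance = c(psi, 1 - psi),
           planted = c(IR = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_mxe <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                         psi = 0.5) {
  e1 <- c(0, 400); ma <- c(1000, 1400); mb <- c(2000, 2400)
  e4 <- c(3000, 3400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(e1, ma, e4) + offset,
                           exon_mat(e1, mb, e4) + offset),
           abundance = c(psi, 1 - psi),
           planted = c(MXE = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_a3ss <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                          psi = 0.5) {
  e1 <- c(0, 400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(e1, c(1000, 1600)) + offset,  # proximal
                           exon_mat(e1, c(1200, 1600)) + offset), # distal
           abundance = c(psi, 1 - psi),
           planted = c(A3SS = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_a5ss <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                          psi = 0.5) {
  e2 <- c(1000, 1400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(c(0, 600), e2) + offset,
                           exon_mat(c(0, 400), e2) + offset),
           abundance = c(psi, 1 - psi),
           planted = c(A5SS = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_tce <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                         psi = 0.5) {
  e1 <- c(0, 400); c1 <- c(1000, 1400); c2 <- c(2000, 2400)
  e4 <- c(3000, 3400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(e1, c1, c2, e4) + offset,
                           exon_mat(e1, e4) + offset),
           abundance = c(psi, 1 - psi),
           planted = c(TCE = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_afe <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                         psi = 0.5) {
  f1 <- c(0, 400); f2 <- c(1000, 1400); e3 <- c(2000, 2400)
  e4 <- c(3000, 3400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(f1, e3, e4) + offset,
                           exon_mat(f2, e3, e4) + offset),
           abundance = c(psi, 1 - psi),
           planted = c(AFE = 1L))
}

#' @rdname toy_archetypes
#' @export
toy_gene_ale <- function(gene_id, chrom = "chrT", strand = "+", offset = 0,
                         psi = 0.5) {
  e1 <- c(0, 400); e2 <- c(1000, 1400); l1 <- c(2000, 2400)
  l2 <- c(3000, 3400)
  toy_gene(gene_id, chrom, strand,
           isoforms = list(exon_mat(e1, e2, l1) + offset,
                           exon_mat(e1, e2, l2) + offset),
           abundance = c(psi, 1 - psi),
           planted = c(ALE = 1L))
}

#' Standard 20-gene mixed panel
#'
#' Five cassette-exon genes, three intron-retention genes, and two each of
#' MXE, A3SS, A5SS, TCE, AFE and ALE, laid out on one toy chromosome.
#'
#' @param psi inclusion levels recycled across genes (default 0.5).
#' @return list of `toy_gene`.
#' @export
toy_gene_panel <- function(psi = 0.5) {
  makers <- c(rep(list(toy_gene_ce), 5), rep(list(toy_gene_ir), 3),
              rep(list(toy_gene_mxe), 2), rep(list(toy_gene_a3ss), 2),
              rep(list(toy_gene_a5ss), 2), rep(list(toy_gene_tce), 2),
              rep(list(toy_gene_afe), 2), rep(list(toy_gene_ale), 2))
  psi <- rep_len(psi, length(makers))
  out <- list()
  for (k in seq_along(makers)) {
    out[[k]] <- makers[[k]](sprintf("g%02d", k), offset = (k - 1) * 10000,
                            psi = psi[k])
  }
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

# ---------------------------------------------------------------------------
# GFF3 emission and ground truth

#' Write a GFF3 annotation for toy genes
#'
#' Emits a well-formed gene/mRNA/exon hierarchy whose [parse_annotation()]
#' reproduces each gene's intended splicegraph, and computes the ground-truth
#' tables: per-edge relative abundance and per-LSV-edge true PSI.
#'
#' @param genes list of `toy_gene`.
#' @param path output GFF3 path.
#' @return list with `path`, `splicegraphs` (parsed back), `edges`
#'   (data.frame gene_id/chrom/type/start/end/rel_abundance) and `truth_psi`
#'   (data.frame lsv_id/type/start/end/psi_true).
#' @export
make_annotation <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (g in genes) {
    b <- range(unlist(lapply(g$isoforms, function(m) c(m[, 1], m[, 2]))))
    lines <- c(lines, sprintf(
      "%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom, b[1] + 1L, b[2],
      g$strand, g$gene_id))
    for (t in seq_along(g$isoforms)) {
      tid <- sprintf("%s.t%d", g$gene_id, t)
      iso <- g$isoforms[[t]]
      lines <- c(lines, sprintf(
        "%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", g$chrom,
        min(iso[, 1]) + 1L, max(iso[, 2]), g$strand, tid, g$gene_id))
      for (e in seq_len(nrow(iso))) {
        lines <- c(lines, sprintf(
          "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s", g$chrom,
          iso[e, 1] + 1L, iso[e, 2], g$strand, tid, e, tid))
      }
    }
  }
  writeLines(lines, path)
  sgs <- parse_annotation(path)
  edges <- NULL
  truth <- NULL
  for (g in genes) {
    sg <- sgs[[g$gene_id]]
    ed <- sg_edges(sg)
    rel <- vapply(seq_len(nrow(ed)), function(k) {
      sum(g$abundance[vapply(g$isoforms, isoform_contains_edge,
                             logical(1), type = ed$type[k],
                             s = ed$start[k], e = ed$end[k])])
    }, numeric(1))
    edges <- rbind(edges, data.frame(
      gene_id = g$gene_id, chrom = g$chrom, type = ed$type,
      start = ed$start, end = ed$end, rel_abundance = rel))
    for (lsv in define_lsvs(sg)) {
      ab <- vapply(seq_len(nrow(lsv$edges)), function(k) {
        rel[ed$type == lsv$edges$type[k] & ed$start == lsv$edges$start[k] &
              ed$end == lsv$edges$end[k]]
      }, numeric(1))
      if (sum(ab) == 0) next
      truth <- rbind(truth, data.frame(
        gene_id = g$gene_id, lsv_id = lsv$lsv_id, type = lsv$edges$type,
        start = lsv$edges$start, end = lsv$edges$end,
        psi_true = ab / sum(ab)))
    }
  }
  list(path = path, splicegraphs = sgs, edges = edges, truth_psi = truth)
}

# does an isoform (exon interval matrix) use a junction / cover an intron?
isoform_contains_edge <- function(iso, type, s, e) {
  if (type == "junction") {
    n <- nrow(iso)
    if (n < 2) return(FALSE)
    any(iso[-n, 2] == s & iso[-1, 1] == e)
  } else {
    any(iso[, 1] <= s & e <= iso[, 2])
  }
}

# ---------------------------------------------------------------------------
# Sample simulation

#' Sample specification
#'
#' @param depth expected reads per edge at full inclusion.
#' @param read_length nominal read length L.
#' @param dispersion between-sample PSI dispersion in \[0, 1): 0 simulates
#'   replicates; s > 0 draws each edge's per-sample inclusion from a Beta
#'   with mean at the true value and variance `s^2 * mu * (1 - mu)`.
#' @param seed integer seed.
#' @return list of class `sample_spec`.
#' @export
sample_spec <- function(depth = 100, read_length = 100L, dispersion = 0,
                        seed = 1L) {
  stopifnot(depth > 0, dispersion >= 0, dispersion < 1)
  structure(list(depth = depth, read_length = read_length,
                 dispersion = dispersion, seed = seed),
            class = "sample_spec")
}

#' Simulate per-position coverage for one experiment
#'
#' For each edge of the annotation's ground truth, the read total is
#' Poisson(depth x a) where a is the edge's (possibly dispersed) relative
#' abundance, and reads are spread uniformly over the `L - 1` positions.
#'
#' @param truth result of [make_annotation()].
#' @param spec a [sample_spec()].
#' @param experiment experiment identifier.
#' @return list as returned by [read_sj()]: `experiment`, `read_length`,
#'   `coverage`.
#' @export
simulate_sample <- function(truth, spec, experiment = "sim") {
  set.seed(spec$seed)
  L <- spec$read_length
  np <- L - 1L
  coverage <- list()
  ed <- truth$edges
  for (k in seq_len(nrow(ed))) {
    mu <- ed$rel_abundance[k]
    a <- mu
    if (spec$dispersion > 0 && mu > 0 && mu < 1) {
      nu <- 1 / spec$dispersion^2 - 1
      a <- stats::rbeta(1, mu * nu, (1 - mu) * nu)
    }
    reads <- stats::rpois(1, spec$depth * a)
    counts <- numeric(np)
    if (reads > 0) {
      pos <- sample.int(np, reads, replace = TRUE)
      counts <- tabulate(pos, nbins = np)
    }
    cv <- edge_coverage(list(chrom = ed$chrom[k], type = ed$type[k],
                             start = ed$start[k], end = ed$end[k]), counts)
    coverage[[sj_key(ed$chrom[k], ed$type[k], ed$start[k], ed$end[k])]] <- cv
  }
  list(experiment = experiment, read_length = L, coverage = coverage)
}

#' Emit a minimal SAM file realizing simulated coverage
#'
#' Junction reads get a split CIGAR (`pM gN (L-p)M`) whose gap is the
#' junction's excised interval; intron reads are contiguous `LM` alignments
#' placed so the coverage module recovers the simulated placements.  Useful
#' for exercising the alignment-parsing path on the same ground truth.
#'
#' @param sim result of [simulate_sample()] (junction coverage is realized
#'   exactly; intron coverage is realized through boundary-spanning reads).
#' @param truth result of [make_annotation()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, truth, path) {
  L <- sim$read_length
  chroms <- unique(truth$edges$chrom)
  maxend <- vapply(chroms, function(ch)
    max(truth$edges$end[truth$edges$chrom == ch]) + 10L * L, integer(1))
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chroms, maxend))
  seq_str <- strrep("A", L)
  blocks <- vector("list", length(sim$coverage))
  rid <- 0L
  for (b in seq_along(sim$coverage)) {
    cv <- sim$coverage[[b]]
    e <- cv$edge
    nz <- which(cv$position_counts > 0)
    if (length(nz) == 0) next
    p <- rep(nz, times = cv$position_counts[nz])
    start1 <- e$start - p + 1L  # 1-based read start
    cigar <- if (e$type == "junction")
      sprintf("%dM%dN%dM", p, e$end - e$start, L - p)
    else sprintf("%dM", L)  # boundary-spanning contiguous read
    blocks[[b]] <- sprintf("r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                           rid + seq_along(p), e$chrom, start1, cigar,
                           seq_str)
    rid <- rid + length(p)
  }
  writeLines(c(lines, unlist(blocks)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# LSV-level simulation shortcut (two-edge LSVs) used for calibration and
# power studies: same coverage model as simulate_sample but bypassing the
# annotation, so hundreds of null/changing LSVs are cheap to draw.

#' Simulate per-experiment LSV data for two groups
#'
#' Each experiment of a group draws its own inclusion level around the group
#' mean (Beta with variance `dispersion^2 * mu * (1 - mu)`; a point mass when
#' `dispersion = 0`), realizes Poisson read totals per edge spread uniformly
#' over read positions, and runs the standard masking + bootstrap path.
#'
#' @param psi1,psi2 group mean inclusion of edge 1 (edge 2 gets the
#'   complement).
#' @param n_per_group experiments per group.
#' @param depth expected reads for the LSV.
#' @param dispersion between-sample PSI dispersion.
#' @param M bootstrap replicates.
#' @param read_length nominal read length.
#' @param seed integer seed.
#' @return list with elements `g1`, `g2`: lists (one per experiment) of
#'   `boot` (M x 2), `raw_reads`, `positions` — the input shape expected by
#'   [group_psi()] and the HET pipeline.
#' @export
simulate_lsv_groups <- function(psi1, psi2 = psi1, n_per_group = 10L,
                                depth = 100, dispersion = 0, M = 30L,
                                read_length = 100L, seed = 1L) {
  set.seed(seed)
  draw_group <- function(mu) {
    lapply(seq_len(n_per_group), function(i) {
      p <- mu
      if (dispersion > 0 && mu > 0 && mu < 1) {
        nu <- 1 / dispersion^2 - 1
        p <- stats::rbeta(1, mu * nu, (1 - mu) * nu)
      }
      np <- read_length - 1L
      boot <- matrix(0, M, 2)
      raw_reads <- 0; positions <- 0L
      for (j in 1:2) {
        pe <- if (j == 1) p else 1 - p
        reads <- stats::rpois(1, depth * pe)
        counts <- numeric(np)
        if (reads > 0) counts <- tabulate(sample.int(np, reads,
                                                     replace = TRUE),
                                          nbins = np)
        cv <- edge_coverage(list(chrom = "sim", type = "junction",
                                 start = j, end = j + 1L), counts)
        raw_reads <- raw_reads + sum(counts)
        positions <- positions + sum(counts > 0)
        cv <- mask_outliers(cv)
        boot[, j] <- bootstrap_rates(cv, M)$replicates
      }
      list(boot = boot, raw_reads = raw_reads, positions = positions)
    })
  }
  list(g1 = draw_group(psi1), g2 = draw_group(psi2))
}
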