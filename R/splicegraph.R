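#' @importFrom stats median quantile rbinom rpois runif setNames var
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end) for exons and
# retained introns.  A junction spans the excised interval: `start` is the
# first intronic base (== donor exon end) and `end` is the first base of the
# acceptor exon.  GFF3 (1-based inclusive) is converted at the boundary.

#' Construct a splicegraph
#'
#' A splicegraph models one gene as non-overlapping exons (vertices) connected
#' by junctions and retained introns (edges).  Coordinates are 0-based
#' half-open on the forward genomic strand; source/target orientation is
#' resolved by strand only when LSVs are defined.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end`, `annotated`,
#'   `denovo_extended`.
#' @param junctions data.frame with columns `start`, `end`, `annotated`,
#'   `simplified`.
#' @param introns data.frame with the same columns as `junctions`.
#' @return An object of class `splicegraph`.
#' @export
splicegraph <- function(gene_id, chrom, strand, exons = NULL, junctions = NULL,
                        introns = NULL) {
  stopifnot(strand %in% c("+", "-"))
  sg <- structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand,
      exons = normalize_exon_df(exons),
      junctions = normalize_edge_df(junctions),
      introns = normalize_edge_df(introns)
    ),
    class = "splicegraph"
  )
  sort_splicegraph(sg)
}

normalize_exon_df <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      annotated = logical(), denovo_extended = logical()))
  }
  df <- as.data.frame(df)
  if (is.null(df$annotated)) df$annotated <- TRUE
  if (is.null(df$denovo_extended)) df$denovo_extended <- FALSE
  df[, c("start", "end", "annotated", "denovo_extended")]
}

normalize_edge_df <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      annotated = logical(), simplified = logical()))
  }
  df <- as.data.frame(df)
  if (is.null(df$annotated)) df$annotated <- TRUE
  if (is.null(df$simplified)) df$simplified <- FALSE
  df[, c("start", "end", "annotated", "simplified")]
}

sort_splicegraph <- function(sg) {
  for (slot in c("exons", "junctions", "introns")) {
    df <- sg[[slot]]
    o <- order(df$start, df$end)
    sg[[slot]] <- df[o, , drop = FALSE]
    rownames(sg[[slot]]) <- NULL
  }
  sg
}

#' @export
print.splicegraph <- function(x, ...) {
  cat(sprintf("splicegraph %s (%s%s) %d exons, %d junctions, %d introns\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              nrow(x$junctions), nrow(x$introns)))
  invisible(x)
}

#' Gene boundaries of a splicegraph
#' @param sg a `splicegraph`.
#' @return integer vector `c(start, end)` (0-based half-open).
#' @export
sg_boundaries <- function(sg) {
  if (nrow(sg$exons) == 0) return(c(NA_integer_, NA_integer_))
  c(min(sg$exons$start), max(sg$exons$end))
}

# index of the exon whose interval contains genomic position `pos`
# (0-based base position), or NA
exon_containing <- function(sg, pos) {
  hit <- which(sg$exons$start <= pos & pos < sg$exons$end)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# exon index on the donor side of a junction starting at `start`
# (donor exon must contain the base just before the intron)
donor_exon <- function(sg, start) exon_containing(sg, start - 1L)
# exon on the acceptor side (contains the first exonic base after the intron)
acceptor_exon <- function(sg, end) exon_containing(sg, end)

edge_key <- function(type, start, end) sprintf("%s:%d:%d", type, start, end)

# all edges of a splicegraph as one data.frame with a `type` column
sg_edges <- function(sg, include_simplified = TRUE) {
  j <- sg$junctions
  i <- sg$introns
  out <- rbind(
    if (nrow(j)) cbind(type = "junction", j) else NULL,
    if (nrow(i)) cbind(type = "intron", i) else NULL
  )
  if (is.null(out)) {
    out <- data.frame(type = character(), start = integer(), end = integer(),
                      annotated = logical(), simplified = logical())
  }
  if (!include_simplified) out <- out[!out$simplified, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate splicegraph invariants
#'
#' Checks that exons are sorted and pairwise non-overlapping, that every edge
#' has `start < end`, and that every non-simplified junction connects two
#' different exons of the gene.
#'
#' @param sg a `splicegraph`.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_splicegraph <- function(sg) {
  ex <- sg$exons
  if (nrow(ex)) {
    if (any(ex$start >= ex$end))
      stop(sprintf("gene %s: exon with start >= end", sg$gene_id))
    if (is.unsorted(ex$start))
      stop(sprintf("gene %s: exons not sorted", sg$gene_id))
    if (nrow(ex) > 1 && any(ex$end[-nrow(ex)] > ex$start[-1]))
      stop(sprintf("gene %s: overlapping exons", sg$gene_id))
  }
  for (slot in c("junctions", "introns")) {
    df <- sg[[slot]]
    if (nrow(df) && any(df$start >= df$end))
      stop(sprintf("gene %s: %s with start >= end", sg$gene_id, slot))
  }
  j <- sg$junctions
  if (nrow(j)) {
    for (k in seq_len(nrow(j))) {
      if (j$simplified[k]) next
      de <- donor_exon(sg, j$start[k])
      ae <- acceptor_exon(sg, j$end[k])
      if (is.na(de) || is.na(ae) || de == ae)
        stop(sprintf("gene %s: junction %d-%d does not connect two exons",
                     sg$gene_id, j$start[k], j$end[k]))
    }
  }
  i <- sg$introns
  if (nrow(i)) {
    for (k in seq_len(nrow(i))) {
      left <- which(sg$exons$end == i$start[k])
      right <- which(sg$exons$start == i$end[k])
      if (length(left) != 1 || length(right) != 1)
        stop(sprintf("gene %s: intron %d-%d not between adjacent exons",
                     sg$gene_id, i$start[k], i$end[k]))
      if (any(sg$exons$start < i$end[k] & sg$exons$end > i$start[k]))
        stop(sprintf("gene %s: exon overlaps intron %d-%d",
                     sg$gene_id, i$start[k], i$end[k]))
    }
  }
  invisible(TRUE)
}

#' Parse a GFF3 annotation into splicegraphs
#'
#' Builds, for each gene, the minimal splicegraph containing every
#' transcript's exons and junctions.  Overlapping transcript exons are merged;
#' wherever a transcript exon spans the excised interval of another
#' transcript's junction, the spanning exon is split and an annotated retained
#' intron is recorded, so that every junction starts and ends in different
#' exons.
#'
#' @param gff3_path path to a GFF3 file with a gene/transcript/exon hierarchy.
#' @return named list of `splicegraph` objects, one per gene.
#' @export
parse_annotation <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  typ <- tolower(as.character(gr$type))
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList

  is_gene <- typ == "gene"
  is_tx <- typ %in% c("mrna", "transcript")
  is_exon <- typ == "exon"

  gene_ids <- ids[is_gene]
  gene_meta <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE
  )

  # transcript -> gene
  tx_idx <- which(is_tx)
  tx2gene <- character(0)
  for (k in tx_idx) {
    par <- as.character(parents[[k]])
    if (length(par) != 1 || !(par %in% gene_ids))
      stop(sprintf("malformed hierarchy: transcript '%s' has no gene parent",
                   ids[k]))
    tx2gene[ids[k]] <- par
  }

  # exon -> transcript(s)
  ex_idx <- which(is_exon)
  tx_exons <- list()  # tx id -> data.frame(start, end) 0-based half-open
  for (k in ex_idx) {
    par <- as.character(parents[[k]])
    if (length(par) == 0)
      stop(sprintf("malformed hierarchy: exon record %d has no Parent", k))
    for (p in par) {
      if (!(p %in% names(tx2gene)))
        stop(sprintf("malformed hierarchy: exon record %d names unknown transcript '%s'",
                     k, p))
      tx_exons[[p]] <- rbind(
        tx_exons[[p]],
        data.frame(start = GenomicRanges::start(gr)[k] - 1L,
                   end = GenomicRanges::end(gr)[k])
      )
    }
  }

  out <- list()
  for (g in seq_len(nrow(gene_meta))) {
    gid <- gene_meta$gene_id[g]
    txs <- names(tx2gene)[tx2gene == gid]
    exon_sets <- lapply(txs, function(t) {
      df <- tx_exons[[t]]
      if (is.null(df)) return(NULL)
      df[order(df$start), , drop = FALSE]
    })
    exon_sets <- Filter(Negate(is.null), exon_sets)
    if (length(exon_sets) == 0) {
      warning(sprintf("gene %s has no exons; skipped", gid))
      next
    }
    sg <- build_annotated_sg(gid, gene_meta$chrom[g], gene_meta$strand[g],
                             exon_sets)
    out[[gid]] <- sg
  }
  out
}

# Assemble one gene's splicegraph from per-transcript exon tables.
build_annotated_sg <- function(gene_id, chrom, strand, exon_sets) {
  all_ex <- do.call(rbind, exon_sets)
  # junctions: gaps between consecutive exons of each transcript
  jn <- do.call(rbind, lapply(exon_sets, function(df) {
    n <- nrow(df)
    if (n < 2) return(NULL)
    data.frame(start = df$end[-n], end = df$start[-1])
  }))
  if (is.null(jn)) jn <- data.frame(start = integer(), end = integer())
  jn <- unique(jn)

  # merge exon coverage into maximal regions
  ir <- IRanges::reduce(IRanges::IRanges(all_ex$start + 1L, all_ex$end))
  regions <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))

  # retained-intron carving: a junction interval strictly inside one region
  exon_rows <- NULL
  intron_rows <- NULL
  for (r in seq_len(nrow(regions))) {
    rs <- regions$start[r]; re <- regions$end[r]
    inside <- jn$start > rs & jn$end < re
    carves <- unique(jn[inside, , drop = FALSE])
    if (nrow(carves) == 0) {
      exon_rows <- rbind(exon_rows, data.frame(start = rs, end = re))
      next
    }
    cuts <- sort(unique(c(rs, carves$start, carves$end, re)))
    seg <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
    carve_keys <- sprintf("%d:%d", carves$start, carves$end)
    is_intron <- sprintf("%d:%d", seg$start, seg$end) %in% carve_keys
    intron_rows <- rbind(intron_rows, seg[is_intron, , drop = FALSE])
    # merge touching exon segments back together
    exseg <- seg[!is_intron, , drop = FALSE]
    if (nrow(exseg)) {
      m <- IRanges::reduce(IRanges::IRanges(exseg$start + 1L, exseg$end))
      exon_rows <- rbind(exon_rows,
                         data.frame(start = IRanges::start(m) - 1L,
                                    end = IRanges::end(m)))
    }
  }

  sg <- splicegraph(
    gene_id, chrom, strand,
    exons = cbind(exon_rows, annotated = TRUE, denovo_extended = FALSE),
    junctions = if (nrow(jn))
      cbind(jn, annotated = TRUE, simplified = FALSE) else NULL,
    introns = if (!is.null(intron_rows) && nrow(intron_rows))
      cbind(unique(intron_rows), annotated = TRUE, simplified = FALSE)
      else NULL
  )
  validate_splicegraph(sg)
  sg
}

#' Assign a junction to a gene
#'
#' Resolves the gene of an observed junction among candidate genes on the same
#' chromosome and strand, by priority: (1) a gene already containing the
#' junction; (2) a gene where both junction coordinates are within 400 bp of
#' an exon; (3) a gene whose boundaries contain the junction.  Ties within a
#' tier are broken by distance between the junction midpoint and the gene
#' boundary midpoint, then lexicographic gene id.
#'
#' @param junction list or vector with elements `start`, `end` (0-based).
#' @param candidate_genes list of `splicegraph` objects.
#' @param window proximity window for tier 2, in bp (default 400).
#' @return gene id (character) or `NA_character_` if no tier matches.
#' @export
assign_junction_to_gene <- function(junction, candidate_genes, window = 400L) {
  js <- junction[["start"]]; je <- junction[["end"]]
  tiers <- vapply(candidate_genes, function(sg) {
    keys <- edge_key("junction", sg$junctions$start, sg$junctions$end)
    if (edge_key("junction", js, je) %in% keys) return(1L)
    ex <- sg$exons
    if (nrow(ex)) {
      dist_to <- function(p) {
        d <- pmax(ex$start - p, p - (ex$end - 1L), 0L)
        min(d)
      }
      if (dist_to(js) <= window && dist_to(je) <= window) return(2L)
    }
    b <- sg_boundaries(sg)
    if (!is.na(b[1]) && b[1] <= js && je <= b[2]) return(3L)
    NA_integer_
  }, integer(1))
  if (all(is.na(tiers))) return(NA_character_)
  best <- min(tiers, na.rm = TRUE)
  cand <- which(!is.na(tiers) & tiers == best)
  if (length(cand) > 1) {
    mid_j <- (js + je) / 2
    d <- vapply(candidate_genes[cand], function(sg) {
      b <- sg_boundaries(sg)
      abs(mid_j - (b[1] + b[2]) / 2)
    }, numeric(1))
    ids <- vapply(candidate_genes[cand], function(sg) sg$gene_id, character(1))
    cand <- cand[order(d, ids)]
  }
  candidate_genes[[cand[1]]]$gene_id
}
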