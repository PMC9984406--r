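# Splicegraph update from read evidence, simplification, and LSV definition.

#' Default builder thresholds
#'
#' De novo elements need stricter evidence than annotated ones: a de novo
#' junction/intron is accepted only with `min_denovo_reads` total reads and
#' `min_denovo_pos` nonzero positions in enough experiments of one build
#' group.  `min_experiments = NULL` means ceiling(half the group size).
#'
#' @param min_denovo_reads,min_denovo_pos acceptance filters for unannotated
#'   elements.
#' @param min_reads,min_pos retention filters for annotated elements.
#' @param max_extension maximum exon extension (bp) to host a de novo
#'   junction endpoint; farther endpoints get a new de novo exon.
#' @return list of thresholds.
#' @export
build_thresholds <- function(min_denovo_reads = 5L, min_denovo_pos = 3L,
                             min_reads = 3L, min_pos = 2L,
                             max_extension = 400L) {
  list(min_denovo_reads = min_denovo_reads, min_denovo_pos = min_denovo_pos,
       min_reads = min_reads, min_pos = min_pos,
       max_extension = max_extension)
}

#' Define a build group
#'
#' @param name group label.
#' @param experiments character vector of experiment identifiers.
#' @param min_experiments how many experiments must individually pass the
#'   evidence filters for the group to accept an element; default
#'   `ceiling(length(experiments)/2)`.
#' @return list of class `build_group`.
#' @export
build_group <- function(name, experiments, min_experiments = NULL) {
  if (is.null(min_experiments))
    min_experiments <- as.integer(ceiling(length(experiments) / 2))
  stopifnot(min_experiments <= length(experiments))
  structure(list(name = name, experiments = experiments,
                 min_experiments = min_experiments), class = "build_group")
}

# does a candidate pass the per-group evidence rule?
# ev: data.frame(experiment, reads, positions) for ONE candidate
group_accepts <- function(ev, groups, min_reads, min_pos) {
  for (g in groups) {
    sub <- ev[ev$experiment %in% g$experiments, , drop = FALSE]
    n_pass <- sum(sub$reads >= min_reads & sub$positions >= min_pos)
    if (n_pass >= g$min_experiments) return(TRUE)
  }
  FALSE
}

#' Update a splicegraph with read evidence
#'
#' Adds de novo junctions and introns supported by enough reads and read
#' positions in at least `min_experiments` experiments of one build group.
#' Exons are extended (up to `max_extension` bp) or created de novo to host
#' accepted junction endpoints; introns overlapped by new exon boundaries are
#' split, each fragment inheriting the original intron's flags (and, by
#' construction, its per-position coverage estimate).  Evidence already
#' present in the graph leaves it unchanged.
#'
#' @param sg a `splicegraph`.
#' @param evidence data.frame with columns `experiment`, `type`
#'   (`"junction"`/`"intron"`), `start`, `end`, `reads`, `positions`.
#' @param groups list of [build_group()] objects.
#' @param thresholds list from [build_thresholds()].
#' @return updated `splicegraph`.
#' @export
update_splicegraph <- function(sg, evidence, groups,
                               thresholds = build_thresholds()) {
  if (nrow(evidence) == 0) return(sg)
  cand <- unique(evidence[, c("type", "start", "end")])
  for (k in seq_len(nrow(cand))) {
    typ <- cand$type[k]; s <- cand$start[k]; e <- cand$end[k]
    slot <- if (typ == "junction") "junctions" else "introns"
    if (any(sg[[slot]]$start == s & sg[[slot]]$end == e)) next  # idempotent
    ev <- evidence[evidence$type == typ & evidence$start == s &
                     evidence$end == e, , drop = FALSE]
    if (!group_accepts(ev, groups, thresholds$min_denovo_reads,
                       thresholds$min_denovo_pos)) next
    if (typ == "junction") {
      sg <- host_junction_endpoint(sg, s, side = "donor",
                                   max_ext = thresholds$max_extension)
      sg <- host_junction_endpoint(sg, e, side = "acceptor",
                                   max_ext = thresholds$max_extension)
      sg$junctions <- rbind(sg$junctions,
                            data.frame(start = s, end = e, annotated = FALSE,
                                       simplified = FALSE))
      sg <- split_introns_at_exons(sg)
    } else {
      sg <- add_intron_fragments(sg, s, e, annotated = FALSE)
    }
    sg <- sort_splicegraph(sg)
  }
  validate_splicegraph(sg)
  sg
}

# Ensure some exon hosts a junction endpoint, extending an existing exon by
# at most `max_ext` bp or creating a minimal de novo exon.
host_junction_endpoint <- function(sg, coord, side, max_ext) {
  pos <- if (side == "donor") coord - 1L else coord
  if (!is.na(exon_containing(sg, pos))) return(sg)
  ex <- sg$exons
  if (side == "donor") {
    # nearest exon ending at or before the junction start
    cand <- which(ex$end <= coord)
    if (length(cand)) {
      i <- cand[which.max(ex$end[cand])]
      if (coord - ex$end[i] <= max_ext) {
        sg$exons$end[i] <- coord
        sg$exons$denovo_extended[i] <- TRUE
        return(split_introns_at_exons(sg))
      }
    }
    sg$exons <- rbind(ex, data.frame(start = coord - 1L, end = coord,
                                     annotated = FALSE,
                                     denovo_extended = FALSE))
  } else {
    cand <- which(ex$start >= coord)
    if (length(cand)) {
      i <- cand[which.min(ex$start[cand])]
      if (ex$start[i] - coord <= max_ext) {
        sg$exons$start[i] <- coord
        sg$exons$denovo_extended[i] <- TRUE
        return(split_introns_at_exons(sg))
      }
    }
    sg$exons <- rbind(ex, data.frame(start = coord, end = coord + 1L,
                                     annotated = FALSE,
                                     denovo_extended = FALSE))
  }
  split_introns_at_exons(sg)
}

# Clip every intron against the exon list: fragments overlapped by exons are
# removed, remaining gap fragments between adjacent exons are kept with the
# original intron's flags.
split_introns_at_exons <- function(sg) {
  if (nrow(sg$introns) == 0) return(sg)
  ex <- sg$exons[order(sg$exons$start), , drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(sg$introns))) {
    s <- sg$introns$start[k]; e <- sg$introns$end[k]
    frags <- subtract_intervals(s, e, ex$start, ex$end)
    if (nrow(frags)) {
      out <- rbind(out, data.frame(start = frags$start, end = frags$end,
                                   annotated = sg$introns$annotated[k],
                                   simplified = sg$introns$simplified[k]))
    }
  }
  sg$introns <- if (is.null(out)) normalize_edge_df(NULL) else unique(out)
  sg
}

# interval [s, e) minus the union of [starts_i, ends_i)
subtract_intervals <- function(s, e, starts, ends) {
  keep <- data.frame(start = integer(), end = integer())
  cur <- s
  o <- order(starts)
  for (i in o) {
    if (ends[i] <= cur || starts[i] >= e) next
    if (starts[i] > cur)
      keep <- rbind(keep, data.frame(start = cur, end = starts[i]))
    cur <- max(cur, ends[i])
    if (cur >= e) break
  }
  if (cur < e) keep <- rbind(keep, data.frame(start = cur, end = e))
  keep
}

# Add an accepted (possibly de novo) intron, clipped to exon gaps.
add_intron_fragments <- function(sg, s, e, annotated) {
  ex <- sg$exons
  frags <- subtract_intervals(s, e, ex$start, ex$end)
  if (nrow(frags) == 0) return(sg)
  # keep only fragments lying exactly between adjacent exons
  ok <- vapply(seq_len(nrow(frags)), function(i) {
    any(ex$end == frags$start[i]) && any(ex$start == frags$end[i])
  }, logical(1))
  frags <- frags[ok, , drop = FALSE]
  if (nrow(frags) == 0) return(sg)
  new <- data.frame(start = frags$start, end = frags$end,
                    annotated = annotated, simplified = FALSE)
  key_old <- edge_key("intron", sg$introns$start, sg$introns$end)
  new <- new[!(edge_key("intron", new$start, new$end) %in% key_old), ,
             drop = FALSE]
  sg$introns <- rbind(sg$introns, new)
  sg
}

# ---------------------------------------------------------------------------
# Simplifier

# For one splicegraph, the per-edge LSV membership used by the simplifier and
# LSV definition: each edge belongs to the split at its left exon (edges
# leaving it rightward) and the split at its right exon.
edge_exon_sides <- function(sg, edges) {
  li <- integer(nrow(edges)); ri <- integer(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    if (edges$type[k] == "junction") {
      li[k] <- donor_exon(sg, edges$start[k])
      ri[k] <- acceptor_exon(sg, edges$end[k])
    } else {
      l <- which(sg$exons$end == edges$start[k])
      r <- which(sg$exons$start == edges$end[k])
      li[k] <- if (length(l)) l[1] else NA_integer_
      ri[k] <- if (length(r)) r[1] else NA_integer_
    }
  }
  cbind(left = li, right = ri)
}

#' Simplify a splicegraph by relative coverage
#'
#' Flags edges whose raw read rate is consistently low, in every build group,
#' relative to the other edges of each of the (up to two) LSVs the edge
#' belongs to.  Simplified edges are kept in the graph but excluded from LSV
#' definition.  A group in which an LSV has zero total rate abstains (counts
#' as low) provided the threshold is positive; with `threshold = 0` nothing
#' is ever simplified.
#'
#' @param sg a `splicegraph`.
#' @param rates data.frame with columns `group`, `type`, `start`, `end`,
#'   `rate` (aggregate raw read rate of the edge in the group).
#' @param threshold simplifier ratio threshold in \[0, 1\].
#' @return `splicegraph` with updated `simplified` flags.
#' @export
simplify_splicegraph <- function(sg, rates, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (threshold == 0) return(sg)
  edges <- sg_edges(sg)
  if (nrow(edges) == 0) return(sg)
  sides <- edge_exon_sides(sg, edges)
  groups <- unique(rates$group)
  rate_of <- function(g, k) {
    r <- rates$rate[rates$group == g & rates$type == edges$type[k] &
                      rates$start == edges$start[k] &
                      rates$end == edges$end[k]]
    if (length(r) == 0) 0 else sum(r)
  }
  simplified <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    low_everywhere <- TRUE
    for (g in groups) {
      rk <- rate_of(g, k)
      for (side in c("left", "right")) {
        members <- which(sides[, side] == sides[k, side])
        tot <- sum(vapply(members, function(m) rate_of(g, m), numeric(1)))
        low <- if (tot == 0) TRUE else (rk / tot) < threshold
        if (!low) { low_everywhere <- FALSE; break }
      }
      if (!low_everywhere) break
    }
    simplified[k] <- low_everywhere
  }
  for (k in which(simplified)) {
    slot <- if (edges$type[k] == "junction") "junctions" else "introns"
    hit <- sg[[slot]]$start == edges$start[k] & sg[[slot]]$end == edges$end[k]
    sg[[slot]]$simplified[hit] <- TRUE
  }
  sg
}

# ---------------------------------------------------------------------------
# LSV definition

#' Enumerate local splicing variations (LSVs)
#'
#' A source (target) LSV is the choice over the edges leaving (entering) a
#' reference exon toward (from) different exons; only splits with at least
#' two non-simplified edges are kept.  Source/target is resolved by strand:
#' on the forward strand the source side of an exon faces increasing
#' coordinates.
#'
#' @param sg a `splicegraph`.
#' @return list of `lsv` objects: each has `lsv_id`, `gene_id`, `direction`
#'   (`"source"`/`"target"`), `ref_exon` and an `edges` data.frame ordered by
#'   genomic coordinate.
#' @export
define_lsvs <- function(sg) {
  edges <- sg_edges(sg, include_simplified = FALSE)
  if (nrow(edges) == 0) return(list())
  sides <- edge_exon_sides(sg, edges)
  out <- list()
  for (i in seq_len(nrow(sg$exons))) {
    for (facing in c("right", "left")) {
      members <- which(sides[, if (facing == "right") "left" else "right"] == i)
      if (length(members) < 2) next
      direction <- if (sg$strand == "+") {
        if (facing == "right") "source" else "target"
      } else {
        if (facing == "right") "target" else "source"
      }
      e <- edges[members, , drop = FALSE]
      e <- e[order(e$start, e$end), , drop = FALSE]
      rownames(e) <- NULL
      ref <- c(sg$exons$start[i], sg$exons$end[i])
      out[[length(out) + 1]] <- structure(list(
        lsv_id = sprintf("%s:%s:%d-%d", sg$gene_id,
                         substr(direction, 1, 1), ref[1] + 1L, ref[2]),
        gene_id = sg$gene_id, chrom = sg$chrom, strand = sg$strand,
        direction = direction, ref_exon = ref,
        edges = e[, c("type", "start", "end")]
      ), class = "lsv")
    }
  }
  out
}

#' @export
print.lsv <- function(x, ...) {
  cat(sprintf("LSV %s (%d edges)\n", x$lsv_id, nrow(x$edges)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Splicegraph TSV dump (versioned text container)

SG_DUMP_VERSION <- 1L

#' Write / read a splicegraph set as a versioned TSV container
#'
#' One table holding exons, junctions and introns of every gene with their
#' flags; round-trips losslessly through [read_splicegraph_tsv()].
#'
#' @param sgs named list of `splicegraph` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_splicegraph_tsv <- function(sgs, path) {
  rows <- do.call(rbind, lapply(sgs, function(sg) {
    e <- sg$exons; j <- sg$junctions; i <- sg$introns
    rbind(
      if (nrow(e)) data.frame(gene_id = sg$gene_id, chrom = sg$chrom,
                              strand = sg$strand, feature = "exon",
                              start = e$start, end = e$end,
                              annotated = e$annotated,
                              flag = e$denovo_extended) else NULL,
      if (nrow(j)) data.frame(gene_id = sg$gene_id, chrom = sg$chrom,
                              strand = sg$strand, feature = "junction",
                              start = j$start, end = j$end,
                              annotated = j$annotated,
                              flag = j$simplified) else NULL,
      if (nrow(i)) data.frame(gene_id = sg$gene_id, chrom = sg$chrom,
                              strand = sg$strand, feature = "intron",
                              start = i$start, end = i$end,
                              annotated = i$annotated,
                              flag = i$simplified) else NULL
    )
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#splicegraph_version: %d", SG_DUMP_VERSION), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_splicegraph_tsv
#' @export
read_splicegraph_tsv <- function(path) {
  first <- readLines(path, n = 1)
  ver <- as.integer(sub("#splicegraph_version: *", "", first))
  if (is.na(ver) || ver != SG_DUMP_VERSION)
    stop(sprintf("splicegraph container version mismatch: file has '%s', reader expects %d",
                 first, SG_DUMP_VERSION))
  tab <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  out <- list()
  for (gid in unique(tab$gene_id)) {
    sub <- tab[tab$gene_id == gid, , drop = FALSE]
    ex <- sub[sub$feature == "exon", , drop = FALSE]
    jn <- sub[sub$feature == "junction", , drop = FALSE]
    it <- sub[sub$feature == "intron", , drop = FALSE]
    out[[gid]] <- splicegraph(
      gid, sub$chrom[1], sub$strand[1],
      exons = data.frame(start = ex$start, end = ex$end,
                         annotated = ex$annotated,
                         denovo_extended = ex$flag),
      junctions = if (nrow(jn)) data.frame(start = jn$start, end = jn$end,
                                           annotated = jn$annotated,
                                           simplified = jn$flag) else NULL,
      introns = if (nrow(it)) data.frame(start = it$start, end = it$end,
                                         annotated = it$annotated,
                                         simplified = it$flag) else NULL
    )
  }
  out
}
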