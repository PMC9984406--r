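# Alternative-splicing modules: single-entry/single-exit regions of a
# simplified splicegraph, decomposed into classified binary AS events.

AS_EVENT_TYPES <- c("CE", "TCE", "MES", "MXE", "A3SS", "A5SS", "AFE", "ALE",
                    "pAFE", "pALE", "pA3SS", "pA5SS", "IR", "other")

#' Default changing / non-changing flag thresholds
#'
#' @param psi_simplify decomplexify threshold on group-median E\[PSI\].
#' @param dpsi_changing minimum |difference of group medians| for a changing
#'   call.
#' @param p_changing maximum p for a changing call (all requested statistics).
#' @param dpsi_nonchanging maximum |difference of group medians| for a
#'   non-changing call.
#' @param iqr_nonchanging maximum within-group IQR for a non-changing call.
#' @param p_nonchanging minimum p for a non-changing call.
#' @return list of thresholds.
#' @export
flag_thresholds <- function(psi_simplify = 0.05, dpsi_changing = 0.20,
                            p_changing = 0.05, dpsi_nonchanging = 0.05,
                            iqr_nonchanging = 0.10, p_nonchanging = 0.05) {
  stopifnot(dpsi_nonchanging < dpsi_changing)
  list(psi_simplify = psi_simplify, dpsi_changing = dpsi_changing,
       p_changing = p_changing, dpsi_nonchanging = dpsi_nonchanging,
       iqr_nonchanging = iqr_nonchanging, p_nonchanging = p_nonchanging)
}

#' Remove lowly included edges before module definition
#'
#' An edge is removed from module consideration when its group-median E\[PSI\]
#' stays below `psi_threshold` in every group (edges lacking quantification
#' in all groups are removed too).  The original splicegraph is untouched:
#' the returned graph is a view for the modulizer only.
#'
#' @param sg a `splicegraph`.
#' @param edge_medians data.frame with columns `type`, `start`, `end`,
#'   `group`, `median_psi`.
#' @param psi_threshold decomplexify threshold (default 0.05); 0 keeps
#'   everything.
#' @return a `splicegraph` view; removed edges are recorded in
#'   `attr(, "removed")`.
#' @export
decomplexify <- function(sg, edge_medians, psi_threshold = 0.05) {
  view <- sg
  removed <- NULL
  if (psi_threshold > 0) {
    for (slot in c("junctions", "introns")) {
      df <- view[[slot]]
      if (nrow(df) == 0) next
      typ <- if (slot == "junctions") "junction" else "intron"
      keep <- vapply(seq_len(nrow(df)), function(k) {
        m <- edge_medians$median_psi[edge_medians$type == typ &
                                       edge_medians$start == df$start[k] &
                                       edge_medians$end == df$end[k]]
        length(m) > 0 && any(m >= psi_threshold)
      }, logical(1))
      if (any(!keep))
        removed <- rbind(removed, cbind(type = typ,
                                        df[!keep, c("start", "end"),
                                           drop = FALSE]))
      view[[slot]] <- df[keep, , drop = FALSE]
    }
  }
  attr(view, "removed") <- removed
  view
}

#' Detect alternative-splicing modules
#'
#' A module is a maximal region of the splicegraph between a single entering
#' and single exiting junction path: connected components of edges (by
#' overlap of the exon gaps they span) with at least two member edges.
#' Simplified edges are excluded; purely constitutive stretches yield no
#' module.
#'
#' @param sg_view a (decomplexified) `splicegraph`.
#' @return list of `as_module` objects: `gene_id`, `entry_exon`,
#'   `exit_exon` (exon indices), `edges` data.frame with exon-index columns
#'   `li`, `ri`.
#' @export
detect_modules <- function(sg_view) {
  edges <- sg_edges(sg_view, include_simplified = FALSE)
  if (nrow(edges) == 0) return(list())
  sides <- edge_exon_sides(sg_view, edges)
  edges$li <- sides[, "left"]; edges$ri <- sides[, "right"]
  edges <- edges[!is.na(edges$li) & !is.na(edges$ri), , drop = FALSE]
  if (nrow(edges) == 0) return(list())
  # gap g lies between exon g and exon g+1; edge spans gaps li..ri-1
  comp <- rep(NA_integer_, nrow(edges))
  o <- order(edges$li, edges$ri)
  cur <- 0L; cur_end <- -1L
  for (k in o) {
    if (edges$li[k] >= cur_end) {  # no shared gap with the open component
      cur <- cur + 1L
      cur_end <- edges$ri[k]
    } else {
      cur_end <- max(cur_end, edges$ri[k])
    }
    comp[k] <- cur
  }
  out <- list()
  for (cc in unique(comp)) {
    memb <- edges[comp == cc, , drop = FALSE]
    if (nrow(memb) < 2) next
    rownames(memb) <- NULL
    out[[length(out) + 1]] <- structure(list(
      gene_id = sg_view$gene_id, strand = sg_view$strand,
      entry_exon = min(memb$li), exit_exon = max(memb$ri),
      edges = memb
    ), class = "as_module")
  }
  out
}

#' @export
print.as_module <- function(x, ...) {
  cat(sprintf("AS module %s exons %d..%d (%d edges)\n", x$gene_id,
              x$entry_exon, x$exit_exon, nrow(x$edges)))
  invisible(x)
}

# strand-aware event label: patterns are matched in genomic orientation and
# renamed on the minus strand
flip_event_type <- function(type, strand) {
  if (strand == "+") return(type)
  map <- c(A3SS = "A5SS", A5SS = "A3SS", pA3SS = "pA5SS", pA5SS = "pA3SS",
           AFE = "ALE", ALE = "AFE", pAFE = "pALE", pALE = "pAFE")
  if (type %in% names(map)) map[[type]] else type
}

mod_junc <- function(m, i, j) {
  which(m$edges$type == "junction" & m$edges$li == i & m$edges$ri == j)
}
mod_intron <- function(m, i, j) {
  which(m$edges$type == "intron" & m$edges$li == i & m$edges$ri == j)
}

new_event <- function(type, module, inclusion, exclusion, sg) {
  ref_l <- module$edges$li[c(inclusion, exclusion)]
  ref_r <- module$edges$ri[c(inclusion, exclusion)]
  lsv_ref <- function(i, facing) {
    dir_char <- if (sg$strand == "+") {
      if (facing == "right") "s" else "t"
    } else if (facing == "right") "t" else "s"
    sprintf("%s:%s:%d-%d", sg$gene_id, dir_char,
            sg$exons$start[i] + 1L, sg$exons$end[i])
  }
  structure(list(
    event_type = type,
    gene_id = module$gene_id,
    inclusion = module$edges[inclusion, c("type", "start", "end"),
                             drop = FALSE],
    exclusion = module$edges[exclusion, c("type", "start", "end"),
                             drop = FALSE],
    source_lsv = lsv_ref(min(ref_l), "right"),
    target_lsv = lsv_ref(max(ref_r), "left"),
    changing = FALSE, nonchanging = FALSE
  ), class = "as_event")
}

#' @export
print.as_event <- function(x, ...) {
  cat(sprintf("%s event in %s (%d inclusion, %d exclusion edges)%s\n",
              x$event_type, x$gene_id, nrow(x$inclusion), nrow(x$exclusion),
              if (x$changing) " [changing]"
              else if (x$nonchanging) " [nonchanging]" else ""))
  invisible(x)
}

#' Classify the binary AS events of a module
#'
#' Pattern-matches the module's exon/junction/intron structure to the basic
#' AS event types: cassette exon (CE), tandem cassette (TCE), multi-exon
#' skipping (MES), mutually exclusive exons (MXE), alternative 3'/5' splice
#' sites (A3SS/A5SS), alternative first/last exons (AFE/ALE), their putative
#' variants (pAFE/pALE from unannotated terminal exons; pA3SS/pA5SS from a
#' cassette whose inclusion junction was simplified away but whose retained
#' intron is sufficiently included), and intron retention (IR).  A module in
#' which no pattern matches yields one "other" event over all its edges.
#'
#' @param module an `as_module`.
#' @param sg the (decomplexified) `splicegraph` the module came from.
#' @param full_sg the pre-decomplexify graph (for simplified-edge lookups);
#'   defaults to `sg`.
#' @param edge_medians optional data.frame (`type`, `start`, `end`, `group`,
#'   `median_psi`) used by the putative splice-site patterns.
#' @param psi_simplify inclusion threshold for the retained intron in the
#'   pA3SS/pA5SS patterns (default 0.05).
#' @return list of `as_event` objects.
#' @export
classify_events <- function(module, sg, full_sg = sg, edge_medians = NULL,
                            psi_simplify = 0.05) {
  m <- module
  strand <- sg$strand
  events <- list()
  add <- function(type, inclusion, exclusion) {
    events[[length(events) + 1]] <<- new_event(flip_event_type(type, strand),
                                               m, inclusion, exclusion, sg)
  }
  exon_idx <- sort(unique(c(m$edges$li, m$edges$ri)))

  # IR: intron between adjacent exons with the matching junction present
  for (k in which(m$edges$type == "intron")) {
    j <- mod_junc(m, m$edges$li[k], m$edges$ri[k])
    if (length(j)) add("IR", k, j[1])
  }

  # exon-pair junction groups: alternative 3'/5' splice sites
  jn <- which(m$edges$type == "junction")
  if (length(jn) > 1) {
    pair_key <- sprintf("%d:%d", m$edges$li[jn], m$edges$ri[jn])
    for (pk in unique(pair_key[duplicated(pair_key)])) {
      grp <- jn[pair_key == pk]
      for (a in seq_along(grp)) for (b in seq_along(grp)) {
        if (a >= b) next
        e1 <- grp[a]; e2 <- grp[b]
        same_start <- m$edges$start[e1] == m$edges$start[e2]
        same_end <- m$edges$end[e1] == m$edges$end[e2]
        if (same_start && !same_end) {
          # alternative acceptor: 3' splice site on the forward strand
          add("A3SS", e1, e2)
        } else if (same_end && !same_start) {
          add("A5SS", e1, e2)
        }
      }
    }
  }

  # skip-junction patterns: CE, TCE, MES, and MXE
  for (k in jn) {
    i <- m$edges$li[k]; j <- m$edges$ri[k]
    middles <- exon_idx[exon_idx > i & exon_idx < j]
    if (length(middles) == 1) {
      cm <- middles[1]
      inc1 <- mod_junc(m, i, cm); inc2 <- mod_junc(m, cm, j)
      if (length(inc1) && length(inc2)) add("CE", c(inc1[1], inc2[1]), k)
    } else if (length(middles) >= 2) {
      # any inclusion path through the skipped exons -> MES
      chain_edges <- integer(0)
      seqs <- c(i, middles, j)
      full_chain <- TRUE
      for (t in seq_len(length(seqs) - 1)) {
        e <- mod_junc(m, seqs[t], seqs[t + 1])
        if (length(e) == 0) { full_chain <- FALSE; break }
        chain_edges <- c(chain_edges, e[1])
      }
      if (full_chain) {
        add("MES", chain_edges, k)
        add("TCE", chain_edges, k)
      } else if (path_exists(m, i, j, via = middles)) {
        add("MES", path_edges(m, i, j, via = middles), k)
      }
    }
  }

  # MXE: two middles each connected to both flanks, not to each other,
  # and no skip junction between the flanks
  if (length(exon_idx) >= 4) {
    for (i in exon_idx) for (j in exon_idx[exon_idx > i]) {
      middles <- exon_idx[exon_idx > i & exon_idx < j]
      if (length(middles) != 2) next
      m1 <- middles[1]; m2 <- middles[2]
      if (length(mod_junc(m, i, m1)) && length(mod_junc(m, m1, j)) &&
          length(mod_junc(m, i, m2)) && length(mod_junc(m, m2, j)) &&
          length(mod_junc(m, m1, m2)) == 0 && length(mod_junc(m, i, j)) == 0) {
        add("MXE", c(mod_junc(m, i, m1)[1], mod_junc(m, m1, j)[1]),
            c(mod_junc(m, i, m2)[1], mod_junc(m, m2, j)[1]))
      }
    }
  }

  # alternative first/last exons: two left-terminal (or right-terminal)
  # exons converging on a shared exon
  left_terminal <- setdiff(m$edges$li, m$edges$ri)
  right_terminal <- setdiff(m$edges$ri, m$edges$li)
  if (length(left_terminal) >= 2) {
    for (a in seq_along(left_terminal)) for (b in seq_along(left_terminal)) {
      if (a >= b) next
      t1 <- left_terminal[a]; t2 <- left_terminal[b]
      common <- intersect(m$edges$ri[m$edges$li == t1],
                          m$edges$ri[m$edges$li == t2])
      if (length(common) == 0) next
      c0 <- min(common)
      putative <- !sg$exons$annotated[t1] || !sg$exons$annotated[t2]
      add(if (putative) "pAFE" else "AFE",
          mod_junc(m, t2, c0)[1], mod_junc(m, t1, c0)[1])
    }
  }
  if (length(right_terminal) >= 2) {
    for (a in seq_along(right_terminal)) for (b in seq_along(right_terminal)) {
      if (a >= b) next
      t1 <- right_terminal[a]; t2 <- right_terminal[b]
      common <- intersect(m$edges$li[m$edges$ri == t1],
                          m$edges$li[m$edges$ri == t2])
      if (length(common) == 0) next
      c0 <- max(common)
      putative <- !sg$exons$annotated[t1] || !sg$exons$annotated[t2]
      add(if (putative) "pALE" else "ALE",
          mod_junc(m, c0, t1)[1], mod_junc(m, c0, t2)[1])
    }
  }

  # putative alternative splice sites: cassette with one inclusion junction
  # simplified away, replaced by sufficiently retained intron
  full_edges <- sg_edges(full_sg)
  sides_full <- if (nrow(full_edges))
    edge_exon_sides_in(full_sg, sg, full_edges) else NULL
  for (k in jn) {
    i <- m$edges$li[k]; j <- m$edges$ri[k]
    middles <- exon_idx[exon_idx > i & exon_idx < j]
    if (length(middles) != 1) next
    cm <- middles[1]
    has_left <- length(mod_junc(m, i, cm)) > 0
    has_right <- length(mod_junc(m, cm, j)) > 0
    if (has_left == has_right) next  # CE (both) or nothing (neither)
    miss <- if (has_left) c(cm, j) else c(i, cm)
    present_incl <- if (has_left) mod_junc(m, i, cm)[1] else
      mod_junc(m, cm, j)[1]
    # missing junction must exist simplified/removed in the full graph
    gone <- edge_gone_between(full_sg, sg, miss[1], miss[2], sides_full,
                              full_edges)
    if (!gone) next
    ir <- mod_intron(m, miss[1], miss[2])
    if (length(ir) == 0) next
    if (!intron_sufficiently_included(m$edges[ir[1], ], edge_medians,
                                      psi_simplify)) next
    # low-inclusion junction on the left of the cassette exon -> its 3' ss
    # is putatively alternative (forward strand)
    add(if (has_right) "pA3SS" else "pA5SS", c(present_incl, ir[1]), k)
  }

  if (length(events) == 0 && nrow(m$edges) >= 2) {
    add("other", seq_len(nrow(m$edges)), integer(0))
  }
  events
}

# breadth-first search for an inclusion path i -> j restricted to `via` exons
path_exists <- function(m, i, j, via) {
  length(path_edges(m, i, j, via)) > 0
}

path_edges <- function(m, i, j, via) {
  allowed <- c(i, via, j)
  frontier <- list(list(node = i, edges = integer(0)))
  visited <- i
  while (length(frontier)) {
    st <- frontier[[1]]; frontier <- frontier[-1]
    nxt <- which(m$edges$li == st$node & m$edges$ri %in% allowed &
                   m$edges$type == "junction")
    for (e in nxt) {
      node <- m$edges$ri[e]
      if (node == j && st$node != i) return(c(st$edges, e))
      if (node %in% visited || node == j) next
      visited <- c(visited, node)
      frontier[[length(frontier) + 1]] <- list(node = node,
                                               edges = c(st$edges, e))
    }
  }
  integer(0)
}

# map full-graph edges onto the view's exon indexing
edge_exon_sides_in <- function(full_sg, view_sg, edges) {
  li <- integer(nrow(edges)); ri <- integer(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    if (edges$type[k] == "junction") {
      li[k] <- donor_exon(view_sg, edges$start[k])
      ri[k] <- acceptor_exon(view_sg, edges$end[k])
    } else {
      l <- which(view_sg$exons$end == edges$start[k])
      r <- which(view_sg$exons$start == edges$end[k])
      li[k] <- if (length(l)) l[1] else NA_integer_
      ri[k] <- if (length(r)) r[1] else NA_integer_
    }
  }
  cbind(left = li, right = ri)
}

# was there a junction between view exons i and j in the full graph that is
# simplified or decomplexified away?
edge_gone_between <- function(full_sg, view_sg, i, j, sides_full, full_edges) {
  if (is.null(sides_full)) return(FALSE)
  cand <- which(full_edges$type == "junction" & sides_full[, "left"] == i &
                  sides_full[, "right"] == j)
  for (k in cand) {
    in_view <- any(view_sg$junctions$start == full_edges$start[k] &
                     view_sg$junctions$end == full_edges$end[k] &
                     !view_sg$junctions$simplified)
    if (!in_view || full_edges$simplified[k]) return(TRUE)
  }
  FALSE
}

intron_sufficiently_included <- function(intron_edge, edge_medians,
                                         psi_simplify) {
  if (is.null(edge_medians)) return(TRUE)
  med <- edge_medians$median_psi[edge_medians$type == "intron" &
                                   edge_medians$start == intron_edge$start &
                                   edge_medians$end == intron_edge$end]
  length(med) > 0 && any(med >= psi_simplify)
}

#' Module type label (event-type multiset with redundancy rule)
#'
#' A module is labelled by the multiset of its event types.  Partially
#' redundant types are kept only when they out-count the type they overlap
#' with: MES is kept alongside TCE only when `count(MES) > count(TCE)`, and
#' IR alongside pA3SS/pA5SS only when
#' `count(IR) > count(pA3SS) + count(pA5SS)`.
#'
#' @param events list of `as_event` from [classify_events()].
#' @return named integer vector of event-type counts after the rule.
#' @export
label_module_types <- function(events) {
  types <- vapply(events, `[[`, character(1), "event_type")
  counts <- table(factor(types, levels = AS_EVENT_TYPES))
  counts <- counts[counts > 0]
  counts <- stats::setNames(as.integer(counts), names(counts))
  if ("TCE" %in% names(counts) && "MES" %in% names(counts) &&
      counts[["MES"]] <= counts[["TCE"]]) {
    counts <- counts[names(counts) != "MES"]
  }
  n_pss <- sum(counts[names(counts) %in% c("pA3SS", "pA5SS")])
  if (n_pss > 0 && "IR" %in% names(counts) && counts[["IR"]] <= n_pss) {
    counts <- counts[names(counts) != "IR"]
  }
  counts
}

#' Flag events as changing or non-changing
#'
#' An event is changing when at least one of its edges has an absolute
#' difference of group medians of `dpsi_changing` or more AND every requested
#' statistic's p value is below `p_changing`.  It is non-changing when every
#' edge has |median difference| at most `dpsi_nonchanging`, within-group IQR
#' at most `iqr_nonchanging`, and all p values at least `p_nonchanging`.
#' Events with edges lacking quantification stay unflagged.
#'
#' @param events list of `as_event`.
#' @param quant data.frame with one row per edge: `type`, `start`, `end`,
#'   `median_diff`, `iqr1`, `iqr2`, and one `p_<stat>` column per statistic.
#' @param thresholds list from [flag_thresholds()].
#' @param stats statistics whose p values participate (default all columns
#'   named `p_*` in `quant`).
#' @return the events, with `changing`/`nonchanging` set.
#' @export
flag_events <- function(events, quant, thresholds = flag_thresholds(),
                        stats = NULL) {
  pcols <- grep("^p_", names(quant), value = TRUE)
  if (!is.null(stats)) pcols <- paste0("p_", stats)
  lapply(events, function(ev) {
    edges <- rbind(ev$inclusion, ev$exclusion)
    rows <- lapply(seq_len(nrow(edges)), function(k) {
      quant[quant$type == edges$type[k] & quant$start == edges$start[k] &
              quant$end == edges$end[k], , drop = FALSE]
    })
    if (any(vapply(rows, nrow, integer(1)) == 0)) return(ev)
    q <- do.call(rbind, rows)
    pvals <- as.matrix(q[, pcols, drop = FALSE])
    changing <- any(abs(q$median_diff) >= thresholds$dpsi_changing) &&
      all(pvals < thresholds$p_changing)
    nonchanging <- all(abs(q$median_diff) <= thresholds$dpsi_nonchanging) &&
      all(q$iqr1 <= thresholds$iqr_nonchanging) &&
      all(q$iqr2 <= thresholds$iqr_nonchanging) &&
      all(pvals >= thresholds$p_nonchanging)
    ev$changing <- changing
    ev$nonchanging <- nonchanging && !changing
    ev
  })
}
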