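edge_medians_for <- function(sg, value = 0.5, group = "G1") {
  ed <- lsvquant:::sg_edges(sg)
  data.frame(gene_id = sg$gene_id, type = ed$type, start = ed$start,
             end = ed$end, group = group, median_psi = value)
}

test_that("decomplexify removes edges below the PSI threshold in every group", {
  sg <- cassette_sg()
  med <- rbind(edge_medians_for(sg, 0.5, "G1"), edge_medians_for(sg, 0.5, "G2"))
  # skip junction lowly included in both groups -> removed
  skip <- med$type == "junction" & med$start == 400 & med$end == 2000
  med$median_psi[skip] <- c(0.02, 0.03)
  view <- decomplexify(sg, med, 0.05)
  expect_equal(nrow(view$junctions), 2)
  expect_equal(nrow(attr(view, "removed")), 1)
  # one passing group keeps the edge
  med$median_psi[skip] <- c(0.02, 0.60)
  view2 <- decomplexify(sg, med, 0.05)
  expect_equal(nrow(view2$junctions), 3)
  # threshold zero is the identity
  view3 <- decomplexify(sg, med, 0)
  expect_equal(view3$junctions, sg$junctions)
  # edges lacking quantification everywhere are removed
  view4 <- decomplexify(sg, med[!skip, ], 0.05)
  expect_equal(nrow(view4$junctions), 2)
})

test_that("module detection finds single-entry/single-exit regions", {
  # one cassette -> one module spanning E1..E3
  mods <- detect_modules(cassette_sg())
  expect_length(mods, 1)
  expect_equal(mods[[1]]$entry_exon, 1)
  expect_equal(mods[[1]]$exit_exon, 3)

  # two cassettes separated by a constitutive exon -> two modules
  sg2 <- splicegraph(
    "g2", "chr1", "+",
    exons = data.frame(start = c(0, 1000, 2000, 3000, 4000, 5000, 6000),
                       end = c(400, 1400, 2400, 3400, 4400, 5400, 6400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(
      start = c(400, 400, 1400, 2400, 3400, 3400, 4400, 5400),
      end = c(1000, 2000, 2000, 3000, 4000, 5000, 5000, 6000),
      annotated = TRUE, simplified = FALSE))
  mods2 <- detect_modules(sg2)
  expect_length(mods2, 2)
  # no edge belongs to two modules
  keys <- unlist(lapply(mods2, function(m)
    paste(m$edges$type, m$edges$start, m$edges$end)))
  expect_equal(anyDuplicated(keys), 0)

  # purely linear gene -> no module
  sg3 <- splicegraph(
    "g3", "chr1", "+",
    exons = data.frame(start = c(0, 1000, 2000), end = c(400, 1400, 2400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(start = c(400, 1400), end = c(1000, 2000),
                           annotated = TRUE, simplified = FALSE))
  expect_length(detect_modules(sg3), 0)
})

test_that("event classification matches hand-enumerated patterns", {
  # cassette exon
  sg <- cassette_sg()
  evs <- classify_events(detect_modules(sg)[[1]], sg)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$event_type, "CE")
  expect_equal(nrow(evs[[1]]$inclusion), 2)
  expect_equal(evs[[1]]$exclusion$start, 400)
  expect_equal(evs[[1]]$exclusion$end, 2000)
  # both LSV quantification references are attached
  expect_match(evs[[1]]$source_lsv, "^g:s:")
  expect_match(evs[[1]]$target_lsv, "^g:t:")

  # intron retention
  sg_ir <- splicegraph(
    "gi", "chr1", "+",
    exons = data.frame(start = c(0, 1000), end = c(400, 1400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(start = 400, end = 1000, annotated = TRUE,
                           simplified = FALSE),
    introns = data.frame(start = 400, end = 1000, annotated = TRUE,
                         simplified = FALSE))
  evs_ir <- classify_events(detect_modules(sg_ir)[[1]], sg_ir)
  expect_equal(vapply(evs_ir, `[[`, character(1), "event_type"), "IR")

  # mutually exclusive exons: J12,J24 vs J13,J34, no J23, no J14
  sg_mxe <- splicegraph(
    "gm", "chr1", "+",
    exons = data.frame(start = c(0, 1000, 2000, 3000),
                       end = c(400, 1400, 2400, 3400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(start = c(400, 1400, 400, 2400),
                           end = c(1000, 3000, 2000, 3000),
                           annotated = TRUE, simplified = FALSE))
  evs_mxe <- classify_events(detect_modules(sg_mxe)[[1]], sg_mxe)
  expect_equal(vapply(evs_mxe, `[[`, character(1), "event_type"), "MXE")
})

test_that("strand flips alternative splice-site and terminal-exon labels", {
  g_fwd <- toy_gene_a3ss("gf", strand = "+")
  g_rev <- toy_gene_a3ss("gr", strand = "-")
  truth <- make_annotation(list(g_fwd, g_rev))
  types <- function(gid) {
    sg <- truth$splicegraphs[[gid]]
    m <- detect_modules(sg)[[1]]
    vapply(classify_events(m, sg), `[[`, character(1), "event_type")
  }
  expect_equal(types("gf"), "A3SS")
  expect_equal(types("gr"), "A5SS")
})

test_that("an unannotated terminal exon makes the first/last-exon event putative", {
  g <- toy_gene_afe("ga")
  truth <- make_annotation(list(g))
  sg <- truth$splicegraphs[["ga"]]
  sg$exons$annotated[2] <- FALSE  # the alternative first exon is de novo
  m <- detect_modules(sg)[[1]]
  evs <- classify_events(m, sg)
  expect_equal(vapply(evs, `[[`, character(1), "event_type"), "pAFE")
})

test_that("putative splice sites arise from simplified inclusion + retained intron", {
  # cassette E1,E2,E3 with J12 simplified away and an intron E1..E2
  sg_full <- splicegraph(
    "gp", "chr1", "+",
    exons = data.frame(start = c(0, 1000, 2000), end = c(400, 1400, 2400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(start = c(400, 400, 1400),
                           end = c(1000, 2000, 2000),
                           annotated = TRUE,
                           simplified = c(TRUE, FALSE, FALSE)),
    introns = data.frame(start = 400, end = 1000, annotated = TRUE,
                         simplified = FALSE))
  view <- sg_full
  view$junctions <- view$junctions[!view$junctions$simplified, , drop = FALSE]
  med <- data.frame(gene_id = "gp", type = "intron", start = 400, end = 1000,
                    group = "G1", median_psi = 0.3)
  m <- detect_modules(view)[[1]]
  evs <- classify_events(m, view, full_sg = sg_full, edge_medians = med)
  types <- vapply(evs, `[[`, character(1), "event_type")
  expect_true("pA3SS" %in% types)
  # with the intron below the inclusion threshold the pattern is not called
  med$median_psi <- 0.01
  evs2 <- classify_events(m, view, full_sg = sg_full, edge_medians = med)
  expect_false("pA3SS" %in% vapply(evs2, `[[`, character(1), "event_type"))
})

test_that("module labels apply the redundancy rule for TCE/MES and IR/putative-SS", {
  stub <- function(types) lapply(types, function(tp)
    structure(list(event_type = tp), class = "as_event"))
  expect_equal(label_module_types(stub(c("TCE", "MES"))), c(TCE = 1L))
  expect_equal(label_module_types(stub(c("TCE", "MES", "MES"))),
               c(TCE = 1L, MES = 2L))
  expect_equal(label_module_types(stub("CE")), c(CE = 1L))
  expect_equal(label_module_types(stub(c("pA3SS", "IR"))), c(pA3SS = 1L))
  expect_equal(label_module_types(stub(c("pA5SS", "IR", "IR"))),
               c(pA5SS = 1L, IR = 2L))
})

test_that("planted panel compositions are recovered exactly", {
  panel <- toy_gene_panel()
  truth <- make_annotation(panel)
  for (g in panel) {
    sg <- truth$splicegraphs[[g$gene_id]]
    med <- edge_medians_for(sg)
    view <- decomplexify(sg, med, 0.05)
    mods <- detect_modules(view)
    expect_length(mods, 1)
    label <- label_module_types(
      classify_events(mods[[1]], view, full_sg = sg, edge_medians = med))
    expect_equal(label[order(names(label))],
                 g$planted[order(names(g$planted))], info = g$gene_id)
  }
})

test_that("event flags follow the changing/non-changing conjunctions", {
  sg <- cassette_sg()
  evs <- classify_events(detect_modules(sg)[[1]], sg)
  ed <- lsvquant:::sg_edges(sg)
  quant <- data.frame(type = ed$type, start = ed$start, end = ed$end,
                      median_diff = 0.25, iqr1 = 0.05, iqr2 = 0.05,
                      p_welch = 0.01, p_mwu = 0.01, p_tnom = 0.01,
                      p_infoscore = 0.01)
  f <- flag_events(evs, quant)
  expect_true(f[[1]]$changing)
  expect_false(f[[1]]$nonchanging)

  quant2 <- transform(quant, median_diff = 0.01, iqr1 = 0.04, iqr2 = 0.04,
                      p_welch = 0.6, p_mwu = 0.6, p_tnom = 0.6,
                      p_infoscore = 0.6)
  f2 <- flag_events(evs, quant2)
  expect_false(f2[[1]]$changing)
  expect_true(f2[[1]]$nonchanging)

  # one failing statistic breaks the changing conjunction
  quant3 <- transform(quant, p_tnom = 0.2)
  f3 <- flag_events(evs, quant3)
  expect_false(f3[[1]]$changing)
  expect_false(f3[[1]]$nonchanging)

  # missing quantification leaves the event unflagged
  f4 <- flag_events(evs, quant[-1, ])
  expect_false(f4[[1]]$changing || f4[[1]]$nonchanging)
})

test_that("changing and nonchanging are mutually exclusive for any valid thresholds", {
  sg <- cassette_sg()
  evs <- classify_events(detect_modules(sg)[[1]], sg)
  ed <- lsvquant:::sg_edges(sg)
  set.seed(14)
  for (i in 1:50) {
    quant <- data.frame(type = ed$type, start = ed$start, end = ed$end,
                        median_diff = runif(3, -0.5, 0.5),
                        iqr1 = runif(3, 0, 0.3), iqr2 = runif(3, 0, 0.3),
                        p_welch = runif(3), p_mwu = runif(3),
                        p_tnom = runif(3), p_infoscore = runif(3))
    f <- flag_events(evs, quant)
    expect_false(f[[1]]$changing && f[[1]]$nonchanging)
  }
})

test_that("every surviving LSV edge lands in exactly one module's events", {
  panel <- toy_gene_panel()
  truth <- make_annotation(panel)
  for (g in panel) {
    sg <- truth$splicegraphs[[g$gene_id]]
    med <- edge_medians_for(sg)
    view <- decomplexify(sg, med, 0.05)
    mods <- detect_modules(view)
    lsv_edges <- unique(do.call(rbind, lapply(define_lsvs(view),
                                              function(l) l$edges)))
    covered <- unique(do.call(rbind, lapply(mods, function(m) {
      evs <- classify_events(m, view, full_sg = sg, edge_medians = med)
      do.call(rbind, lapply(evs, function(e) rbind(e$inclusion, e$exclusion)))
    })))
    for (k in seq_len(nrow(lsv_edges))) {
      hit <- covered$type == lsv_edges$type[k] &
        covered$start == lsv_edges$start[k] &
        covered$end == lsv_edges$end[k]
      expect_true(any(hit), info = sprintf("%s %s:%d-%d", g$gene_id,
                                           lsv_edges$type[k],
                                           lsv_edges$start[k],
                                           lsv_edges$end[k]))
    }
  }
})
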