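test_that("annotation parsing merges transcripts into the minimal splicegraph", {
  g <- toy_gene("gA", "chr1", "+",
                isoforms = list(exon_mat(c(0, 400), c(1000, 1400),
                                         c(2000, 2400)),
                                exon_mat(c(0, 400), c(2000, 2400))),
                abundance = c(1, 1))
  truth <- make_annotation(list(g))
  sg <- truth$splicegraphs[["gA"]]
  expect_equal(nrow(sg$exons), 3)
  expect_equal(nrow(sg$junctions), 3)
  expect_equal(nrow(sg$introns), 0)
  expect_true(all(sg$exons$annotated))
  validate_splicegraph(sg)
})

test_that("a transcript exon spanning another's junction is split into a retained intron", {
  g <- toy_gene("gB", "chr1", "+",
                isoforms = list(exon_mat(c(0, 400), c(1000, 1400)),
                                exon_mat(c(0, 1400))),
                abundance = c(1, 1))
  sg <- make_annotation(list(g))$splicegraphs[["gB"]]
  expect_equal(nrow(sg$exons), 2)
  expect_equal(sg$introns$start, 400)
  expect_equal(sg$introns$end, 1000)
  expect_true(sg$introns$annotated)
  # the junction connects two different exons after the split
  validate_splicegraph(sg)
})

test_that("generator round trip: parsed structure matches the panel's bookkeeping", {
  panel <- toy_gene_panel()
  truth <- make_annotation(panel)
  expect_length(truth$splicegraphs, length(panel))
  # per archetype: expected exon/junction/intron counts
  expected <- list(
    CE = c(3, 3, 0), IR = c(2, 1, 1), MXE = c(4, 4, 0), A3SS = c(2, 2, 0),
    A5SS = c(2, 2, 0), TCE = c(4, 4, 0), AFE = c(4, 3, 0), ALE = c(4, 3, 0))
  for (g in panel) {
    sg <- truth$splicegraphs[[g$gene_id]]
    exp_counts <- expected[[names(g$planted)[1]]]
    expect_equal(c(nrow(sg$exons), nrow(sg$junctions), nrow(sg$introns)),
                 exp_counts, info = g$gene_id)
    validate_splicegraph(sg)
  }
})

test_that("gene with no exons is skipped with a warning", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t100\t.\t+\t.\tID=gEmpty",
               "chr1\ttoy\tgene\t200\t700\t.\t+\t.\tID=gOK",
               "chr1\ttoy\tmRNA\t200\t700\t.\t+\t.\tID=t1;Parent=gOK",
               "chr1\ttoy\texon\t200\t400\t.\t+\t.\tID=e1;Parent=t1",
               "chr1\ttoy\texon\t600\t700\t.\t+\t.\tID=e2;Parent=t1"),
             path)
  expect_warning(sgs <- parse_annotation(path), "no exons")
  expect_named(sgs, "gOK")
})

test_that("malformed hierarchy raises a structured error naming the record", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t700\t.\t+\t.\tID=g1",
               "chr1\ttoy\tmRNA\t1\t700\t.\t+\t.\tID=t1;Parent=gMissing"),
             path)
  expect_error(parse_annotation(path), "t1")
})

test_that("junction-to-gene assignment honours the three priority tiers", {
  gA <- cassette_sg("A")
  # gene B overlaps A's span but lacks the junction; exons within 100 bp
  gB <- splicegraph("B", "chr1", "+",
                    exons = data.frame(start = c(300, 2100),
                                       end = c(500, 2300),
                                       annotated = TRUE,
                                       denovo_extended = FALSE))
  gC <- splicegraph("C", "chr1", "+",
                    exons = data.frame(start = 0, end = 5000,
                                       annotated = TRUE,
                                       denovo_extended = FALSE))
  # tier 1 beats containment: junction annotated in A, inside B and C too
  expect_equal(assign_junction_to_gene(list(start = 400, end = 2000),
                                       list(gA, gB, gC)), "A")
  # tier 2 beats tier 3: both ends within 400 bp of B's exons
  expect_equal(assign_junction_to_gene(list(start = 600, end = 2050),
                                       list(gB, gC)), "B")
  # one end farther than 400 bp -> only containment matches
  expect_equal(assign_junction_to_gene(list(start = 1000, end = 4900),
                                       list(gB, gC)), "C")
  # no tier matches
  expect_true(is.na(assign_junction_to_gene(list(start = 7000, end = 8000),
                                            list(gA, gB, gC))))
})

test_that("tie within a tier breaks by boundary midpoint then gene id", {
  g1 <- splicegraph("zeta", "chr1", "+",
                    exons = data.frame(start = 0, end = 3000,
                                       annotated = TRUE,
                                       denovo_extended = FALSE))
  g2 <- splicegraph("alpha", "chr1", "+",
                    exons = data.frame(start = 0, end = 3000,
                                       annotated = TRUE,
                                       denovo_extended = FALSE))
  # same boundaries -> lexicographic id
  expect_equal(assign_junction_to_gene(list(start = 1200, end = 1300),
                                       list(g1, g2)), "alpha")
})

test_that("de novo junctions are accepted by the reads+positions group filter", {
  sg <- cassette_sg()
  groups <- list(build_group("G", c("e1", "e2"), min_experiments = 2))
  ev_pass <- data.frame(experiment = c("e1", "e2"), type = "junction",
                        start = 420, end = 1000, reads = 6, positions = 4)
  thr <- build_thresholds(min_denovo_reads = 5, min_denovo_pos = 3)
  sg2 <- update_splicegraph(sg, ev_pass, groups, thr)
  expect_true(any(sg2$junctions$start == 420 & !sg2$junctions$annotated))

  # positions filter fails despite many reads
  ev_fail <- data.frame(experiment = c("e1", "e2"), type = "junction",
                        start = 440, end = 1000, reads = 100, positions = 1)
  sg3 <- update_splicegraph(sg, ev_fail, groups, thr)
  expect_false(any(sg3$junctions$start == 440))

  # only one of two required experiments passes
  ev_half <- data.frame(experiment = c("e1", "e2"), type = "junction",
                        start = 450, end = 1000,
                        reads = c(6, 1), positions = c(4, 1))
  sg4 <- update_splicegraph(sg, ev_half, groups, thr)
  expect_false(any(sg4$junctions$start == 450))
})

test_that("accepted junction endpoints extend exons within 400 bp, else new exon", {
  sg <- cassette_sg()
  groups <- list(build_group("G", "e1", min_experiments = 1))
  # donor 50 bp past exon 1 end -> exon extended
  ev <- data.frame(experiment = "e1", type = "junction", start = 450,
                   end = 2000, reads = 10, positions = 5)
  sg2 <- update_splicegraph(sg, ev, groups)
  expect_equal(sg2$exons$end[1], 450)
  expect_true(sg2$exons$denovo_extended[1])
  validate_splicegraph(sg2)
  # acceptor 500 bp before the nearest exon start -> de novo exon created
  ev2 <- data.frame(experiment = "e1", type = "junction", start = 400,
                    end = 1500, reads = 10, positions = 5)
  sg3 <- update_splicegraph(sg, ev2, groups)
  expect_true(any(!sg3$exons$annotated))
  validate_splicegraph(sg3)
})

test_that("update is idempotent on evidence already incorporated", {
  sg <- cassette_sg()
  groups <- list(build_group("G", "e1", min_experiments = 1))
  ev <- data.frame(experiment = "e1", type = "junction", start = 420,
                   end = 1000, reads = 10, positions = 5)
  sg1 <- update_splicegraph(sg, ev, groups)
  sg2 <- update_splicegraph(sg1, ev, groups)
  expect_identical(sg1, sg2)
  # annotated evidence is a no-op too
  ev_ann <- data.frame(experiment = "e1", type = "junction", start = 400,
                       end = 1000, reads = 10, positions = 5)
  expect_identical(update_splicegraph(sg, ev_ann, groups), sg)
})

test_that("accepted de novo exon boundary splits overlapping introns", {
  g <- toy_gene("gI", "chr1", "+",
                isoforms = list(exon_mat(c(0, 400), c(1000, 1400)),
                                exon_mat(c(0, 1400))),
                abundance = c(1, 1))
  sg <- make_annotation(list(g))$splicegraphs[["gI"]]
  groups <- list(build_group("G", "e1", min_experiments = 1))
  # de novo junction landing mid-intron creates an exon inside the intron
  ev <- data.frame(experiment = "e1", type = "junction",
                   start = 400, end = 700, reads = 10, positions = 5)
  sg2 <- update_splicegraph(sg, ev, groups)
  expect_gte(nrow(sg2$introns), 1)
  expect_true(all(sg2$introns$end <= 1000 | sg2$introns$start >= 700))
  validate_splicegraph(sg2)
})

test_that("simplifier flags consistently low edges and only those", {
  sg <- cassette_sg()
  # minor edge J13: source ratio 2/100, target ratio 2/52
  rates <- data.frame(group = "G1",
                      type = "junction",
                      start = c(400, 400, 1400),
                      end = c(1000, 2000, 2000),
                      rate = c(98, 2, 50))
  sg2 <- simplify_splicegraph(sg, rates, threshold = 0.05)
  expect_true(sg2$junctions$simplified[sg2$junctions$end == 2000 &
                                         sg2$junctions$start == 400])
  expect_equal(sum(sg2$junctions$simplified), 1)

  # a second group where the edge is well used -> not simplified
  rates2 <- rbind(rates,
                  data.frame(group = "G2", type = "junction",
                             start = c(400, 400, 1400),
                             end = c(1000, 2000, 2000),
                             rate = c(50, 30, 50)))
  sg3 <- simplify_splicegraph(sg, rates2, threshold = 0.05)
  expect_false(any(sg3$junctions$simplified))
})

test_that("simplifier: threshold 0 is the identity and raising it is monotone", {
  sg <- cassette_sg()
  rates <- data.frame(group = "G1", type = "junction",
                      start = c(400, 400, 1400), end = c(1000, 2000, 2000),
                      rate = c(98, 2, 50))
  expect_identical(simplify_splicegraph(sg, rates, 0), sg)
  prev <- rep(FALSE, 3)
  for (thr in c(0.01, 0.05, 0.2, 0.5)) {
    cur <- simplify_splicegraph(sg, rates, thr)$junctions$simplified
    expect_true(all(cur[prev]), info = sprintf("threshold %.2f", thr))
    prev <- cur
  }
})

test_that("LSV definition matches the cassette-exon contract", {
  sg <- cassette_sg()
  lsvs <- define_lsvs(sg)
  expect_length(lsvs, 2)
  dirs <- vapply(lsvs, `[[`, character(1), "direction")
  expect_setequal(dirs, c("source", "target"))
  src <- lsvs[[which(dirs == "source")]]
  expect_equal(src$ref_exon, c(0, 400))
  expect_equal(nrow(src$edges), 2)
  # simplifying the skip junction drops both splits below two edges
  sg$junctions$simplified[sg$junctions$start == 400 &
                            sg$junctions$end == 2000] <- TRUE
  expect_length(define_lsvs(sg), 0)
})

test_that("an intron and junction between the same exons form two LSVs", {
  sg <- splicegraph(
    "g", "chr1", "+",
    exons = data.frame(start = c(0, 1000), end = c(400, 1400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(start = 400, end = 1000, annotated = TRUE,
                           simplified = FALSE),
    introns = data.frame(start = 400, end = 1000, annotated = TRUE,
                         simplified = FALSE))
  lsvs <- define_lsvs(sg)
  expect_length(lsvs, 2)
  for (l in lsvs) {
    expect_setequal(l$edges$type, c("junction", "intron"))
  }
})

test_that("source/target orientation flips with strand", {
  lsvs_fwd <- define_lsvs(cassette_sg(strand = "+"))
  lsvs_rev <- define_lsvs(cassette_sg(strand = "-"))
  ref_of <- function(lsvs, dir) {
    l <- lsvs[[which(vapply(lsvs, `[[`, character(1), "direction") == dir)]]
    l$ref_exon
  }
  expect_equal(ref_of(lsvs_fwd, "source"), c(0, 400))
  expect_equal(ref_of(lsvs_rev, "source"), c(2000, 2400))
})

test_that("every edge appears in at most two LSVs gene-wide", {
  panel <- toy_gene_panel()
  truth <- make_annotation(panel)
  for (sg in truth$splicegraphs) {
    seen <- list()
    for (lsv in define_lsvs(sg)) {
      for (k in seq_len(nrow(lsv$edges))) {
        key <- paste(lsv$edges$type[k], lsv$edges$start[k],
                     lsv$edges$end[k])
        seen[[key]] <- c(seen[[key]], lsv$direction)
      }
    }
    for (key in names(seen)) {
      expect_lte(length(seen[[key]]), 2)
      expect_equal(length(unique(seen[[key]])), length(seen[[key]]))
    }
  }
})

test_that("splicegraph TSV container round-trips and rejects wrong versions", {
  panel <- toy_gene_panel()
  truth <- make_annotation(panel[c(1, 6, 9)])
  path <- tempfile(fileext = ".tsv")
  write_splicegraph_tsv(truth$splicegraphs, path)
  back <- read_splicegraph_tsv(path)
  expect_equal(back[order(names(back))],
               truth$splicegraphs[order(names(truth$splicegraphs))])
  lines <- readLines(path)
  lines[1] <- "#splicegraph_version: 99"
  writeLines(lines, path)
  expect_error(read_splicegraph_tsv(path), "version mismatch")
})
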