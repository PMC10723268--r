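# Anchor annotation, interaction categories, censuses and the
# p300-only/H3K27me3 anchoring fraction.

sizes <- c(chr1 = 1e6)
empty_peaks <- bed_to_gr(character(0), integer(0), integer(0))

test_that("boundary windows flank TAD edges and clip at zero", {
  tads <- bed_to_gr(c("chr1", "chr1"), c(100000, 0), c(500000, 100000),
                    sizes = sizes, name = c("t1", "t2"))
  bd <- tad_boundaries(tads, 5000, sizes)
  expect_equal(length(bd$left) + length(bd$right), 4L)
  b1 <- gr_to_bed(bd$left[1])
  expect_equal(c(b1$start, b1$end), c(95000, 105000))
  r1 <- gr_to_bed(bd$right[1])
  expect_equal(c(r1$start, r1$end), c(495000, 505000))
  b2 <- gr_to_bed(bd$left[2])   # TAD starting at 0 clips to (0, flank)
  expect_equal(c(b2$start, b2$end), c(0, 5000))
})

test_that("merge_loops collapses near-duplicates and respects the slack", {
  a <- loop_set(bed_to_gr("chr1", 0, 10000), bed_to_gr("chr1", 50000, 60000))
  merged <- merge_loops(list(a, a), slack = 5000)
  expect_equal(length(merged), 1L)
  # offset by slack + 1 at one anchor: both kept
  b <- loop_set(bed_to_gr("chr1", 5001, 15001), bed_to_gr("chr1", 50000, 60000))
  expect_equal(length(merge_loops(list(a, b), slack = 5000)), 2L)
  # random duplicated sets match the brute-force clustering oracle
  set.seed(31)
  n <- 60
  s1 <- sample.int(900000, n)
  s2 <- s1 + sample(20000:50000, n, replace = TRUE)
  jitter <- sample(-3000:3000, n, replace = TRUE)
  df <- data.frame(chrom1 = "chr1", start1 = c(s1, s1 + jitter),
                   end1 = c(s1, s1 + jitter) + 1000,
                   chrom2 = "chr1", start2 = c(s2, s2),
                   end2 = c(s2, s2) + 1000)
  ls <- loop_set(bed_to_gr(df$chrom1, df$start1, df$end1),
                 bed_to_gr(df$chrom2, df$start2, df$end2))
  got <- merge_loops(ls, slack = 2000)
  expect_equal(length(got), length(oracle_merge_loops(df, 2000)))
})

test_that("anchor annotation applies promoter > terminator > gene body", {
  g <- make_gene("chr1", 50000, 150000, "+", gene_id = "gA", sizes = sizes)
  anchor <- bed_to_gr("chr1", 48000, 52000)
  ann <- annotate_anchors(anchor, g, empty_peaks, empty_peaks)
  expect_equal(ann$gene_feature, "promoter")   # TSS window 49000-51000
  expect_equal(ann$gene_ids[[1]], "gA")
  body <- annotate_anchors(bed_to_gr("chr1", 80000, 84000), g,
                           empty_peaks, empty_peaks)
  expect_equal(body$gene_feature, "gene_body")
  term <- annotate_anchors(bed_to_gr("chr1", 146000, 152000), g,
                           empty_peaks, empty_peaks)
  expect_equal(term$gene_feature, "terminator")  # TES window 144999-154999
  p300 <- bed_to_gr("chr1", 700000, 700400)
  desert <- annotate_anchors(bed_to_gr("chr1", 699000, 701000), g,
                             p300, empty_peaks)
  expect_equal(desert$gene_feature, "intergenic")
  expect_true(desert$has_p300_only)
  expect_equal(desert$gene_ids[[1]], character(0))
})

test_that("interaction labels are symmetric with marks taking precedence", {
  ann <- function(feature, p300 = FALSE, me3 = FALSE)
    data.frame(gene_feature = feature, gene_ids = I(list("g")),
               has_p300_only = p300, has_h3k27me3 = me3)
  expect_equal(classify_interaction(ann("promoter"), ann("gene_body")),
               "Genebody-Promoter")
  expect_equal(classify_interaction(ann("intergenic", p300 = TRUE),
                                    ann("promoter", me3 = TRUE)),
               "H3K27me3-p300only")
  set.seed(32)
  feats <- c("promoter", "terminator", "gene_body", "intergenic")
  for (k in 1:25) {
    a1 <- ann(sample(feats, 1), sample(c(TRUE, FALSE), 1),
              sample(c(TRUE, FALSE), 1))
    a2 <- ann(sample(feats, 1), sample(c(TRUE, FALSE), 1),
              sample(c(TRUE, FALSE), 1))
    expect_equal(classify_interaction(a1, a2), classify_interaction(a2, a1))
  }
})

test_that("census counts conserve pairs and mark_fraction matches its rule", {
  cats <- c(rep("Genebody-Promoter", 3), "Promoter-Promoter")
  cen <- interaction_census(cats)
  expect_equal(unname(cen["Genebody-Promoter"]), 3L)
  expect_equal(sum(cen), 4L)
  expect_equal(interaction_census(character(0)), integer(0))

  flags <- function(p, m) data.frame(gene_feature = "intergenic",
                                     gene_ids = I(list(character(0))),
                                     has_p300_only = p, has_h3k27me3 = m)
  a1 <- do.call(rbind, c(lapply(1:2, function(i) flags(TRUE, FALSE)),
                         lapply(1:22, function(i) flags(FALSE, FALSE))))
  a2 <- do.call(rbind, c(lapply(1:2, function(i) flags(FALSE, TRUE)),
                         lapply(1:22, function(i) flags(FALSE, FALSE))))
  mf <- mark_fraction(a1, a2)
  expect_equal(mf$percent, 8.33)      # 2 qualifying of 24
  expect_equal(mf$n_qualifying, 2L)
  none <- mark_fraction(a1[3:24, ], a2[3:24, ])
  expect_equal(none$fraction, 0)
  expect_error(mark_fraction(a1[0, ], a2[0, ]), "zero pairs")
  # same-anchor co-occurrence only counts when enabled
  co1 <- flags(TRUE, TRUE)
  co2 <- flags(FALSE, FALSE)
  expect_equal(mark_fraction(co1, co2)$fraction, 0)
  expect_equal(mark_fraction(co1, co2, same_anchor = TRUE)$fraction, 1)
})

test_that("loop census on synthetic data matches the planted composition", {
  ds <- default_dataset()
  p300_only <- derive_p300_only(ds$peaks$p300, ds$peaks$h3k27ac, 1000,
                                ds$sizes)
  ann <- annotate_loops(ds$loops, ds$genes, p300_only, ds$peaks$h3k27me3)
  expect_equal(sum(ann$census), length(ds$loops))
  expect_equal(unname(ann$census["H3K27me3-p300only"]),
               length(ds$truth$planted_loop_ids))
  expect_equal(ann$mark_fraction$fraction,
               length(ds$truth$planted_loop_ids) / length(ds$loops))
  # census is invariant to pair order
  perm <- sample(length(ds$loops))
  ann_p <- annotate_loops(ds$loops[perm], ds$genes, p300_only,
                          ds$peaks$h3k27me3)
  expect_equal(ann_p$census, ann$census)
})
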