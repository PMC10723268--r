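# Interval model, BED-family IO and the interval algebra.

sizes10k <- c(chr1 = 10000)

test_that("BED dialect readers map fields and report malformed lines", {
  bed3 <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200", "chr1\t300\t400"), bed3)
  gr <- read_intervals(bed3, "bed3")
  expect_equal(gr_to_bed(gr)$start, c(100, 300))
  expect_equal(gr_to_bed(gr)$strand, c(".", "."))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tpk1\t800\t.\t7.5\t-1\t-1\t50", np)
  pk <- read_intervals(np, "narrowPeak")
  expect_equal(pk$score, 7.5)          # signalValue column stored as score
  expect_equal(pk$summit, 50L)

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100", bad)
  expect_error(read_intervals(bad, "bed3"), "line 1")
  writeLines(c("# c", "chr1\t100\t200\tx\t0\tz"), bad)
  expect_error(read_intervals(bad, "bed6"), "strand")
})

test_that("readers handle gzip and round-trip through the writers", {
  gr <- bed_to_gr(c("chr1", "chr1"), c(10, 500), c(120, 900),
                  c("+", "-"), name = c("a", "b"), score = c(1.5, 2.5))
  f <- tempfile(fileext = ".bed")
  write_intervals(gr, f, "bed6")
  back <- read_intervals(f, "bed6")
  expect_equal(gr_to_bed(back), gr_to_bed(gr))
  expect_equal(back$score, gr$score)
  expect_equal(back$name, gr$name)

  gz <- tempfile(fileext = ".bed.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(f), con)
  close(con)
  expect_equal(gr_to_bed(read_intervals(gz, "bed6")), gr_to_bed(gr))
})

test_that("BED6 import agrees with rtracklayer on the same file", {
  skip_if_not_installed("rtracklayer")
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpeak1\t5\t+", "chr2\t0\t50\tpeak2\t7\t-"), f)
  mine <- read_intervals(f, "bed6")
  ref <- sort(rtracklayer::import(f), ignore.strand = TRUE)
  expect_equal(gr_to_bed(mine)[c("chrom", "start", "end", "strand")],
               gr_to_bed(ref)[c("chrom", "start", "end", "strand")])
  expect_equal(mine$score, ref$score)
})

test_that("BEDPE loops are canonically ordered and inter-chromosomal flagged", {
  f <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t0\t10000\tchr1\t50000\t60000",
               "chr1\t50000\t60000\tchr1\t0\t10000",
               "chr1\t0\t10000\tchr2\t0\t10000"), f)
  lp <- read_pairs(f)
  expect_equal(length(lp), 3L)
  d <- as.data.frame(lp)
  # reversed record collapses onto the same canonical anchors
  expect_equal(d[1, c("start1", "start2")], d[2, c("start1", "start2")],
               ignore_attr = TRUE)
  expect_equal(d$inter_chromosomal, c(FALSE, FALSE, TRUE))
  rt <- tempfile()
  write_pairs(lp, rt)
  expect_equal(as.data.frame(read_pairs(rt))[, 1:6], d[, 1:6])
})

test_that("gene models give strand-aware TSS/TES and expand BED12 blocks", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000\tgeneA\t0\t+",
               "chr1\t1000\t5000\tgeneB\t0\t-"), f)
  g <- read_genes(f)
  expect_equal(tss_position(g), c(1000, 4999))
  expect_equal(tes_position(g), c(4999, 1000))

  b12 <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t3100\tgeneC\t0\t+\t1000\t1000\t0\t3\t100,100,100\t0,1000,2000",
             b12)
  gc <- read_genes(b12)
  ex <- gc$exons[[1]]
  expect_equal(length(ex), 3L)
  # per-base coverage of expanded exons matches the block definition
  bits <- logical(3200)
  for (k in seq_along(ex)) bits[IRanges::start(ex)[k]:IRanges::end(ex)[k]] <- TRUE
  expected <- logical(3200)
  for (s in c(1000, 2000, 3000)) expected[(s + 1):(s + 100)] <- TRUE
  expect_equal(bits, expected)

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t5000\tgeneD\t0\t.", bad)
  expect_error(read_genes(bad), "strand")
})

test_that("expression reader resolves duplicates by max TPM and rejects negatives", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tTPM", "gA\t10.0", "gB\t0.0"), f)
  expect_equal(nrow(read_expression(f)), 2L)
  writeLines(c("gene_id\tTPM", "gA\t1.0", "gA\t3.0"), f)
  expect_message(tab <- read_expression(f), "duplicate")
  expect_equal(tab$tpm[tab$gene_id == "gA"], 3.0)
  writeLines(c("gene_id\tTPM", "gC\t-1"), f)
  expect_error(read_expression(f), "negative")
})

test_that("slop extends, clips and composes", {
  gr <- bed_to_gr("chr1", 1000, 1500)
  out <- gr_to_bed(slop(gr, 1000, sizes10k))
  expect_equal(c(out$start, out$end), c(0, 2500))
  expect_equal(gr_to_bed(slop(gr, 0, sizes10k)), gr_to_bed(gr))
  hi <- gr_to_bed(slop(bed_to_gr("chr1", 9500, 9800), 1000, sizes10k))
  expect_equal(c(hi$start, hi$end), c(8500, 10000))
  expect_error(slop(bed_to_gr("chrX", 0, 10), 5, sizes10k), "chrX")
  # composition when no clipping occurs
  mid <- bed_to_gr("chr1", 4000, 4200)
  expect_equal(gr_to_bed(slop(slop(mid, 300, sizes10k), 200, sizes10k)),
               gr_to_bed(slop(mid, 500, sizes10k)))
})

test_that("overlap predicate is half-open and matches the per-base oracle", {
  b <- bed_to_gr("chr1", 150, 300)
  expect_true(overlaps_any(bed_to_gr("chr1", 100, 200), b))
  expect_false(overlaps_any(bed_to_gr("chr1", 100, 200),
                            bed_to_gr("chr1", 200, 300)))
  set.seed(11)
  len <- 10000
  for (rep in 1:5) {
    a <- random_intervals(100, "toy", len, 500)
    bset <- random_intervals(20, "toy", len, 500)
    got <- overlaps_any(a, bset)
    ab <- gr_to_bed(a)
    want <- vapply(seq_len(nrow(ab)), function(i)
      oracle_overlaps("toy", ab$start[i], ab$end[i], bset, len), logical(1))
    expect_identical(got, want)
  }
})

test_that("filter_nonoverlapping keeps whole intervals and partitions its input", {
  a <- bed_to_gr(c("chr1", "chr1"), c(5000, 12000), c(5200, 12300))
  b <- bed_to_gr("chr1", 9900, 12100)
  kept <- filter_nonoverlapping(a, b)
  expect_equal(gr_to_bed(kept)$start, 5000)
  expect_equal(length(filter_nonoverlapping(a, bed_to_gr(character(0),
    integer(0), integer(0)))), 2L)
  set.seed(12)
  x <- random_intervals(200, "toy", 50000)
  y <- random_intervals(50, "toy", 50000)
  expect_equal(length(filter_nonoverlapping(x, y)) + sum(overlaps_any(x, y)),
               length(x))
})

test_that("merge_intervals unions book-ended runs and matches bit coverage", {
  m <- merge_intervals(bed_to_gr(c("chr1", "chr1"), c(0, 5), c(10, 20)))
  expect_equal(gr_to_bed(m)[, c("start", "end")],
               data.frame(start = 0, end = 20))
  disjoint <- bed_to_gr(c("chr1", "chr1"), c(0, 100), c(10, 120))
  expect_equal(gr_to_bed(merge_intervals(disjoint))[, c("start", "end")],
               gr_to_bed(disjoint)[, c("start", "end")])
  set.seed(13)
  for (rep in 1:3) {
    x <- random_intervals(500, "toy", 50000)
    merged <- merge_intervals(x)
    expect_equal(sum(IRanges::width(merged)),
                 sum(coverage_bits(x, "toy", 50000)))
    expect_true(all(IRanges::width(IRanges::gaps(IRanges::ranges(merged))) > 0))
  }
})
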