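# Contact-matrix IO, VC_SQRT balancing, virtual 4C and APA.

test_that("COO loading mirrors entries and validates indices", {
  f <- tempfile()
  writeLines(c("0\t0\t4", "0\t1\t2", "1\t1\t4"), f)
  cm <- load_contact_matrix(f, "chr1", 25000, n_bins = 2)
  expect_equal(cm$matrix, matrix(c(4, 2, 2, 4), 2))
  # empty file: zero matrix of the requested size
  writeLines(character(0), f)
  expect_equal(load_contact_matrix(f, "chr1", 25000, n_bins = 3)$matrix,
               matrix(0, 3, 3))
  writeLines("0\t5\t1", f)
  expect_error(load_contact_matrix(f, "chr1", 25000, n_bins = 3),
               "out of range")
  writeLines(c("0\t1\t2", "1\t0\t7"), f)
  expect_error(load_contact_matrix(f, "chr1", 25000, n_bins = 2),
               "conflicting")
})

test_that("contact matrices round-trip through COO text", {
  set.seed(51)
  n <- 30
  m <- matrix(rpois(n * n, 3), n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- contact_matrix(m, "chr2", 10000)
  f <- tempfile()
  write_contact_matrix(cm, f)
  back <- load_contact_matrix(f, "chr2", 10000, n_bins = n)
  expect_equal(back$matrix, cm$matrix)
})

test_that("VC_SQRT divides by row/column coverage and preserves shape", {
  m <- matrix(c(4, 2, 2, 4), 2)
  norm <- vc_sqrt_normalize(contact_matrix(m, "chr1", 25000))
  # pre-rescale entries are m_ij / 6; rescaling is a single constant, so
  # ratios match the hand arithmetic
  expect_equal(norm$matrix[1, 1] / norm$matrix[1, 2], 2)
  expect_equal(mean(norm$matrix[norm$matrix > 0]), mean(m[m > 0]))
  expect_true(norm$normalized)
  # equal row sums: normalization is a uniform scaling
  u <- matrix(c(1, 3, 3, 1), 2)
  nu <- vc_sqrt_normalize(contact_matrix(u, "chr1", 25000))
  expect_equal(nu$matrix / u, matrix(1, 2, 2))
  # symmetry preserved on random symmetric input; zero rows untouched
  set.seed(52)
  r <- matrix(rpois(100, 4), 10)
  r <- r + t(r)
  r[3, ] <- 0
  r[, 3] <- 0
  nr <- vc_sqrt_normalize(contact_matrix(r, "chr1", 1000))
  expect_equal(nr$matrix, t(nr$matrix))
  expect_equal(nr$matrix[3, ], rep(0, 10))
  expect_equal(attr(nr, "zero_rows"), 2L)
  expect_error(vc_sqrt_normalize(contact_matrix(matrix(0, 2, 2),
                                                "chr1", 1)), "all-zero")
})

test_that("VC_SQRT is idempotent up to scale on balanced matrices", {
  m <- matrix(2, 4, 4) + diag(4)
  n1 <- vc_sqrt_normalize(contact_matrix(m, "chr1", 1000))
  n2 <- vc_sqrt_normalize(contact_matrix(n1$matrix, "chr1", 1000))
  expect_equal(n2$matrix / n1$matrix, matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("virtual 4C extracts anchor-bin row means", {
  m <- matrix(c(1, 2, 3, 2, 5, 6, 3, 6, 9), 3)
  cm <- contact_matrix(m, "chr1", 1000)
  p <- virtual_4c(cm, bed_to_gr("chr1", 1000, 2000))
  expect_equal(p$signal, c(2, 5, 6))
  p2 <- virtual_4c(cm, bed_to_gr("chr1", 0, 2000))   # bins 0-1
  expect_equal(p2$signal, colMeans(m[1:2, ]))
  # symmetry: a row profile equals the column extraction
  expect_equal(p$signal, m[, 2])
  expect_error(virtual_4c(cm, bed_to_gr("chr1", 5000, 6000)), "outside")
  expect_error(virtual_4c(cm, bed_to_gr("chr2", 0, 1000)), "chromosome")
})

test_that("virtual 4C sees planted loop enrichment over the decay baseline", {
  cfg <- synthetic_config(seed = 9, n_genes = 80, n_loops = 40,
                          n_tads = 20, n_headtail = 2L, n_pp = 1L,
                          n_pg = 1L, tad_enrichment = 1)
  ds <- generate_dataset(cfg)
  mats <- generate_contact_matrices(cfg, ds$tads, ds$truth$planted_pixels)
  px <- ds$truth$planted_pixels
  px <- px[px$chrom == "chr1", ][1, ]
  res <- cfg$resolution
  prof <- virtual_4c(mats$chr1, bed_to_gr("chr1", px$bin1 * res,
                                          (px$bin1 + 1) * res))
  d <- px$bin2 - px$bin1
  baseline <- cfg$total_contacts * (1 + d)^(-cfg$decay_alpha)
  expect_gt(prof$signal[px$bin2 + 1], 1.5 * baseline)
})

test_that("APA aggregates loop windows with the corner-ratio score", {
  # constant field with one hot pixel: score = center / corner
  n <- 60
  m <- matrix(3, n, n)
  m[15, 45] <- 9
  m[45, 15] <- 9
  cm <- contact_matrix(m, "chr1", 1000, normalized = TRUE, method = "test")
  lp <- loop_set(bed_to_gr("chr1", 14000, 15000),
                 bed_to_gr("chr1", 44000, 45000))
  res <- apa(cm, lp, window = 6)
  expect_equal(res$aggregate[7, 7], 9)
  expect_equal(res$score, 3)
  # uniform matrix scores exactly 1
  u <- contact_matrix(matrix(5, n, n), "chr1", 1000, normalized = TRUE,
                      method = "test")
  expect_equal(apa(u, lp)$score, 1)
  # near-diagonal and out-of-matrix loops are skipped with reasons
  near <- loop_set(bed_to_gr("chr1", 10000, 11000),
                   bed_to_gr("chr1", 15000, 16000))
  edge <- loop_set(bed_to_gr("chr1", 2000, 3000),
                   bed_to_gr("chr1", 58000, 59000))
  both <- merge_loops(list(lp, near, edge), slack = 0)
  res2 <- apa(cm, both, window = 6)
  expect_equal(res2$n_used, 1L)
  expect_equal(unname(res2$skip_reasons["near_diagonal"]), 1L)
  expect_equal(unname(res2$skip_reasons["out_of_matrix"]), 1L)
  expect_error(apa(cm, near, window = 6), "no loops survived")
})

test_that("APA score is invariant to raw sequencing depth", {
  cfg <- synthetic_config(seed = 10, n_genes = 80, n_loops = 40,
                          n_tads = 20, n_headtail = 2L, n_pp = 1L,
                          n_pg = 1L)
  ds <- generate_dataset(cfg)
  mats <- generate_contact_matrices(cfg, ds$tads, ds$truth$planted_pixels)
  pl <- ds$loops[ds$loops$name %in% ds$truth$planted_loop_ids]
  s1 <- apa(lapply(mats, vc_sqrt_normalize), pl)$score
  doubled <- lapply(mats, function(cm)
    contact_matrix(cm$matrix * 2, cm$chrom, cm$resolution))
  s2 <- apa(lapply(doubled, vc_sqrt_normalize), pl)$score
  expect_equal(s1, s2, tolerance = 1e-12)
})
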