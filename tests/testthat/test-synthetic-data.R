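# Synthetic dataset generator: determinism, planted structure
# self-consistency, expression marginals and the contact model.

test_that("identical seeds reproduce the dataset, different seeds do not", {
  cfg <- synthetic_config(seed = 3, n_genes = 120, n_loops = 60,
                          n_tads = 30, n_headtail = 3L, n_pp = 2L,
                          n_pg = 2L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_equal(gr_to_bed(a$genes), gr_to_bed(b$genes))
  expect_equal(a$expression, b$expression)
  expect_equal(as.data.frame(a$loops), as.data.frame(b$loops))
  c <- generate_dataset(synthetic_config(seed = 4, n_genes = 120,
                                         n_loops = 60, n_tads = 30,
                                         n_headtail = 3L, n_pp = 2L,
                                         n_pg = 2L))
  expect_false(identical(gr_to_bed(a$genes), gr_to_bed(c$genes)))
})

test_that("planted counts follow the configuration exactly", {
  cfg <- synthetic_config(seed = 7, n_loops = 100, planted_fraction = 0.1,
                          n_genes = 150, n_tads = 30, n_headtail = 3L,
                          n_pp = 2L, n_pg = 2L)
  ds <- generate_dataset(cfg)
  expect_length(ds$truth$planted_loop_ids, 10L)
  expect_length(ds$truth$headtail_tad_ids, cfg$n_headtail)
  expect_equal(sum(ds$truth$gene_group == "repressed"), 10L)
  expect_equal(length(ds$loops), 100L)
  # TADs tile each chromosome: abutting, covering, non-nested
  tb <- gr_to_bed(ds$tads)
  for (ch in names(ds$sizes)) {
    d <- tb[tb$chrom == ch, ]
    d <- d[order(d$start), ]
    expect_equal(d$start[1], 0)
    expect_equal(d$end[nrow(d)], unname(ds$sizes[ch]))
    expect_equal(d$start[-1], d$end[-nrow(d)])
  }
})

test_that("plants are self-consistent with the downstream operations", {
  ds <- default_dataset()
  p300_only <- derive_p300_only(ds$peaks$p300, ds$peaks$h3k27ac, 1000,
                                ds$sizes)
  # every planted p300 peak survives; every common peak is removed
  expect_equal(length(p300_only), ds$truth$n_p300_only)
  expect_true(all(grepl("planted", p300_only$name)))
  # repressive anchor2 carries H3K27me3, anchor1 a surviving p300 peak
  planted <- ds$loops[ds$loops$name %in% ds$truth$planted_loop_ids]
  expect_true(all(overlaps_any(planted$anchor1, p300_only)))
  expect_true(all(overlaps_any(planted$anchor2, ds$peaks$h3k27me3)))
  # repressed genes are exactly those with a promoter inside a planted
  # H3K27me3 anchor
  prom <- promoter_windows(ds$genes, 1000)
  hit <- unique(ds$genes$gene_id[overlaps_any(prom, planted$anchor2)])
  expect_setequal(hit, ds$truth$repressed_gene_ids)
})

test_that("background log2(TPM+1) marginal matches the configured normal law", {
  cfg <- synthetic_config(seed = 11, n_genes = 600, n_loops = 60,
                          n_tads = 30, n_headtail = 3L, n_pp = 2L,
                          n_pg = 2L)
  ds <- generate_dataset(cfg)
  lg <- log2_tpm(ds$expression$tpm)
  names(lg) <- ds$expression$gene_id
  bg <- lg[ds$truth$gene_group[names(lg)] == "background"]
  expect_gt(length(bg), 500)
  expect_equal(mean(bg), cfg$expr_mu_hi, tolerance = 3 / sqrt(length(bg)))
  expect_equal(stats::sd(bg), cfg$expr_sigma, tolerance = 0.15)
})

test_that("contact matrices follow the decay model with planted enrichment", {
  cfg <- synthetic_config(seed = 5, n_genes = 80, n_loops = 40,
                          n_tads = 20, n_headtail = 2L, n_pp = 1L,
                          n_pg = 1L, tad_enrichment = 1,
                          loop_enrichment = 3)
  ds <- generate_dataset(cfg)
  mats <- generate_contact_matrices(cfg, ds$tads, ds$truth$planted_pixels)
  m <- mats$chr1$matrix
  expect_equal(m, t(m))
  expect_true(all(m == round(m)) && all(m >= 0))
  # decay: mean count at distance d within 3 standard errors of the
  # closed form N (1+d)^-alpha (loop pixels excluded)
  px <- ds$truth$planted_pixels
  px1 <- px[px$chrom == "chr1", ]
  for (d in c(1, 5, 20, 80)) {
    idx <- which(row(m) + d == col(m))
    drop <- idx[row(m)[idx] %in% (px1$bin1 + 1) &
                col(m)[idx] %in% (px1$bin2 + 1)]
    idx <- setdiff(idx, drop)
    mu <- cfg$total_contacts * (1 + d)^(-cfg$decay_alpha)
    se <- sqrt(mu / length(idx))
    expect_lt(abs(mean(m[idx]) - mu), 3 * se)
  }
  # planted pixels realize ~loop_enrichment times the decay expectation
  obs <- exp_ <- numeric(0)
  for (ch in names(mats)) {
    p <- px[px$chrom == ch, ]
    if (nrow(p) == 0) next
    obs <- c(obs, mats[[ch]]$matrix[cbind(p$bin1 + 1, p$bin2 + 1)])
    exp_ <- c(exp_, cfg$total_contacts *
                (1 + p$bin2 - p$bin1)^(-cfg$decay_alpha))
  }
  ratio <- sum(obs) / sum(exp_)
  se_r <- sqrt(sum(cfg$loop_enrichment * exp_)) / sum(exp_)
  expect_lt(abs(ratio - cfg$loop_enrichment), 4 * se_r)
})

test_that("infeasible configurations raise capacity errors, not truncation", {
  expect_error(synthetic_config(chrom_length = 1e6 + 1),
               "divide")
  expect_error(generate_dataset(synthetic_config(
    seed = 1, n_tads = 300, n_chroms = 1, chrom_length = 2e6)),
    "max_loop_dist|capacity")
  expect_error(generate_dataset(synthetic_config(
    seed = 1, n_genes = 10)), "capacity")
})

test_that("genome reflection maps windows consistently", {
  ds <- default_dataset()
  g <- ds$genes
  r <- reflect_genome(g, ds$sizes)
  expect_equal(length(r), length(g))
  # reflecting twice restores the original coordinates
  rr <- reflect_genome(r, ds$sizes)
  expect_equal(sort(gr_to_bed(rr)$start), sort(gr_to_bed(g)$start))
  # TSS maps to (len - 1 - TSS)
  gid <- g$gene_id[1]
  tss_orig <- tss_position(g[g$gene_id == gid])[1]
  tss_ref <- tss_position(r[r$gene_id == gid])
  len <- unname(ds$sizes[as.character(GenomeInfoDb::seqnames(g[1]))])
  expect_true((len - 1 - tss_orig) %in% tss_ref)
})
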