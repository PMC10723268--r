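# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles operate on per-base logical vectors over toy
# chromosomes and never call the interval algebra they check.

# logical coverage vector over BED positions 0..(len-1)
coverage_bits <- function(gr, chrom, len) {
  bits <- logical(len)
  b <- gr_to_bed(gr)
  b <- b[b$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(b))) {
    lo <- max(b$start[i], 0) + 1L
    hi <- min(b$end[i], len)
    if (lo <= hi) bits[lo:hi] <- TRUE
  }
  bits
}

# per-base overlap oracle: does interval (chrom,start,end) share a base
# with any interval in gr?
oracle_overlaps <- function(chrom, start, end, gr, len) {
  bits <- coverage_bits(gr, chrom, len)
  any(bits[(start + 1):end])
}

# random interval set on a single toy chromosome
random_intervals <- function(n, chrom = "toy", len = 50000,
                             max_width = 2000) {
  start <- sample.int(len - 1L, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  end <- pmin(start + width, len)
  bed_to_gr(rep(chrom, n), start, end,
            sizes = stats::setNames(len, chrom))
}

# brute-force slop oracle in BED arithmetic
oracle_slop <- function(gr, flank, len) {
  b <- gr_to_bed(gr)
  data.frame(start = pmax(b$start - flank, 0), end = pmin(b$end + flank, len))
}

# independent greedy first-encounter loop clustering used against
# merge_loops
oracle_merge_loops <- function(df, slack) {
  c1 <- (df$start1 + df$end1) / 2
  c2 <- (df$start2 + df$end2) / 2
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (df$chrom1[j] == df$chrom1[i] && df$chrom2[j] == df$chrom2[i] &&
          abs(c1[j] - c1[i]) <= slack && abs(c2[j] - c2[i]) <= slack) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  which(keep)
}

# single-gene GRanges fixture with explicit exon structure (BED coords)
make_gene <- function(chrom, start, end, strand, gene_id = "g1",
                      exons = NULL, cds = c(NA, NA),
                      sizes = NULL) {
  gr <- bed_to_gr(chrom, start, end, strand, sizes = sizes,
                  gene_id = gene_id)
  if (is.null(exons)) exons <- cbind(start, end)
  S4Vectors::mcols(gr)$exons <- IRanges::IRangesList(
    IRanges::IRanges(start = exons[, 1] + 1L, end = exons[, 2]))
  S4Vectors::mcols(gr)$cds_start <- cds[1]
  S4Vectors::mcols(gr)$cds_end <- cds[2]
  gr
}

# shared default synthetic dataset (seed 7), built once per session
.fixture_env <- new.env()
default_dataset <- function() {
  if (is.null(.fixture_env$ds7)) {
    cfg <- synthetic_config(seed = 7)
    .fixture_env$cfg7 <- cfg
    .fixture_env$ds7 <- generate_dataset(cfg)
  }
  .fixture_env$ds7
}
default_config <- function() {
  default_dataset()
  .fixture_env$cfg7
}
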