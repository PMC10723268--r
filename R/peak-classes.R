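# Derivation of H3K27ac-independent ("p300-only") peaks and their
# characterization: genomic-feature annotation and signal profiles around
# peak centers.

#' Derive p300-only peaks
#'
#' A p300 peak is "p300-only" when it does not overlap any H3K27ac peak
#' extended by `extend` bp on each side (default 1 kb). Whole peaks are kept
#' or dropped, never truncated.
#'
#' @param p300,h3k27ac peak `GRanges`.
#' @param extend H3K27ac extension in bp.
#' @param sizes named chromosome lengths (required when `h3k27ac` is
#'   non-empty, for clipping the extension).
#' @return Subset of `p300` disjoint from the extended H3K27ac set.
#' @export
derive_p300_only <- function(p300, h3k27ac, extend = 1000, sizes = NULL) {
  stopifnot(extend >= 0)
  if (length(h3k27ac) == 0) return(p300)
  if (is.null(sizes))
    stop("chromosome sizes are required to extend H3K27ac peaks")
  extended <- slop(h3k27ac, extend, sizes)
  out <- filter_nonoverlapping(p300, extended)
  stopifnot(!any(overlaps_any(out, extended)))
  out
}

# feature labels in precedence order
FEATURE_LEVELS <- c("promoter", "utr5", "utr3", "exon", "intron_1st",
                    "intron_other", "downstream", "intergenic")

# classify one genomic point (BED coordinate) against one gene model
point_feature_for_gene <- function(pos, gene) {
  plus <- as.character(GenomicRanges::strand(gene)) == "+"
  exons <- gene$exons[[1]]                      # 1-based closed, sorted
  base <- pos + 1L                              # 1-based base index
  in_exon <- any(base >= IRanges::start(exons) & base <= IRanges::end(exons))
  if (in_exon) {
    cds_s <- gene$cds_start
    cds_e <- gene$cds_end
    if (!is.na(cds_s) && !is.na(cds_e)) {
      if (pos < cds_s) return(if (plus) "utr5" else "utr3")
      if (pos >= cds_e) return(if (plus) "utr3" else "utr5")
    }
    return("exon")
  }
  span <- base >= GenomicRanges::start(gene) & base <= GenomicRanges::end(gene)
  if (!span) return(NA_character_)
  # intron: number in transcription order (intron 1 follows exon 1)
  n_ex <- length(exons)
  if (n_ex < 2) return(NA_character_)
  after <- sum(base > IRanges::end(exons))      # introns passed, left to right
  intron_idx <- if (plus) after else n_ex - after
  if (intron_idx == 1) "intron_1st" else "intron_other"
}

#' Annotate peaks with the genomic feature at their midpoint
#'
#' Each peak gets exactly one label, decided at its midpoint with precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > downstream > intergenic.
#' Introns are numbered in transcription order, so intron 1 of a `-` strand
#' gene is its highest-coordinate intron. UTR labels require CDS bounds
#' (BED12 thickStart/thickEnd); without CDS they collapse into `exon`.
#'
#' @param peaks peak `GRanges`.
#' @param genes gene `GRanges` from [read_genes()].
#' @param promoter_flank promoter half-width around the TSS (bp).
#' @param downstream_flank length of the downstream window past the TES (bp).
#' @return data.frame with `feature` (factor) and `gene_id` columns, one row
#'   per peak.
#' @export
annotate_features <- function(peaks, genes, promoter_flank = 1000,
                              downstream_flank = 5000) {
  if (length(genes) == 0) stop("gene list is empty")
  b <- gr_to_bed(peaks)
  mid <- (b$start + b$end) %/% 2
  points <- bed_to_gr(b$chrom, mid, mid + 1)
  prom <- promoter_windows(genes, promoter_flank)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  ds_start <- ifelse(plus, GenomicRanges::end(genes),
                     GenomicRanges::start(genes) - 1L - downstream_flank)
  down <- bed_to_gr(as.character(GenomeInfoDb::seqnames(genes)),
                    pmax(ds_start, 0), pmax(ds_start, 0) + downstream_flank,
                    gene_id = genes$gene_id)
  hit_prom <- GenomicRanges::findOverlaps(points, prom, ignore.strand = TRUE)
  hit_gene <- GenomicRanges::findOverlaps(points, genes, ignore.strand = TRUE)
  hit_down <- GenomicRanges::findOverlaps(points, down, ignore.strand = TRUE)
  feature <- rep("intergenic", length(peaks))
  gene_id <- rep(NA_character_, length(peaks))
  rank <- stats::setNames(seq_along(FEATURE_LEVELS), FEATURE_LEVELS)
  best <- rep(rank[["intergenic"]], length(peaks))
  consider <- function(i, lab, gid) {
    if (!is.na(lab) && rank[[lab]] < best[i]) {
      best[i] <<- rank[[lab]]
      feature[i] <<- lab
      gene_id[i] <<- gid
    }
  }
  for (k in seq_along(hit_prom))
    consider(S4Vectors::queryHits(hit_prom)[k], "promoter",
             prom$gene_id[S4Vectors::subjectHits(hit_prom)[k]])
  for (k in seq_along(hit_gene)) {
    i <- S4Vectors::queryHits(hit_gene)[k]
    g <- S4Vectors::subjectHits(hit_gene)[k]
    consider(i, point_feature_for_gene(mid[i], genes[g]), genes$gene_id[g])
  }
  for (k in seq_along(hit_down))
    consider(S4Vectors::queryHits(hit_down)[k], "downstream",
             down$gene_id[S4Vectors::subjectHits(hit_down)[k]])
  data.frame(feature = factor(feature, levels = FEATURE_LEVELS),
             gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Feature distribution of a peak set
#'
#' @inheritParams annotate_features
#' @return Named numeric vector of proportions over all peaks (sums to 1).
#' @export
feature_distribution <- function(peaks, genes, promoter_flank = 1000,
                                 downstream_flank = 5000) {
  if (length(peaks) == 0) stop("peak set is empty")
  ann <- annotate_features(peaks, genes, promoter_flank, downstream_flank)
  tab <- table(ann$feature)
  prop <- as.numeric(tab) / length(peaks)
  stats::setNames(prop, names(tab))
}

#' Signal profile around peak centers
#'
#' Mean bedGraph signal in fixed-width bins across `[mid - flank, mid +
#' flank)` for each peak midpoint; positions without signal contribute 0 and
#' windows extending past a chromosome end are 0-filled. Rows of the matrix
#' are sorted by mean signal in the central 10% of bins, descending
#' (recorded in the `sorted_by` attribute).
#'
#' @param signal bedGraph `GRanges` with a `score` column.
#' @param centers peak `GRanges` whose midpoints anchor the windows.
#' @param flank half-width of the window (bp).
#' @param bin_width bin size (bp); must divide `2 * flank`.
#' @return List with `matrix` (regions x bins), `mean` (column means),
#'   `offset` (bin-center offsets from the peak midpoint, bp) and
#'   `row_order` (original peak indices in displayed order).
#' @export
signal_profile <- function(signal, centers, flank = 5000, bin_width = 50) {
  if ((2 * flank) %% bin_width != 0)
    stop("bin_width must divide 2 * flank")
  n_bins <- as.integer(2 * flank / bin_width)
  cov <- GenomicRanges::coverage(signal, weight = signal$score)
  b <- gr_to_bed(centers)
  mid <- (b$start + b$end) %/% 2
  mat <- matrix(0, nrow = length(centers), ncol = n_bins)
  for (i in seq_along(centers)) {
    chrom <- b$chrom[i]
    v <- numeric(2 * flank)
    if (chrom %in% names(cov)) {
      rle <- cov[[chrom]]
      len <- length(rle)
      lo <- mid[i] - flank + 1L            # 1-based window bounds
      hi <- mid[i] + flank
      s <- max(lo, 1L)
      e <- min(hi, len)
      if (s <= e)
        v[(s - lo + 1L):(e - lo + 1L)] <- as.numeric(rle[s:e])
    }
    mat[i, ] <- colMeans(matrix(v, nrow = bin_width))
  }
  mean_profile <- colMeans(mat)
  central <- max(1L, n_bins %/% 2 - n_bins %/% 20):(n_bins %/% 2 + n_bins %/% 20 + 1L)
  ord <- order(rowMeans(mat[, central, drop = FALSE]), decreasing = TRUE)
  out <- list(matrix = mat[ord, , drop = FALSE], mean = mean_profile,
              offset = seq(-flank + bin_width / 2, flank - bin_width / 2,
                           by = bin_width),
              row_order = ord)
  attr(out, "sorted_by") <- "mean_central_signal_desc"
  out
}
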