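# Annotation of loop anchors and TAD-boundary windows against gene features
# and histone marks; interaction-category census and the
# p300-only/H3K27me3 anchoring fraction.

#' TAD boundary windows
#'
#' For a domain `[s, e)` the boundary windows are `[s - flank, s + flank)`
#' and `[e - flank, e + flank)` (default 5 kb half-width), clipped to the
#' chromosome.
#'
#' @param tads domain `GRanges`.
#' @param flank half-width in bp.
#' @param sizes optional chromosome lengths.
#' @return List with `left` and `right` `GRanges`, each parallel to `tads`
#'   and carrying `tad_id`.
#' @export
tad_boundaries <- function(tads, flank = 5000, sizes = NULL) {
  stopifnot(flank > 0)
  b <- gr_to_bed(tads)
  id <- if (!is.null(tads$name)) tads$name else paste0("tad", seq_along(tads))
  left <- window_around_point(b$chrom, b$start, flank, sizes)
  right <- window_around_point(b$chrom, b$end, flank, sizes)
  S4Vectors::mcols(left)$tad_id <- id
  S4Vectors::mcols(right)$tad_id <- id
  list(left = left, right = right)
}

#' Merge loop sets by anchor proximity
#'
#' Loops whose two anchor centers each lie within `slack` bp of an already
#' kept loop's centers collapse onto that first-encountered representative.
#'
#' @param loop_sets list of [loop_set] objects (or a single one).
#' @param slack center-to-center tolerance in bp.
#' @return A [loop_set] of representatives, in first-encounter order.
#' @export
merge_loops <- function(loop_sets, slack) {
  stopifnot(slack >= 0)
  if (inherits(loop_sets, "loop_set")) loop_sets <- list(loop_sets)
  dfs <- lapply(loop_sets, as.data.frame.loop_set)
  all <- do.call(rbind, dfs)
  if (nrow(all) == 0) return(loop_sets[[1]])
  c1 <- (all$start1 + all$end1) / 2
  c2 <- (all$start2 + all$end2) / 2
  keep <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    prior <- which(keep)
    dup <- any(all$chrom1[prior] == all$chrom1[i] &
               all$chrom2[prior] == all$chrom2[i] &
               abs(c1[prior] - c1[i]) <= slack &
               abs(c2[prior] - c2[i]) <= slack)
    keep[i] <- !dup
  }
  kept <- all[keep, , drop = FALSE]
  loop_set(bed_to_gr(kept$chrom1, kept$start1, kept$end1),
           bed_to_gr(kept$chrom2, kept$start2, kept$end2),
           score = kept$score, name = kept$name)
}

#' Annotate anchors with gene features and histone-mark flags
#'
#' The gene feature is decided by precedence promoter > terminator >
#' gene body > intergenic over all genes whose windows intersect the
#' anchor; the mark flags record a >= 1 bp overlap with the p300-only and
#' H3K27me3 peak sets and are independent of the gene feature.
#'
#' @param anchors anchor `GRanges`.
#' @param genes gene `GRanges`.
#' @param p300_only,h3k27me3 peak `GRanges` (may be empty).
#' @param promoter_flank,terminator_flank window half-widths (bp).
#' @return data.frame with `gene_feature`, `gene_ids` (list column),
#'   `has_p300_only`, `has_h3k27me3`.
#' @export
annotate_anchors <- function(anchors, genes, p300_only, h3k27me3,
                             promoter_flank = 1000, terminator_flank = 5000) {
  n <- length(anchors)
  feature <- rep("intergenic", n)
  gene_ids <- rep(list(character(0)), n)
  layers <- list(
    promoter = promoter_windows(genes, promoter_flank),
    terminator = terminator_windows(genes, terminator_flank),
    gene_body = genes)
  for (lab in rev(names(layers))) {   # apply in increasing precedence
    win <- layers[[lab]]
    hits <- GenomicRanges::findOverlaps(anchors, win, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) {
      feature[i] <- lab
      gene_ids[[i]] <- unique(win$gene_id[s[q == i]])
    }
  }
  data.frame(
    gene_feature = feature,
    gene_ids = I(gene_ids),
    has_p300_only = overlaps_any(anchors, p300_only),
    has_h3k27me3 = overlaps_any(anchors, h3k27me3),
    stringsAsFactors = FALSE)
}

DISPLAY_CLASS <- c(promoter = "Promoter", terminator = "Terminator",
                   gene_body = "Genebody", intergenic = "Intergenic")

# per-anchor display class: marks take precedence over gene features
display_class <- function(ann) {
  ifelse(ann$has_p300_only, "p300only",
         ifelse(ann$has_h3k27me3, "H3K27me3",
                DISPLAY_CLASS[ann$gene_feature]))
}

#' Interaction category of an anchor pair
#'
#' The label is the unordered pair of per-anchor display classes
#' ("p300only" if the anchor carries a p300-only peak, else "H3K27me3" if it
#' carries that mark, else its gene feature), joined with "-" in C-locale
#' sorted order so the label is symmetric in anchor order.
#'
#' @param ann1,ann2 annotation data.frames from [annotate_anchors()],
#'   row-parallel.
#' @return Character vector of category labels.
#' @export
classify_interaction <- function(ann1, ann2) {
  c1 <- display_class(ann1)
  c2 <- display_class(ann2)
  vapply(seq_along(c1), function(i)
    paste(sort(c(c1[i], c2[i]), method = "radix"), collapse = "-"),
    character(1))
}

#' Census of interaction categories
#'
#' @param categories character vector from [classify_interaction()].
#' @return Named integer vector of counts, decreasing; sums to the number of
#'   pairs.
#' @export
interaction_census <- function(categories) {
  if (length(categories) == 0) return(integer(0))
  tab <- table(categories)
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Fraction of pairs anchored by p300-only and H3K27me3 on opposite anchors
#'
#' A pair qualifies when one anchor carries a p300-only peak and the other
#' an H3K27me3 peak. With `same_anchor = TRUE` a single anchor carrying both
#' marks also qualifies (off by default).
#'
#' @param ann1,ann2 row-parallel annotation data.frames.
#' @param same_anchor also accept co-occurrence on one anchor.
#' @return List with `fraction`, `percent` (2 decimals), `n_pairs`,
#'   `n_qualifying` and the logical `qualifying` vector.
#' @export
mark_fraction <- function(ann1, ann2, same_anchor = FALSE) {
  n <- nrow(ann1)
  if (is.null(n) || n == 0) stop("mark_fraction is undefined for zero pairs")
  q <- (ann1$has_p300_only & ann2$has_h3k27me3) |
       (ann2$has_p300_only & ann1$has_h3k27me3)
  if (same_anchor)
    q <- q | (ann1$has_p300_only & ann1$has_h3k27me3) |
             (ann2$has_p300_only & ann2$has_h3k27me3)
  f <- mean(q)
  list(fraction = f, percent = round(100 * f, 2), n_pairs = n,
       n_qualifying = sum(q), qualifying = q)
}

#' Annotate and classify a loop set in one call
#'
#' @param loops a [loop_set].
#' @inheritParams annotate_anchors
#' @param same_anchor passed to [mark_fraction()].
#' @return List with `ann1`, `ann2`, `category`, `census`, `mark_fraction`.
#' @export
annotate_loops <- function(loops, genes, p300_only, h3k27me3,
                           promoter_flank = 1000, terminator_flank = 5000,
                           same_anchor = FALSE) {
  ann1 <- annotate_anchors(loops$anchor1, genes, p300_only, h3k27me3,
                           promoter_flank, terminator_flank)
  ann2 <- annotate_anchors(loops$anchor2, genes, p300_only, h3k27me3,
                           promoter_flank, terminator_flank)
  category <- classify_interaction(ann1, ann2)
  list(ann1 = ann1, ann2 = ann2, category = category,
       census = interaction_census(category),
       mark_fraction = mark_fraction(ann1, ann2, same_anchor = same_anchor))
}
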