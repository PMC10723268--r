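# Detection of head-to-tail TAD-boundary gene pairs: two same-strand genes
# at the two boundaries of one domain, the upstream gene's terminator on
# one boundary window and the downstream gene's promoter on the other.

# per-boundary gene feature with precedence P > T > G; returns list with
# feature code and contributing gene ids
boundary_feature <- function(windows, genes, promoter_flank, terminator_flank) {
  prom <- promoter_windows(genes, promoter_flank)
  term <- terminator_windows(genes, terminator_flank)
  pick <- function(layer) {
    hits <- GenomicRanges::findOverlaps(windows, layer, ignore.strand = TRUE)
    split(layer$gene_id[S4Vectors::subjectHits(hits)],
          factor(S4Vectors::queryHits(hits), levels = seq_along(windows)))
  }
  gp <- pick(prom)
  gt <- pick(term)
  gg <- pick(genes)
  feature <- character(length(windows))
  ids <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    if (length(gp[[i]])) { feature[i] <- "P"; ids[[i]] <- unique(gp[[i]]) }
    else if (length(gt[[i]])) { feature[i] <- "T"; ids[[i]] <- unique(gt[[i]]) }
    else if (length(gg[[i]])) { feature[i] <- "G"; ids[[i]] <- unique(gg[[i]]) }
    else { feature[i] <- "none"; ids[[i]] <- character(0) }
  }
  list(feature = feature, gene_ids = ids)
}

pair_label <- function(f1, f2) {
  ord <- c(P = 1L, T = 2L, G = 3L)
  ifelse(f1 == "none" | f2 == "none", NA_character_,
         ifelse(ord[f1] <= ord[f2], paste0(f1, f2), paste0(f2, f1)))
}

#' Gene-feature pairs at TAD boundaries
#'
#' Each boundary window is labelled `P` if it intersects a promoter window,
#' else `T` for a terminator window, else `G` for a gene body, else `none`.
#' TADs whose two boundaries both carry a gene feature receive a pair
#' category such as `PG`, `PT` or `PP`.
#'
#' @param tads domain `GRanges`.
#' @param genes gene `GRanges`.
#' @param promoter_flank,terminator_flank,boundary_flank window half-widths
#'   in bp.
#' @param sizes optional chromosome lengths.
#' @return data.frame with one row per TAD: `tad_id`, `left_feature`,
#'   `right_feature`, `category` (`NA` unless both boundaries carry a
#'   feature), `left_genes`, `right_genes` (list columns).
#' @export
boundary_gene_pairs <- function(tads, genes, promoter_flank = 1000,
                                terminator_flank = 5000,
                                boundary_flank = 5000, sizes = NULL) {
  bd <- tad_boundaries(tads, boundary_flank, sizes)
  left <- boundary_feature(bd$left, genes, promoter_flank, terminator_flank)
  right <- boundary_feature(bd$right, genes, promoter_flank, terminator_flank)
  data.frame(
    tad_id = bd$left$tad_id,
    left_feature = left$feature,
    right_feature = right$feature,
    category = pair_label(left$feature, right$feature),
    left_genes = I(left$gene_ids),
    right_genes = I(right$gene_ids),
    stringsAsFactors = FALSE)
}

#' Detect head-to-tail TAD-boundary gene pairs
#'
#' A pair (upstream gene, downstream gene) is reported for a TAD when both
#' genes share a strand, the upstream gene (in transcription direction) has
#' its terminator window overlapping one boundary window, and the
#' downstream gene has its promoter window overlapping the other boundary
#' window of the same TAD. For `+` genes the terminator must sit at the
#' left boundary; for `-` genes at the right (transcription runs
#' right-to-left). Isoforms sharing a gene id are tested independently and
#' deduplicated by id, one record per (TAD, upstream, downstream) triple.
#'
#' @inheritParams boundary_gene_pairs
#' @param body_as_terminator also accept a gene-body overlap (rather than
#'   only the terminator window) for the upstream gene's boundary.
#' @return data.frame with `tad_id`, `upstream_gene`, `downstream_gene`,
#'   `strand`, `category`.
#' @export
detect_head_to_tail <- function(tads, genes, promoter_flank = 1000,
                                terminator_flank = 5000,
                                boundary_flank = 5000, sizes = NULL,
                                body_as_terminator = FALSE) {
  bd <- tad_boundaries(tads, boundary_flank, sizes)
  prom <- promoter_windows(genes, promoter_flank)
  term <- terminator_windows(genes, terminator_flank)
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- tss_position(genes)
  hits_of <- function(windows, layer)
    GenomicRanges::findOverlaps(windows, layer, ignore.strand = TRUE)
  term_layer <- if (body_as_terminator) genes else term
  res <- list()
  emit <- function(tad_id, boundary, g_term, g_prom) {
    # same strand, and upstream (terminator gene) before downstream in
    # transcription direction
    for (a in g_term) for (b in g_prom) {
      if (strand[a] != strand[b]) next
      if (genes$gene_id[a] == genes$gene_id[b]) next
      up_first <- if (strand[a] == "+") tss[a] < tss[b] else tss[a] > tss[b]
      if (!up_first) next
      cat_lab <- if (!body_as_terminator ||
                     overlaps_any(boundary, term[a])) "PT" else "PG"
      res[[length(res) + 1L]] <<- data.frame(
        tad_id = tad_id,
        upstream_gene = genes$gene_id[a],
        downstream_gene = genes$gene_id[b],
        strand = strand[a], category = cat_lab, stringsAsFactors = FALSE)
    }
  }
  for (side in c("plus", "minus")) {
    # + strand: terminator at left boundary, promoter at right;
    # - strand: mirrored
    tw <- if (side == "plus") bd$left else bd$right
    pw <- if (side == "plus") bd$right else bd$left
    ht <- hits_of(tw, term_layer)
    hp <- hits_of(pw, prom)
    tmap <- split(S4Vectors::subjectHits(ht),
                  factor(S4Vectors::queryHits(ht), levels = seq_along(tw)))
    pmap <- split(S4Vectors::subjectHits(hp),
                  factor(S4Vectors::queryHits(hp), levels = seq_along(pw)))
    want <- if (side == "plus") "+" else "-"
    for (i in seq_along(tw)) {
      g_term <- tmap[[i]][strand[tmap[[i]]] == want]
      g_prom <- pmap[[i]][strand[pmap[[i]]] == want]
      if (length(g_term) && length(g_prom))
        emit(tw$tad_id[i], tw[i], g_term, g_prom)
    }
  }
  if (length(res) == 0)
    return(data.frame(tad_id = character(0), upstream_gene = character(0),
                      downstream_gene = character(0), strand = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[!duplicated(out[c("tad_id", "upstream_gene", "downstream_gene")]), ]
  rownames(out) <- NULL
  out
}

#' Scan head-to-tail pairs against an oncogene list
#'
#' @param pairs data.frame from [detect_head_to_tail()].
#' @param oncogenes character vector of gene ids (non-empty).
#' @return List with `pairs` (rows whose upstream gene is an oncogene) and
#'   `fraction` = distinct upstream oncogenes / size of the oncogene list.
#' @export
oncogene_scan <- function(pairs, oncogenes) {
  if (length(oncogenes) == 0) stop("oncogene list is empty")
  oncogenes <- unique(oncogenes)
  hit <- pairs[pairs$upstream_gene %in% oncogenes, , drop = FALSE]
  list(pairs = hit,
       fraction = length(unique(hit$upstream_gene)) / length(oncogenes))
}
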