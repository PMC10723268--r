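# Synthetic dataset generator: genes, peak sets, TADs, loops, expression
# and distance-decay contact matrices with planted structure (repressive
# p300-only/H3K27me3 loops, active p300-only/promoter loops, head-to-tail
# boundary gene pairs, promoter-repression expression deficits) plus the
# ground truth needed for recovery tests.

#' Synthetic dataset configuration
#'
#' Defaults describe a desk-scale genome: two 10 Mb chromosomes binned at
#' 25 kb, 40 TADs, 400 genes, 200 loops of which a fraction
#' `planted_fraction` are repressive p300-only/H3K27me3 anchor pairs (and
#' an equal `active_fraction` are p300-only/active-promoter pairs so the
#' expression comparison has both groups), 5 head-to-tail boundary gene
#' pairs, and a two-group normal expression model on the log2(TPM+1) scale
#' (background mean `expr_mu_hi`, repressed deficit `expr_delta`, sd
#' `expr_sigma`). Contact matrices follow
#' `E[C_ij] = N (1+|i-j|)^(-alpha)` times TAD (`tad_enrichment`) and
#' planted-pixel (`loop_enrichment`) factors, with Poisson counts.
#'
#' @param seed integer RNG seed driving every placement.
#' @param n_chroms,chrom_length,resolution genome shape (resolution must
#'   divide `chrom_length`).
#' @param n_genes,n_tads,n_loops,n_headtail structure counts.
#' @param n_pp,n_pg TADs planted with promoter-promoter and
#'   promoter-genebody boundary gene pairs (so the boundary-category
#'   expression comparison has its PP/PG/PT groups).
#' @param planted_fraction fraction of loops planted as repressive
#'   p300-only/H3K27me3 pairs.
#' @param active_fraction fraction of loops planted as p300-only/unmarked
#'   promoter pairs.
#' @param expr_mu_hi,expr_sigma,expr_delta expression model parameters
#'   (log2(TPM+1) scale).
#' @param decay_alpha,loop_enrichment,tad_enrichment,total_contacts contact
#'   model parameters.
#' @param collision_free forbid accidental mark/window coincidences so
#'   recovery is exact.
#' @param n_common_peaks,n_extra_ac,n_extra_me3 background peak counts.
#' @param min_loop_dist,max_loop_dist anchor separation range in bins.
#' @param min_tad_bins minimum TAD width in bins.
#' @param gene_length_range gene length range (bp), drawn log-uniformly.
#' @param isoform_fraction fraction of background genes given a second
#'   isoform with an internal alternative promoter.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 10e6,
                             resolution = 25000, n_genes = 400L,
                             n_tads = 60L, n_loops = 200L,
                             planted_fraction = 0.1, active_fraction = 0.1,
                             n_headtail = 5L, n_pp = 5L, n_pg = 8L,
                             expr_mu_hi = 4,
                             expr_sigma = 1, expr_delta = 1,
                             decay_alpha = 1, loop_enrichment = 3,
                             tad_enrichment = 1.5, total_contacts = 2000,
                             collision_free = TRUE, n_common_peaks = 50L,
                             n_extra_ac = 50L, n_extra_me3 = 30L,
                             min_loop_dist = 60L, max_loop_dist = 200L,
                             min_tad_bins = 8L,
                             gene_length_range = c(2000, 100000),
                             isoform_fraction = 0.1) {
  cfg <- as.list(environment())
  if (chrom_length %% resolution != 0)
    stop("resolution must divide chrom_length")
  counts <- c(n_chroms, n_genes, n_tads, n_loops, n_headtail, n_pp, n_pg,
              n_common_peaks, n_extra_ac, n_extra_me3)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (planted_fraction < 0 || planted_fraction > 1 ||
      active_fraction < 0 || active_fraction > 1)
    stop("planted/active fractions must lie in [0, 1]")
  if (expr_delta < 0) stop("expr_delta must be >= 0")
  if (loop_enrichment < 1 || tad_enrichment < 1)
    stop("enrichment factors must be >= 1")
  bins <- chrom_length / resolution
  if (max_loop_dist >= bins - 16)
    stop("max_loop_dist too large for the chromosome")
  cfg$n_planted <- as.integer(round(planted_fraction * n_loops))
  cfg$n_active <- as.integer(round(active_fraction * n_loops))
  if (cfg$n_planted + cfg$n_active > n_loops)
    stop("planted + active loops exceed n_loops")
  structure(cfg, class = "synthetic_config")
}

# deterministic sub-seed for a named stage
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

rlog_uniform <- function(n, range) {
  round(exp(stats::runif(n, log(range[1]), log(range[2]))))
}

# random exon structure covering [start, end) (BED coords); first exon
# starts at `start`, last ends at `end`
make_exons <- function(start, end) {
  width <- end - start
  n_ex <- if (width < 5000) 1L else sample(1:5, 1)
  if (n_ex == 1L) return(IRanges::IRanges(start = start + 1L, end = end))
  inner <- sort(sample(seq(start + 200L, end - 200L), 2L * (n_ex - 1L)))
  es <- c(start, inner[seq(2, length(inner), by = 2)])
  ee <- c(inner[seq(1, length(inner), by = 2)], end)
  IRanges::IRanges(start = es + 1L, end = ee)
}

#' Generate the synthetic dataset
#'
#' Places TADs tiling each chromosome, head-to-tail boundary gene pairs,
#' repressive and active planted loops with their peaks and genes,
#' background genes/loops/peaks, and draws expression from the two-group
#' normal model. With `collision_free = TRUE` (default) background
#' placements are rejected whenever they could create accidental
#' head-to-tail pairs or mark co-occurrences, so downstream recovery is
#' exact. Identical seeds give identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return List with `genes`, `peaks` (list `p300`, `h3k27ac`,
#'   `h3k27me3`), `tads`, `loops`, `expression`, `truth`, `sizes`,
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  res <- config$resolution
  L <- config$chrom_length
  bins <- as.integer(L / res)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  sizes <- stats::setNames(rep(L, config$n_chroms), chroms)

  ## ---- TADs tiling each chromosome ----------------------------------------
  tpc <- rep(config$n_tads %/% config$n_chroms, config$n_chroms)
  extra <- config$n_tads %% config$n_chroms
  if (extra > 0) tpc[seq_len(extra)] <- tpc[seq_len(extra)] + 1L
  tad_rows <- list()
  for (c_i in seq_along(chroms)) {
    k <- tpc[c_i]
    if (k * config$min_tad_bins > bins)
      stop("capacity error: ", k, " TADs of >= ", config$min_tad_bins,
           " bins do not fit on ", chroms[c_i])
    spare <- bins - k * config$min_tad_bins
    cuts <- if (k > 1) sort(sample(0:spare, k - 1, replace = TRUE)) else integer(0)
    w <- config$min_tad_bins + diff(c(0L, cuts, spare))
    ends <- cumsum(w) * res
    starts <- c(0, utils::head(ends, -1))
    tad_rows[[c_i]] <- data.frame(chrom = chroms[c_i], start = starts,
                                  end = ends,
                                  name = sprintf("tad_%s_%02d", chroms[c_i],
                                                 seq_len(k)))
  }
  tad_df <- do.call(rbind, tad_rows)
  tads <- bed_to_gr(tad_df$chrom, tad_df$start, tad_df$end, sizes = sizes,
                    name = tad_df$name)
  boundary_pos <- split(c(tad_df$start, tad_df$end),
                        c(tad_df$chrom, tad_df$chrom))

  ## ---- bookkeeping ---------------------------------------------------------
  empty_gr <- bed_to_gr(character(0), integer(0), integer(0), sizes = sizes)
  # occupancy as plain per-chromosome interval vectors (1 kb buffer baked in)
  occ <- stats::setNames(lapply(chroms, function(x)
    list(s = numeric(0), e = numeric(0))), chroms)
  gene_rows <- list()
  gene_n <- 0L
  margin_ok <- function(chrom, pos, margin) {
    !config$collision_free || all(abs(boundary_pos[[chrom]] - pos) >= margin)
  }
  add_gene <- function(chrom, start, end, strand, gene_id = NULL) {
    gene_n <<- gene_n + 1L
    if (is.null(gene_id)) gene_id <- sprintf("g%04d", gene_n)
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      gene_id = gene_id, stringsAsFactors = FALSE)
    occ[[chrom]]$s <<- c(occ[[chrom]]$s, max(start - 1000, 0))
    occ[[chrom]]$e <<- c(occ[[chrom]]$e, min(end + 1000, L))
    gene_id
  }
  overlaps_occupied <- function(chrom, start, end) {
    any(start < occ[[chrom]]$e & occ[[chrom]]$s < end)
  }

  ## ---- planted boundary TADs (head-to-tail, PP, PG) ------------------------
  ht_tads <- character(0)
  ht_genes <- character(0)
  pp_tads <- character(0)
  pg_tads <- character(0)
  boundary_gene_ids <- character(0)
  n_picks <- config$n_headtail + config$n_pp + config$n_pg
  if (n_picks > 0) {
    eligible <- which(unlist(lapply(tad_rows, function(d) {
      k <- nrow(d)
      seq_len(k) > 1 & seq_len(k) < k   # interior TADs only
    })))
    picked <- integer(0)
    for (cand in sample(eligible, length(eligible))) {
      if (length(picked) == n_picks) break
      if (!any(abs(picked - cand) <= 1)) picked <- c(picked, cand)
    }
    # deterministic sweep tops up when the random greedy pass falls short
    for (cand in eligible) {
      if (length(picked) == n_picks) break
      if (!any(abs(picked - cand) <= 1)) picked <- c(picked, cand)
    }
    if (length(picked) < n_picks)
      stop("capacity error: cannot place ", n_picks,
           " non-adjacent planted TADs")
    picked <- sort(picked)
    class_of <- sample(rep(c("HT", "PP", "PG"),
                           c(config$n_headtail, config$n_pp, config$n_pg)))
    # gene with a fixed end at `anchor`; dir +1 grows right, -1 grows left;
    # `margin_end` is checked 12 kb clear of every boundary
    place_len <- function(td, anchor, dir, len_range = config$gene_length_range) {
      for (try in 1:200) {
        len <- rlog_uniform(1, len_range)
        s <- if (dir > 0) anchor else anchor - len
        e <- s + len
        far <- if (dir > 0) e - 1 else s
        if (s < 0 || e > L) next
        if (!margin_ok(td$chrom, far, 12000)) next
        if (overlaps_occupied(td$chrom, s, e)) next
        return(c(s, e))
      }
      stop("capacity error: cannot place planted gene near ", td$name)
    }
    ht_k <- 0L
    for (k in seq_along(picked)) {
      td <- tad_df[picked[k], ]
      cls <- class_of[k]
      if (cls == "HT") {
        # upstream terminator on one boundary, downstream promoter on the
        # other; strands alternate so planted TADs two apart cannot chain
        ht_k <- ht_k + 1L
        strand <- if (ht_k %% 2 == 1) "+" else "-"
        if (strand == "+") {
          up <- place_len(td, td$start, -1)  # TES at left boundary
          dn <- place_len(td, td$end, +1)    # TSS at right boundary
        } else {
          up <- place_len(td, td$end, +1)    # TES (bed start) at right
          dn <- place_len(td, td$start, -1)  # TSS (bed end - 1) at left
        }
        g_up <- add_gene(td$chrom, up[1], up[2], strand)
        g_dn <- add_gene(td$chrom, dn[1], dn[2], strand)
        ht_tads <- c(ht_tads, td$name)
        ht_genes <- c(ht_genes, g_up, g_dn)
        boundary_gene_ids <- c(boundary_gene_ids, g_up, g_dn)
      } else if (cls == "PP") {
        # promoters on both boundaries, growing into the domain
        g1 <- place_len(td, td$start, +1)    # "+": TSS at left boundary
        id1 <- add_gene(td$chrom, g1[1], g1[2], "+")
        g2 <- place_len(td, td$end + 1, -1)  # "-": TSS at right boundary
        id2 <- add_gene(td$chrom, g2[1], g2[2], "-")
        pp_tads <- c(pp_tads, td$name)
        boundary_gene_ids <- c(boundary_gene_ids, id1, id2)
      } else {
        # gene body crossing the left boundary, promoter on the right
        placed <- FALSE
        for (try in 1:200) {
          len <- rlog_uniform(1, c(30000, config$gene_length_range[2]))
          offset <- round(stats::runif(1, 12000, len - 12000))
          s <- td$start - offset
          e <- s + len
          if (s < 0 || e > L) next
          if (!margin_ok(td$chrom, s, 12000) || !margin_ok(td$chrom, e - 1, 12000))
            next
          if (overlaps_occupied(td$chrom, s, e)) next
          id1 <- add_gene(td$chrom, s, e, sample(c("+", "-"), 1))
          placed <- TRUE
          break
        }
        if (!placed)
          stop("capacity error: cannot place body gene at ", td$name)
        g2 <- place_len(td, td$end + 1, -1)  # "-": TSS at right boundary
        id2 <- add_gene(td$chrom, g2[1], g2[2], "-")
        pg_tads <- c(pg_tads, td$name)
        boundary_gene_ids <- c(boundary_gene_ids, id1, id2)
      }
    }
  }

  ## ---- planted loops (repressive and active) -------------------------------
  used_bins <- stats::setNames(vector("list", length(chroms)), chroms)
  p300_rows <- list()
  ac_rows <- list()
  me3_rows <- list()
  loop_rows <- list()
  repressed_genes <- character(0)
  active_genes <- character(0)
  pixel_rows <- list()
  bin_margin <- 8L
  draw_bin_pair <- function(chrom) {
    for (try in 1:500) {
      b1 <- sample(bin_margin:(bins - 1L - bin_margin - config$min_loop_dist), 1)
      d <- sample(config$min_loop_dist:config$max_loop_dist, 1)
      b2 <- b1 + d
      if (b2 > bins - 1L - bin_margin) next
      if (b1 %in% used_bins[[chrom]] || b2 %in% used_bins[[chrom]]) next
      return(c(b1, b2))
    }
    stop("capacity error: cannot place loop anchors on ", chrom)
  }
  place_anchor_gene <- function(chrom, tss) {
    # gene with its TSS fixed at `tss` (bin center); strand random; NULL
    # when the location cannot host a gene (caller redraws the bin pair)
    for (try in 1:50) {
      strand <- sample(c("+", "-"), 1)
      len <- rlog_uniform(1, config$gene_length_range)
      if (strand == "+") { s <- tss; e <- tss + len } else {
        e <- tss + 1; s <- e - len
      }
      tes <- if (strand == "+") e - 1 else s
      if (s < 0 || e > L) next
      if (!margin_ok(chrom, tes, 12000)) next
      if (overlaps_occupied(chrom, s, e)) next
      return(list(id = add_gene(chrom, s, e, strand), strand = strand))
    }
    NULL
  }
  n_plant_all <- config$n_planted + config$n_active
  plant_class <- rep(c("repressive", "active"),
                     c(config$n_planted, config$n_active))
  for (k in seq_len(n_plant_all)) {
    chrom <- chroms[(k - 1L) %% length(chroms) + 1L]
    g <- NULL
    for (try in 1:100) {
      bp <- draw_bin_pair(chrom)
      c1 <- bp[1] * res + res %/% 2
      c2 <- bp[2] * res + res %/% 2
      g <- place_anchor_gene(chrom, c2)
      if (!is.null(g)) break
    }
    if (is.null(g))
      stop("capacity error: cannot place planted loop ", k, " on ", chrom)
    used_bins[[chrom]] <- c(used_bins[[chrom]], bp)
    p300_rows[[length(p300_rows) + 1L]] <-
      data.frame(chrom = chrom, start = c1 - 200, end = c1 + 200,
                 name = sprintf("p300_planted_%03d", k))
    if (plant_class[k] == "repressive") {
      me3_rows[[length(me3_rows) + 1L]] <-
        data.frame(chrom = chrom, start = c2 - 500, end = c2 + 500,
                   name = sprintf("me3_planted_%03d", k))
      repressed_genes <- c(repressed_genes, g$id)
    } else {
      active_genes <- c(active_genes, g$id)
    }
    loop_rows[[length(loop_rows) + 1L]] <-
      data.frame(chrom = chrom, start1 = bp[1] * res, end1 = (bp[1] + 1) * res,
                 start2 = bp[2] * res, end2 = (bp[2] + 1) * res,
                 class = plant_class[k])
    pixel_rows[[length(pixel_rows) + 1L]] <-
      data.frame(chrom = chrom, bin1 = bp[1], bin2 = bp[2],
                 class = plant_class[k])
  }

  ## ---- background loops ----------------------------------------------------
  for (k in seq_len(config$n_loops - n_plant_all)) {
    chrom <- chroms[(k - 1L) %% length(chroms) + 1L]
    bp <- draw_bin_pair(chrom)
    used_bins[[chrom]] <- c(used_bins[[chrom]], bp)
    loop_rows[[length(loop_rows) + 1L]] <-
      data.frame(chrom = chrom, start1 = bp[1] * res, end1 = (bp[1] + 1) * res,
                 start2 = bp[2] * res, end2 = (bp[2] + 1) * res,
                 class = "background")
  }
  loop_df <- do.call(rbind, loop_rows)
  loop_df$name <- sprintf("loop%04d", seq_len(nrow(loop_df)))

  ## ---- background genes (some with a second isoform) -----------------------
  n_bg <- config$n_genes - 2L * (config$n_headtail + config$n_pp +
                                 config$n_pg) - n_plant_all
  if (n_bg < 0)
    stop("capacity error: n_genes too small for the planted structure")
  anchor_bin_hit <- function(chrom, s, e, pad = 0) {
    b <- used_bins[[chrom]]
    length(b) > 0 && any(s < (b + 1) * res + pad & b * res - pad < e)
  }
  bg_ids <- character(0)
  for (k in seq_len(n_bg)) {
    placed <- FALSE
    for (try in 1:500) {
      chrom <- sample(chroms, 1)
      len <- rlog_uniform(1, config$gene_length_range)
      s <- sample.int(L - len, 1) - 1L
      e <- s + len
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") s else e - 1
      tes <- if (strand == "+") e - 1 else s
      if (!margin_ok(chrom, tss, 12000) || !margin_ok(chrom, tes, 12000)) next
      if (overlaps_occupied(chrom, s, e)) next
      if (config$collision_free &&
          anchor_bin_hit(chrom, tss - 1000, tss + 1000)) next
      bg_ids <- c(bg_ids, add_gene(chrom, s, e, strand))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("capacity error: cannot place background gene ", k)
  }
  # second isoforms with internal alternative promoters
  n_iso <- round(config$isoform_fraction * n_bg)
  if (n_iso > 0 && length(bg_ids) > 0) {
    all_rows <- do.call(rbind, gene_rows)
    for (gid in sample(bg_ids, min(n_iso, length(bg_ids)))) {
      b <- all_rows[all_rows$gene_id == gid, ][1, ]
      width <- b$end - b$start
      if (width < 10000) next
      for (try in 1:50) {
        shift <- round(stats::runif(1, 0.2, 0.6) * width)
        if (b$strand == "+") { s <- b$start + shift; e <- b$end } else {
          s <- b$start; e <- b$end - shift
        }
        tss <- if (b$strand == "+") s else e - 1
        if (!margin_ok(b$chrom, tss, 12000)) next
        if (config$collision_free &&
            anchor_bin_hit(b$chrom, tss - 1000, tss + 1000)) next
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = b$chrom, start = s, end = e, strand = b$strand,
          gene_id = gid, stringsAsFactors = FALSE)
        break
      }
    }
  }
  gdf <- do.call(rbind, gene_rows)
  genes <- bed_to_gr(gdf$chrom, gdf$start, gdf$end, gdf$strand,
                     sizes = sizes, gene_id = gdf$gene_id)
  S4Vectors::mcols(genes)$exons <- IRanges::IRangesList(
    lapply(seq_len(nrow(gdf)), function(i) make_exons(gdf$start[i],
                                                      gdf$end[i])))
  S4Vectors::mcols(genes)$cds_start <- NA_integer_
  S4Vectors::mcols(genes)$cds_end <- NA_integer_
  genes <- sort_intervals(genes)

  ## ---- background peaks ----------------------------------------------------
  draw_clear_pos <- function(width) {
    for (try in 1:500) {
      chrom <- sample(chroms, 1)
      s <- sample.int(L - width - 2000, 1) + 1000
      if (!anchor_bin_hit(chrom, s, s + width, pad = 2000))
        return(list(chrom = chrom, start = s))
    }
    stop("capacity error: cannot place background peak")
  }
  for (k in seq_len(config$n_common_peaks)) {
    p <- draw_clear_pos(800)
    p300_rows[[length(p300_rows) + 1L]] <-
      data.frame(chrom = p$chrom, start = p$start, end = p$start + 600,
                 name = sprintf("p300_common_%03d", k))
    ac_rows[[length(ac_rows) + 1L]] <-
      data.frame(chrom = p$chrom, start = p$start - 100, end = p$start + 700,
                 name = sprintf("ac_common_%03d", k))
  }
  for (k in seq_len(config$n_extra_ac)) {
    p <- draw_clear_pos(800)
    ac_rows[[length(ac_rows) + 1L]] <-
      data.frame(chrom = p$chrom, start = p$start, end = p$start + 800,
                 name = sprintf("ac_extra_%03d", k))
  }
  for (k in seq_len(config$n_extra_me3)) {
    p <- draw_clear_pos(1000)
    me3_rows[[length(me3_rows) + 1L]] <-
      data.frame(chrom = p$chrom, start = p$start, end = p$start + 1000,
                 name = sprintf("me3_extra_%03d", k))
  }
  peak_gr <- function(rows) {
    if (length(rows) == 0) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$name <- character(0)
      S4Vectors::mcols(gr)$score <- numeric(0)
      return(gr)
    }
    d <- do.call(rbind, rows)
    sort_intervals(bed_to_gr(d$chrom, d$start, d$end, sizes = sizes,
                             name = d$name,
                             score = round(stats::runif(nrow(d), 2, 20), 2)))
  }
  peaks <- list(p300 = peak_gr(p300_rows), h3k27ac = peak_gr(ac_rows),
                h3k27me3 = peak_gr(me3_rows))

  ## ---- loops object --------------------------------------------------------
  loops <- loop_set(
    bed_to_gr(loop_df$chrom, loop_df$start1, loop_df$end1, sizes = sizes),
    bed_to_gr(loop_df$chrom, loop_df$start2, loop_df$end2, sizes = sizes),
    name = loop_df$name)

  ## ---- expression ----------------------------------------------------------
  ids <- unique(genes$gene_id)
  log_expr <- stats::rnorm(length(ids), config$expr_mu_hi, config$expr_sigma)
  log_expr[ids %in% repressed_genes] <-
    log_expr[ids %in% repressed_genes] - config$expr_delta
  log_expr <- pmax(log_expr, 0)
  expression <- data.frame(gene_id = ids, tpm = 2^log_expr - 1,
                           stringsAsFactors = FALSE)

  ## ---- ground truth --------------------------------------------------------
  pixels <- if (length(pixel_rows)) do.call(rbind, pixel_rows) else
    data.frame(chrom = character(0), bin1 = integer(0), bin2 = integer(0),
               class = character(0))
  pixels$loop_id <- loop_df$name[seq_len(nrow(pixels))]
  gene_group <- stats::setNames(
    ifelse(ids %in% repressed_genes, "repressed", "background"), ids)
  truth <- list(
    planted_loop_ids = loop_df$name[loop_df$class == "repressive"],
    active_loop_ids = loop_df$name[loop_df$class == "active"],
    headtail_tad_ids = ht_tads,
    headtail_gene_ids = ht_genes,
    pp_tad_ids = pp_tads,
    pg_tad_ids = pg_tads,
    boundary_gene_ids = boundary_gene_ids,
    gene_group = gene_group,
    repressed_gene_ids = repressed_genes,
    active_gene_ids = active_genes,
    planted_pixels = pixels,
    n_p300_only = n_plant_all)

  list(genes = genes, peaks = peaks, tads = tads, loops = loops,
       expression = expression, truth = truth, sizes = sizes,
       config = config)
}

#' Generate Poisson contact matrices with planted structure
#'
#' Expected counts follow `N (1 + |i - j|)^(-alpha)`, multiplied by
#' `tad_enrichment` when bins i and j fall in the same TAD and by
#' `loop_enrichment` at planted loop pixels; realized counts are Poisson
#' and the matrix is symmetric with integer entries.
#'
#' @param config a [synthetic_config()].
#' @param tads domain `GRanges` (bin-aligned, as generated).
#' @param pixels data.frame with `chrom`, `bin1`, `bin2` of enriched
#'   pixels (e.g. `truth$planted_pixels`).
#' @return Named list of raw [contact_matrix()] objects, one per
#'   chromosome.
#' @export
generate_contact_matrices <- function(config, tads, pixels = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "contact_matrix"))
  res <- config$resolution
  bins <- as.integer(config$chrom_length / res)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  tb <- gr_to_bed(tads)
  if (any(tb$start %% res != 0 | tb$end %% res != 0))
    stop("TAD coordinates are not aligned to the matrix resolution")
  if (!is.null(pixels) && nrow(pixels) > 0 &&
      (any(pixels$bin1 < 0 | pixels$bin2 >= bins)))
    stop("planted pixels outside the matrix span")
  out <- list()
  for (chrom in chroms) {
    d <- abs(outer(seq_len(bins) - 1L, seq_len(bins) - 1L, "-"))
    expect <- config$total_contacts * (1 + d)^(-config$decay_alpha)
    # same-TAD factor
    td <- tb[tb$chrom == chrom, , drop = FALSE]
    if (nrow(td) > 0) {
      bin_tad <- rep(NA_integer_, bins)
      for (t_i in seq_len(nrow(td))) {
        lo <- td$start[t_i] %/% res
        hi <- td$end[t_i] %/% res - 1L
        bin_tad[(lo:hi) + 1L] <- t_i
      }
      same <- outer(bin_tad, bin_tad, "==")
      same[is.na(same)] <- FALSE
      expect[same] <- expect[same] * config$tad_enrichment
    }
    if (!is.null(pixels) && nrow(pixels) > 0) {
      px <- pixels[pixels$chrom == chrom, , drop = FALSE]
      if (nrow(px) > 0) {
        idx <- cbind(px$bin1 + 1L, px$bin2 + 1L)
        expect[idx] <- expect[idx] * config$loop_enrichment
        expect[idx[, c(2, 1), drop = FALSE]] <-
          expect[cbind(idx[, 2], idx[, 1])]
      }
    }
    m <- matrix(0L, bins, bins)
    up <- upper.tri(m, diag = TRUE)
    m[up] <- stats::rpois(sum(up), expect[up])
    m <- m + t(m) - diag(diag(m))
    out[[chrom]] <- contact_matrix(m, chrom, res)
  }
  out
}

#' Reflect genomic features through the chromosome midpoint
#'
#' Maps BED position `p` to `length - 1 - p` and flips strand; exon
#' structure is reflected when present. Useful for symmetry checks (a
#' reflected genome must yield mirrored analyses).
#'
#' @param gr `GRanges` (gene models with an `exons` column are handled).
#' @param sizes named chromosome lengths.
#' @return Reflected `GRanges`.
#' @export
reflect_genome <- function(gr, sizes) {
  b <- gr_to_bed(gr)
  len <- unname(sizes[b$chrom])
  ns <- len - b$end
  ne <- len - b$start
  strand <- chartr("+-", "-+", b$strand)
  out <- bed_to_gr(b$chrom, ns, ne, strand, sizes = sizes)
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  if (!is.null(out$exons)) {
    out$exons <- IRanges::IRangesList(lapply(seq_along(gr), function(i) {
      ex <- gr$exons[[i]]
      IRanges::IRanges(start = len[i] - IRanges::end(ex) + 1L,
                       end = len[i] - IRanges::start(ex) + 1L)
    }))
  }
  sort_intervals(out)
}

#' Write a synthetic dataset to a directory
#'
#' Emits genes.bed12, p300/h3k27ac/h3k27me3 narrowPeak files, tads.bed,
#' loops.bedpe, expression.tsv, chrom.sizes, ground_truth.json and, when
#' supplied, one COO matrix per chromosome.
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param matrices optional list from [generate_contact_matrices()].
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, matrices = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_genes(dataset$genes, fp("genes.bed12"))
  for (mark in names(dataset$peaks)) {
    gr <- dataset$peaks[[mark]]
    S4Vectors::mcols(gr)$summit <- IRanges::width(gr) %/% 2L
    write_intervals(gr, fp(paste0(mark, ".narrowPeak")), "narrowPeak")
  }
  write_intervals(dataset$tads, fp("tads.bed"), "bed6")
  write_pairs(dataset$loops, fp("loops.bedpe"))
  write_expression(dataset$expression, fp("expression.tsv"))
  write_chrom_sizes(dataset$sizes, fp("chrom.sizes"))
  truth <- dataset$truth
  truth$gene_group <- as.list(truth$gene_group)
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(matrices))
    for (chrom in names(matrices))
      write_contact_matrix(matrices[[chrom]],
                           fp(sprintf("matrix_%s.coo.tsv", chrom)))
  invisible(dir)
}
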