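# Genomic-interval data model, BED-family readers/writers and the interval
# algebra used by every downstream stage. Files are BED-convention (0-based
# half-open); in memory everything is a GRanges (1-based closed).

## ---- coordinate helpers ----------------------------------------------------

#' Convert BED-style fields to a GRanges
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param strand strand characters; "." is mapped to "*".
#' @param sizes optional named vector of chromosome lengths used to set
#'   `seqlengths`.
#' @param ... further metadata columns.
#' @return A `GRanges`.
#' @export
bed_to_gr <- function(chrom, start, end, strand = ".", sizes = NULL, ...) {
  strand <- rep(ifelse(strand == ".", "*", strand),
                length.out = length(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr)[names(mc)] <- mc
  if (!is.null(sizes)) {
    missing <- setdiff(as.character(unique(chrom)), names(sizes))
    if (length(missing))
      stop("chromosome(s) absent from sizes: ", paste(missing, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(sizes)
  }
  gr
}

#' @rdname bed_to_gr
#' @param gr a `GRanges`.
#' @return `gr_to_bed`: a data.frame with BED-convention `chrom`, `start`,
#'   `end`, `strand` columns.
#' @export
gr_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

# window of `flank` bp on each side of a BED-coordinate point, as GRanges
window_around_point <- function(chrom, pos, flank, sizes = NULL) {
  start <- pmax(pos - flank, 0)
  end <- pos + flank
  if (!is.null(sizes)) end <- pmin(end, unname(sizes[chrom]))
  bed_to_gr(chrom, start, end, sizes = sizes)
}

# canonical (chrom, start) sort ignoring strand
sort_intervals <- function(gr) {
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## ---- file reading ----------------------------------------------------------

# read a whitespace-tab table keeping original line numbers; skips comment,
# track and browser lines; transparently decompresses .gz
read_record_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       line_no = which(keep))
}

parse_int <- function(x, line, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) | as.character(v) != sub("^\\+", "", x)
  if (any(bad))
    stop(sprintf("line %d: %s is not an integer: '%s'",
                 line[bad][1], what, x[bad][1]))
  v
}

parse_num <- function(x, line, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop(sprintf("line %d: %s is not numeric: '%s'",
                 line[is.na(v)][1], what, x[is.na(v)][1]))
  v
}

check_coords <- function(start, end, line) {
  bad <- start < 0
  if (any(bad)) stop(sprintf("line %d: negative start %d", line[bad][1], start[bad][1]))
  bad <- start >= end
  if (any(bad))
    stop(sprintf("line %d: start %d >= end %d", line[bad][1],
                 start[bad][1], end[bad][1]))
  invisible(NULL)
}

field_matrix <- function(rec, min_cols, what) {
  n <- lengths(rec$fields)
  bad <- n < min_cols
  if (any(bad))
    stop(sprintf("line %d: %s requires >= %d columns, found %d",
                 rec$line_no[bad][1], what, min_cols, n[bad][1]))
  rec
}

col_of <- function(rec, i) vapply(rec$fields, `[[`, character(1), i)

#' Read a BED/narrowPeak interval file
#'
#' Supported dialects: `bed3` (chrom, start, end), `bed6` (adds name, score,
#' strand) and ENCODE 10-column `narrowPeak` (signalValue is stored as the
#' interval score; the summit offset is parsed into `summit` but unused by
#' the analyses). Gzip input is handled transparently; comment/track lines
#' are skipped. Malformed coordinates raise an error naming the line.
#'
#' @param path file path (optionally gzipped).
#' @param format one of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param sizes optional chromosome lengths (named vector).
#' @param mark optional label stored in `metadata(x)$mark`.
#' @return A sorted `GRanges` with `name` and `score` metadata columns.
#' @export
read_intervals <- function(path, format = c("bed3", "bed6", "narrowPeak"),
                           sizes = NULL, mark = NULL) {
  format <- match.arg(format)
  min_cols <- switch(format, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  rec <- field_matrix(read_record_lines(path), min_cols, format)
  ln <- rec$line_no
  if (length(ln) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character(0)
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  chrom <- col_of(rec, 1)
  start <- parse_int(col_of(rec, 2), ln, "start")
  end <- parse_int(col_of(rec, 3), ln, "end")
  check_coords(start, end, ln)
  name <- if (min_cols >= 6) col_of(rec, 4) else NA_character_
  strand <- if (min_cols >= 6) col_of(rec, 6) else "."
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad))
    stop(sprintf("line %d: invalid strand '%s'", ln[bad][1], strand[bad][1]))
  score <- if (format == "narrowPeak") {
    parse_num(col_of(rec, 7), ln, "signalValue")
  } else if (min_cols >= 6) parse_num(col_of(rec, 5), ln, "score") else NA_real_
  gr <- bed_to_gr(chrom, start, end, strand, sizes = sizes,
                  name = name, score = score)
  if (format == "narrowPeak")
    S4Vectors::mcols(gr)$summit <- parse_int(col_of(rec, 10), ln, "summit")
  gr <- sort_intervals(gr)
  if (!is.null(mark)) S4Vectors::metadata(gr)$mark <- mark
  gr
}

#' Read a chrom.sizes file
#'
#' @param path two-column (chromosome, length) file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  rec <- field_matrix(read_record_lines(path), 2L, "chrom.sizes")
  len <- parse_num(col_of(rec, 2), rec$line_no, "length")
  if (any(len <= 0))
    stop("chromosome lengths must be positive")
  stats::setNames(len, col_of(rec, 1))
}

## ---- loop sets (BEDPE) -----------------------------------------------------

#' Construct a loop set
#'
#' A loop set holds paired anchors as two parallel `GRanges`. Anchors are
#' stored canonically: for intra-chromosomal loops `anchor1` starts at or
#' before `anchor2`; inter-chromosomal records are retained but flagged.
#'
#' @param anchor1,anchor2 parallel `GRanges` of anchor spans.
#' @param score optional numeric loop scores.
#' @param name optional loop identifiers.
#' @return An object of class `loop_set`.
#' @export
loop_set <- function(anchor1, anchor2, score = NULL, name = NULL) {
  stopifnot(length(anchor1) == length(anchor2))
  n <- length(anchor1)
  if (is.null(score)) score <- rep(NA_real_, n)
  if (is.null(name)) name <- paste0("loop", seq_len(n))
  chr1 <- as.character(GenomeInfoDb::seqnames(anchor1))
  chr2 <- as.character(GenomeInfoDb::seqnames(anchor2))
  inter <- chr1 != chr2
  swap <- !inter & GenomicRanges::start(anchor2) < GenomicRanges::start(anchor1)
  if (any(swap)) {
    a1 <- anchor1
    anchor1[swap] <- anchor2[swap]
    anchor2[swap] <- a1[swap]
  }
  structure(list(anchor1 = anchor1, anchor2 = anchor2,
                 score = score, name = name,
                 inter_chromosomal = inter),
            class = "loop_set")
}

#' @export
length.loop_set <- function(x) length(x$anchor1)

#' @export
`[.loop_set` <- function(x, i) {
  loop_set(x$anchor1[i], x$anchor2[i], x$score[i], x$name[i])
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set with %d loops (%d inter-chromosomal)\n",
              length(x), sum(x$inter_chromosomal)))
  invisible(x)
}

#' @export
as.data.frame.loop_set <- function(x, ...) {
  b1 <- gr_to_bed(x$anchor1)
  b2 <- gr_to_bed(x$anchor2)
  data.frame(chrom1 = b1$chrom, start1 = b1$start, end1 = b1$end,
             chrom2 = b2$chrom, start2 = b2$start, end2 = b2$end,
             name = x$name, score = x$score,
             inter_chromosomal = x$inter_chromosomal,
             stringsAsFactors = FALSE)
}

#' Read paired-anchor interactions (BEDPE)
#'
#' @param path BEDPE file with at least six tab-separated columns.
#' @param sizes optional chromosome lengths.
#' @return A [loop_set] with canonically ordered anchors.
#' @export
read_pairs <- function(path, sizes = NULL) {
  rec <- field_matrix(read_record_lines(path), 6L, "bedpe")
  ln <- rec$line_no
  if (length(ln) == 0)
    return(loop_set(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                    numeric(0), character(0)))
  s1 <- parse_int(col_of(rec, 2), ln, "start1")
  e1 <- parse_int(col_of(rec, 3), ln, "end1")
  s2 <- parse_int(col_of(rec, 5), ln, "start2")
  e2 <- parse_int(col_of(rec, 6), ln, "end2")
  check_coords(s1, e1, ln)
  check_coords(s2, e2, ln)
  name <- vapply(rec$fields, function(f)
    if (length(f) >= 7) f[[7]] else NA_character_, character(1))
  score <- vapply(rec$fields, function(f)
    if (length(f) >= 8) suppressWarnings(as.numeric(f[[8]])) else NA_real_,
    numeric(1))
  a1 <- bed_to_gr(col_of(rec, 1), s1, e1, sizes = sizes)
  a2 <- bed_to_gr(col_of(rec, 4), s2, e2, sizes = sizes)
  if (all(is.na(name))) name <- NULL
  loop_set(a1, a2, score = score, name = name)
}

## ---- gene models (BED6 / BED12) --------------------------------------------

#' Read gene models from BED6 or BED12
#'
#' BED6 records become single-exon genes; BED12 blockStarts/blockSizes are
#' expanded into absolute exon coordinates (stored in the `exons`
#' `IRangesList` column). The thickStart/thickEnd CDS slot is kept when it is
#' non-empty. Strandless records are rejected because TSS/TES are undefined
#' without strand.
#'
#' @param path BED6 or BED12 file; the dialect is chosen per file from the
#'   column count.
#' @param sizes optional chromosome lengths.
#' @return A sorted `GRanges` with columns `gene_id`, `exons`
#'   (`IRangesList`), `cds_start`, `cds_end` (BED coords; `NA` when absent).
#' @export
read_genes <- function(path, sizes = NULL) {
  rec <- read_record_lines(path)
  ln <- rec$line_no
  if (length(ln) == 0) stop("no gene records in ", path)
  ncol <- lengths(rec$fields)
  if (any(ncol < 6))
    stop(sprintf("line %d: gene records require >= 6 columns", ln[ncol < 6][1]))
  bed12 <- all(ncol >= 12)
  chrom <- col_of(rec, 1)
  start <- parse_int(col_of(rec, 2), ln, "start")
  end <- parse_int(col_of(rec, 3), ln, "end")
  check_coords(start, end, ln)
  gene_id <- col_of(rec, 4)
  strand <- col_of(rec, 6)
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop(sprintf("line %d: gene strand must be '+' or '-', found '%s'",
                 ln[bad][1], strand[bad][1]))
  if (bed12) {
    cds_s <- parse_int(col_of(rec, 7), ln, "thickStart")
    cds_e <- parse_int(col_of(rec, 8), ln, "thickEnd")
    n_blocks <- parse_int(col_of(rec, 10), ln, "blockCount")
    sizes_f <- strsplit(sub(",$", "", col_of(rec, 11)), ",", fixed = TRUE)
    starts_f <- strsplit(sub(",$", "", col_of(rec, 12)), ",", fixed = TRUE)
    exons <- vector("list", length(ln))
    for (i in seq_along(ln)) {
      bs <- parse_int(starts_f[[i]], rep(ln[i], length(starts_f[[i]])), "blockStart")
      bw <- parse_int(sizes_f[[i]], rep(ln[i], length(sizes_f[[i]])), "blockSize")
      if (length(bs) != n_blocks[i] || length(bw) != n_blocks[i])
        stop(sprintf("line %d: blockCount %d does not match block lists",
                     ln[i], n_blocks[i]))
      es <- start[i] + bs
      ee <- es + bw
      if (bs[1] != 0 || ee[length(ee)] != end[i])
        stop(sprintf("line %d: blocks must span the record", ln[i]))
      if (is.unsorted(es) || any(ee[-length(ee)] > es[-1]))
        stop(sprintf("line %d: blocks must be sorted and non-overlapping", ln[i]))
      exons[[i]] <- IRanges::IRanges(start = es + 1L, end = ee)
    }
    exons <- IRanges::IRangesList(exons)
    no_cds <- cds_s >= cds_e
    cds_s[no_cds] <- NA_integer_
    cds_e[no_cds] <- NA_integer_
  } else {
    exons <- IRanges::IRangesList(lapply(seq_along(ln), function(i)
      IRanges::IRanges(start = start[i] + 1L, end = end[i])))
    cds_s <- rep(NA_integer_, length(ln))
    cds_e <- rep(NA_integer_, length(ln))
  }
  gr <- bed_to_gr(chrom, start, end, strand, sizes = sizes, gene_id = gene_id)
  S4Vectors::mcols(gr)$exons <- exons
  S4Vectors::mcols(gr)$cds_start <- cds_s
  S4Vectors::mcols(gr)$cds_end <- cds_e
  sort_intervals(gr)
}

#' Transcription start/end positions (BED coordinates)
#'
#' The TSS is the first transcribed base, the TES the last: for a `+` gene
#' these are `start` and `end - 1`; for a `-` gene, `end - 1` and `start`.
#'
#' @param genes gene `GRanges` as returned by [read_genes()].
#' @return Integer vector of 0-based positions.
#' @export
tss_position <- function(genes) {
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  ifelse(plus, GenomicRanges::start(genes) - 1L, GenomicRanges::end(genes) - 1L)
}

#' @rdname tss_position
#' @export
tes_position <- function(genes) {
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  ifelse(plus, GenomicRanges::end(genes) - 1L, GenomicRanges::start(genes) - 1L)
}

#' Promoter and terminator windows
#'
#' The promoter is the window of `flank` bp on each side of the TSS
#' (default 1 kb); the terminator the same around the TES (default 5 kb).
#'
#' @param genes gene `GRanges`.
#' @param flank half-width in bp.
#' @param sizes optional chromosome lengths for clipping.
#' @return A `GRanges` parallel to `genes`, carrying `gene_id`.
#' @export
promoter_windows <- function(genes, flank = 1000, sizes = NULL) {
  w <- window_around_point(as.character(GenomeInfoDb::seqnames(genes)),
                           tss_position(genes), flank, sizes)
  S4Vectors::mcols(w)$gene_id <- genes$gene_id
  w
}

#' @rdname promoter_windows
#' @export
terminator_windows <- function(genes, flank = 5000, sizes = NULL) {
  w <- window_around_point(as.character(GenomeInfoDb::seqnames(genes)),
                           tes_position(genes), flank, sizes)
  S4Vectors::mcols(w)$gene_id <- genes$gene_id
  w
}

## ---- expression ------------------------------------------------------------

#' Read an expression quantification table
#'
#' @param path TSV with a header row.
#' @param gene_col,tpm_col column names holding gene ids and TPM.
#' @return data.frame with unique `gene_id` and non-negative `tpm`;
#'   duplicated ids keep the maximum TPM (with a message).
#' @export
read_expression <- function(path, gene_col = "gene_id", tpm_col = "TPM") {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c(gene_col, tpm_col) %in% names(tab)))
    stop("expression table must contain columns '", gene_col, "' and '",
         tpm_col, "'")
  gene_id <- as.character(tab[[gene_col]])
  tpm <- as.numeric(tab[[tpm_col]])
  if (anyNA(tpm)) stop("non-numeric TPM value in ", path)
  if (any(tpm < 0)) stop("negative TPM for gene ", gene_id[tpm < 0][1])
  if (anyDuplicated(gene_id)) {
    message("read_expression: ", sum(duplicated(gene_id)),
            " duplicate gene ids resolved by maximum TPM")
    o <- order(gene_id, -tpm)
    keep <- !duplicated(gene_id[o])
    idx <- o[keep]
    gene_id <- gene_id[idx]
    tpm <- tpm[idx]
  }
  data.frame(gene_id = gene_id, tpm = tpm, stringsAsFactors = FALSE)
}

#' Read a bedGraph signal track
#'
#' @param path four-column bedGraph (chrom, start, end, value).
#' @param sizes optional chromosome lengths.
#' @return `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path, sizes = NULL) {
  rec <- field_matrix(read_record_lines(path), 4L, "bedGraph")
  ln <- rec$line_no
  start <- parse_int(col_of(rec, 2), ln, "start")
  end <- parse_int(col_of(rec, 3), ln, "end")
  check_coords(start, end, ln)
  sort_intervals(bed_to_gr(col_of(rec, 1), start, end, sizes = sizes,
                           score = parse_num(col_of(rec, 4), ln, "value")))
}

## ---- writers ---------------------------------------------------------------

#' Write intervals in a BED-family dialect
#'
#' @param gr `GRanges` (optionally with `name`/`score`/`summit` columns).
#' @param path output path.
#' @param format `"bed3"`, `"bed6"` or `"narrowPeak"`.
#' @export
write_intervals <- function(gr, path, format = c("bed3", "bed6", "narrowPeak")) {
  format <- match.arg(format)
  b <- gr_to_bed(gr)
  name <- if (!is.null(gr$name)) ifelse(is.na(gr$name), ".", gr$name) else "."
  score <- if (!is.null(gr$score)) gr$score else 0
  tab <- switch(format,
    bed3 = b[c("chrom", "start", "end")],
    bed6 = data.frame(b$chrom, b$start, b$end, name, score, b$strand),
    narrowPeak = data.frame(
      b$chrom, b$start, b$end, name, 0L, b$strand, score, -1, -1,
      if (!is.null(gr$summit)) gr$summit else -1L))
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a loop set as BEDPE
#' @param loops a [loop_set].
#' @param path output path.
#' @export
write_pairs <- function(loops, path) {
  d <- as.data.frame.loop_set(loops)
  d$score[is.na(d$score)] <- "."
  data.table::fwrite(d[, 1:8], path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#' @param genes gene `GRanges` from [read_genes()] or the generator.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  b <- gr_to_bed(genes)
  exons <- genes$exons
  n_blocks <- lengths(exons)
  bsize <- vapply(seq_along(exons), function(i)
    paste0(paste(IRanges::width(exons[[i]]), collapse = ","), ","), character(1))
  bstart <- vapply(seq_along(exons), function(i)
    paste0(paste(IRanges::start(exons[[i]]) - 1L - b$start[i], collapse = ","),
           ","), character(1))
  cds_s <- ifelse(is.na(genes$cds_start), b$start, genes$cds_start)
  cds_e <- ifelse(is.na(genes$cds_end), b$start, genes$cds_end)
  tab <- data.frame(b$chrom, b$start, b$end, genes$gene_id, 0L, b$strand,
                    cds_s, cds_e, 0L, n_blocks, bsize, bstart)
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expression table
#' @param expr data.frame with `gene_id` and `tpm`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene_id = expr$gene_id, TPM = expr$tpm)
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a chrom.sizes table
#' @param sizes named vector of chromosome lengths.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  data.table::fwrite(data.frame(names(sizes), unname(as.integer(sizes))),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- interval algebra ------------------------------------------------------

#' Extend intervals on both sides (bedtools slop)
#'
#' @param gr intervals.
#' @param flank non-negative extension in bp.
#' @param sizes named chromosome lengths; every chromosome present in `gr`
#'   must be listed.
#' @return `GRanges` with each interval extended by `flank` and clipped to
#'   the chromosome; the interval count is preserved.
#' @export
slop <- function(gr, flank, sizes) {
  stopifnot(flank >= 0)
  chroms <- as.character(unique(GenomeInfoDb::seqnames(gr)))
  missing <- setdiff(chroms, names(sizes))
  if (length(missing))
    stop("chromosome(s) absent from sizes: ", paste(missing, collapse = ", "))
  s <- pmax(GenomicRanges::start(gr) - flank, 1)
  e <- pmin(GenomicRanges::end(gr) + flank,
            unname(sizes[as.character(GenomeInfoDb::seqnames(gr))]))
  GenomicRanges::ranges(gr) <- IRanges::IRanges(start = s, end = e)
  gr
}

#' Overlap predicate against a peak set
#'
#' TRUE for each interval of `a` sharing at least one base with some
#' interval of `b` on the same chromosome (strand ignored). Book-ended
#' intervals do not overlap.
#'
#' @param a,b `GRanges`.
#' @return Logical vector along `a`.
#' @export
overlaps_any <- function(a, b) {
  IRanges::overlapsAny(a, b, ignore.strand = TRUE)
}

#' Keep intervals of `a` that do not overlap `b`
#'
#' Whole intervals are kept or dropped; nothing is truncated.
#' @param a,b `GRanges`.
#' @return Subset of `a`.
#' @export
filter_nonoverlapping <- function(a, b) {
  a[!overlaps_any(a, b)]
}

#' Union of overlapping or book-ended intervals
#'
#' @param gr `GRanges`.
#' @return Disjoint sorted `GRanges` covering the same bases.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(sort_intervals(gr), ignore.strand = TRUE)
}
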