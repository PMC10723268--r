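# Contact-matrix container and operations: plain-text COO ingestion,
# VC_SQRT balancing, virtual 4C viewpoint profiles and aggregate peak
# analysis (APA).

#' Contact matrix constructor
#'
#' A symmetric binned intra-chromosomal matrix at fixed resolution; bin `b`
#' (0-based) covers BED interval `[b * resolution, (b + 1) * resolution)`.
#'
#' @param mat square numeric matrix (symmetric, non-negative).
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param normalized logical flag.
#' @param method normalization method name (`"raw"` for counts).
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, chrom, resolution, normalized = FALSE,
                           method = "raw") {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-9 * max(1, max(abs(mat))))
    stop("contact matrix must be symmetric")
  if (any(mat < 0)) stop("contact matrix must be non-negative")
  structure(list(matrix = mat, chrom = chrom, resolution = resolution,
                 n_bins = nrow(mat), normalized = normalized,
                 method = method),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s: %d bins @ %d bp (%s)\n", x$chrom,
              x$n_bins, as.integer(x$resolution),
              if (x$normalized) x$method else "raw counts"))
  invisible(x)
}

#' Load a contact matrix from plain text
#'
#' COO format: three tab-separated columns `bin_i`, `bin_j`, `count`
#' (0-based bins); missing pairs are zero and entries are mirrored.
#' Conflicting duplicate entries (the same unordered pair given twice with
#' different counts) raise an error. `dense` format: an `n x n` TSV.
#'
#' @param path input file.
#' @param chrom chromosome name.
#' @param resolution bin size (bp).
#' @param n_bins bin count; defaults to `ceiling(sizes[chrom]/resolution)`.
#' @param sizes chromosome lengths (used when `n_bins` is missing).
#' @param format `"coo"` or `"dense"`.
#' @return A [contact_matrix()] of raw counts.
#' @export
load_contact_matrix <- function(path, chrom, resolution, n_bins = NULL,
                                sizes = NULL, format = c("coo", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    return(contact_matrix(m, chrom, resolution))
  }
  if (is.null(n_bins)) {
    if (is.null(sizes) || !chrom %in% names(sizes))
      stop("n_bins or sizes[chrom] required for ", chrom)
    n_bins <- as.integer(ceiling(sizes[[chrom]] / resolution))
  }
  m <- matrix(0, n_bins, n_bins)
  rec <- read_record_lines(path)
  if (length(rec$line_no)) {
    rec <- field_matrix(rec, 3L, "COO matrix")
    ln <- rec$line_no
    i <- parse_int(col_of(rec, 1), ln, "bin_i")
    j <- parse_int(col_of(rec, 2), ln, "bin_j")
    v <- parse_num(col_of(rec, 3), ln, "count")
    bad <- i < 0 | j < 0 | i >= n_bins | j >= n_bins
    if (any(bad))
      stop(sprintf("line %d: bin index out of range [0, %d)", ln[bad][1],
                   n_bins))
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    key <- paste(lo, hi)
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      agree <- tapply(v[dup], key[dup], function(x) length(unique(x)) == 1)
      if (!all(agree))
        stop("conflicting duplicate entries for bin pair(s): ",
             paste(names(agree)[!agree], collapse = "; "))
      keep <- !duplicated(key)
      lo <- lo[keep]; hi <- hi[keep]; v <- v[keep]
    }
    m[cbind(lo + 1L, hi + 1L)] <- v
    m[cbind(hi + 1L, lo + 1L)] <- v
  }
  contact_matrix(m, chrom, resolution)
}

#' Write a contact matrix as COO text
#'
#' Upper-triangle non-zero entries, 0-based bins.
#' @param cm a [contact_matrix()].
#' @param path output file.
#' @export
write_contact_matrix <- function(cm, path) {
  idx <- which(upper.tri(cm$matrix, diag = TRUE) & cm$matrix != 0,
               arr.ind = TRUE)
  d <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                  count = cm$matrix[idx])
  d <- d[order(d$i, d$j), ]
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' VC_SQRT balancing
#'
#' Divides each entry by the square roots of its row and column sums
#' (vanilla-coverage square root), leaves all-zero rows untouched (their
#' indices are recorded in the `zero_rows` attribute), then rescales by a
#' single constant so the mean of non-zero entries is preserved. Scores
#' built on ratios of normalized entries are invariant to the rescaling.
#'
#' @param cm raw-count [contact_matrix()].
#' @return Normalized `contact_matrix` (`method = "VC_SQRT"`).
#' @export
vc_sqrt_normalize <- function(cm) {
  m <- cm$matrix
  if (all(m == 0)) stop("cannot normalize an all-zero matrix")
  r <- rowSums(m)
  w <- ifelse(r > 0, 1 / sqrt(r), 0)
  norm <- m * outer(w, w)
  scale <- mean(m[m > 0]) / mean(norm[norm > 0])
  norm <- norm * scale
  out <- contact_matrix(norm, cm$chrom, cm$resolution, normalized = TRUE,
                        method = "VC_SQRT")
  attr(out, "zero_rows") <- which(r == 0) - 1L
  out
}

# 0-based bin range covered by a GRanges span on the matrix chromosome
anchor_bins <- function(cm, anchor) {
  if (length(anchor) != 1)
    stop("exactly one anchor interval is required")
  if (as.character(GenomeInfoDb::seqnames(anchor)) != cm$chrom)
    stop("anchor chromosome does not match matrix chromosome ", cm$chrom)
  b <- gr_to_bed(anchor)
  lo <- b$start %/% cm$resolution
  hi <- (b$end - 1) %/% cm$resolution
  if (lo < 0 || hi >= cm$n_bins)
    stop("anchor outside the matrix span")
  lo:hi
}

#' Virtual 4C viewpoint profile
#'
#' Mean of the matrix rows covered by the anchor: a one-versus-all
#' interaction profile for the viewpoint.
#'
#' @param cm a [contact_matrix()] (raw or normalized; the choice is
#'   recorded in the output).
#' @param anchor single-interval `GRanges` viewpoint on `cm$chrom`.
#' @return data.frame with `bin`, `start`, `end` (BED coords) and `signal`;
#'   attribute `counts` names the matrix state used.
#' @export
virtual_4c <- function(cm, anchor) {
  bins <- anchor_bins(cm, anchor)
  profile <- colMeans(cm$matrix[bins + 1L, , drop = FALSE])
  out <- data.frame(bin = seq_len(cm$n_bins) - 1L,
                    start = (seq_len(cm$n_bins) - 1L) * cm$resolution,
                    end = seq_len(cm$n_bins) * cm$resolution,
                    signal = profile)
  attr(out, "counts") <- if (cm$normalized) cm$method else "raw"
  out
}

#' Aggregate peak analysis (APA)
#'
#' For each intra-chromosomal loop, the `(2w+1) x (2w+1)` submatrix
#' centered on the loop pixel (midpoint bin of each anchor, row = upstream
#' anchor) is extracted; surviving windows are averaged element-wise. Loops
#' are skipped, with counted reasons, when the pixel lies within `2w` bins
#' of the diagonal, when the window leaves the matrix, or when no matrix is
#' supplied for their chromosome. The enrichment score is the center pixel
#' divided by the mean of the `corner x corner` block at the lower-left
#' (short-distance) corner.
#'
#' @param matrices a [contact_matrix()] or named list of them (by
#'   chromosome), normally VC_SQRT-normalized.
#' @param loops a [loop_set].
#' @param window half-width `w` in bins.
#' @param corner corner block edge length (bins).
#' @return Object of class `apa_result`: list with `aggregate`, `score`,
#'   `n_used`, `n_skipped`, `skip_reasons`, `window`.
#' @export
apa <- function(matrices, loops, window = 6, corner = 3) {
  stopifnot(window >= 1, corner >= 1, corner <= window)
  if (inherits(matrices, "contact_matrix"))
    matrices <- stats::setNames(list(matrices), matrices$chrom)
  w <- as.integer(window)
  size <- 2L * w + 1L
  agg <- matrix(0, size, size)
  used <- 0L
  reasons <- c(inter_chromosomal = 0L, no_matrix = 0L, near_diagonal = 0L,
               out_of_matrix = 0L)
  d1 <- as.data.frame.loop_set(loops)
  for (k in seq_len(length(loops))) {
    if (d1$inter_chromosomal[k]) {
      reasons["inter_chromosomal"] <- reasons["inter_chromosomal"] + 1L
      next
    }
    chrom <- d1$chrom1[k]
    cm <- matrices[[chrom]]
    if (is.null(cm)) {
      reasons["no_matrix"] <- reasons["no_matrix"] + 1L
      next
    }
    res <- cm$resolution
    i <- ((d1$start1[k] + d1$end1[k]) %/% 2) %/% res
    j <- ((d1$start2[k] + d1$end2[k]) %/% 2) %/% res
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    if (j - i <= 2L * w) {
      reasons["near_diagonal"] <- reasons["near_diagonal"] + 1L
      next
    }
    if (i - w < 0L || j + w >= cm$n_bins) {
      reasons["out_of_matrix"] <- reasons["out_of_matrix"] + 1L
      next
    }
    agg <- agg + cm$matrix[(i - w):(i + w) + 1L, (j - w):(j + w) + 1L]
    used <- used + 1L
  }
  if (used == 0L)
    stop("no loops survived APA filtering (",
         paste(names(reasons), reasons, sep = "=", collapse = ", "), ")")
  agg <- agg / used
  ll_rows <- (size - corner + 1L):size
  ll_cols <- 1L:corner
  score <- agg[w + 1L, w + 1L] / mean(agg[ll_rows, ll_cols])
  structure(list(aggregate = agg, score = score, n_used = used,
                 n_skipped = sum(reasons), skip_reasons = reasons,
                 window = w),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA: %d loops aggregated (%d skipped), window %d, score %.3f\n",
              x$n_used, x$n_skipped, x$window, x$score))
  invisible(x)
}
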