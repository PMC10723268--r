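# Expression comparison between anchor/boundary gene classes on the
# log2(TPM + 1) scale, with self-contained rank-based tests
# (Mann-Whitney/Wilcoxon rank-sum and Kruskal-Wallis).

#' log2(TPM + 1) transform
#'
#' @param tpm non-negative expression values.
#' @return `log2(tpm + 1)`.
#' @export
log2_tpm <- function(tpm) {
  if (any(tpm < 0)) stop("TPM must be non-negative")
  log2(tpm + 1)
}

#' Empirical cumulative distribution function
#'
#' Thin wrapper over [stats::ecdf()] with an explicit error for empty
#' input; the returned step function is right-continuous with
#' `F(max) = 1`.
#'
#' @param values non-empty numeric vector.
#' @return An `ecdf` step function.
#' @export
ecdf_fun <- function(values) {
  if (length(values) == 0) stop("ecdf of an empty sample is undefined")
  if (any(!is.finite(values))) stop("ecdf requires finite values")
  stats::ecdf(values)
}

# exact two-sided p for the Mann-Whitney U by full enumeration of the
# choose(n1 + n2, n1) assignments of pooled ranks (tie-free samples only)
rank_sum_exact_p <- function(u, n1, n2) {
  n <- n1 + n2
  sets <- utils::combn(n, n1)
  us <- colSums(sets) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports the U statistic of the first sample (`U = R1 - n1(n1+1)/2` with
#' midranks for ties), a tie-corrected normal approximation with optional
#' continuity correction, and a two-sided p value. For tie-free samples
#' with `n1 + n2 <= 10` (or `exact = TRUE`) the p value is computed by full
#' enumeration of all rank assignments.
#'
#' @param x,y non-empty numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   chooses automatically. Exact is only available without ties.
#' @param correct apply the 0.5 continuity correction in the normal
#'   approximation.
#' @return List with `statistic` (U), `z`, `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL, correct = TRUE) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  n <- n1 + n2
  tie_tab <- table(pooled)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  mu <- n1 * n2 / 2
  v <- n1 * n2 / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
  d <- u - mu
  if (v <= 0) {
    z <- 0
  } else {
    cc <- if (correct) 0.5 * sign(d) else 0
    z <- (d - cc) / sqrt(v)
    if (correct && abs(d) < 0.5) z <- 0
  }
  use_exact <- if (is.null(exact)) (n <= 10 && !ties) else (exact && !ties)
  if (use_exact) {
    p <- rank_sum_exact_p(u, n1, n2)
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = u, z = z, p.value = p, method = method)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic over k groups with a chi-square (k - 1 df)
#' upper-tail p value.
#'
#' @param groups list of at least two non-empty numeric samples.
#' @return List with `statistic` (H), `df`, `p.value`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, grp, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  tie_tab <- table(pooled)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  list(statistic = h, df = length(groups) - 1,
       p.value = stats::pchisq(h, length(groups) - 1, lower.tail = FALSE),
       group_sizes = as.integer(sizes))
}

# look up log2(TPM+1) for gene ids, dropping (with a message) ids missing
# from the expression table
expression_values <- function(gene_ids, expression) {
  idx <- match(gene_ids, expression$gene_id)
  missing <- is.na(idx)
  if (any(missing))
    message("compare_groups: dropping ", sum(missing),
            " gene id(s) absent from the expression table")
  list(values = log2_tpm(expression$tpm[idx[!missing]]),
       gene_ids = gene_ids[!missing], n_dropped = sum(missing))
}

#' Compare expression between anchor-defined gene groups
#'
#' Two groupings are supported. `"h3k27me3_vs_not"` follows the repressive
#' loop analysis: over annotated loops, take every anchor paired with a
#' p300-only anchor and collect its genes, split by whether that anchor
#' carries H3K27me3 ("H3K27me3" vs "nonH3K27me3"); groups are made disjoint
#' by gene id with H3K27me3 taking precedence; the two groups are compared
#' with the rank-sum test. `"boundary_pair_category"` follows the boundary
#' analysis: for TADs whose boundary pair falls in `PP`, `PG` or `PT`, each
#' boundary gene's expression is collected under the pair label (counted
#' once per TAD-boundary occurrence) and groups are compared with the
#' Kruskal-Wallis test.
#'
#' @param annotations for `"h3k27me3_vs_not"`, the list returned by
#'   [annotate_loops()]; for `"boundary_pair_category"`, the data.frame from
#'   [boundary_gene_pairs()].
#' @param expression data.frame from [read_expression()].
#' @param grouping one of `"h3k27me3_vs_not"`, `"boundary_pair_category"`.
#' @return List with `groups` (named list of log2(TPM+1) vectors),
#'   `gene_ids`, `sizes`, `medians`, `test`, `n_dropped`.
#' @export
compare_groups <- function(annotations, expression,
                           grouping = c("h3k27me3_vs_not",
                                        "boundary_pair_category")) {
  grouping <- match.arg(grouping)
  if (grouping == "h3k27me3_vs_not") {
    ann1 <- annotations$ann1
    ann2 <- annotations$ann2
    collect <- function(partner_of_p300, partner) {
      sel <- partner_of_p300
      unlist(partner$gene_ids[sel], use.names = FALSE)
    }
    me3 <- unique(c(
      collect(ann1$has_p300_only & ann2$has_h3k27me3, ann2),
      collect(ann2$has_p300_only & ann1$has_h3k27me3, ann1)))
    non <- unique(c(
      collect(ann1$has_p300_only & !ann2$has_h3k27me3, ann2),
      collect(ann2$has_p300_only & !ann1$has_h3k27me3, ann1)))
    non <- setdiff(non, me3)   # disjoint groups, H3K27me3 precedence
    ids <- list(H3K27me3 = me3, nonH3K27me3 = non)
  } else {
    keep <- !is.na(annotations$category) &
      annotations$category %in% c("PP", "PG", "PT")
    ids <- list()
    for (i in which(keep)) {
      lab <- annotations$category[i]
      ids[[lab]] <- c(ids[[lab]], annotations$left_genes[[i]],
                      annotations$right_genes[[i]])
    }
  }
  vals <- lapply(ids, expression_values, expression = expression)
  empty <- names(vals)[vapply(vals, function(v) length(v$values) == 0,
                              logical(1))]
  if (length(empty))
    stop("group(s) empty after filtering: ", paste(empty, collapse = ", "))
  groups <- lapply(vals, `[[`, "values")
  test <- if (grouping == "h3k27me3_vs_not") {
    rank_sum_test(groups[[1]], groups[[2]])
  } else {
    kruskal_wallis(groups)
  }
  list(groups = groups,
       gene_ids = lapply(vals, `[[`, "gene_ids"),
       sizes = vapply(groups, length, integer(1)),
       medians = vapply(groups, stats::median, numeric(1)),
       test = test,
       n_dropped = sum(vapply(vals, `[[`, numeric(1), "n_dropped")))
}
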