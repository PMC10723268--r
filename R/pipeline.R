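# Orchestration of the two end-to-end analyses: the loop analysis
# (p300-only derivation -> anchor annotation -> census/mark fraction ->
# expression comparison -> APA) and the boundary analysis (boundary
# windows -> gene-feature pairs -> census -> head-to-tail detection ->
# oncogene scan -> per-category expression comparison).

#' Pipeline configuration
#'
#' Parameter defaults are the analysis' canonical values: promoter TSS +/-
#' 1 kb, terminator TES +/- 5 kb, boundary +/- 5 kb, H3K27ac extension +/-
#' 1 kb, APA at 25 kb bins with window 6. Input paths may be `NULL` when
#' the corresponding stage is skipped or when an in-memory dataset is
#' supplied to [run_pipeline()].
#'
#' @param genes,p300,h3k27ac,h3k27me3,loops,tads,expression input file
#'   paths (BED12, narrowPeak, narrowPeak, narrowPeak, BEDPE, BED,
#'   expression TSV).
#' @param matrices named character vector of COO matrix paths, one per
#'   chromosome.
#' @param chrom_sizes chrom.sizes path.
#' @param oncogenes optional path to a one-id-per-line oncogene list.
#' @param out_dir output directory (`NULL` = no files written).
#' @param promoter_flank,terminator_flank,boundary_flank,h3k27ac_extend
#'   window parameters in bp.
#' @param apa_resolution,apa_window APA parameters.
#' @param merge_slack loop-merging tolerance in bp (defaults to one bin).
#' @param seed seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genes = NULL, p300 = NULL, h3k27ac = NULL,
                            h3k27me3 = NULL, loops = NULL, tads = NULL,
                            expression = NULL, matrices = NULL,
                            chrom_sizes = NULL, oncogenes = NULL,
                            out_dir = NULL,
                            promoter_flank = 1000, terminator_flank = 5000,
                            boundary_flank = 5000, h3k27ac_extend = 1000,
                            apa_resolution = 25000, apa_window = 6,
                            merge_slack = apa_resolution, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

load_pipeline_inputs <- function(config) {
  sizes <- if (!is.null(config$chrom_sizes))
    read_chrom_sizes(config$chrom_sizes) else NULL
  read_if <- function(path, fun, ...) if (is.null(path)) NULL else fun(path, ...)
  list(
    sizes = sizes,
    genes = read_if(config$genes, read_genes, sizes = sizes),
    p300 = read_if(config$p300, read_intervals, format = "narrowPeak",
                   sizes = sizes),
    h3k27ac = read_if(config$h3k27ac, read_intervals, format = "narrowPeak",
                      sizes = sizes),
    h3k27me3 = read_if(config$h3k27me3, read_intervals,
                       format = "narrowPeak", sizes = sizes),
    loops = read_if(config$loops, read_pairs, sizes = sizes),
    tads = read_if(config$tads, read_intervals, format = "bed6",
                   sizes = sizes),
    expression = read_if(config$expression, read_expression),
    oncogenes = if (is.null(config$oncogenes)) NULL else
      readLines(config$oncogenes),
    matrices = if (is.null(config$matrices)) NULL else
      stats::setNames(lapply(names(config$matrices), function(ch)
        load_contact_matrix(config$matrices[[ch]], ch,
                            config$apa_resolution, sizes = sizes)),
        names(config$matrices)))
}

#' Loop analysis: repressive p300-only/H3K27me3 loops
#'
#' Derives p300-only peaks, annotates both anchors of every loop, censuses
#' interaction categories, computes the p300-only/H3K27me3 anchoring
#' fraction, compares expression of genes looped to p300-only anchors
#' (split by H3K27me3), and runs APA over the qualifying loops on
#' VC_SQRT-normalized matrices.
#'
#' @param genes gene `GRanges`.
#' @param p300,h3k27ac,h3k27me3 peak `GRanges`.
#' @param loops a [loop_set].
#' @param sizes chromosome lengths.
#' @param expression optional expression data.frame.
#' @param matrices optional named list of raw [contact_matrix()] objects.
#' @param config a [pipeline_config()] supplying parameters.
#' @return List: `p300_only`, `annotation` (see [annotate_loops()]),
#'   `census`, `mark_fraction`, `expr` (or `NULL`), `apa` (or `NULL`).
#' @export
run_loop_analysis <- function(genes, p300, h3k27ac, h3k27me3, loops, sizes,
                              expression = NULL, matrices = NULL,
                              config = pipeline_config()) {
  log_stage("p300only", "%d p300 peaks vs %d H3K27ac peaks (extend %d bp)",
            length(p300), length(h3k27ac), config$h3k27ac_extend)
  p300_only <- derive_p300_only(p300, h3k27ac, config$h3k27ac_extend, sizes)
  log_stage("p300only", "%d p300-only peaks", length(p300_only))
  ann <- annotate_loops(loops, genes, p300_only, h3k27me3,
                        config$promoter_flank, config$terminator_flank)
  log_stage("classify-loops", "%d loops; %.2f%% p300only-H3K27me3 anchored",
            length(loops), ann$mark_fraction$percent)
  expr <- NULL
  if (!is.null(expression)) {
    expr <- compare_groups(ann, expression, "h3k27me3_vs_not")
    log_stage("expr-compare",
              "H3K27me3 n=%d median=%.2f vs nonH3K27me3 n=%d median=%.2f, p=%.3g",
              expr$sizes[1], expr$medians[1], expr$sizes[2], expr$medians[2],
              expr$test$p.value)
  }
  apa_res <- NULL
  if (!is.null(matrices)) {
    norm <- lapply(matrices, vc_sqrt_normalize)
    qualifying <- loops[ann$mark_fraction$qualifying]
    apa_res <- apa(norm, qualifying, window = config$apa_window)
    log_stage("apa", "%d qualifying loops, score %.3f", apa_res$n_used,
              apa_res$score)
  }
  list(p300_only = p300_only, annotation = ann, census = ann$census,
       mark_fraction = ann$mark_fraction, expr = expr, apa = apa_res)
}

#' Boundary analysis: TAD-boundary gene pairs and head-to-tail detection
#'
#' Annotates the +/- flank windows of every TAD boundary, censuses boundary
#' interaction categories and the p300-only/H3K27me3 anchoring fraction,
#' derives gene-feature pairs, detects head-to-tail pairs, optionally scans
#' them against an oncogene list, and compares expression across PT/PG/PP
#' boundary categories.
#'
#' @param genes gene `GRanges`.
#' @param tads domain `GRanges`.
#' @param p300_only,h3k27me3 peak `GRanges`.
#' @param sizes chromosome lengths.
#' @param expression optional expression data.frame.
#' @param oncogenes optional character vector of oncogene ids.
#' @param config a [pipeline_config()].
#' @return List: `boundaries`, `annotation` (`ann1`/`ann2` left/right),
#'   `census`, `mark_fraction`, `pairs`, `headtail`, `oncogene` (or
#'   `NULL`), `expr` (or `NULL`).
#' @export
run_boundary_analysis <- function(genes, tads, p300_only, h3k27me3, sizes,
                                  expression = NULL, oncogenes = NULL,
                                  config = pipeline_config()) {
  bd <- tad_boundaries(tads, config$boundary_flank, sizes)
  log_stage("classify-boundaries", "%d TADs -> %d boundary windows",
            length(tads), 2L * length(tads))
  ann1 <- annotate_anchors(bd$left, genes, p300_only, h3k27me3,
                           config$promoter_flank, config$terminator_flank)
  ann2 <- annotate_anchors(bd$right, genes, p300_only, h3k27me3,
                           config$promoter_flank, config$terminator_flank)
  category <- classify_interaction(ann1, ann2)
  mf <- mark_fraction(ann1, ann2)
  log_stage("classify-boundaries", "%.2f%% boundary pairs p300only-H3K27me3",
            mf$percent)
  pairs <- boundary_gene_pairs(tads, genes, config$promoter_flank,
                               config$terminator_flank,
                               config$boundary_flank, sizes)
  ht <- detect_head_to_tail(tads, genes, config$promoter_flank,
                            config$terminator_flank, config$boundary_flank,
                            sizes)
  log_stage("headtail", "%d head-to-tail pairs", nrow(ht))
  onc <- NULL
  if (!is.null(oncogenes)) {
    onc <- oncogene_scan(ht, oncogenes)
    log_stage("headtail", "oncogene fraction %.3f", onc$fraction)
  }
  expr <- NULL
  if (!is.null(expression)) {
    expr <- tryCatch(
      compare_groups(pairs, expression, "boundary_pair_category"),
      error = function(e) {
        log_stage("expr-compare", "skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(expr))
      log_stage("expr-compare", "Kruskal-Wallis H=%.2f p=%.3g",
                expr$test$statistic, expr$test$p.value)
  }
  list(boundaries = bd,
       annotation = list(ann1 = ann1, ann2 = ann2, category = category),
       census = interaction_census(category), mark_fraction = mf,
       pairs = pairs, headtail = ht, oncogene = onc, expr = expr)
}

#' Run the end-to-end pipeline
#'
#' Runs the requested analyses from a configuration (file inputs) or an
#' in-memory synthetic dataset; when `config$out_dir` is set, writes
#' per-stage TSV/JSON outputs plus a resolved-config snapshot. Outputs are
#' deterministic given config and seed.
#'
#' @param config a [pipeline_config()].
#' @param analysis subset of `c("loops", "boundaries")`.
#' @param dataset optional list from [generate_dataset()]; overrides file
#'   inputs.
#' @param matrices optional named list of raw [contact_matrix()] objects
#'   (used with `dataset`).
#' @return List with the requested analysis reports.
#' @export
run_pipeline <- function(config, analysis = c("loops", "boundaries"),
                         dataset = NULL, matrices = NULL) {
  analysis <- match.arg(analysis, several.ok = TRUE)
  set.seed(config$seed)
  if (is.null(dataset)) {
    inp <- load_pipeline_inputs(config)
  } else {
    inp <- list(sizes = dataset$sizes, genes = dataset$genes,
                p300 = dataset$peaks$p300, h3k27ac = dataset$peaks$h3k27ac,
                h3k27me3 = dataset$peaks$h3k27me3, loops = dataset$loops,
                tads = dataset$tads, expression = dataset$expression,
                oncogenes = NULL, matrices = matrices)
  }
  report <- list()
  if ("loops" %in% analysis) {
    if (is.null(inp$loops)) stop("stage classify-loops: no loop input")
    report$loops <- run_loop_analysis(inp$genes, inp$p300, inp$h3k27ac,
                                      inp$h3k27me3, inp$loops, inp$sizes,
                                      inp$expression, inp$matrices, config)
  }
  if ("boundaries" %in% analysis) {
    if (is.null(inp$tads)) stop("stage classify-boundaries: no TAD input")
    p300_only <- if (!is.null(report$loops)) report$loops$p300_only else
      derive_p300_only(inp$p300, inp$h3k27ac, config$h3k27ac_extend,
                       inp$sizes)
    report$boundaries <- run_boundary_analysis(inp$genes, inp$tads,
                                               p300_only, inp$h3k27me3,
                                               inp$sizes, inp$expression,
                                               inp$oncogenes, config)
  }
  if (!is.null(config$out_dir)) write_report(report, config)
  invisible(report)
}

# serialize the per-stage outputs next to a resolved-config snapshot
write_report <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(config$out_dir, x)
  cfg <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(cfg, fp("resolved_config.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(report$loops)) {
    r <- report$loops
    write_intervals(r$p300_only, fp("p300_only.bed"), "bed6")
    summary <- list(census = as.list(r$census),
                    mark_fraction = r$mark_fraction[
                      c("fraction", "percent", "n_pairs", "n_qualifying")])
    if (!is.null(r$expr))
      summary$expression <- list(sizes = as.list(r$expr$sizes),
                                 medians = as.list(r$expr$medians),
                                 p = r$expr$test$p.value)
    if (!is.null(r$apa))
      summary$apa <- list(score = r$apa$score, n_used = r$apa$n_used)
    jsonlite::write_json(summary, fp("loop_report.json"), auto_unbox = TRUE,
                         digits = NA)
    d <- data.frame(category = r$annotation$category,
                    qualifying = r$mark_fraction$qualifying)
    data.table::fwrite(d, fp("loop_categories.tsv"), sep = "\t")
  }
  if (!is.null(report$boundaries)) {
    r <- report$boundaries
    data.table::fwrite(r$headtail, fp("headtail_pairs.tsv"), sep = "\t")
    summary <- list(census = as.list(r$census),
                    mark_fraction = r$mark_fraction[
                      c("fraction", "percent", "n_pairs", "n_qualifying")],
                    n_headtail = nrow(r$headtail))
    if (!is.null(r$oncogene)) summary$oncogene_fraction <- r$oncogene$fraction
    if (!is.null(r$expr))
      summary$expression <- list(sizes = as.list(r$expr$sizes),
                                 p = r$expr$test$p.value)
    jsonlite::write_json(summary, fp("boundary_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(config$out_dir)
}
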