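# End-to-end orchestration over synthetic or user-supplied inputs, plus the
# ratio-string report formatting used throughout the summaries.

#' Build a validated pipeline configuration
#'
#' Houses the analysis constants: similarity retention threshold 1e-5 for
#' phylostratigraphy, 1e-40 for OR-to-reference association, tandem-array
#' gap bound 20 kbp, raw-count restriction threshold 10, and the adjusted-p
#' cutoff 0.05, with Benjamini-Hochberg adjustment.
#'
#' @param evalue_threshold_phylostrat,evalue_threshold_association E-value
#'   thresholds, > 0.
#' @param max_gap_bp Tandem-array gap bound (bp), > 0.
#' @param restriction_count_threshold Raw-count threshold, > 0.
#' @param alpha_padj Adjusted-p cutoff in (0, 1).
#' @param focal_tissue,focal_species Focal labels.
#' @param adjustment_method Multiple-testing method (stats::p.adjust name).
#' @param seed Integer seed governing all synthetic stages.
#' @param n_genes_counts,n_genes_families,n_genes_layout Problem sizes for
#'   the synthetic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_threshold_phylostrat = 1e-5,
                            evalue_threshold_association = 1e-40,
                            max_gap_bp = 20000,
                            restriction_count_threshold = 10,
                            alpha_padj = 0.05,
                            focal_tissue = "antennae",
                            focal_species = "focal_sp",
                            adjustment_method = "BH",
                            seed = 1,
                            n_genes_counts = 2000,
                            n_genes_families = 50,
                            n_genes_layout = 60) {
  stopifnot(evalue_threshold_phylostrat > 0, evalue_threshold_association > 0,
            max_gap_bp > 0, restriction_count_threshold > 0,
            alpha_padj > 0, alpha_padj < 1)
  cfg <- list(evalue_threshold_phylostrat = evalue_threshold_phylostrat,
              evalue_threshold_association = evalue_threshold_association,
              max_gap_bp = max_gap_bp,
              restriction_count_threshold = restriction_count_threshold,
              alpha_padj = alpha_padj, focal_tissue = focal_tissue,
              focal_species = focal_species,
              adjustment_method = adjustment_method, seed = seed,
              n_genes_counts = n_genes_counts,
              n_genes_families = n_genes_families,
              n_genes_layout = n_genes_layout)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(unclass(cfg)))]), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic pipeline end to end
#'
#' Generates synthetic inputs for the enabled stages under the config seed
#' and runs each analysis: phylostratigraphy (direct-hit simulation ->
#' best-hit reduction -> stratum assignment -> TRPs), tandem arrays (planted
#' layout -> detection -> size histogram), and expression (NB counts ->
#' pruning -> per-tissue DE -> upregulated-vs-all -> upset counts ->
#' restriction filter). Each stage's recovered quantities are paired with
#' the generator's planted truth in the returned report, which is stamped
#' with the config hash and seed; rerunning with an identical config gives
#' an identical report.
#'
#' @param config A `pipeline_config`.
#' @param stages Character subset of `c("phylostrat", "arrays",
#'   "expression")`.
#' @return List of class `pipeline_report` with one element per enabled
#'   stage plus `config_hash` and `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("phylostrat", "arrays", "expression")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(config_hash = config_hash(config), seed = config$seed)

  if ("phylostrat" %in% stages) {
    sim_tree <- simulate_species_set(config$seed)
    fam <- simulate_gene_families(sim_tree$tree, n_genes = config$n_genes_families,
                                  mode = "direct_hits", seed = config$seed)
    best <- best_hit_per_species(fam$hits)
    assign <- assign_strata(best, sim_tree$tree, fam$truth$gene_id)
    report$phylostrat <- list(
      assignments = assign,
      trps = find_trps(assign),
      truth = fam$truth,
      stratum_recovery = mean(assign$node_distance ==
                                fam$truth$birth_distance[match(assign$protein_id,
                                                               fam$truth$gene_id)]))
  }

  if ("arrays" %in% stages) {
    layout <- simulate_genome_layout(n_genes = config$n_genes_layout,
                                     seed = config$seed)
    arrays <- detect_arrays(layout$genes, max_gap = config$max_gap_bp)
    planted <- lapply(layout$truth$planted_arrays, sort)
    detected <- lapply(arrays$members, sort)
    report$arrays <- list(
      arrays = arrays,
      histogram = array_size_histogram(arrays),
      truth = layout$truth,
      exact_recovery = setequal(
        vapply(planted, paste, character(1), collapse = ","),
        vapply(detected, paste, character(1), collapse = ",")))
  }

  if ("expression" %in% stages) {
    sim <- simulate_counts(n_genes = config$n_genes_counts, seed = config$seed)
    pruned <- prune_single_sample(sim$counts)
    other <- setdiff(tissues(pruned), config$focal_tissue)
    de <- lapply(other, function(t) nb_de_test(pruned, config$focal_tissue, t))
    names(de) <- other
    up_sets <- lapply(de, upregulated_set, alpha = config$alpha_padj)
    up_all <- upregulated_vs_all(de, alpha = config$alpha_padj)
    restricted <- expression_restricted(pruned, config$focal_tissue,
                                        threshold = config$restriction_count_threshold)
    planted <- sim$truth$planted_upregulated
    no_effect <- c(setdiff(rownames(pruned$counts),
                           c(planted, sim$truth$planted_restricted)))
    report$expression <- list(
      n_genes_pruned = nrow(sim$counts$counts) - nrow(pruned$counts),
      upregulated_sets = up_sets,
      upregulated_vs_all = up_all,
      upset = upset_counts(up_sets),
      restricted = restricted,
      truth = sim$truth,
      recovery = length(intersect(up_all, planted)) / max(1, length(planted)),
      false_inclusion = length(intersect(up_all, no_effect)) / max(1, length(up_all)))
  }
  class(report) <- "pipeline_report"
  report
}

#' Format a count ratio the way the results are reported
#'
#' `"k/n, p%"` strings. One-decimal percentages truncate toward zero (so
#' 125/367 prints as `"34.0%"`); integer percentages round to the nearest
#' whole percent (so 376/4288 prints as `"9%"`).
#'
#' @param k,n Numerator and denominator counts.
#' @param style `"decimal"` (default) or `"integer"`.
#' @return Character scalar.
#' @export
format_ratio <- function(k, n, style = c("decimal", "integer")) {
  style <- match.arg(style)
  pct <- 100 * k / n
  if (style == "decimal") {
    sprintf("%d/%d, %.1f%%", k, n, trunc(pct * 10 + 1e-9) / 10)
  } else {
    sprintf("%d/%d, %.0f%%", k, n, round(pct))
  }
}

#' Human-readable pipeline summary
#'
#' One line per stage with the record counts and recovered-vs-planted rates,
#' in the `k/n, p%` presentation style.
#'
#' @param report A `pipeline_report`.
#' @return Character vector of summary lines (also printed).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  lines <- c(sprintf("pipeline run: seed %d, config %s", report$seed,
                     report$config_hash))
  if (!is.null(report$phylostrat)) {
    p <- report$phylostrat
    lines <- c(lines,
               sprintf("phylostrat: %s proteins age-assigned; TRPs %s; stratum recovery %.1f%%",
                       nrow(p$assignments),
                       format_ratio(length(p$trps), nrow(p$assignments)),
                       100 * p$stratum_recovery))
  }
  if (!is.null(report$arrays)) {
    a <- report$arrays
    lines <- c(lines,
               sprintf("arrays: %d arrays over %d genes; planted partition recovered: %s",
                       nrow(a$arrays), sum(a$arrays$size),
                       ifelse(a$exact_recovery, "yes", "no")))
  }
  if (!is.null(report$expression)) {
    e <- report$expression
    lines <- c(lines,
               sprintf("expression: %d genes pruned; %d upregulated-vs-all; planted recovery %.1f%%; false inclusion %.1f%%",
                       e$n_genes_pruned, length(e$upregulated_vs_all),
                       100 * e$recovery, 100 * e$false_inclusion))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.pipeline_report <- function(x, ...) {
  summarize_report(x)
  invisible(x)
}
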