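# Count filters, a simplified negative-binomial DE test for synthetic
# end-to-end runs, multi-tissue upregulation set logic, upset counts, and
# Fisher enrichment.

#' Prune transcripts detected in at most one sample
#'
#' Removes genes whose count is nonzero in at most one sample across all
#' samples (all-zero rows are removed too). All other genes are retained
#' unchanged.
#'
#' @param counts A `count_matrix`.
#' @return A `count_matrix` with the surviving genes.
#' @export
prune_single_sample <- function(counts) {
  keep <- rowSums(counts$counts > 0) >= 2L
  count_matrix(counts$counts[keep, , drop = FALSE], counts$tissue_of)
}

.size_factors <- function(m) {
  # median-of-ratios; fall back to library-size ratios when no gene is
  # positive in every sample
  pos <- rowSums(m > 0) == ncol(m)
  if (any(pos)) {
    logref <- rowMeans(log(m[pos, , drop = FALSE]))
    sf <- apply(m[pos, , drop = FALSE], 2, function(col) exp(median(log(col) - logref)))
  } else {
    ls <- colSums(m)
    sf <- ls / exp(mean(log(ls)))
  }
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial differential-expression test
#'
#' A transparent stand-in used for synthetic end-to-end runs; real analyses
#' supply externally fitted DE tables through [read_de_table()]. Per
#' comparison: median-of-ratios size factors over the samples of the two
#' tissues; per-gene group means on normalized counts; per-gene
#' method-of-moments dispersion (variance = mu + alpha * mu^2) pooled across
#' the two groups, floored at 1e-8 and moderated toward a fitted
#' mean-dispersion trend `alpha(mu) = a0 + a1/mu` (weights: residual df vs a
#' prior weight of 10, the usual shrinkage recipe for 3-4 replicates); a
#' Wald test on the log2 fold change (delta-method standard error, t
#' reference whose df adds the prior weight to the residual df);
#' Benjamini-Hochberg adjustment within the comparison.
#'
#' @param counts A `count_matrix`.
#' @param tissue_A,tissue_B Tissue labels to compare; positive `log2fc`
#'   means higher in `tissue_A`. Each needs >= 2 samples.
#' @return data.frame with columns `gene_id`, `base_mean`, `log2fc`,
#'   `pvalue`, `padj`; attribute `comparison` = c(tissue_A, tissue_B).
#' @export
nb_de_test <- function(counts, tissue_A, tissue_B) {
  sel_A <- names(counts$tissue_of)[counts$tissue_of == tissue_A]
  sel_B <- names(counts$tissue_of)[counts$tissue_of == tissue_B]
  if (length(sel_A) < 2 || length(sel_B) < 2) {
    stop("each tissue needs >= 2 samples (", tissue_A, ": ", length(sel_A),
         ", ", tissue_B, ": ", length(sel_B), ")")
  }
  m <- counts$counts[, c(sel_A, sel_B), drop = FALSE]
  sf <- .size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  iA <- seq_along(sel_A); iB <- length(sel_A) + seq_along(sel_B)
  nA <- length(iA); nB <- length(iB)
  muA <- rowMeans(norm[, iA, drop = FALSE])
  muB <- rowMeans(norm[, iB, drop = FALSE])
  vA <- apply(norm[, iA, drop = FALSE], 1, var)
  vB <- apply(norm[, iB, drop = FALSE], 1, var)
  v_pool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu_pool <- (nA * muA + nB * muB) / (nA + nB)
  alpha_raw <- pmax((v_pool - mu_pool) / pmax(mu_pool, 1e-8)^2, 1e-8)
  df_res <- nA + nB - 2
  d_prior <- 10
  use <- mu_pool > 1
  if (sum(use) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu_pool[use]), alpha_raw[use])
    a0 <- max(fit$coefficients[1], 1e-8)
    a1 <- max(fit$coefficients[2], 0)
    trend <- pmax(a0 + a1 / pmax(mu_pool, 1e-8), 1e-8)
    alpha <- (df_res * alpha_raw + d_prior * trend) / (df_res + d_prior)
  } else {
    alpha <- alpha_raw
    d_prior <- 0
  }
  pc <- 0.5  # pseudocount keeps log2fc finite for all-zero groups
  log2fc <- log2((muA + pc) / (muB + pc))
  # delta method on log2 of shifted means; Var(mean of K/sf) summed per sample
  var_mean <- function(idx, mu) {
    v <- rep(0, nrow(m))
    for (s in idx) v <- v + (mu / sf[s] + alpha * mu^2)
    v / length(idx)^2
  }
  se2 <- var_mean(iA, muA) / (muA + pc)^2 + var_mean(iB, muB) / (muB + pc)^2
  se <- sqrt(se2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pt(-abs(z), df = df_res + d_prior)
  p[muA + muB == 0] <- 1
  out <- data.frame(gene_id = rownames(m), base_mean = rowMeans(norm),
                    log2fc = log2fc, pvalue = p,
                    padj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "comparison") <- c(tissue_A, tissue_B)
  out
}

#' Read an externally produced differential-expression table
#'
#' TSV with columns `gene_id`, `log2fc`, `pvalue`, `padj` (positive `log2fc`
#' = higher in the focal tissue of the comparison).
#'
#' @param path Path to a TSV file.
#' @param comparison Optional length-2 character vector (tissue_A, tissue_B)
#'   stored as an attribute.
#' @return data.frame of DE results.
#' @export
read_de_table <- function(path, comparison = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  ok <- !is.na(tab$padj) & !is.na(tab$pvalue)
  if (any(tab$padj[ok] < tab$pvalue[ok] - 1e-12)) stop("padj < pvalue in ", path)
  attr(tab, "comparison") <- comparison
  tab
}

#' Genes upregulated in the focal tissue versus every other tissue
#'
#' The conjunction rule: a gene qualifies when it has `log2fc > 0` and
#' `padj < alpha` in every supplied comparison (one DE table per non-focal
#' tissue, focal tissue first in each comparison). Missing or NA adjusted
#' p-values never qualify.
#'
#' @param results Named list of DE tables (one per non-focal tissue).
#' @param alpha Adjusted-p threshold, strict; default 0.05.
#' @return Character vector of gene ids.
#' @export
upregulated_vs_all <- function(results, alpha = 0.05) {
  if (length(results) == 0L) stop("no comparison tables supplied")
  sets <- lapply(results, upregulated_set, alpha = alpha)
  Reduce(intersect, sets)
}

#' Upregulated genes in a single comparison
#' @param de A DE table.
#' @param alpha Adjusted-p threshold, strict.
#' @return Character vector of gene ids with `log2fc > 0` and `padj < alpha`.
#' @export
upregulated_set <- function(de, alpha = 0.05) {
  sel <- !is.na(de$padj) & de$padj < alpha & de$log2fc > 0
  de$gene_id[sel]
}

#' Exclusive intersection (upset) counts over a family of sets
#'
#' Standard upset semantics: each element is counted once, under the exact
#' signature of sets it belongs to; the signature label joins the member set
#' names with `&` in the input order. Per-set marginal totals are returned
#' alongside.
#'
#' @param sets Named list of character vectors (>= 1 set).
#' @return List with `intersections` (named integer vector over non-empty
#'   signatures, sorted by decreasing count) and `marginals` (named integer
#'   vector, one entry per input set).
#' @export
upset_counts <- function(sets) {
  if (length(sets) < 1L) stop("need at least one set")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("sets must be named")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  inter <- table(sig)
  inter <- sort(setNames(as.integer(inter), names(inter)), decreasing = TRUE)
  list(intersections = inter,
       marginals = vapply(sets, function(s) length(unique(s)), integer(1)))
}

#' Expression-restricted transcripts
#'
#' Genes whose raw (un-normalized, possibly fractional) count is below
#' `threshold` in every sample of every non-focal tissue — the strict
#' per-sample reading of "counts < 10 in other tissues". With
#' `per_sample = FALSE` the rule applies to per-tissue mean counts instead.
#' No condition is placed on focal-tissue expression unless `require_focal`
#' is set, in which case at least one focal sample must reach `threshold`.
#'
#' @param counts A `count_matrix`.
#' @param focal_tissue Tissue whose expression is exempt from the filter.
#' @param threshold Raw-count threshold, strict upper bound; default 10.
#' @param per_sample Apply the rule per sample (default) or to tissue means.
#' @param require_focal Additionally require focal expression >= threshold
#'   in some sample; default FALSE.
#' @return Character vector of gene ids.
#' @export
expression_restricted <- function(counts, focal_tissue, threshold = 10,
                                  per_sample = TRUE, require_focal = FALSE) {
  if (!focal_tissue %in% counts$tissue_of) stop("focal tissue not present: ", focal_tissue)
  non_focal <- names(counts$tissue_of)[counts$tissue_of != focal_tissue]
  m <- counts$counts
  if (per_sample) {
    ok <- apply(m[, non_focal, drop = FALSE], 1, max) < threshold
  } else {
    tis <- counts$tissue_of[non_focal]
    tlabs <- unique(unname(tis))
    means <- matrix(0, nrow(m), length(tlabs))
    for (k in seq_along(tlabs)) {
      means[, k] <- rowMeans(m[, non_focal[tis == tlabs[k]], drop = FALSE])
    }
    ok <- apply(means, 1, max) < threshold
  }
  if (require_focal) {
    focal <- names(counts$tissue_of)[counts$tissue_of == focal_tissue]
    ok <- ok & apply(m[, focal, drop = FALSE], 1, max) >= threshold
  }
  rownames(m)[ok]
}

# two-sided Fisher exact p by hypergeometric enumeration over the 2x2 table
# [[a, b], [c, d]]: sum of point probabilities not exceeding the observed
# one (with the conventional 1e-7 relative tolerance for floating-point ties)
.fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact enrichment of a category within a hit set
#'
#' Builds the 2x2 table (in-category & in-hit-set, in-category & out,
#' out-of-category & in-hit-set, out & out) over `universe` and computes the
#' two-sided Fisher exact p by full hypergeometric enumeration, plus the
#' sample odds ratio `ad/bc` (`Inf` when `bc == 0`, `NaN` for 0/0).
#'
#' @param hit_set,category_set Character vectors, subsets of `universe`.
#' @param universe Character vector, the gene universe (non-empty).
#' @return List with the cells `a`, `b`, `c`, `d`, `odds_ratio`, `p`, and
#'   `sidedness = "two-sided"`.
#' @export
fisher_enrichment <- function(hit_set, category_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hit_set <- unique(hit_set); category_set <- unique(category_set)
  if (length(setdiff(hit_set, universe)) || length(setdiff(category_set, universe))) {
    stop("hit_set and category_set must be subsets of universe")
  }
  a <- length(intersect(category_set, hit_set))
  b <- length(setdiff(category_set, hit_set))
  c <- length(setdiff(hit_set, category_set))
  d <- length(universe) - a - b - c
  list(a = a, b = b, c = c, d = d,
       odds_ratio = (a * d) / (b * c),
       p = .fisher_p(a, b, c, d),
       sidedness = "two-sided")
}

#' Fisher exact comparison of two proportions
#'
#' Two-sided Fisher exact p for the 2x2 table
#' `[[k1, n1 - k1], [k2, n2 - k2]]` — e.g. comparing the proportion of
#' antennae-upregulated ORs before and after reannotation.
#'
#' @param k1,n1 Successes and total in group 1 (0 <= k1 <= n1).
#' @param k2,n2 Successes and total in group 2.
#' @return List as in [fisher_enrichment()].
#' @export
proportion_fisher <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  list(a = a, b = b, c = c, d = d,
       odds_ratio = (a * d) / (b * c),
       p = .fisher_p(a, b, c, d),
       sidedness = "two-sided")
}
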