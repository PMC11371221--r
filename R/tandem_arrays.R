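# Tandem-array detection: chain same-strand neighbouring genes whose
# inter-gene gap is below a threshold.

#' Detect tandem arrays of genes
#'
#' Genes are partitioned by (scaffold, strand) and sorted by start
#' coordinate; consecutive genes are chained into one array when the gap
#' `start(next) - end(previous)` is strictly less than `max_gap` base pairs
#' (coordinates 1-based inclusive, no off-by-one correction). Chaining is
#' transitive; unchained genes form arrays of size 1, so the result is a
#' partition of the input. Overlapping gene models (negative gap) chain, with
#' a warning — near-adjacent models are common inside OR tandem arrays.
#'
#' By default an intervening gene on the opposite strand does not break a
#' chain (the strand partition comes first); `break_on_opposite_strand =
#' TRUE` instead takes coordinate adjacency over all genes on the scaffold
#' and cuts a chain wherever the next gene lies on the other strand.
#' To detect arrays among ORs only — gaps measured between adjacent ORs,
#' ignoring intervening non-OR genes — subset `genes` before calling.
#'
#' @param genes data.frame of gene models (see [gene_models()]).
#' @param max_gap Maximum gap in bp, strict upper bound; default 20000.
#' @param break_on_opposite_strand Alternative adjacency rule, see above.
#' @return data.frame with one row per array: `array_id`, `scaffold`,
#'   `strand`, `size`, and `members` (list column of gene ids ordered by
#'   start).
#' @export
detect_arrays <- function(genes, max_gap = 20000, break_on_opposite_strand = FALSE) {
  stopifnot(max_gap > 0)
  if (!all(genes$strand %in% c("+", "-"))) stop("genes must have '+' or '-' strand")
  if (nrow(genes) == 0L) {
    return(data.frame(array_id = character(), scaffold = character(),
                      strand = character(), size = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  grp_key <- if (break_on_opposite_strand) genes$scaffold
             else paste(genes$scaffold, genes$strand, sep = "\r")
  arrays <- list()
  for (idx in split(seq_len(nrow(genes)), grp_key)) {
    g <- genes[idx[order(genes$start[idx], genes$end[idx], genes$gene_id[idx])], , drop = FALSE]
    n <- nrow(g)
    if (n == 1L) { new_chain <- logical(1) } else {
      gap <- g$start[-1] - g$end[-n]
      if (any(gap < 0)) warning("overlapping gene models chained on ", g$scaffold[1])
      brk <- gap >= max_gap
      if (break_on_opposite_strand) brk <- brk | (g$strand[-1] != g$strand[-n])
      new_chain <- c(TRUE, brk)
    }
    chain <- cumsum(new_chain)
    for (members in split(seq_len(n), chain)) {
      strands <- unique(g$strand[members])
      # under the alternative rule a chain is still single-strand by construction
      arrays[[length(arrays) + 1L]] <- data.frame(
        scaffold = g$scaffold[1], strand = strands[1],
        size = length(members),
        members = I(list(g$gene_id[members])),
        start = g$start[members[1]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, arrays)
  out <- out[order(out$scaffold, out$start, out$strand), , drop = FALSE]
  out$array_id <- sprintf("array_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("array_id", "scaffold", "strand", "size", "members")]
}

#' Array-size histogram
#'
#' For each observed array size, the number of arrays of that size and the
#' number of genes they contain.
#'
#' @param arrays data.frame from [detect_arrays()].
#' @return data.frame with columns `size`, `n_arrays`, `n_genes`, sorted by
#'   size.
#' @export
array_size_histogram <- function(arrays) {
  if (nrow(arrays) == 0L) {
    return(data.frame(size = integer(), n_arrays = integer(), n_genes = integer()))
  }
  tab <- table(arrays$size)
  size <- as.integer(names(tab))
  data.frame(size = size, n_arrays = as.integer(tab),
             n_genes = size * as.integer(tab))
}

#' Chi-squared test of category composition across array sizes
#'
#' Builds the (category x size-bin) table of gene counts — each gene counted
#' under the size of the array containing it — and tests departure from
#' marginal proportions with Pearson chi-squared (no continuity correction).
#' A non-significant result means categories are spread across array sizes
#' in proportion to their share of the repertoire.
#'
#' @param arrays data.frame from [detect_arrays()].
#' @param categories Named character vector gene id -> category; every array
#'   member must be present.
#' @param size_bins Optional named vector mapping array size (as string) to a
#'   bin label; bins must cover all observed sizes. Default: each size its
#'   own bin.
#' @return List with `chi2`, `df`, `p`, and the `table` tested.
#' @export
category_array_chisq <- function(arrays, categories, size_bins = NULL) {
  members <- unlist(arrays$members)
  sizes <- rep(arrays$size, arrays$size)
  miss <- setdiff(members, names(categories))
  if (length(miss)) stop("array member(s) without category: ",
                         paste(head(miss, 5), collapse = ", "))
  cat_of <- unname(categories[members])
  if (is.null(size_bins)) {
    bin <- factor(sizes, levels = sort(unique(sizes)))
  } else {
    key <- as.character(sizes)
    miss_s <- setdiff(unique(key), names(size_bins))
    if (length(miss_s)) stop("array size(s) missing from size_bins: ",
                             paste(miss_s, collapse = ", "))
    lev <- unique(size_bins[order(as.integer(names(size_bins)))])
    bin <- factor(unname(size_bins[key]), levels = unique(lev))
  }
  tab <- table(category = cat_of, size_bin = bin)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("degenerate table: need >= 2 categories and >= 2 size bins")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) stop("expected cell < 1; use coarser size_bins")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), table = tab)
}
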