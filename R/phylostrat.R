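# Node-distance phylostratigraphy: protein ages from the most distant
# species with a retained hit, TRP detection, and stratum enrichment tests.

#' Construct a species tree with a designated focal tip
#'
#' @param phy An [ape::phylo] rooted tree with unique tip labels, or a Newick
#'   string.
#' @param focal Tip label of the focal species.
#' @return Object of class `species_tree`.
#' @export
species_tree <- function(phy, focal) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (!focal %in% phy$tip.label) stop("focal species '", focal, "' is not a tip")
  structure(list(phy = phy, focal = focal), class = "species_tree")
}

#' Read a species tree from a Newick file
#' @param path Path to a Newick file.
#' @param focal Tip label of the focal species.
#' @return A `species_tree`.
#' @export
read_species_tree <- function(path, focal) {
  species_tree(ape::read.tree(path), focal)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d tips, focal = %s\n",
              length(x$phy$tip.label), x$focal))
  invisible(x)
}

#' Node distance between the focal species and another tip
#'
#' The age metric: the number of internal nodes on the unique path between
#' the focal tip and `other`, counting the MRCA and every intermediate
#' internal node but neither tip. Sister species are at distance 1; the focal
#' species itself is at distance 0. Larger values mean deeper divergence.
#' Works on multifurcating trees.
#'
#' @param tree A `species_tree`.
#' @param other Character vector of tip labels.
#' @return Integer vector of node distances.
#' @export
node_distance <- function(tree, other) {
  stopifnot(inherits(tree, "species_tree"))
  tips <- tree$phy$tip.label
  unknown <- setdiff(other, tips)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  i_focal <- match(tree$focal, tips)
  vapply(other, function(sp) {
    i <- match(sp, tips)
    if (i == i_focal) return(0L)
    length(ape::nodepath(tree$phy, i_focal, i)) - 2L
  }, integer(1), USE.NAMES = !is.null(names(other)) || length(other) > 1)
}

#' Assign phylostratigraphic ages to proteins
#'
#' Each protein's stratum is the node distance of the most distant species
#' with a retained hit; focal-species self-hits are ignored. Proteins with no
#' non-focal hit are taxonomically restricted (TRP): node distance 0 and no
#' deepest species. When several species attain the maximal distance the
#' lexicographically smallest name is reported as `deepest_species`.
#'
#' @param best_hits A `hit_table`, already reduced with
#'   [best_hit_per_species()] (any hit table works — the per-species maximum
#'   is unchanged by the reduction).
#' @param tree A `species_tree`; every hit species must be a tip.
#' @param protein_ids Character vector of all focal proteins to assign
#'   (including ones with no hits).
#' @return data.frame with columns `protein_id`, `node_distance`,
#'   `deepest_species` (NA for TRPs), `is_trp`; one row per element of
#'   `protein_ids`.
#' @export
assign_strata <- function(best_hits, tree, protein_ids) {
  stopifnot(inherits(tree, "species_tree"))
  if (anyDuplicated(protein_ids)) stop("duplicate protein ids")
  h <- best_hits[best_hits$subject_species != tree$focal, , drop = FALSE]
  if (nrow(h) > 0) {
    sp <- unique(h$subject_species)
    bad <- setdiff(sp, tree$phy$tip.label)
    if (length(bad)) stop("hit species not in tree: ", paste(bad, collapse = ", "))
    dist_of <- setNames(node_distance(tree, sp), sp)
  } else {
    dist_of <- setNames(integer(0), character(0))
  }
  out <- data.frame(protein_id = protein_ids, node_distance = 0L,
                    deepest_species = NA_character_, is_trp = TRUE,
                    stringsAsFactors = FALSE)
  if (nrow(h) > 0) {
    h <- h[h$query_id %in% protein_ids, , drop = FALSE]
    d <- unname(dist_of[h$subject_species])
    for (grp in split(seq_len(nrow(h)), h$query_id)) {
      q <- h$query_id[grp[1]]
      dmax <- max(d[grp])
      deepest <- min(h$subject_species[grp][d[grp] == dmax])
      i <- match(q, out$protein_id)
      out$node_distance[i] <- dmax
      out$deepest_species[i] <- deepest
      out$is_trp[i] <- FALSE
    }
  }
  out
}

#' Taxonomically restricted proteins
#'
#' Proteins with no retained hit in any non-focal species.
#'
#' @param assignments data.frame from [assign_strata()].
#' @return Character vector of TRP protein ids.
#' @export
find_trps <- function(assignments) {
  assignments$protein_id[assignments$is_trp]
}

#' Category-by-stratum contingency table
#'
#' Counts proteins per (gene category, stratum). Strata columns are integer
#' node distances in ascending order, or clade-style bins if `strata_bins`
#' is supplied (a named vector mapping each observed distance to a bin
#' label; bin column order follows the minimum distance in each bin).
#'
#' @param assignments data.frame from [assign_strata()].
#' @param categories Named character vector protein id -> category; every
#'   assigned protein must be present.
#' @param strata_bins Optional named vector distance -> bin label (names are
#'   the distances as strings).
#' @return Integer matrix, categories in rows, strata (or bins) in columns.
#' @export
strata_contingency <- function(assignments, categories, strata_bins = NULL) {
  miss <- setdiff(assignments$protein_id, names(categories))
  if (length(miss)) stop("protein(s) without category: ", paste(head(miss, 5), collapse = ", "))
  cat_of <- unname(categories[assignments$protein_id])
  d <- assignments$node_distance
  if (is.null(strata_bins)) {
    lev <- sort(unique(d))
    stratum <- factor(d, levels = lev)
  } else {
    key <- as.character(d)
    miss_d <- setdiff(unique(key), names(strata_bins))
    if (length(miss_d)) stop("distance(s) missing from strata_bins: ",
                             paste(miss_d, collapse = ", "))
    lab <- unname(strata_bins[key])
    lev <- unique(strata_bins[order(as.integer(names(strata_bins)))])
    stratum <- factor(lab, levels = unique(lev))
  }
  tab <- table(category = cat_of, stratum = stratum)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Chi-squared test for stratum-distribution differences between categories
#'
#' Pearson chi-squared (no continuity correction) on the 2 x k sub-table of
#' a strata contingency table formed by `focal_category` and
#' `background_category`. Columns empty in both categories are dropped.
#' Errors if any expected cell falls below 1 (merge bins first) or if a
#' category has zero total.
#'
#' @param table Matrix from [strata_contingency()].
#' @param focal_category,background_category Row names to compare.
#' @return List with `chi2`, `df`, `p`.
#' @export
stratum_enrichment_test <- function(table, focal_category, background_category) {
  for (cc in c(focal_category, background_category)) {
    if (!cc %in% rownames(table)) stop("category not in table: ", cc)
  }
  sub <- table[c(focal_category, background_category), , drop = FALSE]
  sub <- sub[, colSums(sub) > 0, drop = FALSE]
  if (any(rowSums(sub) == 0)) stop("degenerate table: a category has zero total")
  if (ncol(sub) < 2) stop("need at least two non-empty strata")
  expected <- outer(rowSums(sub), colSums(sub)) / sum(sub)
  if (any(expected < 1)) stop("expected cell < 1; merge strata into coarser bins")
  ct <- suppressWarnings(chisq.test(sub, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Run a family of stratum-enrichment comparisons with FDR control
#'
#' Applies [stratum_enrichment_test()] to each (focal, background) pair and
#' adjusts the p-values across the family with Benjamini-Hochberg.
#'
#' @param table Matrix from [strata_contingency()].
#' @param comparisons List of 2-element character vectors
#'   (focal, background).
#' @return data.frame with one row per comparison: `focal`, `background`,
#'   `chi2`, `df`, `p`, `padj`.
#' @export
stratum_enrichment <- function(table, comparisons) {
  rows <- lapply(comparisons, function(cp) {
    r <- stratum_enrichment_test(table, cp[1], cp[2])
    data.frame(focal = cp[1], background = cp[2], chi2 = r$chi2,
               df = r$df, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out
}
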