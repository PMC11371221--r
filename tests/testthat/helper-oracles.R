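# Independent reference implementations used to cross-check the package:
# deliberately brute-force and shared by the unit and acceptance suites.

# quadratic-time Smith-Waterman with affine gaps (gap of length L costs
# gap_open + L * gap_extend), three-matrix DP
sw_dp_oracle <- function(a, b, mat, gap_open = 10, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)     # ends in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (deletion)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (insertion)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# node distance via an explicit breadth-first walk on the tree graph,
# counting internal nodes on the tip-to-tip path
path_walk_distance <- function(phy, focal, other) {
  if (focal == other) return(0L)
  g <- igraph::graph_from_edgelist(cbind(as.character(phy$edge[, 1]),
                                         as.character(phy$edge[, 2])),
                                   directed = FALSE)
  from <- as.character(match(focal, phy$tip.label))
  to <- as.character(match(other, phy$tip.label))
  p <- igraph::shortest_paths(g, from, to)$vpath[[1]]
  ids <- as.integer(igraph::V(g)$name[p])
  sum(ids > length(phy$tip.label))
}

# drop hit_table class/attributes for frame-level comparisons
strip_ht <- function(x) {
  class(x) <- "data.frame"
  attr(x, "threshold_applied") <- NULL
  rownames(x) <- NULL
  x
}

# per-(query, species) minimum e-value by explicit nested grouping
group_min_oracle <- function(hits) {
  hits <- strip_ht(hits)
  out <- list()
  for (q in unique(hits$query_id)) {
    hq <- hits[hits$query_id == q, , drop = FALSE]
    for (sp in unique(hq$subject_species)) {
      hs <- hq[hq$subject_species == sp, , drop = FALSE]
      hs <- hs[order(hs$evalue, -hs$bitscore, hs$subject_id), , drop = FALSE]
      out[[length(out) + 1L]] <- hs[1, , drop = FALSE]
    }
  }
  o <- do.call(rbind, out)
  o <- o[order(o$query_id, o$subject_species), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# tandem arrays as connected components of the gap graph: edges join
# coordinate-adjacent genes of the same (scaffold, strand) at gap < max_gap
array_components_oracle <- function(genes, max_gap) {
  edges <- matrix(character(0), ncol = 2)
  for (key in unique(paste(genes$scaffold, genes$strand))) {
    g <- genes[paste(genes$scaffold, genes$strand) == key, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    if (nrow(g) < 2) next
    for (i in seq_len(nrow(g) - 1)) {
      if (g$start[i + 1] - g$end[i] < max_gap) {
        edges <- rbind(edges, c(g$gene_id[i], g$gene_id[i + 1]))
      }
    }
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- gr + igraph::vertices(setdiff(genes$gene_id, igraph::V(gr)$name))
  comp <- igraph::components(gr)$membership
  unname(lapply(split(names(comp), comp), sort))
}

# exclusive intersection counts by explicit power-set enumeration
upset_oracle <- function(sets) {
  nm <- names(sets)
  universe <- unique(unlist(sets))
  out <- integer(0)
  for (mask in seq_len(2^length(sets) - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(sets) - 1)))
    members <- universe
    for (i in seq_along(sets)) {
      members <- if (inset[i]) intersect(members, sets[[i]])
                 else setdiff(members, sets[[i]])
    }
    if (length(members)) out[paste(nm[inset], collapse = "&")] <- length(members)
  }
  out
}

# random gene layout on a handful of scaffolds, for partition properties
random_gene_layout <- function(n_genes, n_scaffolds = 3) {
  scaffold <- sample(sprintf("s%d", seq_len(n_scaffolds)), n_genes, replace = TRUE)
  start <- sample(1:500000, n_genes)
  len <- sample(500:8000, n_genes, replace = TRUE)
  gene_models(sprintf("g%03d", seq_len(n_genes)), scaffold, start, start + len - 1,
              sample(c("+", "-"), n_genes, replace = TRUE))
}

# random hit table over a species panel
random_hit_table <- function(n_queries = 8, n_hits = 40, species) {
  q <- sprintf("q%d", sample(n_queries, n_hits, replace = TRUE))
  sp <- sample(species, n_hits, replace = TRUE)
  hit_table(data.frame(
    query_id = q,
    subject_id = sprintf("%s_p%d", sp, sample(5, n_hits, replace = TRUE)),
    subject_species = sp,
    evalue = 10^-runif(n_hits, 6, 60),
    bitscore = round(runif(n_hits, 50, 400), 1),
    stringsAsFactors = FALSE))
}
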