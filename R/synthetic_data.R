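# Seeded generators producing inputs with the statistical structure every
# pipeline stage assumes, with the planted truth recorded alongside.

#' Simulate a reference species set on a ladder tree
#'
#' Builds a rooted caterpillar (ladder) tree with the focal species nested
#' deepest, so that node distances 1 .. n_species - 1 are all realized —
#' maximal stratum coverage at small n. Deterministic given the arguments.
#'
#' @param seed Integer seed (kept for interface symmetry; the topology is
#'   deterministic).
#' @param n_species Number of species including the focal one; >= 3.
#' @param focal Name of the focal tip.
#' @return List with `tree` (a `species_tree`) and `species` (character
#'   vector, focal first, then tips in increasing node distance).
#' @export
simulate_species_set <- function(seed = 1, n_species = 12, focal = "focal_sp") {
  stopifnot(n_species >= 3)
  others <- sprintf("sp%02d", seq_len(n_species - 1))
  nwk <- focal
  for (s in others) nwk <- sprintf("(%s,%s)", nwk, s)
  tree <- species_tree(paste0(nwk, ";"), focal)
  list(tree = tree, species = c(focal, others))
}

#' Simulate gene families with planted phylogenetic birth nodes
#'
#' Every gene receives a planted birth node distance d: homologs exist in
#' exactly the species at node distance <= d from the focal species. TRPs
#' (fraction `trp_fraction`) get d = 0, i.e. no non-focal homolog. Two
#' emission modes:
#'
#' * `direct_hits` — a hit table is emitted directly, one hit per homologous
#'   species at e-value 1e-50, so stratum assignment must recover the
#'   planted ages exactly;
#' * `sequences` — a random focal protein is drawn per gene and each
#'   homolog is a per-site mutated copy (substitution probability
#'   `1 - exp(-rate * distance)`, no indels), so the similarity search has
#'   to recover the hits before assignment.
#'
#' @param tree A `species_tree` from [simulate_species_set()].
#' @param n_genes Number of focal genes.
#' @param trp_fraction Fraction of genes planted as taxonomically
#'   restricted, in `[0, 1]`.
#' @param mode `"direct_hits"` or `"sequences"`.
#' @param mutation_rate_per_node Per-site substitution rate per unit node
#'   distance (sequences mode); default 0.03.
#' @param seed Integer seed.
#' @param length_range Protein length range (sequences mode).
#' @return List with `truth` (data.frame `gene_id`, `birth_distance`,
#'   `is_trp`), and either `hits` (direct_hits) or `queries` +
#'   `subjects` + `species_of` (sequences).
#' @export
simulate_gene_families <- function(tree, n_genes = 50, trp_fraction = 0.1,
                                   mode = c("direct_hits", "sequences"),
                                   mutation_rate_per_node = 0.03, seed = 1,
                                   length_range = c(120, 360)) {
  mode <- match.arg(mode)
  stopifnot(trp_fraction >= 0, trp_fraction <= 1)
  withr::local_seed(seed)
  tips <- setdiff(tree$phy$tip.label, tree$focal)
  dists <- node_distance(tree, tips)
  names(dists) <- tips
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  n_trp <- round(trp_fraction * n_genes)
  is_trp <- c(rep(TRUE, n_trp), rep(FALSE, n_genes - n_trp))
  birth <- ifelse(is_trp, 0L, sample(sort(unique(dists)), n_genes, replace = TRUE))
  truth <- data.frame(gene_id = gene_id, birth_distance = as.integer(birth),
                      is_trp = is_trp, stringsAsFactors = FALSE)
  if (mode == "direct_hits") {
    recs <- lapply(seq_len(n_genes), function(i) {
      sp <- names(dists)[dists <= birth[i]]
      if (birth[i] == 0L || length(sp) == 0L) return(NULL)
      data.frame(query_id = gene_id[i],
                 subject_id = paste0(sp, "_", gene_id[i]),
                 subject_species = sp, evalue = 1e-50, bitscore = 200,
                 stringsAsFactors = FALSE)
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    hits <- if (length(recs)) do.call(rbind, recs) else empty_hits()
    return(list(truth = truth, hits = hit_table(hits, threshold_applied = 1e-5)))
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
  qseq <- vapply(lens, function(L) paste(sample(aa, L, replace = TRUE), collapse = ""),
                 character(1))
  subj <- character(0); subj_sp <- character(0)
  for (i in seq_len(n_genes)) {
    sp <- names(dists)[dists <= birth[i]]
    if (birth[i] == 0L || length(sp) == 0L) next
    base <- strsplit(qseq[i], "")[[1]]
    for (s in sp) {
      p_mut <- 1 - exp(-mutation_rate_per_node * dists[[s]])
      mut <- runif(length(base)) < p_mut
      hom <- base
      if (any(mut)) hom[mut] <- sample(aa, sum(mut), replace = TRUE)
      subj <- c(subj, paste(hom, collapse = ""))
      subj_sp <- c(subj_sp, s)
    }
  }
  queries <- Biostrings::AAStringSet(setNames(qseq, gene_id))
  sid <- if (length(subj)) sprintf("%s_h%04d", subj_sp, seq_along(subj)) else character(0)
  subjects <- Biostrings::AAStringSet(setNames(subj, sid))
  list(truth = truth, queries = queries, subjects = subjects,
       species_of = setNames(subj_sp, sid))
}

#' Simulate a genome annotation with planted tandem arrays
#'
#' Genes are laid out scaffold by scaffold in planted arrays: within an
#' array, consecutive same-strand genes are separated by gaps drawn from
#' `within_gap_range` (below the chaining threshold); consecutive arrays are
#' separated by gaps of at least `between_gap_min` (at or above it), so the
#' planted partition is exactly recoverable by [detect_arrays()] at the
#' default 20 kbp rule.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param n_genes Total number of genes.
#' @param array_size_distribution Numeric vector of probabilities over array
#'   sizes 1, 2, 3, ...; default favours small arrays, as OR arrays do.
#' @param within_gap_range Length-2 integer range (bp) for intra-array gaps;
#'   max must stay below `between_gap_min`.
#' @param between_gap_min Minimum inter-array gap (bp); default 20000.
#' @param nine_exon_fraction Fraction of genes labelled `nine_exon_or`
#'   (the rest `other_or`); assigned per gene at random.
#' @param seed Integer seed.
#' @return List with `genes` (gene-model data.frame) and `truth`
#'   (`planted_arrays`: list of member-id vectors).
#' @export
simulate_genome_layout <- function(n_scaffolds = 4, n_genes = 60,
                                   array_size_distribution = c(0.45, 0.25, 0.15, 0.1, 0.05),
                                   within_gap_range = c(200, 19999),
                                   between_gap_min = 20000,
                                   nine_exon_fraction = 0.37, seed = 1) {
  stopifnot(max(within_gap_range) < between_gap_min)
  withr::local_seed(seed)
  sizes <- integer(0); total <- 0L
  while (total < n_genes) {
    s <- sample(seq_along(array_size_distribution), 1, prob = array_size_distribution)
    s <- min(s, n_genes - total)
    sizes <- c(sizes, s); total <- total + s
  }
  scaffold_of <- sort(sample(sprintf("scaf%02d", seq_len(n_scaffolds)),
                             length(sizes), replace = TRUE))
  gene_len <- function(k) sample(800:6000, k, replace = TRUE)
  rows <- list(); planted <- list(); gi <- 0L
  for (sc in unique(scaffold_of)) {
    pos <- sample(1000:5000, 1)
    for (ai in which(scaffold_of == sc)) {
      k <- sizes[ai]
      strand <- sample(c("+", "-"), 1)
      ids <- sprintf("or%04d", gi + seq_len(k)); gi <- gi + k
      lens <- gene_len(k)
      starts <- integer(k); ends <- integer(k)
      for (j in seq_len(k)) {
        starts[j] <- pos
        ends[j] <- pos + lens[j] - 1L
        if (j < k) {
          gap_choices <- within_gap_range[1]:within_gap_range[2]
          pos <- ends[j] + gap_choices[sample.int(length(gap_choices), 1)]
        }
      }
      pos <- ends[k] + between_gap_min + sample(0:50000, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ids, scaffold = sc, start = starts, end = ends,
        strand = strand, stringsAsFactors = FALSE)
      planted[[length(planted) + 1L]] <- ids
    }
  }
  g <- do.call(rbind, rows)
  category <- ifelse(runif(nrow(g)) < nine_exon_fraction, "nine_exon_or", "other_or")
  genes <- gene_models(g$gene_id, g$scaffold, g$start, g$end, g$strand,
                       category_map = setNames(category, g$gene_id))
  list(genes = genes, truth = list(planted_arrays = planted))
}

#' Simulate a negative-binomial count matrix with planted tissue effects
#'
#' Counts are negative binomial in mean-dispersion form (variance =
#' mu + dispersion * mu^2) with gene baselines log-uniform over
#' `baseline_range`. Planted antennae-upregulated genes have their focal
#' tissue mean multiplied by `fold_change`. A configurable fraction of genes
#' is made single-sample-detected (to exercise pruning) and another fraction
#' focal-tissue-restricted: near-zero means (0.3) outside the focal tissue,
#' high expression inside (to exercise the raw-count < 10 filter). The four
#' planted classes are disjoint.
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue labels; first is the focal tissue.
#' @param replicates Integer vector of replicate counts per tissue (>= 2
#'   each); defaults mirror a 3/4/4/3 design.
#' @param upregulated_fraction Fraction of genes planted as focal-tissue
#'   upregulated; ignored (empty set) when `fold_change == 1`.
#' @param fold_change Planted fold change in the focal tissue.
#' @param nb_dispersion NB dispersion alpha; 0 gives Poisson counts.
#' @param single_sample_fraction Fraction of genes detected in exactly one
#'   sample.
#' @param restricted_fraction Fraction of genes expression-restricted to the
#'   focal tissue.
#' @param baseline_range Length-2 range of baseline means.
#' @param seed Integer seed.
#' @return List with `counts` (a `count_matrix`) and `truth` (list with
#'   `planted_upregulated`, `planted_restricted`, `planted_single_sample`,
#'   `params`).
#' @export
simulate_counts <- function(n_genes = 2000,
                            tissues = c("antennae", "head", "thorax", "leg"),
                            replicates = c(3, 4, 4, 3),
                            upregulated_fraction = 0.05, fold_change = 4,
                            nb_dispersion = 0.05,
                            single_sample_fraction = 0.02,
                            restricted_fraction = 0.02,
                            baseline_range = c(20, 2000), seed = 1) {
  stopifnot(length(tissues) == length(replicates), all(replicates >= 2))
  withr::local_seed(seed)
  focal <- tissues[1]
  sample_ids <- unlist(lapply(seq_along(tissues), function(i) {
    sprintf("%s_%d", tissues[i], seq_len(replicates[i]))
  }))
  tissue_of <- setNames(rep(tissues, replicates), sample_ids)
  gene_id <- sprintf("t%05d", seq_len(n_genes))

  n_up <- if (fold_change == 1) 0L else round(upregulated_fraction * n_genes)
  n_ss <- round(single_sample_fraction * n_genes)
  n_rs <- round(restricted_fraction * n_genes)
  stopifnot(n_up + n_ss + n_rs <= n_genes)
  cls <- rep("background", n_genes)
  cls[seq_len(n_up)] <- "upregulated"
  if (n_ss > 0) cls[n_up + seq_len(n_ss)] <- "single_sample"
  if (n_rs > 0) cls[n_up + n_ss + seq_len(n_rs)] <- "restricted"

  base <- exp(runif(n_genes, log(baseline_range[1]), log(baseline_range[2])))
  mu <- matrix(base, n_genes, length(sample_ids),
               dimnames = list(gene_id, sample_ids))
  focal_cols <- tissue_of == focal
  mu[cls == "upregulated", focal_cols] <- mu[cls == "upregulated", focal_cols] * fold_change
  mu[cls == "restricted", !focal_cols] <- 0.3
  mu[cls == "restricted", focal_cols] <- pmax(mu[cls == "restricted", focal_cols], 100)

  draw <- function(mu_vec) {
    if (nb_dispersion <= 0) rpois(length(mu_vec), mu_vec)
    else rnbinom(length(mu_vec), mu = mu_vec, size = 1 / nb_dispersion)
  }
  m <- matrix(draw(as.vector(mu)), n_genes, length(sample_ids),
              dimnames = dimnames(mu))
  if (n_ss > 0) {
    ss_rows <- which(cls == "single_sample")
    m[ss_rows, ] <- 0
    keep_col <- sample(seq_along(sample_ids), n_ss, replace = TRUE)
    m[cbind(ss_rows, keep_col)] <- pmax(1, draw(base[ss_rows]))
  }
  counts <- count_matrix(m, tissue_of)
  list(counts = counts,
       truth = list(
         planted_upregulated = gene_id[cls == "upregulated"],
         planted_restricted = gene_id[cls == "restricted"],
         planted_single_sample = gene_id[cls == "single_sample"],
         baseline = setNames(base, gene_id),
         params = list(n_genes = n_genes, tissues = tissues,
                       replicates = replicates, fold_change = fold_change,
                       nb_dispersion = nb_dispersion, seed = seed)))
}
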