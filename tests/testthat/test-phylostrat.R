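test_that("node distance counts internal nodes between tips, excluding the tips", {
  tr <- species_tree("((focal,other),outgroup);", focal = "focal")
  expect_equal(node_distance(tr, "focal"), 0L)
  expect_equal(node_distance(tr, "other"), 1L)   # MRCA only
  expect_equal(node_distance(tr, "outgroup"), 2L)
  expect_error(node_distance(tr, "missing"), "unknown tip")
})

test_that("node distance matches a breadth-first path walk on a 12-tip ladder", {
  sim <- simulate_species_set(31, n_species = 12)
  d_mine <- node_distance(sim$tree, sim$species)
  d_oracle <- vapply(sim$species, function(sp) {
    path_walk_distance(sim$tree$phy, sim$tree$focal, sp)
  }, numeric(1))
  expect_equal(unname(d_mine), unname(as.integer(d_oracle)))
  # ladder: strictly increasing along the species order
  expect_equal(unname(d_mine), 0:11)
})

test_that("node distance handles multifurcating trees", {
  tr <- species_tree("((focal,a,b),(c,d));", focal = "focal")
  expect_equal(unname(node_distance(tr, c("a", "b", "c", "d"))),
               c(1L, 1L, 3L, 3L))
})

test_that("stratum assignment takes the most distant hit species and flags TRPs", {
  sim <- simulate_species_set(32, n_species = 10)
  tr <- sim$tree
  hits <- hit_table(data.frame(
    query_id = c("p1", "p1"), subject_id = c("x", "y"),
    subject_species = c("sp03", "sp09"),   # distances 3 and 9
    evalue = c(1e-30, 1e-8), bitscore = c(250, 60), stringsAsFactors = FALSE))
  a <- assign_strata(hits, tr, c("p1", "p2"))
  expect_equal(a$node_distance[a$protein_id == "p1"], 9L)
  expect_equal(a$deepest_species[a$protein_id == "p1"], "sp09")
  expect_false(a$is_trp[a$protein_id == "p1"])
  # p2 has no hits at all
  expect_true(a$is_trp[a$protein_id == "p2"])
  expect_equal(a$node_distance[a$protein_id == "p2"], 0L)
  expect_true(is.na(a$deepest_species[a$protein_id == "p2"]))

  bad <- hit_table(data.frame(query_id = "p1", subject_id = "x",
                              subject_species = "not_a_tip", evalue = 1e-10,
                              bitscore = 100, stringsAsFactors = FALSE))
  expect_error(assign_strata(bad, tr, "p1"), "not_a_tip")
})

test_that("focal self-hits are ignored in stratum assignment", {
  sim <- simulate_species_set(33, n_species = 6)
  hits <- hit_table(data.frame(
    query_id = "p1", subject_id = "self", subject_species = sim$tree$focal,
    evalue = 0, bitscore = 999, stringsAsFactors = FALSE))
  a <- assign_strata(hits, sim$tree, "p1")
  expect_true(a$is_trp)
})

test_that("assignment equals brute-force max-over-species on random hit tables", {
  withr::local_seed(34)
  sim <- simulate_species_set(34, n_species = 8)
  dists <- node_distance(sim$tree, setdiff(sim$species, sim$tree$focal))
  names(dists) <- setdiff(sim$species, sim$tree$focal)
  for (i in 1:100) {
    h <- random_hit_table(n_queries = 6, n_hits = 30, species = names(dists))
    ids <- sprintf("q%d", 1:6)
    a <- assign_strata(best_hit_per_species(h), sim$tree, ids)
    for (q in ids) {
      sp <- unique(h$subject_species[h$query_id == q])
      want <- if (length(sp)) max(dists[sp]) else 0L
      expect_equal(a$node_distance[a$protein_id == q], as.integer(want))
    }
  }
})

test_that("adding a hit at distance d never decreases an assignment below d", {
  withr::local_seed(35)
  sim <- simulate_species_set(35, n_species = 9)
  other <- setdiff(sim$species, sim$tree$focal)
  dists <- setNames(node_distance(sim$tree, other), other)
  h <- random_hit_table(n_queries = 4, n_hits = 12, species = other)
  base <- assign_strata(best_hit_per_species(h), sim$tree, "q1")
  for (sp in other) {
    extra <- rbind(as.data.frame(h),
                   data.frame(query_id = "q1", subject_id = paste0(sp, "_new"),
                              subject_species = sp, evalue = 1e-12, bitscore = 100))
    a2 <- assign_strata(best_hit_per_species(hit_table(extra)), sim$tree, "q1")
    expect_gte(a2$node_distance, dists[[sp]])
    expect_gte(a2$node_distance, base$node_distance)
  }
})

test_that("TRP detection equals a raw-table scan for queries without non-focal hits", {
  withr::local_seed(36)
  sim <- simulate_species_set(36, n_species = 7)
  other <- setdiff(sim$species, sim$tree$focal)
  ids <- sprintf("q%d", 1:10)
  h <- random_hit_table(n_queries = 10, n_hits = 18, species = other)
  a <- assign_strata(best_hit_per_species(h), sim$tree, ids)
  expect_equal(sort(find_trps(a)),
               sort(setdiff(ids, unique(h$query_id))))
  # all-proteins-hit and one-hitless edge cases
  a_all <- assign_strata(h, sim$tree, unique(h$query_id))
  expect_length(find_trps(a_all), 0)
})

test_that("strata contingency counts match a nested-loop oracle and conserve totals", {
  one <- data.frame(protein_id = "p1", node_distance = 3L,
                    deepest_species = "x", is_trp = FALSE)
  tab1 <- strata_contingency(one, c(p1 = "other_or"))
  expect_equal(dim(tab1), c(1, 1))
  expect_equal(tab1[1, 1], 1L)

  withr::local_seed(37)
  n <- 80
  a <- data.frame(protein_id = sprintf("p%d", 1:n),
                  node_distance = sample(0:6, n, replace = TRUE),
                  deepest_species = "x", is_trp = FALSE)
  cats <- setNames(sample(c("nine_exon_or", "other_or", "non_or"), n, TRUE),
                   a$protein_id)
  tab <- strata_contingency(a, cats)
  for (cc in rownames(tab)) for (s in colnames(tab)) {
    expect_equal(tab[cc, s],
                 sum(cats[a$protein_id] == cc & a$node_distance == as.integer(s)))
  }
  expect_equal(sum(tab), n)
  expect_equal(unname(rowSums(tab)), unname(as.integer(table(cats)[rownames(tab)])))

  # merging every stratum into one bin leaves category sizes
  bins <- setNames(rep("all", 7), as.character(0:6))
  tab_all <- strata_contingency(a, cats, strata_bins = bins)
  expect_equal(unname(tab_all[, "all"]), unname(as.integer(table(cats)[rownames(tab_all)])))

  expect_error(strata_contingency(a, cats[-1]), "without category")
})

test_that("stratum enrichment chi-squared matches hand-computed Pearson values", {
  tab <- matrix(c(5L, 5L, 3L, 3L, 2L, 2L), nrow = 2,
                dimnames = list(c("nine_exon_or", "non_or"), c("1", "2", "3")))
  r <- stratum_enrichment_test(tab, "nine_exon_or", "non_or")
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  tab2 <- matrix(c(10L, 0L, 0L, 10L), nrow = 2,
                 dimnames = list(c("a", "b"), c("1", "2")))
  r2 <- stratum_enrichment_test(tab2, "a", "b")
  expect_equal(r2$chi2, 20)   # hand Pearson: 4 cells of (5)^2/5
  expect_equal(r2$df, 1)

  degen <- matrix(c(0L, 5L, 0L, 5L), nrow = 2,
                  dimnames = list(c("a", "b"), c("1", "2")))
  expect_error(stratum_enrichment_test(degen, "a", "b"), "degenerate|expected")
})

test_that("a family of enrichment comparisons gets BH adjustment", {
  tab <- matrix(c(30L, 10L, 25L, 10L, 20L, 25L, 5L, 35L), nrow = 4,
                dimnames = list(c("nine_exon_or", "other_or", "non_or", "up"),
                                c("1", "2")))
  res <- stratum_enrichment(tab, list(c("nine_exon_or", "non_or"),
                                      c("other_or", "non_or"),
                                      c("up", "non_or")))
  expect_equal(nrow(res), 3)
  expect_true(all(res$padj >= res$p))
  expect_equal(res$padj, p.adjust(res$p, "BH"))
})
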