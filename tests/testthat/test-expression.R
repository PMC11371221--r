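mk_counts <- function(m, tissue_of) count_matrix(m, tissue_of)

test_that("pruning removes genes detected in at most one sample", {
  m <- rbind(one = c(5, 0, 0, 0), two = c(5, 1, 0, 0), zero = c(0, 0, 0, 0))
  colnames(m) <- c("a1", "a2", "h1", "h2")
  cm <- mk_counts(m, c(a1 = "antennae", a2 = "antennae", h1 = "head", h2 = "head"))
  pruned <- prune_single_sample(cm)
  expect_equal(rownames(pruned$counts), "two")

  withr::local_seed(51)
  for (i in 1:5) {
    big <- matrix(rbinom(100 * 14, 1, 0.12) * sample(1:50, 100 * 14, TRUE), 100, 14,
                  dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:14)))
    cmb <- mk_counts(big, setNames(rep(c("a", "b"), 7), colnames(big)))
    survivors <- rownames(prune_single_sample(cmb)$counts)
    oracle <- rownames(big)[apply(big, 1, function(r) sum(r > 0) >= 2)]
    expect_equal(survivors, oracle)
  }
})

test_that("the NB test reports zero log-fold-change for identical group means", {
  m <- matrix(rep(c(10, 10, 20, 20), each = 4), nrow = 4, byrow = TRUE)
  m <- rbind(g1 = c(10, 10, 10, 10), g2 = c(40, 40, 40, 40), g3 = c(7, 7, 7, 7))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  cm <- mk_counts(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  de <- nb_de_test(cm, "A", "B")
  expect_equal(de$log2fc, rep(0, 3))

  expect_error(nb_de_test(cm, "A", "missing"), ">= 2 samples")
})

test_that("planted 4-fold effects at n=4/group are recovered at padj < .05", {
  sim <- simulate_counts(n_genes = 1000, tissues = c("antennae", "head"),
                         replicates = c(4, 4), upregulated_fraction = 0.05,
                         fold_change = 4, nb_dispersion = 0.05,
                         single_sample_fraction = 0, restricted_fraction = 0,
                         seed = 52)
  de <- nb_de_test(sim$counts, "antennae", "head")
  i <- match(sim$truth$planted_upregulated, de$gene_id)
  expect_gte(mean(de$padj[i] < 0.05 & de$log2fc[i] > 0), 0.9)
  expect_true(all(de$padj >= de$pvalue - 1e-12))
})

test_that("upregulated-vs-all is the conjunction over every comparison", {
  de1 <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(2, 2, -2),
                    pvalue = c(.001, .001, .001), padj = c(.01, .01, .01))
  de2 <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(2, 2, 2),
                    pvalue = c(.001, .2, .001), padj = c(.01, .3, .01))
  de3 <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(2, 2, 2),
                    pvalue = c(.001, .001, .001), padj = c(.01, .01, .01))
  # g2 significant in only 2 of 3; g3 down in one comparison
  expect_equal(upregulated_vs_all(list(a = de1, b = de2, c = de3)), "g1")

  empty <- data.frame(gene_id = character(), log2fc = numeric(),
                      pvalue = numeric(), padj = numeric())
  expect_length(upregulated_vs_all(list(a = empty, b = empty)), 0)
  expect_error(upregulated_vs_all(list()), "no comparison")

  # brute-force set logic on randomized tables, and monotonicity in alpha
  withr::local_seed(53)
  for (i in 1:20) {
    tabs <- lapply(1:3, function(j) {
      data.frame(gene_id = sprintf("g%d", 1:40),
                 log2fc = runif(40, -3, 3), pvalue = runif(40),
                 padj = runif(40))
    })
    names(tabs) <- c("head", "thorax", "leg")
    got <- upregulated_vs_all(tabs, alpha = 0.3)
    oracle <- sprintf("g%d", 1:40)
    for (tb in tabs) {
      oracle <- intersect(oracle, tb$gene_id[tb$log2fc > 0 & tb$padj < 0.3])
    }
    expect_setequal(got, oracle)
    expect_true(all(got %in% upregulated_vs_all(tabs, alpha = 0.5)))
  }
})

test_that("upset counts use exclusive signatures and conserve the union", {
  same <- list(a = "g1", b = "g1", c = "g1")
  u <- upset_counts(same)
  expect_equal(unname(u$intersections["a&b&c"]), 1L)
  expect_length(u$intersections, 1)

  disj <- list(a = "g1", b = "g2", c = "g3")
  u2 <- upset_counts(disj)
  expect_equal(sort(names(u2$intersections)), c("a", "b", "c"))
  expect_equal(unname(u2$marginals), c(1L, 1L, 1L))

  withr::local_seed(54)
  for (i in 1:20) {
    sets <- lapply(1:4, function(j) sample(sprintf("g%d", 1:30), sample(0:20, 1)))
    names(sets) <- c("w", "x", "y", "z")
    u3 <- upset_counts(sets)
    oracle <- upset_oracle(sets)
    expect_equal(u3$intersections[sort(names(u3$intersections))],
                 oracle[sort(names(oracle))])
    expect_equal(sum(u3$intersections), length(unique(unlist(sets))))
  }
})

test_that("expression restriction applies a strict per-sample raw-count rule", {
  m <- rbind(in_  = c(500, 9.9, 9.9, 9.9),
             out_ = c(500, 9.9, 10, 9.9),
             silent = c(2, 1, 1, 1))
  colnames(m) <- c("ant1", "h1", "h2", "l1")
  cm <- mk_counts(m, c(ant1 = "antennae", h1 = "head", h2 = "head", l1 = "leg"))
  r <- expression_restricted(cm, "antennae", threshold = 10)
  expect_true("in_" %in% r)      # 9.9 < 10 everywhere outside antennae
  expect_false("out_" %in% r)    # one sample at exactly 10
  expect_true("silent" %in% r)   # no focal condition by default
  expect_false("silent" %in% expression_restricted(cm, "antennae", require_focal = TRUE))

  # tissue-mean semantics admit a gene whose mean, not max, is under threshold
  mean_ok <- rbind(g = c(100, 5, 14, 2))
  colnames(mean_ok) <- colnames(m)
  cm2 <- mk_counts(mean_ok, c(ant1 = "antennae", h1 = "head", h2 = "head", l1 = "leg"))
  expect_length(expression_restricted(cm2, "antennae", per_sample = TRUE), 0)
  expect_equal(expression_restricted(cm2, "antennae", per_sample = FALSE), "g")

  withr::local_seed(55)
  for (i in 1:10) {
    big <- matrix(runif(60 * 8, 0, 30), 60, 8,
                  dimnames = list(sprintf("g%d", 1:60), sprintf("s%d", 1:8)))
    tis <- setNames(rep(c("antennae", "head"), each = 4), colnames(big))
    got <- expression_restricted(mk_counts(big, tis), "antennae", threshold = 10)
    oracle <- rownames(big)[apply(big[, 5:8], 1, max) < 10]
    expect_setequal(got, oracle)
  }
})

test_that("Fisher enrichment p equals the reference implementation on random tables", {
  r <- proportion_fisher(1, 1, 0, 1)   # table [[1,0],[0,1]]
  expect_equal(r$p, 1)
  # category == hit set == universe: degenerate, p = 1
  expect_equal(fisher_enrichment(letters, letters, letters)$p, 1)
  expect_equal(proportion_fisher(1, 2, 1, 2)$p, 1)

  r2 <- proportion_fisher(10, 10, 0, 10)
  expect_lt(r2$p, 0.001)
  expect_equal(r2$p, fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-10)

  withr::local_seed(56)
  for (i in 1:200) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) next
    mine <- proportion_fisher(cells[1], cells[1] + cells[2],
                              cells[3], cells[3] + cells[4])$p
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10,
                 info = paste(cells, collapse = ","))
    # symmetry under simultaneous swap of rows and columns
    swapped <- proportion_fisher(cells[4], cells[4] + cells[3],
                                 cells[2], cells[2] + cells[1])$p
    expect_equal(mine, swapped, tolerance = 1e-12)
  }
})

test_that("enrichment cells and odds ratio come from the declared 2x2 layout", {
  universe <- sprintf("g%d", 1:100)
  hit <- universe[1:20]
  cat_ <- universe[11:40]
  r <- fisher_enrichment(hit, cat_, universe)
  expect_equal(c(r$a, r$b, r$c, r$d), c(10, 20, 10, 60))
  expect_equal(r$a + r$b + r$c + r$d, 100)
  expect_equal(r$odds_ratio, (10 * 60) / (20 * 10))
  expect_equal(r$p, fisher.test(matrix(c(10, 20, 10, 60), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)
  expect_error(fisher_enrichment("g1", "g1", character(0)), "empty universe")
  expect_error(fisher_enrichment("nope", "g1", universe), "subsets")
})

test_that("externally supplied DE tables are validated on read", {
  f <- withr::local_tempfile(lines = c("gene_id\tlog2fc\tpvalue\tpadj",
                                       "g1\t2.0\t0.001\t0.01",
                                       "g2\t-1.0\t0.5\t0.7"))
  de <- read_de_table(f, comparison = c("antennae", "head"))
  expect_equal(de$gene_id, c("g1", "g2"))
  expect_equal(upregulated_set(de), "g1")

  bad <- withr::local_tempfile(lines = c("gene_id\tlog2fc\tpvalue\tpadj",
                                         "g1\t2.0\t0.1\t0.01"))
  expect_error(read_de_table(bad), "padj < pvalue")
})
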