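#!/usr/bin/env Rscript
# Stage 2: the antennal-expression analysis. Prune transcripts detected in at
# most one sample, test antennae against every other tissue, intersect the
# upregulated calls (upset logic), apply the raw-count < 10 restriction
# filter, and compare everything against the planted truth from stage 1.

suppressPackageStartupMessages(library(orstrat))
inp <- "results/synthetic"; out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tis <- read.delim(file.path(inp, "tissues.tsv"))
counts <- read_counts(file.path(inp, "counts.tsv"),
                      tissue_of = setNames(tis$tissue, tis$sample_id))
pruned <- prune_single_sample(counts)
cat(sprintf("pruning: %d of %d transcripts detected in <= 1 sample removed\n",
            nrow(counts$counts) - nrow(pruned$counts), nrow(counts$counts)))

non_focal <- setdiff(tissues(pruned), "antennae")
de <- lapply(non_focal, function(t) {
  res <- nb_de_test(pruned, "antennae", t)
  write.table(res, file.path(out, sprintf("de_antennae_vs_%s.tsv", t)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res
})
names(de) <- non_focal

up_sets <- lapply(de, upregulated_set, alpha = 0.05)
up_all <- upregulated_vs_all(de, alpha = 0.05)
writeLines(up_all, file.path(out, "antennae_upregulated_vs_all.txt"))
u <- upset_counts(up_sets)
write.table(data.frame(signature = names(u$intersections),
                       count = as.integer(u$intersections)),
            file.path(out, "upset_counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

restricted <- expression_restricted(pruned, "antennae", threshold = 10)
writeLines(restricted, file.path(out, "antennae_restricted.txt"))

planted <- readLines(file.path(inp, "truth_planted_upregulated.txt"))
cat(sprintf("antennae-upregulated vs all tissues: %s of the pruned set\n",
            format_ratio(length(up_all), nrow(pruned$counts))))
cat(sprintf("planted-effect recovery: %s; expression-restricted transcripts: %d\n",
            format_ratio(length(intersect(up_all, planted)), length(planted)),
            length(restricted)))
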