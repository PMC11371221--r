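#!/usr/bin/env Rscript
# Stage 4: phylostratigraphy. Reduce the similarity hits to the best hit per
# species, assign each protein the node distance of its most distant hit
# species, flag taxonomically restricted proteins, and test whether gene
# categories differ in their stratum distributions.

suppressPackageStartupMessages(library(orstrat))
inp <- "results/synthetic"; out <- "results/phylostrat"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- read_species_tree(file.path(inp, "species.nwk"), focal = "focal_sp")
truth <- read.delim(file.path(inp, "truth_families.tsv"))

# subjects were emitted as <species>_<gene>; rebuild the species map from ids
hits_raw <- read.delim(file.path(inp, "hits.tsv"), header = FALSE)
subj_ids <- unique(hits_raw$V2)
species_of <- setNames(sub("_g[0-9]+$", "", subj_ids), subj_ids)
hits <- read_blast_tab(file.path(inp, "hits.tsv"), species_of)

best <- best_hit_per_species(hits)
assignments <- assign_strata(best, tree, truth$gene_id)
write.table(assignments, file.path(out, "stratum_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
trps <- find_trps(assignments)
writeLines(trps, file.path(out, "trps.txt"))

recovered <- mean(assignments$node_distance ==
                    truth$birth_distance[match(assignments$protein_id, truth$gene_id)])
cat(sprintf("assigned %d proteins; TRPs: %s; planted-stratum recovery %.1f%%\n",
            nrow(assignments),
            format_ratio(length(trps), nrow(assignments)),
            100 * recovered))

# stratum enrichment between two synthetic categories: old genes (deep birth)
# vs the rest, binned into three clade-like strata
cats <- setNames(ifelse(truth$birth_distance >= 6, "deep_born", "recent_born"),
                 truth$gene_id)
d_seen <- sort(unique(assignments$node_distance))
bins <- setNames(ifelse(d_seen == 0, "restricted",
                 ifelse(d_seen <= 5, "recent", "ancient")),
                 as.character(d_seen))
tab <- strata_contingency(assignments, cats, strata_bins = bins)
write.table(tab, file.path(out, "strata_table.tsv"), sep = "\t", quote = FALSE)
enr <- stratum_enrichment(tab, list(c("deep_born", "recent_born")))
write.table(enr, file.path(out, "stratum_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("deep-born vs recent-born strata: chi2 = %.2f, df %d, adj. p = %.2g\n",
            enr$chi2, enr$df, enr$padj))
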