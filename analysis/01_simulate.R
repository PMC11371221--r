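#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs on disk — a reference species
# ladder (Newick), gene families with planted birth nodes (FASTA + truth), a
# genome annotation with planted tandem arrays (GFF3 + truth), and an NB
# count matrix with planted antennal effects (TSV + truth). Later stages read
# only these files.

suppressPackageStartupMessages(library(orstrat))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_species_set(seed, n_species = 12)
ape::write.tree(sim$tree$phy, file.path(out, "species.nwk"))

fam <- simulate_gene_families(sim$tree, n_genes = 50, trp_fraction = 0.1,
                              mode = "direct_hits", seed = seed)
write_blast_tab(cbind(fam$hits,
                      pident = 90, length = 100, mismatch = 10, gapopen = 0,
                      qstart = 1, qend = 100, sstart = 1, send = 100),
                file.path(out, "hits.tsv"))
write.table(fam$truth, file.path(out, "truth_families.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lay <- simulate_genome_layout(n_scaffolds = 4, n_genes = 60, seed = seed)
write_gff3(lay$genes, file.path(out, "genome.gff3"))
writeLines(vapply(lay$truth$planted_arrays, paste, character(1), collapse = ","),
           file.path(out, "truth_arrays.txt"))

simc <- simulate_counts(n_genes = 2000, seed = seed)
write_counts(simc$counts, file.path(out, "counts.tsv"))
write.table(data.frame(sample_id = names(simc$counts$tissue_of),
                       tissue = unname(simc$counts$tissue_of)),
            file.path(out, "tissues.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
for (f in c("planted_upregulated", "planted_restricted", "planted_single_sample")) {
  writeLines(simc$truth[[f]], file.path(out, paste0("truth_", f, ".txt")))
}

cat(sprintf("simulated: 12-species ladder; %d gene families (%d TRPs); %d genes in %d planted arrays; %d x %d count matrix\n",
            nrow(fam$truth), sum(fam$truth$is_trp),
            nrow(lay$genes), length(lay$truth$planted_arrays),
            nrow(simc$counts$counts), ncol(simc$counts$counts)))
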