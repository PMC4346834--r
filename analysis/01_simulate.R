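#!/usr/bin/env Rscript
# Generate the default synthetic study: gene catalog with planted families,
# tandem arrays, half-depth allelic twins and pseudogenes; pooled-library
# count matrix across biotic/abiotic/developmental/tissue conditions;
# homology hits with planted phylostratum ages; and a codon alignment with
# planted selected sites. Every later script reads these files.

suppressPackageStartupMessages(library(immunexpand))

seed <- as.integer(Sys.getenv("IMMUNEXPAND_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
cat("simulating study (seed", seed, "):", cfg$n_genes, "gene models,",
    nrow(cfg$design), "conditions\n")

sim_cat <- simulate_catalog(cfg)
write_gene_models(sim_cat$catalog, file.path(out, "genes.gff3"))
write_tsv(sim_cat$depths, file.path(out, "depths.tsv"))
write_tsv(sim_cat$domains, file.path(out, "domains.tsv"))

sim_cnt <- simulate_counts(sim_cat$catalog, cfg)
em <- sim_cnt$expr
counts <- data.frame(gene_id = rownames(em$counts), em$counts,
                     check.names = FALSE)
write_tsv(counts, file.path(out, "counts.tsv"))
write_tsv(em$design, file.path(out, "design.tsv"))
write_tsv(data.frame(condition = names(em$lib_sizes),
                     mapped_reads = as.numeric(em$lib_sizes)),
          file.path(out, "libsizes.tsv"))

sim_hom <- simulate_homology(sim_cat$catalog, cfg)
write_hit_table(sim_hom$hits, file.path(out, "hits.outfmt6.tsv"))
write_tsv(sim_hom$stratum_map, file.path(out, "stratum_map.tsv"))

aln <- simulate_codon_alignment(cfg)
write_fasta(codon_alignment_strings(aln), file.path(out, "codon_alignment.fasta"))

truth <- list(
  subtypes = sim_cat$truth$subtypes,
  tandem_arrays = sim_cat$truth$tandem_arrays,
  duplicate_pairs = sim_cat$truth$duplicate_pairs,
  pseudogenes = sim_cat$truth$pseudogenes,
  de = sim_cnt$truth$de,
  response = sim_cnt$truth$response,
  specific = sim_cnt$truth$specific,
  silent = sim_cnt$truth$silent,
  ages = sim_hom$truth,
  selected_sites = aln$truth$selected_sites
)
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     dataframe = "columns", auto_unbox = TRUE, digits = NA)

cat("planted:", length(truth$tandem_arrays), "tandem arrays,",
    nrow(truth$duplicate_pairs), "allelic twins,",
    nrow(truth$de), "DE gene-condition pairs,",
    length(truth$selected_sites), "selected codon sites\n")
cat("wrote raw datasets to", out, "\n")
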