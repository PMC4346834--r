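#!/usr/bin/env Rscript
# Differential expression for the replicate-free pooled libraries: per-challenge
# DE calls (exact conditional-binomial test, P < 0.001, fold-change >= 2 versus
# both untreated and PBS), challenge-specific (Venn) sets, infection time-course
# response classes, biotic/abiotic stress categories, organ/stage specificity
# (tau), and domain enrichment of up-regulated genes.

suppressPackageStartupMessages(library(immunexpand))

data_dir <- "results/data"
catalog <- parse_gene_models(file.path(data_dir, "genes.gff3"))
counts <- read_tsv(file.path(data_dir, "counts.tsv"))
design <- read_tsv(file.path(data_dir, "design.tsv"))
design$time_h <- suppressWarnings(as.numeric(design$time_h))
libs <- read_tsv(file.path(data_dir, "libsizes.tsv"))
domains <- read_tsv(file.path(data_dir, "domains.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)

cm <- as.matrix(counts[, -1]); rownames(cm) <- counts$gene_id
em <- expression_matrix(cm, design,
                        setNames(libs$mapped_reads, libs$condition),
                        setNames(catalog$end - catalog$start, catalog$gene_id))

## per-challenge DE versus both biotic controls
ctrls <- design$condition[design$axis == "biotic" & design$control]
challenges <- design$condition[design$axis == "biotic" & !design$control &
                                 is.na(design$time_h)]
de <- lapply(challenges, function(ch) call_de(em, ch, ctrls))
names(de) <- challenges
all_calls <- do.call(rbind, de)
write_tsv(all_calls[all_calls$direction != "ns", ], "results/de_calls.tsv")
n_de <- vapply(de, function(d) sum(d$direction != "ns"), 0L)
cat("DE genes per challenge (P<0.001, FC>=2 vs untreated AND PBS):\n")
print(n_de)

truth_keys <- paste(truth$de$gene_id, truth$de$condition)
called_keys <- unlist(lapply(challenges, function(ch) {
  d <- de[[ch]]; paste(d$gene_id[d$direction != "ns"], ch)
}))
in_scope <- truth_keys[truth$de$condition %in% challenges]
cat(sprintf("planted-DE recovery: sensitivity %.3f, FDR %.3f\n",
            mean(in_scope %in% called_keys),
            if (length(called_keys)) mean(!(called_keys %in% in_scope)) else 0))

## challenge-specific sets (Venn partition over four representative challenges)
sets <- lapply(de[c("LPS", "M_luteus", "Vibrio_anguillarum", "OsHV1")],
               function(d) d$gene_id[d$direction != "ns"])
venn <- condition_specific_sets(sets)
spec_counts <- lengths(venn$specific)
cat("challenge-specific DE counts:\n"); print(spec_counts)
write_tsv(data.frame(challenge = names(spec_counts), n_specific = spec_counts),
          "results/challenge_specific.tsv")

## infection time-course response classes
tc <- design[!is.na(design$time_h), ]
t0 <- tc$condition[tc$time_h == 0]
tc_calls <- do.call(rbind, lapply(tc$condition[tc$time_h > 0], function(cc) {
  d <- call_de(em, cc, t0)
  d$time_h <- tc$time_h[tc$condition == cc]
  d
}))
resp <- response_classify(tc_calls[, c("gene_id", "time_h", "direction")])
planted <- merge(resp, truth$response, by = "gene_id",
                 suffixes = c("_called", "_true"))
cat("time-course response classes of planted genes:\n")
print(table(planted$class_true, planted$class_called))
write_tsv(resp[resp$class != "flat", ], "results/response_classes.tsv")

## stress categories over the whole catalog
ab <- design$condition[design$axis == "abiotic" & !design$control]
ab_ctrl <- design$condition[design$axis == "abiotic" & design$control]
de_ab <- lapply(ab, function(ch) call_de(em, ch, ab_ctrl))
biotic_flag <- rownames(cm) %in% unique(unlist(sets))
abiotic_flag <- rownames(cm) %in%
  unique(unlist(lapply(de_ab, function(d) d$gene_id[d$direction != "ns"])))
cat("stress categories:\n")
print(table(stress_category(biotic_flag, abiotic_flag)))

## organ- and stage-specific expression by tau
tau_frac <- function(axis) {
  conds <- design$condition[design$axis == axis & !design$control]
  rp <- em$rpkm[, conds]
  mean(vapply(seq_len(nrow(rp)), function(i)
    isTRUE(specificity_index(rp[i, ])$specific), logical(1)))
}
cat(sprintf("organ-specific: %.1f%%; stage-specific: %.1f%%\n",
            100 * tau_frac("tissue"), 100 * tau_frac("development")))

## domain enrichment of genes up-regulated under any biotic challenge
up <- unique(unlist(lapply(de, function(d) d$gene_id[d$direction == "up"])))
dm <- data.frame(gene_id = rep(domains$gene_id,
                               lengths(strsplit(domains$tokens, ","))),
                 domain = unlist(strsplit(domains$tokens, ",")))
enr <- domain_enrichment(up, rownames(cm), dm)
enr <- enr[order(enr$p), ]
write_tsv(enr, "results/domain_enrichment.tsv")
cat("most enriched domains in biotic up-set (-log2 p):\n")
print(head(enr[, c("domain", "k", "K", "neg_log2_p", "q")], 5), row.names = FALSE)
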