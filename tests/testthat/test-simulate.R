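test_that("catalog simulation is deterministic and respects its invariants", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_catalog(cfg)
  b <- simulate_catalog(cfg)
  expect_identical(a, b)

  cat1 <- a$catalog
  expect_equal(nrow(cat1), cfg$n_genes)
  expect_true(all(cat1$start < cat1$end))
  # non-overlapping half-open intervals per scaffold
  for (sc in unique(cat1$scaffold)) {
    sub <- cat1[cat1$scaffold == sc, ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # family sizes as configured
  expect_equal(sum(cat1$family %in% "TLR"), 30)
  expect_equal(sum(cat1$family %in% "MyD88"), 10)
})

test_that("planted tandem arrays are consecutive runs, 8-array on s599", {
  a <- simulate_catalog(small_sim_config(seed = 3))
  arr8 <- Filter(function(x) length(x$members) == 8, a$truth$tandem_arrays)
  expect_length(arr8, 1)
  expect_equal(arr8[[1]]$scaffold, "s599")
  sub <- a$catalog[a$catalog$scaffold == "s599", ]
  pos <- match(arr8[[1]]$members, sub$gene_id)
  expect_equal(sort(diff(sort(pos))), rep(1L, 7))  # consecutive gene models
  expect_true(all(sub$family[sort(pos)] == "TLR"))
})

test_that("allelic twins sit at half depth; none planted means none below", {
  cfg <- small_sim_config(seed = 5)
  a <- simulate_catalog(cfg)
  twins <- a$truth$duplicate_pairs$twin_id
  expect_equal(length(twins), round(0.1 * cfg$n_genes))
  d <- a$depths
  expect_lt(mean(d$depth[d$gene_id %in% twins]), 60)
  expect_gt(mean(d$depth[!(d$gene_id %in% twins)]), 95)

  none <- simulate_catalog(small_sim_config(seed = 5, duplicate_fraction = 0))
  q5 <- qnorm(0.05, 105, 10.5)
  expect_lt(mean(none$depths$depth < q5), 0.08)
  expect_gt(min(none$depths$depth), 52.5)
})

test_that("domain architectures match planted subtypes", {
  a <- simulate_catalog(small_sim_config(seed = 9))
  calls <- classify_catalog(a$domains)
  m <- merge(calls, a$truth$subtypes, by = "gene_id",
             suffixes = c("_call", "_true"))
  m <- m[!is.na(m$subtype_true), ]
  expect_gt(nrow(m), 30)
  expect_equal(m$subtype_call, m$subtype_true)
})

test_that("config validation rejects impossible plants", {
  expect_error(small_sim_config(n_genes = 30), "exceed")
  expect_error(simulation_config(nb = list(mean = -5, dispersion = 0.1)),
               "nonpositive")
  expect_error(simulation_config(age_spec = rep(0.1, 9)), "age_spec")
  expect_error(simulation_config(
    selection = list(n_sequences = 5, n_codons = 20, selected_sites = 25,
                     multiplier = 2, ns_accept = .1, events_per_codon = 1)),
    "selected-site")
  expect_error(simulation_config(
    selection = list(n_sequences = 5, n_codons = 5, selected_sites = 2,
                     multiplier = 2, ns_accept = .1, events_per_codon = 1)),
    "n_codons")
})

test_that("count simulation is deterministic; planted fold-change is realised", {
  cfg <- small_sim_config(seed = 21)
  cat1 <- simulate_catalog(cfg)$catalog
  a <- simulate_counts(cat1, cfg)
  b <- simulate_counts(cat1, cfg)
  expect_identical(a$expr$counts, b$expr$counts)
  expect_equal(nrow(a$truth$de), 20)

  # Monte-Carlo: mean count ratio of an lfc=+3 gene vs control is ~8
  # after library-size scaling (averaged over planted genes and seeds)
  ratios <- c()
  for (s in 1:8) {
    cfg_s <- small_sim_config(seed = 100 + s)
    cat_s <- simulate_catalog(cfg_s)$catalog
    sim <- simulate_counts(cat_s, cfg_s)
    de <- sim$truth$de[sim$truth$de$lfc == 3, ]
    ctrl <- "untreated"
    lib <- sim$expr$lib_sizes
    for (r in seq_len(nrow(de))) {
      ct <- sim$expr$counts[de$gene_id[r], de$condition[r]] / lib[[de$condition[r]]]
      cc <- sim$expr$counts[de$gene_id[r], ctrl] / lib[[ctrl]]
      if (cc > 0) ratios <- c(ratios, ct / cc)
    }
  }
  expect_gt(length(ratios), 50)
  expect_equal(mean(ratios), 8, tolerance = 0.15)
})

test_that("zero planted fold-changes leave the DE ground truth empty", {
  cfg <- small_sim_config(seed = 2)
  cfg$de_spec$n_de <- 0L
  cat1 <- simulate_catalog(cfg)$catalog
  sim <- simulate_counts(cat1, cfg)
  expect_equal(nrow(sim$truth$de), 0)
})

test_that("homology simulation plants recoverable ages", {
  cfg <- small_sim_config(seed = 31)
  hm <- simulate_homology(paste0("g", 1:200), cfg)
  expect_identical(hm, simulate_homology(paste0("g", 1:200), cfg))
  lv <- hm$stratum_map$level[match(sub("\\|.*$", "", hm$hits$sseqid),
                                   hm$stratum_map$subject)]
  hits <- data.frame(query = hm$hits$qseqid, subject = hm$hits$sseqid,
                     evalue = hm$hits$evalue, level = lv)
  # no qualifying hit older than the true age; >=1 at the true age
  for (g in sample(hm$truth$gene_id, 40)) {
    age <- hm$truth$age[hm$truth$gene_id == g]
    qual <- hits[hits$query == g & hits$evalue <= 1e-3, ]
    expect_gte(min(qual$level), age)
    expect_true(age %in% qual$level)
  }
})

test_that("decoy-free full-detection homology yields hits at exactly a..10", {
  cfg <- small_sim_config(
    seed = 8, homology = list(detection_prob = 1, decoy_fraction = 0,
                              orgs_per_level = 2L))
  hm <- simulate_homology(paste0("g", 1:50), cfg)
  lv <- hm$stratum_map$level[match(sub("\\|.*$", "", hm$hits$sseqid),
                                   hm$stratum_map$subject)]
  for (g in hm$truth$gene_id) {
    age <- hm$truth$age[hm$truth$gene_id == g]
    expect_setequal(unique(lv[hm$hits$qseqid == g]), age:10)
  }
})

test_that("codon alignments: no stops, deterministic, rate 0 inert", {
  cfg <- small_sim_config(seed = 41)
  aln <- simulate_codon_alignment(cfg)
  expect_identical(aln, simulate_codon_alignment(cfg))
  ct <- codon_table()
  expect_false(any(ct[aln$codons] == "*"))

  frozen <- small_sim_config(seed = 41,
    selection = list(n_sequences = 6L, n_codons = 30L, selected_sites = 3L,
                     multiplier = 5, ns_accept = 0.05, events_per_codon = 0))
  a0 <- simulate_codon_alignment(frozen)
  expect_true(all(apply(a0$codons, 1, identical, a0$ancestor)))
})

test_that("planted site has the top nonsynonymous count in most replicates", {
  pm <- immunexpand:::codon_pair_matrices()
  hits <- 0; nrep <- 25
  for (r in seq_len(nrep)) {
    cfg <- simulation_config(seed = 500 + r,
      selection = list(n_sequences = 20L, n_codons = 100L,
                       selected_sites = 5L, multiplier = 10,
                       ns_accept = 0.03, events_per_codon = 6))
    aln <- simulate_codon_alignment(cfg)
    pr <- combn(nrow(aln$codons), 2)
    nsd <- vapply(seq_len(ncol(aln$codons)), function(j) {
      sum(pm$N[cbind(aln$codons[pr[1, ], j], aln$codons[pr[2, ], j])])
    }, numeric(1))
    if (which.max(nsd) == 5) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.95)
})
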