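test_that("evidence merging unions provenance and resolves family conflicts", {
  base <- tiny_catalog()
  set1 <- base[1:4, ]
  set3 <- base[c(2, 3, 5, 6), ]
  set3$family[set3$gene_id == "g2"] <- "TNF"
  merged <- merge_evidence(list(interproscan_set = set1, nr_set = set3))
  expect_equal(nrow(merged), 6)
  expect_equal(merged$provenance[merged$gene_id == "g2"],
               "interproscan_set,nr_set")
  # interproscan outranks nr: TLR kept, conflict recorded
  expect_equal(merged$family[merged$gene_id == "g2"], "TLR")
  conf <- attr(merged, "family_conflicts")
  expect_equal(conf$gene_id, "g2")
  expect_equal(conf$dropped, "TNF")

  disjoint <- merge_evidence(list(a = base[1:3, ], b = base[4:6, ]),
                             priority = c("a", "b"))
  expect_equal(nrow(disjoint), 6)
})

test_that("evidence merging rejects conflicting coordinates", {
  base <- tiny_catalog()
  moved <- base[1, ]
  moved$start <- 10L; moved$end <- 900L
  expect_error(merge_evidence(list(a = base[1, ], b = moved)),
               "conflicting coordinates for g1")
})

test_that("depth filter removes strictly-below-threshold genes and is idempotent", {
  cat1 <- tiny_catalog()
  depths <- data.frame(gene_id = cat1$gene_id,
                       depth = c(79.9, 80.0, 80.1, 110, 52, 105))
  out <- depth_filter(cat1, depths, threshold = 80)
  expect_setequal(out$report$removed_ids, c("g1", "g5"))
  expect_equal(out$report$n_removed_depth, 2)
  expect_equal(nrow(out$catalog) + out$report$n_removed_depth, nrow(cat1))
  expect_true("g2" %in% out$catalog$gene_id)  # exactly 80 kept

  again <- depth_filter(out$catalog, depths, threshold = 80)
  expect_equal(again$report$n_removed_depth, 0)
  expect_equal(again$catalog$gene_id, out$catalog$gene_id)

  expect_error(depth_filter(cat1, depths[-1, ], threshold = 80),
               "missing depth for gene g1")
  exempted <- depth_filter(cat1, depths[-1, ], threshold = 80, exempt = "g1")
  expect_true("g1" %in% exempted$catalog$gene_id)
})

test_that("planted half-depth twins are removed with high F1 on simulated data", {
  sim <- simulate_catalog(small_sim_config(seed = 4, n_genes = 500))
  out <- depth_filter(sim$catalog, sim$depths, threshold = 80)
  twins <- sim$truth$duplicate_pairs$twin_id
  removed <- out$report$removed_ids
  tp <- length(intersect(removed, twins))
  expect_gte(tp / length(twins), 0.95)
  normal <- setdiff(sim$catalog$gene_id, twins)
  expect_lte(length(setdiff(removed, twins)) / length(normal), 0.02)
})

test_that("functionality flag is strict RPKM > 1 on the max over conditions", {
  # gene_length 1000, lib 1e7: count 10 -> RPKM exactly 1
  counts <- matrix(c(10, 10, 10, 10,
                     11, 10, 10, 10,
                     0, 0, 0, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("border", "above", "zero"),
                                   c("ctrl", "PBS", "trtA", "trtB")))
  em <- tiny_expression(counts)
  ff <- functional_filter(em)
  expect_equal(ff$functional, c(FALSE, TRUE, FALSE))
  expect_equal(ff$max_rpkm[1], 1.0)

  missing <- gene_catalog(data.frame(gene_id = "ghost", scaffold = "s",
                                     start = 0L, end = 10L, strand = "+"))
  expect_error(functional_filter(em, missing), "absent.*ghost")
})

test_that("manual overrides drop and relabel after filtering", {
  cat1 <- tiny_catalog()
  ov <- data.frame(gene_id = c("g1", "g3"), action = c("drop", "family"),
                   family = c(NA, "TLR"))
  out <- apply_overrides(cat1, ov)
  expect_false("g1" %in% out$gene_id)
  expect_equal(out$family[out$gene_id == "g3"], "TLR")
  expect_error(apply_overrides(cat1, data.frame(gene_id = "g2",
                                                action = "explode")),
               "unknown override action")
})
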