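test_that("rpkm follows its defining arithmetic, scalar and matrix alike", {
  expect_equal(rpkm(100, 1000, 1e7), 10)
  expect_equal(rpkm(0, 123, 456), 0)
  expect_error(rpkm(-1, 100, 100), "negative")
  expect_error(rpkm(1, 0, 100), "positive")

  withr::local_seed(1)
  counts <- matrix(rpois(20, 50), 4, 5,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  len <- c(500, 1000, 1500, 2000)
  lib <- c(1e7, 2e7, 1e7, 3e7, 1e7)
  m <- rpkm(counts, len, lib)
  for (i in 1:4) for (j in 1:5)
    expect_equal(m[i, j], rpkm(counts[i, j], len[i], lib[j]))
})

test_that("max normalisation scales rows into [0,1] with zero rows untouched", {
  m <- rbind(a = c(2, 4, 8), b = c(0, 0, 0), c = c(5, 5, 5))
  out <- max_normalize(m)
  expect_equal(out["a", ], c(0.25, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(all(out >= 0 & out <= 1))
  nz <- apply(m, 1, max) > 0
  expect_true(all(apply(out[nz, ], 1, max) == 1))
})

test_that("exact Poisson-rate test matches the enumeration oracle", {
  expect_equal(de_exact_test(0, 0), 1)
  p_eq <- de_exact_test(10, 10)
  expect_gte(p_eq, 0.99)
  expect_equal(p_eq, oracle_exact_p(10, 10), tolerance = 1e-12)
  expect_equal(de_exact_test(50, 5), oracle_exact_p(50, 5), tolerance = 1e-12)
  # unequal libraries
  expect_equal(de_exact_test(30, 10, 3e7, 1e7),
               oracle_exact_p(30, 10, 3e7, 1e7), tolerance = 1e-12)
  # symmetry
  expect_equal(de_exact_test(17, 40, 2e7, 3e7),
               de_exact_test(40, 17, 3e7, 2e7), tolerance = 1e-14)
  # vectorised equals elementwise
  a <- c(0, 3, 50, 120); b <- c(0, 30, 5, 100)
  expect_equal(de_exact_test(a, b),
               mapply(oracle_exact_p, a, b), tolerance = 1e-12)
})

test_that("DE calls require both significance and fold-change against all controls", {
  em <- tiny_expression()
  calls <- call_de(em, "trtA", c("ctrl", "PBS"))
  expect_equal(calls$direction[calls$gene_id == "gA"], "up")
  expect_equal(calls$direction[calls$gene_id == "gB"], "ns")
  expect_equal(calls$direction[calls$gene_id == "gC"], "ns")

  # significant but below fold-change threshold stays ns
  counts <- matrix(c(1000, 1000, 1500, 1000), 1,
                   dimnames = list("gX", c("ctrl", "PBS", "trtA", "trtB")))
  em2 <- tiny_expression(counts)
  c2 <- call_de(em2, "trtA", c("ctrl", "PBS"))
  expect_lt(c2$p, 0.001)
  expect_equal(c2$direction, "ns")

  # up versus one control only is not enough
  counts3 <- matrix(c(100, 700, 800, 100), 1,
                    dimnames = list("gY", c("ctrl", "PBS", "trtA", "trtB")))
  em3 <- tiny_expression(counts3)
  expect_equal(call_de(em3, "trtA", c("ctrl", "PBS"))$direction, "ns")
  expect_equal(call_de(em3, "trtA", "ctrl")$direction, "up")

  expect_error(call_de(em, "trtA", character()), "empty control")
  expect_error(call_de(em, "nope", "ctrl"), "unknown condition")
})

test_that("time-course response classes follow the early/late windows", {
  mk <- function(dirs) data.frame(gene_id = "g", time_h = c(6, 12, 24, 48),
                                  direction = dirs)
  expect_equal(response_classify(mk(c("up", "ns", "ns", "ns")))$class, "early")
  expect_equal(response_classify(mk(c("ns", "up", "ns", "up")))$class,
               "early_and_late")
  expect_equal(response_classify(mk(c("ns", "ns", "up", "ns")))$class, "late")
  expect_equal(response_classify(mk(c("ns", "ns", "down", "ns")))$class, "down")
  expect_equal(response_classify(mk(c("ns", "ns", "ns", "ns")))$class, "flat")
  # a down call alongside an up call does not make the gene "down"
  expect_equal(response_classify(mk(c("up", "ns", "down", "ns")))$class, "early")
  expect_error(response_classify(
    data.frame(gene_id = "g", time_h = c(6, 12, 24), direction = "ns")),
    "missing time point")
})

test_that("tau specificity matches its formula and boundary behaviour", {
  one <- specificity_index(c(0, 0, 10, 0))
  expect_equal(one$tau, 1)
  expect_true(one$specific)
  expect_equal(one$peak, 3)

  flat <- specificity_index(c(5, 5, 5, 5))
  expect_equal(flat$tau, 0)
  expect_false(flat$specific)

  x <- c(1, 2, 100)
  expect_equal(specificity_index(x)$tau, oracle_tau(x))

  zero <- specificity_index(c(0, 0, 0))
  expect_true(is.na(zero$tau))
  expect_false(zero$specific)

  # dim peak: tau can be high but the specific flag needs peak >= 1 RPKM
  dim_peak <- specificity_index(c(0, 0, 0.5, 0))
  expect_equal(dim_peak$tau, 1)
  expect_false(dim_peak$specific)

  # concentrating mass never decreases tau
  withr::local_seed(42)
  for (i in 1:20) {
    x <- runif(5, 0, 10)
    j <- which.max(x)
    y <- x; y[j] <- y[j] * 2
    expect_gte(specificity_index(y)$tau + 1e-12, specificity_index(x)$tau)
  }
})

test_that("challenge-specific sets partition the union", {
  sets <- list(A = c("g1", "g2"), B = c("g2"))
  out <- condition_specific_sets(sets)
  expect_equal(out$specific$A, "g1")
  expect_length(out$specific$B, 0)
  expect_setequal(unlist(out$cells), c("g1", "g2"))

  disjoint <- condition_specific_sets(list(A = c("x", "y"), B = c("z")))
  expect_setequal(disjoint$specific$A, c("x", "y"))
  expect_equal(disjoint$specific$B, "z")

  withr::local_seed(7)
  sets4 <- lapply(1:4, function(i) sample(paste0("g", 1:50), 20))
  names(sets4) <- LETTERS[1:4]
  part <- condition_specific_sets(sets4)
  expect_equal(sort(unname(unlist(part$cells))), sort(unique(unlist(sets4))))
  expect_equal(sum(lengths(part$cells)), length(unique(unlist(sets4))))
})

test_that("stress categories form a four-way partition", {
  expect_equal(stress_category(TRUE, FALSE), "biotic_only")
  expect_equal(stress_category(TRUE, TRUE), "both")
  expect_equal(stress_category(FALSE, FALSE), "neither")
  b <- c(TRUE, TRUE, FALSE, FALSE); a <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(sum(table(stress_category(b, a))), 4)
})

test_that("domain enrichment matches the hypergeometric enumeration oracle", {
  genes <- paste0("g", 1:100)
  dmap <- data.frame(gene_id = genes[1:10], domain = "C1Q")
  up <- c(genes[1:5], genes[50:54])
  out <- domain_enrichment(up, genes, dmap)
  expect_equal(out$p, oracle_hyper_upper(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(out$neg_log2_p, -log2(out$p))

  # universal domain and empty overlap both give p = 1
  dall <- data.frame(gene_id = genes, domain = "UBIQ")
  expect_equal(domain_enrichment(genes[1:10], genes, dall)$p, 1)
  dmiss <- data.frame(gene_id = genes[20:29], domain = "TIR")
  expect_equal(domain_enrichment(genes[1:10], genes, dmiss)$p, 1)

  expect_error(domain_enrichment("ghost", genes, dmap), "subset")
  expect_warning(
    domain_enrichment(genes[1:2], genes,
                      rbind(dmap, data.frame(gene_id = "zz", domain = "ELSEWHERE"))),
    "skipped")
})

test_that("exact-test type-I error is controlled near the nominal level", {
  withr::local_seed(2024)
  a <- rpois(4000, 100); b <- rpois(4000, 100)
  p <- de_exact_test(a, b)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("planted DE is recovered with high sensitivity and low FDR", {
  cfg <- small_sim_config(seed = 77)
  sim_cat <- simulate_catalog(cfg)
  sim <- simulate_counts(sim_cat$catalog, cfg)
  des <- sim$expr$design
  ctrls <- des$condition[des$axis == "biotic" & des$control]
  challenges <- unique(sim$truth$de$condition)
  called <- character()
  for (ch in challenges) {
    d <- call_de(sim$expr, ch, ctrls)
    called <- c(called, paste(d$gene_id[d$direction != "ns"], ch))
  }
  truth_keys <- paste(sim$truth$de$gene_id, sim$truth$de$condition)
  expect_gte(mean(truth_keys %in% called), 0.9)
  if (length(called) > 0)
    expect_lte(mean(!(called %in% truth_keys)), 0.05)
})
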