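test_that("tandem arrays link by intervening-gene and distance rules", {
  # 8 adjacent same-family genes -> one array of 8
  cat8 <- gene_catalog(data.frame(
    gene_id = paste0("t", 1:8), scaffold = "s599",
    start = seq(0, 7) * 5000L, end = seq(0, 7) * 5000L + 1500L,
    strand = "+", family = "TLR"))
  arr <- tandem_clusters(cat8, "TLR")
  expect_length(arr, 1)
  expect_equal(arr[[1]]$members, paste0("t", 1:8))

  # two family genes separated by 6 other gene models -> no array
  df <- data.frame(
    gene_id = c("a", paste0("x", 1:6), "b"),
    scaffold = "s1",
    start = seq(0, 7) * 3000L, end = seq(0, 7) * 3000L + 1000L,
    strand = "+",
    family = c("TLR", rep(NA, 6), "TLR"))
  expect_length(tandem_clusters(gene_catalog(df), "TLR"), 0)
  # with 5 intervening they do link
  df5 <- df[-2, ]
  expect_length(tandem_clusters(gene_catalog(df5), "TLR"), 1)

  # distance guard: adjacent but over 100 kb apart
  far <- gene_catalog(data.frame(
    gene_id = c("a", "b"), scaffold = "s1",
    start = c(0L, 150000L), end = c(1500L, 151500L),
    strand = "+", family = "TLR"))
  expect_length(tandem_clusters(far, "TLR"), 0)

  expect_error(tandem_clusters(cat8, "NLRP"), "unknown family")
})

test_that("tandem clustering is invariant under order-preserving shifts", {
  sim <- simulate_catalog(small_sim_config(seed = 13))
  arr1 <- tandem_clusters(sim$catalog, "TLR")
  shifted <- sim$catalog
  shifted$start <- shifted$start + 250L
  shifted$end <- shifted$end + 250L
  arr2 <- tandem_clusters(shifted, "TLR")
  expect_equal(lapply(arr1, `[[`, "members"), lapply(arr2, `[[`, "members"))
})

test_that("planted arrays are recovered exactly on simulated catalogs", {
  sim <- simulate_catalog(small_sim_config(seed = 17))
  got <- c(tandem_clusters(sim$catalog, "TLR"),
           tandem_clusters(sim$catalog, "MyD88"))
  got_members <- lapply(got, function(a) sort(a$members))
  want_members <- lapply(sim$truth$tandem_arrays, function(a) sort(a$members))
  expect_setequal(vapply(got_members, paste, "", collapse = "|"),
                  vapply(want_members, paste, "", collapse = "|"))
})

test_that("protein distances: identity, closed form, symmetry, gaps", {
  aln <- rbind(A = c("M", "K", "L", "V", "P", "Q", "R", "S", "T", "W"),
               B = c("M", "K", "L", "V", "P", "Q", "R", "S", "T", "W"),
               C = c("M", "K", "L", "V", "P", "Q", "R", "S", "T", "F"))
  D <- protein_distance(aln)
  expect_equal(D["A", "B"], 0)
  expect_equal(D["A", "C"], -log(1 - 0.1))  # p = 0.1
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), rownames(aln)))

  gappy <- rbind(A = c("M", "-", "L"), B = c("M", "K", "V"))
  expect_equal(protein_distance(gappy, model = "p")["A", "B"], 0.5)
  allgap <- rbind(A = c("-", "-"), B = c("K", "-"))
  expect_error(protein_distance(allgap), "no comparable columns")

  sat <- rbind(A = c("M", "M"), B = c("K", "K"))
  expect_equal(protein_distance(sat)["A", "B"], 10)  # p = 1 capped
})

test_that("NJ recovers 3- and 4-leaf trees from their additive distances", {
  # three-point formulas
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D3)
  expect_equal(sort(tr$edge.length), sort(c(2, 3, 7)))

  # known 4-leaf additive tree: ((A:1,B:2):3,(C:4,D:5))
  D4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D4["A", "B"] <- D4["B", "A"] <- 3
  D4["A", "C"] <- D4["C", "A"] <- 8
  D4["A", "D"] <- D4["D", "A"] <- 9
  D4["B", "C"] <- D4["C", "B"] <- 9
  D4["B", "D"] <- D4["D", "B"] <- 10
  D4["C", "D"] <- D4["D", "C"] <- 9
  tr4 <- nj_tree(D4)
  back <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_lt(max(abs(back - D4)), 1e-9)

  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
  bad <- D3; bad[1, 2] <- NaN; bad[2, 1] <- NaN
  expect_error(nj_tree(bad), "NaN")
  neg <- D3; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(nj_tree(neg), "negative")
})

test_that("NJ equals the additive-tree oracle on random 8-leaf trees", {
  withr::local_seed(31)
  for (i in 1:20) {
    ra <- random_additive(8)
    tr <- nj_tree(ra$D)
    back <- ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)]
    expect_lt(max(abs(back - ra$D)), 1e-9)
    expect_equal(ape::dist.topo(tr, ra$tree), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic, bounded, and high for clear splits", {
  withr::local_seed(5)
  # two clearly separated clades: low divergence within, high between
  block <- function(base, n, len = 60) {
    t(vapply(seq_len(n), function(i) {
      s <- base
      s[sample(len, 2)] <- sample(LETTERS[1:20], 2, replace = TRUE)
      s
    }, character(len)))
  }
  b1 <- sample(LETTERS[1:20], 60, replace = TRUE)
  b2 <- rev(b1)
  aln <- rbind(block(b1, 4), block(b2, 4))
  rownames(aln) <- paste0(rep(c("oy", "mu"), each = 4), 1:4)

  t1 <- bootstrap_support(aln, B = 100, seed = 42)
  t2 <- bootstrap_support(aln, B = 100, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- as.integer(t1$node.label[t1$node.label != ""])
  expect_true(all(sup >= 0 & sup <= 100))

  # the oyster/mussel split should be supported in >= 99% of replicates
  part <- ape::prop.part(t1)
  labs <- attr(part, "labels")
  split_found <- FALSE
  for (k in seq_along(part)) {
    side <- labs[part[[k]]]
    if (setequal(side, paste0("oy", 1:4)) || setequal(side, paste0("mu", 1:4))) {
      nd <- k  # part index k corresponds to internal node k
      split_found <- TRUE
      expect_gte(as.integer(t1$node.label[k]), 99)
    }
  }
  expect_true(split_found)
  expect_error(bootstrap_support(aln, B = 0), "B must be")
})

test_that("lineage-specific clades are maximal single-taxon clades", {
  tr <- ape::read.tree(text = "(((o1:1,o2:1):1,(o3:1,o4:1):1):2,((m1:1,m2:1):1,(o5:1,o6:1):4):1);")
  taxa <- setNames(c(rep("oyster", 4), rep("mussel", 2), "oyster", "oyster"),
                   c("o1", "o2", "o3", "o4", "m1", "m2", "o5", "o6"))
  clades <- lineage_specific_clades(tr, taxa, min_size = 3)
  oy <- Filter(function(x) x$taxon == "oyster", clades)
  expect_gte(length(oy), 1)
  # maximality: no clade contained in another
  for (a in clades) for (b in clades) {
    if (!identical(a, b)) expect_false(all(a$members %in% b$members))
  }

  # alternating caterpillar has no pure clade of size 3
  cater <- ape::read.tree(text = "((((a1:1,b1:1):1,a2:1):1,b2:1):1,(a3:1,b3:1):1);")
  taxa2 <- setNames(rep(c("A", "B"), 3), c("a1", "b1", "a2", "b2", "a3", "b3"))
  expect_length(lineage_specific_clades(cater, taxa2, min_size = 3), 0)

  expect_error(lineage_specific_clades(tr, taxa[-1]), "untagged leaf")
})
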