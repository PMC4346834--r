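test_that("ng86 handles identity, pure-synonymous and error cases", {
  cds <- "ATGGGAAAACTT"
  same <- ng86_dnds(cds, cds)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$omega))

  # GGA <-> GGG is synonymous (Gly)
  syn <- ng86_dnds("ATGGGACTT", "ATGGGGCTT")
  expect_equal(syn$dN, 0)
  expect_gt(syn$dS, 0)

  expect_error(ng86_dnds("ATGG", "ATGG"), "multiple of 3")
  expect_error(ng86_dnds("ATGTAACTT", "ATGTACCTT"), "stop codon at codon 2")
  # terminal stop tolerated
  ok <- ng86_dnds("ATGAAATAA", "ATGAAGTAA")
  expect_gte(ok$dN, 0)
})

test_that("ng86 is symmetric and recoding synonymously leaves dN at zero", {
  withr::local_seed(11)
  a <- random_cds(40)
  b <- random_cds(40)
  r1 <- ng86_dnds(a, b)
  r2 <- ng86_dnds(b, a)
  expect_equal(r1$dN, r2$dN, tolerance = 1e-12)
  expect_equal(r1$dS, r2$dS, tolerance = 1e-12)

  # recoding by single-nucleotide synonymous substitutions: dN stays 0
  code <- codon_table()
  one_step <- function(cd) {
    nt <- strsplit(cd, "")[[1]]
    out <- character()
    for (pos in 1:3) for (bb in setdiff(c("A", "C", "G", "T"), nt[pos])) {
      x <- nt; x[pos] <- bb
      out <- c(out, paste0(x, collapse = ""))
    }
    out
  }
  cods <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  recoded <- vapply(cods, function(cd) {
    syns <- intersect(one_step(cd), names(code)[code == code[[cd]]])
    if (length(syns)) sample(syns, 1) else cd
  }, character(1))
  r <- ng86_dnds(a, paste0(recoded, collapse = ""))
  expect_equal(r$dN, 0)
})

test_that("ng86 matches the brute-force pathway-enumeration oracle", {
  withr::local_seed(23)
  for (i in 1:8) {
    a <- random_cds(30)
    b <- random_cds(30)
    got <- ng86_dnds(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$pN, want$pN, tolerance = 1e-10)
    expect_equal(got$pS, want$pS, tolerance = 1e-10)
    if (!is.na(want$dN)) expect_equal(got$dN, want$dN, tolerance = 1e-10)
    if (!is.na(want$dS)) expect_equal(got$dS, want$dS, tolerance = 1e-10)
  }
})

test_that("gapped codons are excluded pairwise", {
  r <- ng86_dnds("ATG---AAA", "ATGCCCAAG")
  full <- ng86_dnds("ATGAAA", "ATGAAG")
  expect_equal(r$Nd, full$Nd)
  expect_equal(r$Sd, full$Sd)
})

test_that("site scan flags planted sites and stays quiet on invariant columns", {
  cfg <- simulation_config(seed = 7)
  aln <- simulate_codon_alignment(cfg)
  scan <- site_selection_scan(aln)
  called <- scan$sites$site[scan$sites$selected]
  expect_gte(mean(aln$truth$selected_sites %in% called), 0.6)
  if (length(called))
    expect_lte(mean(!(called %in% aln$truth$selected_sites)), 0.2)

  # invariant alignment: no differences, p = 1 everywhere, nothing selected
  inv <- matrix("ATG", 6, 10)
  s0 <- site_selection_scan(inv)
  expect_equal(s0$sites$nonsyn, rep(0, 10))
  expect_true(all(s0$sites$p == 1))
  expect_false(any(s0$sites$selected))

  expect_error(site_selection_scan(matrix("ATG", 3, 10)), ">= 4")
})

test_that("scan power grows with the planted rate multiplier", {
  sens_at <- function(mult, reps = 6) {
    hits <- 0; tot <- 0
    for (r in seq_len(reps)) {
      cfg <- simulation_config(seed = 900 + r,
        selection = list(n_sequences = 20L, n_codons = 100L,
                         selected_sites = c(10L, 30L, 50L, 70L, 90L),
                         multiplier = mult, ns_accept = 0.03,
                         events_per_codon = 6))
      aln <- simulate_codon_alignment(cfg)
      scan <- site_selection_scan(aln)
      called <- scan$sites$site[scan$sites$selected]
      hits <- hits + sum(aln$truth$selected_sites %in% called)
      tot <- tot + length(aln$truth$selected_sites)
    }
    hits / tot
  }
  s1 <- sens_at(1)
  s10 <- sens_at(10)
  expect_lte(s1, 0.1)
  expect_gte(s10, 0.7)
  expect_gt(s10, s1)
})
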