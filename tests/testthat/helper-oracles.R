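# Independent brute-force oracles. Each reimplements the quantity it checks
# from first principles, sharing no code path with the package.

# two-sided doubled-tail binomial p by explicit term summation
oracle_exact_p <- function(a, b, lib_a = 1, lib_b = 1) {
  n <- a + b
  if (n == 0) return(1)
  pr <- lib_a / (lib_a + lib_b)
  terms <- vapply(0:n, function(k) dbinom(k, n, pr), numeric(1))
  lower <- sum(terms[seq_len(a + 1)])
  upper <- sum(terms[(a + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# Pearson chi-square on a 2x2 by the definition sum((O-E)^2/E)
oracle_chisq_2x2 <- function(count_a, total_a, count_b, total_b) {
  O <- matrix(c(count_a, total_a - count_a, count_b, total_b - count_b),
              2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# upper-tail hypergeometric by direct combinatorial summation
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, numeric(1)))
}

# tau specificity by its defining formula
oracle_tau <- function(x) {
  xn <- x / max(x)
  sum(1 - xn) / (length(x) - 1)
}

# --- independent Nei-Gojobori oracle ---------------------------------------

.oracle_code <- local({
  b <- c("A", "C", "G", "T")
  cods <- apply(expand.grid(b, b, b)[, 3:1], 1, paste0, collapse = "")
  aa <- vapply(cods, function(x) seqinr::translate(strsplit(x, "")[[1]]),
               character(1))
  setNames(aa, cods)
})

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# syn/nonsyn sites of one codon, stop-excluded denominators
oracle_sites <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  aa <- .oracle_code[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), nt[pos])
    res <- vapply(alts, function(bb) {
      x <- nt; x[pos] <- bb
      .oracle_code[[paste0(x, collapse = "")]]
    }, character(1))
    res <- res[res != "*"]
    if (length(res)) s <- s + sum(res == aa) / length(res)
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged syn/nonsyn differences between two codons
oracle_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(s = 0, n = 0))
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  dp <- which(n1 != n2)
  eval_path <- function(ord, allow_stop) {
    cur <- n1; s <- 0; n <- 0
    for (p in ord) {
      from <- .oracle_code[[paste0(cur, collapse = "")]]
      cur[p] <- n2[p]
      tocod <- paste0(cur, collapse = "")
      to <- .oracle_code[[tocod]]
      if (to == "*" && !allow_stop && tocod != c2) return(NULL)
      if (from == to) s <- s + 1 else n <- n + 1
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null),
                lapply(oracle_perms(dp), eval_path, allow_stop = FALSE))
  if (!length(res))
    res <- lapply(oracle_perms(dp), eval_path, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(s = mean(m[, 1]), n = mean(m[, 2]))
}

oracle_ng86 <- function(seq1, seq2) {
  sp <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- sp(seq1); c2 <- sp(seq2)
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(c1)) {
    s1 <- oracle_sites(c1[i]); s2 <- oracle_sites(c2[i])
    S <- S + (s1[["s"]] + s2[["s"]]) / 2
    N <- N + (s1[["n"]] + s2[["n"]]) / 2
    d <- oracle_diffs(c1[i], c2[i])
    Sd <- Sd + d[["s"]]; Nd <- Nd + d[["n"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(Nd / N), dS = jc(Sd / S), pN = Nd / N, pS = Sd / S)
}

# random sense codons / CDS
random_cds <- function(n_codons) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# random additive tree and its (additive) distance matrix
random_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# exact two-sided rank-sum p by full enumeration of group assignments (tiny n)
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combs <- combn(n, na)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
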