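## Codon-level machinery shared by the selection module and the codon-alignment
## simulator. The standard genetic code is taken from seqinr and cached as a
## lookup table; counting logic (sites and pathway-averaged differences) follows
## the classical per-codon bookkeeping used by counting dN/dS estimators.

DNA_BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#' @return Character vector of codons.
#' @export
all_codons <- function() {
  if (is.null(.pkg_cache$codons)) {
    g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                     stringsAsFactors = FALSE)
    .pkg_cache$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .pkg_cache$codons
}

#' The standard genetic code as a codon -> amino-acid table
#'
#' Built once from [seqinr::translate()] (universal code); stop codons are
#' `"*"`. Kept as data so an alternative code table can be swapped in.
#'
#' @return Named character vector of length 64.
#' @export
codon_table <- function() {
  if (is.null(.pkg_cache$code)) {
    cod <- all_codons()
    aa <- vapply(cod, function(x) {
      seqinr::translate(strsplit(x, "")[[1]], numcode = 1)
    }, character(1))
    .pkg_cache$code <- setNames(aa, cod)
  }
  .pkg_cache$code
}

is_stop_codon <- function(codon) unname(codon_table()[codon] == "*")

translate_codons <- function(codons) unname(codon_table()[codons])

## Synonymous / nonsynonymous site counts of one codon: at each position the 3
## alternative bases are classified; changes creating a stop codon are excluded
## from the denominator. Each position contributes one site in total.
codon_site_counts <- function(codon) {
  code <- codon_table()
  aa <- code[[codon]]
  nt <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(DNA_BASES, nt[pos])) {
      alt <- nt; alt[pos] <- b
      alt_aa <- code[[paste0(alt, collapse = "")]]
      if (alt_aa == "*") next
      valid <- valid + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(syn = s, nonsyn = 3 - s)
}

.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## Pathway-averaged synonymous/nonsynonymous difference counts between two
## codons: minimal single-nucleotide pathways are enumerated, pathways passing
## through a stop codon are excluded, and counts are averaged over the
## remaining pathways. If every pathway is blocked by a stop, all pathways are
## used (degenerate case, vanishingly rare in-frame).
codon_diff_counts <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  code <- codon_table()
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(n1 != n2)
  walk <- function(order, allow_stop) {
    cur <- n1
    sy <- 0; ns <- 0
    for (p in order) {
      aa_from <- code[[paste0(cur, collapse = "")]]
      cur[p] <- n2[p]
      codon_to <- paste0(cur, collapse = "")
      aa_to <- code[[codon_to]]
      if (aa_to == "*" && !allow_stop && codon_to != c2) return(NULL)
      if (aa_from == aa_to) sy <- sy + 1 else ns <- ns + 1
    }
    c(sy, ns)
  }
  paths <- lapply(.perms[[as.character(length(diff_pos))]], function(ord) {
    walk(diff_pos[ord], allow_stop = FALSE)
  })
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0L) {
    paths <- lapply(.perms[[as.character(length(diff_pos))]], function(ord) {
      walk(diff_pos[ord], allow_stop = TRUE)
    })
  }
  m <- do.call(rbind, paths)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

## 64 x 64 cached matrices of pathway-averaged difference counts, indexed by
## codon string. Used by the vectorised dN/dS and site-scan code.
codon_pair_matrices <- function() {
  if (is.null(.pkg_cache$pairmats)) {
    cod <- all_codons()
    n <- length(cod)
    S <- matrix(0, n, n, dimnames = list(cod, cod))
    N <- matrix(0, n, n, dimnames = list(cod, cod))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- codon_diff_counts(cod[i], cod[j])
        S[i, j] <- d[["syn"]]; N[i, j] <- d[["nonsyn"]]
      }
    }
    sites <- t(vapply(cod, codon_site_counts, numeric(2)))
    .pkg_cache$pairmats <- list(S = S, N = N, sites = sites)
  }
  .pkg_cache$pairmats
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0)
    abort("sequence length ", nchar(seq), " is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}
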