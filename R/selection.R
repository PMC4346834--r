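## Counting-based selection analysis: pairwise dN/dS by the Nei-Gojobori
## (1986) counting method with Jukes-Cantor correction, and a per-site
## positive-selection scan over a codon alignment with an explicit binomial
## null. The scan is a counting surrogate for likelihood site models: per
## column, pathway-averaged nonsynonymous and synonymous pairwise differences
## are tallied over all sequence pairs, de-correlated to per-lineage effective
## counts, and tested against the alignment-wide nonsynonymous fraction.

validate_cds <- function(x, label = "sequence") {
  cod <- if (length(x) > 1) x else split_codons(x)
  stops <- which(!grepl("-", cod, fixed = TRUE) & is_stop_codon(cod))
  internal <- stops[stops < length(cod)]
  if (length(internal))
    abort("internal stop codon at codon ", internal[1], " in ", label)
  if (length(stops) && stops[length(stops)] == length(cod)) cod <- cod[-length(cod)]
  cod
}

#' Pairwise dN/dS by the Nei-Gojobori counting method
#'
#' Synonymous and nonsynonymous sites are counted per codon (changes creating
#' stop codons excluded) and averaged over the two sequences; differences per
#' codon pair are averaged over all minimal substitution pathways, excluding
#' pathways through stop codons. Proportions are Jukes-Cantor corrected,
#' `d = -(3/4) ln(1 - 4p/3)`; `p >= 3/4` leaves the corrected distance
#' undefined (flagged). Codons containing gaps are excluded pairwise.
#'
#' @param cds_a,cds_b in-frame CDS strings of equal length (terminal stop
#'   allowed and trimmed; internal stops are an error).
#' @return A `selection_result` list: `dN`, `dS`, `omega`, `pN`, `pS`,
#'   `N`, `S` (site counts), `Nd`, `Sd` (difference counts), `saturated`
#'   flags.
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  ca <- validate_cds(cds_a, "cds_a")
  cb <- validate_cds(cds_b, "cds_b")
  if (length(ca) != length(cb))
    abort("sequences differ in length (", length(ca), " vs ", length(cb), " codons)")
  use <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[use]; cb <- cb[use]
  pm <- codon_pair_matrices()
  sites_a <- pm$sites[ca, , drop = FALSE]
  sites_b <- pm$sites[cb, , drop = FALSE]
  S <- (sum(sites_a[, "syn"]) + sum(sites_b[, "syn"])) / 2
  N <- (sum(sites_a[, "nonsyn"]) + sum(sites_b[, "nonsyn"])) / 2
  Sd <- sum(pm$S[cbind(ca, cb)])
  Nd <- sum(pm$N[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
                 N = N, S = S, Nd = Nd, Sd = Sd,
                 saturated = c(dN = is.na(dN) && pN >= 0.75,
                               dS = is.na(dS) && pS >= 0.75)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (!is.null(x$dN))
    cat(sprintf("dN = %.4f, dS = %.4f, omega = %s\n", x$dN, x$dS,
                ifelse(is.na(x$omega), "undefined", sprintf("%.3f", x$omega))))
  if (!is.null(x$sites))
    cat(sum(x$sites$selected), "of", nrow(x$sites), "sites called selected\n")
  invisible(x)
}

#' Per-site positive-selection scan of a codon alignment
#'
#' Per column, nonsynonymous and synonymous differences are tallied over all
#' sequence pairs (pathway-averaged) and divided by `n_seq - 1` to undo the
#' pseudo-replication of pairwise counting (each substitution event on one
#' lineage is seen by roughly `n_seq - 1` pairs; this divisor leaves null
#' p-values calibrated). The site statistic is the observed nonsynonymous
#' fraction; the p-value is a one-sided mid-p binomial probability of the
#' effective nonsynonymous count against the alignment-wide expected
#' nonsynonymous fraction, estimated robustly by excluding the upper
#' `trim` share of sites by nonsynonymous fraction so that genuinely
#' selected sites do not contaminate their own null. P-values are
#' Benjamini-Hochberg corrected; a site is selected iff `q < alpha` and its
#' nonsynonymous excess is positive. All-gap columns are skipped with a note.
#'
#' @param aln a `codon_alignment` (see [simulate_codon_alignment()]) or a
#'   character matrix of codon strings (sequences x sites).
#' @param alpha site-level FDR threshold (default 0.05).
#' @param trim share of top-fraction sites excluded from the background
#'   estimate (default 0.1).
#' @return A `selection_result` with data frame `sites`: `site`, `nonsyn`,
#'   `syn`, `fraction`, `p`, `q`, `selected`; attribute `skipped_sites`.
#' @export
site_selection_scan <- function(aln, alpha = 0.05, trim = 0.1) {
  m <- if (inherits(aln, "codon_alignment")) aln$codons else aln
  stopifnot(is.matrix(m))
  if (nrow(m) < 4) abort("need >= 4 sequences")
  pm <- codon_pair_matrices()
  n_seq <- nrow(m)
  pairs <- combn(n_seq, 2)
  ns <- numeric(ncol(m)); sy <- numeric(ncol(m)); skipped <- integer()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ok <- !grepl("-", col, fixed = TRUE)
    if (sum(ok) < 2) { skipped <- c(skipped, j); ns[j] <- NA; sy[j] <- NA; next }
    col <- col[ok]
    pr <- if (length(col) == n_seq) pairs else combn(length(col), 2)
    ci <- col[pr[1, ]]; cj <- col[pr[2, ]]
    ns[j] <- sum(pm$N[cbind(ci, cj)])
    sy[j] <- sum(pm$S[cbind(ci, cj)])
  }
  eff_ns <- ns / (n_seq - 1)
  eff_sy <- sy / (n_seq - 1)
  frac <- ifelse(!is.na(ns) & ns + sy > 0, ns / (ns + sy), NA)
  ## robust alignment-wide background, upper tail trimmed
  usable <- which(!is.na(frac))
  drop <- usable[order(frac[usable], decreasing = TRUE)]
  drop <- drop[seq_len(min(length(drop), ceiling(trim * ncol(m))))]
  pool <- setdiff(usable, drop)
  tot_ns <- sum(ns[pool]); tot_sy <- sum(sy[pool])
  p0 <- if (tot_ns + tot_sy > 0) tot_ns / (tot_ns + tot_sy) else 0.5
  k <- round(eff_ns)
  size <- round(eff_ns + eff_sy)
  p <- rep(NA_real_, ncol(m))
  for (j in seq_len(ncol(m))) {
    if (j %in% skipped) next
    p[j] <- if (size[j] == 0) 1 else
      max(0, pbinom(k[j] - 1, size[j], p0, lower.tail = FALSE) -
            0.5 * dbinom(k[j], size[j], p0))
  }
  q <- rep(NA_real_, ncol(m))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  selected <- !is.na(q) & q < alpha & !is.na(frac) & frac > p0
  sites <- data.frame(site = seq_len(ncol(m)), nonsyn = ns, syn = sy,
                      fraction = frac, p = p, q = q, selected = selected)
  structure(list(sites = sites, expected_fraction = p0, alpha = alpha,
                 skipped_sites = skipped),
            class = "selection_result")
}
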