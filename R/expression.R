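## Expression quantification and differential-expression machinery for
## replicate-free pooled libraries: RPKM, an exact conditional-binomial test
## for equality of Poisson rates between two single-library conditions,
## joint p/fold-change DE calling against every control, time-course response
## classes, a tau specificity index, challenge-specific (Venn) sets,
## biotic/abiotic stress categories and hypergeometric domain enrichment.

#' Construct an expression matrix object
#'
#' @param counts integer matrix, genes x conditions.
#' @param design data frame with `condition`, `axis`, `time_h`, `control`
#'   rows matching the columns of `counts`.
#' @param lib_sizes named numeric vector of mapped reads per condition.
#' @param gene_length named numeric vector of gene lengths in bp.
#' @return An `expression_matrix` list with an `rpkm` matrix attached.
#' @export
expression_matrix <- function(counts, design, lib_sizes, gene_length) {
  stopifnot(is.matrix(counts))
  if (!identical(colnames(counts), design$condition))
    abort("count columns must match design$condition in order")
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  if (any(gene_length <= 0)) abort("gene lengths must be positive")
  if (any(counts < 0)) abort("negative count")
  lib_sizes <- lib_sizes[design$condition]
  gene_length <- gene_length[rownames(counts)]
  if (anyNA(lib_sizes) || anyNA(gene_length))
    abort("lib_sizes/gene_length must cover all conditions/genes")
  rpkm_mat <- counts * 1e9 / outer(gene_length, lib_sizes)
  structure(list(counts = counts, design = design, lib_sizes = lib_sizes,
                 gene_length = gene_length, rpkm = rpkm_mat),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "conditions (", paste(unique(x$design$axis), collapse = "/"), ")\n")
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (gene_length_bp * library_size)`. Vectorised; matrix
#' input is handled elementwise with recycling over rows.
#'
#' @param count raw read count (scalar, vector or matrix).
#' @param gene_length_bp gene length in bp (>0).
#' @param library_size mapped reads in the library (>0).
#' @return RPKM values with the shape of `count`.
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(count < 0)) abort("negative count")
  if (any(gene_length_bp <= 0) || any(library_size <= 0))
    abort("gene length and library size must be positive")
  if (is.matrix(count)) {
    count * 1e9 / outer(as.numeric(gene_length_bp), as.numeric(library_size))
  } else {
    count * 1e9 / (gene_length_bp * library_size)
  }
}

#' Row-wise max normalisation
#'
#' Divides each gene row by its maximum; all-zero rows are left at zero, so
#' output is in `[0, 1]` with every nonzero row peaking at exactly 1.
#'
#' @param m numeric matrix (genes x conditions).
#' @return Matrix of the same shape.
#' @export
max_normalize <- function(m) {
  mx <- apply(m, 1, max)
  mx[mx == 0] <- 1
  sweep(m, 1, mx, "/")
}

#' Exact test for equal Poisson rates between two single libraries
#'
#' Conditional on the total `n = a + b`, `a` is Binomial(n, la/(la+lb)) under
#' the null of equal per-read rates; the two-sided p-value doubles the smaller
#' tail and is capped at 1. `a = b = 0` gives p = 1. Vectorised over `a`, `b`.
#'
#' @param a,b counts in the two conditions.
#' @param lib_a,lib_b library sizes (mapped reads).
#' @return Two-sided p-values in `[0, 1]`.
#' @export
de_exact_test <- function(a, b, lib_a = 1, lib_b = 1) {
  if (any(a < 0) || any(b < 0)) abort("counts must be nonnegative")
  if (any(lib_a <= 0) || any(lib_b <= 0)) abort("library sizes must be positive")
  n <- a + b
  p0 <- lib_a / (lib_a + lib_b)
  lower <- pbinom(a, n, p0)
  upper <- pbinom(a - 1, n, p0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- 1
  p
}

#' Call differential expression against every control
#'
#' A gene is `up` (resp. `down`) for a treatment iff, versus EVERY control
#' condition in `controls`, the exact test p-value is below `p_threshold` AND
#' the RPKM fold-change (with a pseudo-RPKM floor `eps`) is at least
#' `fc_threshold` in the same direction. Everything else is `ns`.
#'
#' @param em an [expression_matrix()].
#' @param treatment treatment condition name.
#' @param controls character vector of control condition names (non-empty).
#' @param p_threshold p-value threshold (default 0.001).
#' @param fc_threshold fold-change threshold (default 2).
#' @param eps pseudo-RPKM floor for fold-changes (default 0.1).
#' @return Data frame: `gene_id`, `treatment`, `p` (max over controls),
#'   `log2fc` (smallest-magnitude over controls), `direction`.
#' @export
call_de <- function(em, treatment, controls, p_threshold = 0.001,
                    fc_threshold = 2, eps = 0.1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(controls) == 0) abort("empty control set")
  missing <- setdiff(c(treatment, controls), colnames(em$counts))
  if (length(missing)) abort("unknown condition(s): ", paste(missing, collapse = ", "))
  a <- em$counts[, treatment]
  la <- em$lib_sizes[[treatment]]
  rp_t <- pmax(em$rpkm[, treatment], eps)
  pmax_ctrl <- rep(0, nrow(em$counts))
  lfc_mat <- matrix(NA_real_, nrow(em$counts), length(controls))
  p_mat <- matrix(NA_real_, nrow(em$counts), length(controls))
  for (i in seq_along(controls)) {
    ctl <- controls[i]
    p_mat[, i] <- de_exact_test(a, em$counts[, ctl], la, em$lib_sizes[[ctl]])
    lfc_mat[, i] <- log2(rp_t / pmax(em$rpkm[, ctl], eps))
  }
  lthr <- log2(fc_threshold)
  up <- apply(p_mat < p_threshold & lfc_mat >= lthr, 1, all)
  down <- apply(p_mat < p_threshold & lfc_mat <= -lthr, 1, all)
  direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  ## report the most conservative evidence across controls
  p_rep <- apply(p_mat, 1, max)
  lfc_rep <- lfc_mat[cbind(seq_len(nrow(lfc_mat)),
                           apply(abs(lfc_mat), 1, which.min))]
  data.frame(gene_id = rownames(em$counts), treatment = treatment,
             p = p_rep, log2fc = lfc_rep, direction = direction,
             stringsAsFactors = FALSE)
}

#' Classify time-course response patterns
#'
#' Given DE calls versus time 0 at 6, 12, 24 and 48 h: `early` = up in the
#' early window (6/12 h) only; `late` = up in the late window (24/48 h) only;
#' `early_and_late` = up in both; `down` = at least one down call and no up
#' call; `flat` otherwise.
#'
#' @param calls data frame with columns `gene_id`, `time_h`, `direction`
#'   covering times 6, 12, 24, 48 for every gene.
#' @return Data frame `gene_id`, `class`.
#' @export
response_classify <- function(calls) {
  need <- c(6, 12, 24, 48)
  for (g in unique(calls$gene_id)) {
    miss <- setdiff(need, calls$time_h[calls$gene_id == g])
    if (length(miss)) abort("missing time point ", miss[1], " for gene ", g)
  }
  one <- function(df) {
    early_up <- any(df$direction == "up" & df$time_h %in% c(6, 12))
    late_up <- any(df$direction == "up" & df$time_h %in% c(24, 48))
    any_down <- any(df$direction == "down")
    if (early_up && late_up) "early_and_late"
    else if (early_up) "early"
    else if (late_up) "late"
    else if (any_down) "down"
    else "flat"
  }
  res <- vapply(split(calls, calls$gene_id), one, character(1))
  data.frame(gene_id = names(res), class = unname(res), stringsAsFactors = FALSE)
}

#' Tau specificity index over one axis
#'
#' `tau = sum(1 - x_i/x_max) / (n - 1)` on the max-normalised profile; a gene
#' is called specific iff `tau >= tau_threshold` and its peak expression is at
#' least `min_peak` (RPKM units). All-zero profiles have undefined tau and are
#' never specific.
#'
#' @param x numeric RPKM profile over >= 3 conditions of one axis.
#' @param tau_threshold specificity cutoff (default 0.90).
#' @param min_peak minimum peak RPKM (default 1).
#' @return List: `tau`, `specific`, `peak` (condition name or index).
#' @export
specificity_index <- function(x, tau_threshold = 0.90, min_peak = 1) {
  if (length(x) < 3) abort("specificity index needs >= 3 conditions")
  if (all(x == 0)) {
    return(list(tau = NA_real_, specific = FALSE, peak = NA))
  }
  mx <- max(x)
  tau <- sum(1 - x / mx) / (length(x) - 1)
  peak <- if (!is.null(names(x))) names(x)[which.max(x)] else which.max(x)
  list(tau = tau, specific = tau >= tau_threshold && mx >= min_peak, peak = peak)
}

#' Challenge-specific sets and full Venn partition
#'
#' For each challenge, the genes DE in it and in no other; plus every
#' intersection cell (cells are named by the `&`-joined member sets and form
#' a partition of the union).
#'
#' @param sets named list (>= 2) of character vectors of DE gene ids.
#' @return List: `specific` (named list) and `cells` (named list).
#' @export
condition_specific_sets <- function(sets) {
  if (length(sets) < 2) abort("need at least 2 challenge sets")
  nm <- names(sets)
  specific <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unique(unlist(sets[-i])))
  })
  names(specific) <- nm
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  key <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  cells <- split(universe, key)
  list(specific = specific, cells = cells)
}

#' Biotic/abiotic stress category
#'
#' @param biotic,abiotic logical vectors: DE under any biotic (resp. abiotic)
#'   challenge.
#' @return Character vector over
#'   `{biotic_only, abiotic_only, both, neither}`.
#' @export
stress_category <- function(biotic, abiotic) {
  ifelse(biotic & abiotic, "both",
         ifelse(biotic, "biotic_only",
                ifelse(abiotic, "abiotic_only", "neither")))
}

#' Hypergeometric domain enrichment of an up-regulated set
#'
#' Per domain, the upper-tail hypergeometric probability `P(X >= k)` of
#' drawing `k` carriers in a sample of `n = |up_set|` from `N = |background|`
#' genes of which `K` carry the domain. Benjamini-Hochberg q-values and
#' `-log2(p)` are attached. Domains absent from the background are skipped
#' with a warning.
#'
#' @param up_set character vector, subset of `background`.
#' @param background character vector of background gene ids.
#' @param domain_map data frame with columns `gene_id`, `domain`.
#' @return Data frame: `domain`, `k`, `K`, `n`, `N`, `p`, `q`, `neg_log2_p`.
#' @export
domain_enrichment <- function(up_set, background, domain_map) {
  if (!all(up_set %in% background)) abort("up_set must be a subset of background")
  dm <- domain_map[domain_map$gene_id %in% background, , drop = FALSE]
  skipped <- setdiff(unique(domain_map$domain), unique(dm$domain))
  if (length(skipped))
    warning("domain(s) absent from background skipped: ",
            paste(skipped, collapse = ", "))
  N <- length(unique(background))
  n <- length(unique(up_set))
  doms <- sort(unique(dm$domain))
  res <- lapply(doms, function(d) {
    carriers <- unique(dm$gene_id[dm$domain == d])
    K <- length(carriers)
    k <- length(intersect(up_set, carriers))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(domain = d, k = k, K = K, n = n, N = N, p = p)
  })
  out <- rbind_dfs(res)
  out$q <- p.adjust(out$p, method = "BH")
  out$neg_log2_p <- -log2(out$p)
  out
}
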