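## Phylostratigraphic age assignment: each gene's age is the most ancient
## (minimum) taxonomic level, over ten ranked strata from cellular organisms
## (1) to the focal bivalve lineage (10), at which it has a qualifying
## homology hit (E-value at or below the cutoff). Genes without qualifying
## hits outside the focal lineage are lineage-specific (age 10).

#' Names of the ten phylostratum levels
#' @return Character vector of length 10.
#' @export
phylostratum_names <- function() {
  c("cellular organisms", "Eukaryota", "Opisthokonta", "Metazoa", "Eumetazoa",
    "Bilateria", "Protostomia", "Lophotrochozoa", "Mollusca", "Bivalvia")
}

#' Assign phylostratigraphic ages from homology hits
#'
#' A qualifying hit has `evalue <= evalue_cutoff`; a gene's age is the
#' minimum level among its qualifying hits, or 10 (lineage-specific) if it
#' has none at levels 1-9. Genes with no hits at all are flagged `no_hit`.
#' Hits whose subject id starts with `focal_prefix` are excluded
#' (self-hits).
#'
#' @param hits data frame with `query`, `subject`, `evalue`, `level` (as from
#'   [parse_hit_table()] or the simulator).
#' @param gene_ids gene ids to assign (genes absent from `hits` get age 10,
#'   flagged).
#' @param evalue_cutoff qualifying E-value cutoff (default 1e-3).
#' @param focal_prefix optional subject-id prefix identifying the focal
#'   species, excluded before assignment.
#' @return Data frame: `gene_id`, `age`, `n_hits`, `n_qualifying`, `no_hit`;
#'   attribute `level_counts` (genes x 10 matrix of qualifying hits per
#'   level).
#' @export
assign_age <- function(hits, gene_ids, evalue_cutoff = 1e-3,
                       focal_prefix = NULL) {
  if (!is.null(focal_prefix))
    hits <- hits[!startsWith(hits$subject, focal_prefix), , drop = FALSE]
  qual <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  min_lvl <- tapply(qual$level, qual$query, min)
  n_hits <- table(hits$query)
  n_qual <- table(qual$query)
  age <- as.integer(min_lvl[gene_ids])
  age[is.na(age)] <- 10L
  lc <- matrix(0L, length(gene_ids), 10,
               dimnames = list(gene_ids, as.character(1:10)))
  if (nrow(qual)) {
    tb <- table(factor(qual$query, levels = gene_ids),
                factor(qual$level, levels = 1:10))
    lc[] <- as.integer(tb)
  }
  out <- data.frame(
    gene_id = gene_ids,
    age = age,
    n_hits = as.integer(ifelse(is.na(n_hits[gene_ids]), 0L, n_hits[gene_ids])),
    n_qualifying = as.integer(ifelse(is.na(n_qual[gene_ids]), 0L, n_qual[gene_ids])),
    stringsAsFactors = FALSE)
  out$no_hit <- out$n_hits == 0L
  attr(out, "level_counts") <- lc
  out
}

#' Compare phylostratum age distributions of two gene sets
#'
#' Per-level frequency vectors (levels 1..10, each summing to 1) and a
#' two-sided Mann-Whitney U test with tie correction. The direction is the
#' sign of the median age difference `a - b`: negative means set A is older
#' (more ancient strata).
#'
#' @param ages_a,ages_b integer age vectors (1..10), both non-empty.
#' @return List: `freq_a`, `freq_b`, `U`, `p.value`, `direction`.
#' @export
compare_age_distributions <- function(ages_a, ages_b) {
  if (length(ages_a) == 0 || length(ages_b) == 0)
    abort("both age sets must be non-empty")
  freq <- function(x) {
    f <- table(factor(x, levels = 1:10))
    as.numeric(f) / length(x)
  }
  ## normal approximation with tie-corrected variance; no continuity
  ## correction so that identical samples give p = 1 exactly
  wt <- suppressWarnings(stats::wilcox.test(ages_a, ages_b, exact = FALSE,
                                            correct = FALSE))
  list(freq_a = freq(ages_a), freq_b = freq(ages_b),
       U = unname(wt$statistic), p.value = wt$p.value,
       direction = sign(median(ages_a) - median(ages_b)))
}
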