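## Rule-based subtype classification from ordered domain architectures, and
## the two-species family-expansion chi-square test.
##
## TLR subtypes follow the five-group scheme used for bivalve TLR repertoires:
## V (vertebrate-type long ectodomain), P (protostome-like double ectodomain,
## long), sPP (double ectodomain, short), sP (short, capless) and Ls
## (LRRCT-only ectodomain). The literature separates long from short
## ectodomains phylogenetically without stating a numeric LRR cutoff; the
## explicit operationalisation here uses `lrr_long_threshold = 8` LRR units,
## configurable.

TLR_SUBTYPES <- c("V", "P", "sP", "sPP", "Ls")

#' Classify a domain architecture into a family subtype
#'
#' Rules are applied in a fixed order and the first match wins, so every valid
#' architecture fires exactly one rule.
#'
#' TLR (architecture must contain TIR to be classifiable):
#' 1. no TIR -> `unclassified`;
#' 2. ectodomain has LRRCT but no LRR and no LRRNT -> `Ls`;
#' 3. an internal LRRCT (>= 1 LRR on both sides) immediately followed by
#'    LRRNT -> `P` if LRR count >= `lrr_long_threshold`, else `sPP`;
#' 4. no LRRNT, no internal LRRCT, LRR count below threshold -> `sP`;
#' 5. N-terminal LRRNT, a single C-terminal LRRCT, LRR count at or above the
#'    threshold -> `V`.
#'
#' MyD88: DEATH+TIR -> `death_tir`; TIR only -> `tir_only`.
#' C1qDC: C1Q+COLLAGEN -> `c1q_collagen`; C1Q only -> `c1q_only`.
#'
#' @param tokens character vector of ordered domain tokens (N to C), or a
#'   single comma-joined string.
#' @param family one of `"TLR"`, `"MyD88"`, `"C1qDC"`.
#' @param frameshift pseudogene flag, passed through.
#' @param lrr_long_threshold LRR count separating short from long ectodomains.
#' @return List: `family`, `subtype`, `pseudogene`, `rule` (fired rule id).
#' @export
classify_family_subtype <- function(tokens, family, frameshift = FALSE,
                                    lrr_long_threshold = 8) {
  if (length(tokens) == 1 && grepl(",", tokens))
    tokens <- strsplit(tokens, ",", fixed = TRUE)[[1]]
  res <- switch(family,
    TLR = classify_tlr(tokens, lrr_long_threshold),
    MyD88 = {
      if (all(c("DEATH", "TIR") %in% tokens)) list(subtype = "death_tir", rule = "myd88_death_tir")
      else if ("TIR" %in% tokens) list(subtype = "tir_only", rule = "myd88_tir_only")
      else list(subtype = "unclassified", rule = character())
    },
    C1qDC = {
      if (all(c("C1Q", "COLLAGEN") %in% tokens)) list(subtype = "c1q_collagen", rule = "c1q_collagen")
      else if ("C1Q" %in% tokens) list(subtype = "c1q_only", rule = "c1q_only")
      else list(subtype = "unclassified", rule = character())
    },
    abort("unknown family: ", family)
  )
  list(family = family, subtype = res$subtype, pseudogene = isTRUE(frameshift),
       rule = res$rule)
}

classify_tlr <- function(tokens, thr) {
  if (!("TIR" %in% tokens)) return(list(subtype = "unclassified", rule = "tlr_no_tir"))
  ## ectodomain: tokens before the TM (or before TIR if no TM annotated)
  cut <- if ("TM" %in% tokens) match("TM", tokens) else match("TIR", tokens)
  ecto <- tokens[seq_len(cut - 1)]
  n_lrr <- sum(ecto == "LRR")
  has_ct <- "LRRCT" %in% ecto
  has_nt <- "LRRNT" %in% ecto
  if (has_ct && n_lrr == 0 && !has_nt)
    return(list(subtype = "Ls", rule = "tlr_ls"))
  ## internal LRRCT: at least one LRR on each side within the ectodomain
  ct_pos <- which(ecto == "LRRCT")
  internal <- ct_pos[vapply(ct_pos, function(i) {
    any(ecto[seq_len(i - 1)] == "LRR") && any(ecto[-seq_len(i)] == "LRR")
  }, logical(1))]
  int_followed <- any(vapply(internal, function(i) {
    i < length(ecto) && ecto[i + 1] == "LRRNT"
  }, logical(1)))
  if (int_followed) {
    return(if (n_lrr >= thr) list(subtype = "P", rule = "tlr_p")
           else list(subtype = "sPP", rule = "tlr_spp"))
  }
  if (!has_nt && length(internal) == 0 && n_lrr < thr)
    return(list(subtype = "sP", rule = "tlr_sp"))
  first_ecto <- setdiff(ecto, "SP")[1]
  single_ct_last <- sum(ecto == "LRRCT") == 1 && ecto[length(ecto)] == "LRRCT"
  if (identical(first_ecto, "LRRNT") && single_ct_last && n_lrr >= thr)
    return(list(subtype = "V", rule = "tlr_v"))
  list(subtype = "unclassified", rule = "tlr_fallthrough")
}

#' Classify every gene of a domain table
#'
#' @param domains data frame with `gene_id`, `family`, `tokens`
#'   (comma-joined), `frameshift`.
#' @param lrr_long_threshold see [classify_family_subtype()].
#' @return Data frame `gene_id`, `family`, `subtype`, `pseudogene`, `rule`;
#'   genes of families without rules get subtype `NA`.
#' @export
classify_catalog <- function(domains, lrr_long_threshold = 8) {
  known <- c("TLR", "MyD88", "C1qDC")
  res <- lapply(seq_len(nrow(domains)), function(i) {
    fam <- domains$family[i]
    if (is.na(fam) || !(fam %in% known)) {
      return(data.frame(gene_id = domains$gene_id[i], family = fam,
                        subtype = NA_character_, pseudogene = domains$frameshift[i],
                        rule = NA_character_, stringsAsFactors = FALSE))
    }
    cl <- classify_family_subtype(domains$tokens[i], fam,
                                  domains$frameshift[i], lrr_long_threshold)
    data.frame(gene_id = domains$gene_id[i], family = fam, subtype = cl$subtype,
               pseudogene = cl$pseudogene,
               rule = if (length(cl$rule)) cl$rule else NA_character_,
               stringsAsFactors = FALSE)
  })
  rbind_dfs(res)
}

#' Two-species family-expansion chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the 2x2
#' table of family versus non-family gene counts in two genomes. The
#' statistic is symmetric in the two species; the direction of the difference
#' is reported separately.
#'
#' @param count_a,total_a family size and genome gene count in species A.
#' @param count_b,total_b same for species B.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return List: `statistic`, `p.value`, `expected`, `direction` (sign of the
#'   proportion difference A - B), `low_expected` (`TRUE` if any expected
#'   cell < 1, with a warning).
#' @export
family_expansion_test <- function(count_a, total_a, count_b, total_b,
                                  correct = FALSE) {
  if (count_a > total_a || count_b > total_b)
    abort("family counts cannot exceed genome totals")
  if (total_a <= 0 || total_b <= 0) abort("genome totals must be positive")
  tab <- matrix(c(count_a, total_a - count_a, count_b, total_b - count_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("family", "other")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- any(expected < 1)
  if (low) warning("expected cell below 1; chi-square approximation is poor")
  if (sum(tab[, "family"]) == 0 || sum(tab[, "other"]) == 0) {
    ## a zero margin: the table carries no information
    stat <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  list(statistic = stat, p.value = p, expected = expected,
       direction = sign(count_a / total_a - count_b / total_b),
       low_expected = low)
}
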