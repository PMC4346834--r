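## Catalog assembly and filtering: merging of evidence sets with provenance,
## the read-depth filter against haplotype-inflated allelic duplicates (whole
## genome coverage ~105x; genes under 80x are removed), the strict RPKM > 1
## functionality flag, and optional manual overrides applied last.

#' Merge gene catalogs from multiple evidence sets
#'
#' Catalogs are united by `gene_id`; provenance is the union of source tags.
#' Conflicting family labels are resolved by a configurable priority order of
#' evidence sets and recorded (attribute `family_conflicts`). Conflicting
#' coordinates for one gene id are an error.
#'
#' @param catalogs named list of [gene_catalog()]s; names are evidence-set
#'   tags (e.g. `interproscan_set`).
#' @param priority evidence-set priority order for family-label conflicts,
#'   highest first.
#' @return A merged [gene_catalog()] with attribute `family_conflicts`.
#' @export
merge_evidence <- function(catalogs,
                           priority = c("manual", "interproscan_set",
                                        "homology_set", "nr_set", "tblastn_set")) {
  stopifnot(length(catalogs) >= 1, !is.null(names(catalogs)))
  merged <- list()
  fam_source <- character()
  conflicts <- list()
  for (tag in names(catalogs)) {
    cat_i <- catalogs[[tag]]
    for (r in seq_len(nrow(cat_i))) {
      row <- cat_i[r, , drop = FALSE]
      id <- row$gene_id
      if (is.null(merged[[id]])) {
        row$provenance <- tag
        merged[[id]] <- row
        fam_source[id] <- tag
      } else {
        prev <- merged[[id]]
        if (prev$scaffold != row$scaffold || prev$start != row$start ||
            prev$end != row$end) {
          abort("conflicting coordinates for ", id, ": ",
                prev$scaffold, ":", prev$start, "-", prev$end, " vs ",
                row$scaffold, ":", row$start, "-", row$end)
        }
        prev$provenance <- paste(sort(unique(c(
          strsplit(prev$provenance, ",")[[1]], tag))), collapse = ",")
        if (!is.na(row$family)) {
          if (is.na(prev$family)) {
            prev$family <- row$family
            fam_source[id] <- tag
          } else if (!identical(prev$family, row$family)) {
            keep_prev <- match(fam_source[id], priority) <= match(tag, priority)
            conflicts[[length(conflicts) + 1L]] <- data.frame(
              gene_id = id, kept = if (keep_prev) prev$family else row$family,
              dropped = if (keep_prev) row$family else prev$family,
              stringsAsFactors = FALSE)
            if (!keep_prev) {
              prev$family <- row$family
              fam_source[id] <- tag
            }
          }
        }
        merged[[id]] <- prev
      }
    }
  }
  out <- gene_catalog(do.call(rbind, c(unname(merged), list(make.row.names = FALSE))))
  attr(out, "family_conflicts") <- rbind_dfs(conflicts)
  out
}

#' Remove genes below a read-depth threshold
#'
#' Genes whose average shotgun coverage is strictly below `threshold` are
#' removed — the guard against counting both haplotypes of one locus as two
#' genes. Exactly-threshold genes are kept. Idempotent.
#'
#' @param catalog a [gene_catalog()].
#' @param depths data frame `gene_id`, `depth` covering the catalog.
#' @param threshold fold-coverage cutoff (default 80).
#' @param exempt gene ids allowed to lack a depth entry.
#' @return List: `catalog` (filtered) and `report` (a `filter_report`:
#'   `n_input`, `n_removed_depth`, `removed_ids`).
#' @export
depth_filter <- function(catalog, depths, threshold = 80, exempt = character()) {
  d <- depths$depth[match(catalog$gene_id, depths$gene_id)]
  missing <- catalog$gene_id[is.na(d) & !(catalog$gene_id %in% exempt)]
  if (length(missing))
    abort("missing depth for gene ", missing[1],
          " (flag it exempt or supply a depth)")
  remove <- !is.na(d) & d < threshold
  report <- structure(list(n_input = nrow(catalog),
                           n_removed_depth = sum(remove),
                           removed_ids = catalog$gene_id[remove],
                           threshold = threshold),
                      class = "filter_report")
  out <- catalog[!remove, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(catalog)
  list(catalog = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("depth filter (<", x$threshold, "x): ", x$n_removed_depth, " of ",
      x$n_input, " genes removed\n", sep = "")
  invisible(x)
}

#' Flag functional genes by peak expression
#'
#' A gene is presumed functional iff its maximum RPKM over all conditions is
#' strictly greater than `threshold` (default 1). Flags only; nothing is
#' removed.
#'
#' @param em an [expression_matrix()].
#' @param catalog optional [gene_catalog()]; every catalog gene must be in the
#'   matrix.
#' @param threshold RPKM cutoff (default 1, strict).
#' @return Data frame: `gene_id`, `max_rpkm`, `functional`.
#' @export
functional_filter <- function(em, catalog = NULL, threshold = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  rp <- em$rpkm
  if (!is.null(catalog)) {
    missing <- setdiff(catalog$gene_id, rownames(rp))
    if (length(missing))
      abort("gene absent from expression matrix: ", missing[1])
    rp <- rp[catalog$gene_id, , drop = FALSE]
  }
  mx <- apply(rp, 1, max)
  data.frame(gene_id = rownames(rp), max_rpkm = mx,
             functional = mx > threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Apply manual overrides to a catalog
#'
#' The manual-correction stage: a table of `gene_id`, `action`
#' (`keep`/`drop`/`family`) and optional `family`, applied after all
#' automatic filtering.
#'
#' @param catalog a [gene_catalog()].
#' @param overrides data frame `gene_id`, `action`, optional `family`.
#' @return The corrected catalog.
#' @export
apply_overrides <- function(catalog, overrides) {
  for (r in seq_len(nrow(overrides))) {
    id <- overrides$gene_id[r]
    act <- overrides$action[r]
    i <- match(id, catalog$gene_id)
    if (act == "drop") {
      if (!is.na(i)) catalog <- catalog[-i, , drop = FALSE]
    } else if (act == "family") {
      if (is.na(i)) abort("override names unknown gene ", id)
      catalog$family[i] <- overrides$family[r]
    } else if (act != "keep") {
      abort("unknown override action: ", act)
    }
  }
  rownames(catalog) <- NULL
  catalog
}
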