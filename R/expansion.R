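## Tandem-array detection on scaffolds, neighbor-joining phylogenetics with
## bootstrap supports, and lineage-specific-expansion (single-taxon clade)
## detection. Trees are ape "phylo" objects throughout; the NJ agglomeration
## itself is implemented here because the workflow pins down tie-breaking
## (lowest index pair) and negative-branch handling (clamp to zero, deficit
## moved to the sister branch) for cross-platform reproducibility.

#' Detect tandem arrays of a gene family on scaffolds
#'
#' Two same-family genes are linked iff they lie on the same scaffold with at
#' most `max_intervening` non-family gene models between them and a
#' start-to-start distance of at most `max_gap_bp`. Arrays are the connected
#' components of this relation; singletons are excluded. Strand is recorded
#' but does not affect adjacency.
#'
#' @param catalog a [gene_catalog()] (sorted by scaffold and start).
#' @param family family label to cluster.
#' @param max_intervening maximum intervening non-family gene models
#'   (default 5).
#' @param max_gap_bp maximum start-to-start distance in bp (default 100000).
#' @return List of arrays; each is a list with `family`, `scaffold`,
#'   `members` (gene ids sorted by start), `span_bp`.
#' @export
tandem_clusters <- function(catalog, family, max_intervening = 5,
                            max_gap_bp = 1e5) {
  if (!(family %in% catalog$family))
    abort("unknown family: ", family)
  catalog <- catalog[order(catalog$scaffold, catalog$start), , drop = FALSE]
  arrays <- list()
  for (sc in unique(catalog$scaffold)) {
    sub <- catalog[catalog$scaffold == sc, , drop = FALSE]
    idx <- which(sub$family %in% family)
    if (length(idx) < 2) next
    linked <- vapply(seq_len(length(idx) - 1), function(k) {
      i <- idx[k]; j <- idx[k + 1]
      (j - i - 1) <= max_intervening &&
        (sub$start[j] - sub$start[i]) <= max_gap_bp
    }, logical(1))
    comp <- cumsum(c(TRUE, !linked))
    for (cc in split(idx, comp)) {
      if (length(cc) < 2) next
      arrays[[length(arrays) + 1L]] <- list(
        family = family, scaffold = sc,
        members = sub$gene_id[cc],
        span_bp = max(sub$end[cc]) - min(sub$start[cc]))
    }
  }
  arrays
}

GAP_CHARS <- c("-", ".", "X", "?", "*")

#' Pairwise protein distances from an alignment
#'
#' p-distances with pairwise deletion of gap/ambiguous columns; under the
#' Poisson correction `d = -ln(1 - p)`, saturated pairs (`p = 1`) are set to
#' `cap`.
#'
#' @param aln character matrix (sequences x columns) or named character
#'   vector of equal-length aligned sequences.
#' @param model `"poisson"` (default) or `"p"` (raw p-distance).
#' @param cap distance assigned at saturation (default 10).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(aln, model = c("poisson", "p"), cap = 10) {
  model <- match.arg(model)
  if (!is.matrix(aln)) {
    lens <- nchar(aln)
    if (length(unique(lens)) != 1) abort("sequences must be aligned (equal length)")
    aln <- do.call(rbind, strsplit(toupper(aln), ""))
  }
  n <- nrow(aln)
  ids <- rownames(aln) %||% paste0("seq", seq_len(n))
  ok <- !(aln %in% GAP_CHARS)
  dim(ok) <- dim(aln)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      if (!any(use))
        abort("no comparable columns between ", ids[i], " and ", ids[j])
      p <- mean(aln[i, use] != aln[j, use])
      d <- if (model == "p") p else if (p >= 1) cap else -log(1 - p)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the rate-corrected Q criterion. Ties in Q
#' are broken by the lowest index pair; negative branch lengths are clamped
#' to zero with the deficit moved to the sister branch. Exact on additive
#' distance matrices.
#'
#' @param D symmetric numeric matrix with zero diagonal, `n >= 3`.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) abort("need at least 3 taxa")
  if (anyNA(D) || any(!is.finite(D))) abort("distance matrix contains NaN/Inf")
  if (any(D < 0)) abort("negative distances")
  if (max(abs(D - t(D))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(diag(D) != 0)) abort("diagonal must be zero")
  labels <- rownames(D) %||% paste0("t", seq_len(n))

  n_node <- 2L * n - 2L                 # unrooted binary: n tips, n-2 internal
  edge <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  add_edge <- function(parent, child, len) {
    edge <<- rbind(edge, c(parent, child))
    edge_len <<- c(edge_len, len)
  }
  active <- seq_len(n)                  # node ids of active cluster roots
  next_internal <- n + 1L
  Dm <- D

  while (length(active) > 3) {
    r <- length(active)
    Rsum <- rowSums(Dm)
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        Q <- (r - 2) * Dm[i, j] - Rsum[i] - Rsum[j]
        if (Q < bestQ - 1e-12) { bestQ <- Q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- 0.5 * Dm[i, j] + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    vj <- Dm[i, j] - vi
    ## clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_id <- next_internal; next_internal <- next_internal + 1L
    add_edge(new_id, active[i], vi)
    add_edge(new_id, active[j], vj)
    dnew <- 0.5 * (Dm[i, -c(i, j), drop = TRUE] + Dm[j, -c(i, j), drop = TRUE] -
                     Dm[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    Dm <- Dm[keep, keep, drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    active <- c(active[keep], new_id)
  }

  ## final three-point join
  i <- 1; j <- 2; k <- 3
  v1 <- (Dm[i, j] + Dm[i, k] - Dm[j, k]) / 2
  v2 <- (Dm[i, j] + Dm[j, k] - Dm[i, k]) / 2
  v3 <- (Dm[i, k] + Dm[j, k] - Dm[i, j]) / 2
  v <- c(v1, v2, v3)
  if (any(v < 0)) {
    for (z in which(v < 0)) {
      others <- setdiff(1:3, z)
      v[others] <- v[others] + v[z] / 2
      v[z] <- 0
    }
  }
  root <- next_internal
  add_edge(root, active[1], v[1])
  add_edge(root, active[2], v[2])
  add_edge(root, active[3], v[3])

  ## renumber to ape convention: tips 1..n, root n+1, internals increasing
  internal_ids <- c(root, sort(unique(edge[, 1][edge[, 1] != root]), decreasing = TRUE))
  map <- integer(max(c(edge)))
  map[seq_len(n)] <- seq_len(n)
  map[internal_ids] <- n + seq_along(internal_ids)
  tree <- list(edge = cbind(map[edge[, 1]], map[edge[, 2]]),
               edge.length = edge_len, tip.label = labels,
               Nnode = n - 2L)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Bootstrap supports for a distance+NJ tree
#'
#' Alignment columns are resampled with replacement `B` times; the distance
#' matrix and NJ tree are rebuilt each time and the support of a split is the
#' number of replicates containing it, reported as integer node labels on the
#' tree from the full alignment.
#'
#' @param aln alignment as in [protein_distance()], >= 4 sequences.
#' @param B number of replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param model distance model passed to [protein_distance()].
#' @return The NJ tree of the full alignment with `node.label` supports.
#' @export
bootstrap_support <- function(aln, B = 1000, seed = 1, model = "poisson") {
  if (B < 1) abort("B must be >= 1")
  if (!is.matrix(aln)) aln <- do.call(rbind, strsplit(toupper(aln), ""))
  if (nrow(aln) < 4) abort("need >= 4 sequences for bootstrap supports")
  tree <- nj_tree(protein_distance(aln, model = model))
  reps <- with_seed(derive_seed(seed, "bootstrap"), {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      nj_tree(protein_distance(aln[, cols, drop = FALSE], model = model))
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.character(counts)
  tree
}

#' Maximal single-taxon clades (lineage-specific expansions)
#'
#' The tree is midpoint-rooted; reported clades are the maximal clades whose
#' leaves all carry one taxon tag and whose size is at least `min_size`. No
#' reported clade is contained in another.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa named character vector mapping every tip label to a taxon.
#' @param min_size minimum clade size (default 3).
#' @return List of clades: `taxon`, `size`, `members`, `support` (node label
#'   of the subtending split, `NA` if absent).
#' @export
lineage_specific_clades <- function(tree, taxa, min_size = 3) {
  untagged <- setdiff(tree$tip.label, names(taxa))
  if (length(untagged)) abort("untagged leaf: ", untagged[1])
  rooted <- phangorn::midpoint(tree)
  n <- length(rooted$tip.label)
  node_tips <- lapply((n + 1):(n + rooted$Nnode), function(nd) {
    ape::extract.clade(rooted, nd)$tip.label
  })
  tip_taxon <- taxa[rooted$tip.label]
  pure <- vapply(node_tips, function(tp) length(unique(taxa[tp])) == 1, logical(1))
  size <- lengths(node_tips)
  cand <- which(pure & size >= min_size)
  ## maximality: drop candidates whose tip set is inside another candidate's
  keep <- cand[vapply(cand, function(a) {
    !any(vapply(cand, function(b) {
      b != a && all(node_tips[[a]] %in% node_tips[[b]])
    }, logical(1)))
  }, logical(1))]
  lapply(keep, function(a) {
    nd <- n + a
    sup <- if (!is.null(rooted$node.label)) rooted$node.label[a] else NA_character_
    list(taxon = unname(unique(taxa[node_tips[[a]]])),
         size = length(node_tips[[a]]),
         members = node_tips[[a]],
         support = if (is.null(sup) || is.na(sup) || sup == "") NA else sup)
  })
}
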