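## Readers and writers for the formats the workflow touches. Internally all
## gene coordinates are 0-based half-open; GFF3's 1-based closed convention is
## converted at the boundary in both directions. The homology-hit reader
## consumes the common 12-column tabular dialect (no header).

EVIDENCE_SETS <- c("manual", "interproscan_set", "homology_set", "nr_set", "tblastn_set")

#' Construct a gene catalog
#'
#' A gene catalog is a data frame with one row per gene model, coordinates
#' 0-based half-open, sorted by (scaffold, start).
#'
#' @param df data frame with at least `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`; optional `family`, `frameshift`, `depth`, `provenance`.
#' @return A `gene_catalog` data frame.
#' @export
gene_catalog <- function(df) {
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("catalog missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    abort("duplicate gene_id in catalog: ", paste(head(dup, 5), collapse = ", "))
  }
  bad <- which(!(df$start < df$end))
  if (length(bad)) abort("start must be < end (0-based half-open); offending gene: ",
                         df$gene_id[bad[1]])
  if (!all(df$strand %in% c("+", "-")))
    abort("strand must be '+' or '-'")
  for (col in c("family", "provenance"))
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
  if (is.null(df$frameshift)) df$frameshift <- rep(FALSE, nrow(df))
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_catalog", "data.frame")
  df
}

parse_gff_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Parse gene models from GFF3 text
#'
#' Reads the restricted gene-line dialect used throughout the workflow (one
#' `gene` feature per row; no mRNA/exon hierarchy). 1-based closed coordinates
#' are converted to 0-based half-open. Attributes `ID` (required), `family`,
#' `frameshift` and `provenance` are honoured.
#'
#' @param path file path, or a character vector of GFF3 lines via `text=`.
#' @param text optional character vector of lines (overrides `path`).
#' @return A [gene_catalog()] sorted by (scaffold, start).
#' @export
parse_gene_models <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("no gene models found; returning empty catalog")
    return(gene_catalog(data.frame(gene_id = character(), scaffold = character(),
                                   start = integer(), end = integer(),
                                   strand = character())[0, ]))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort("malformed GFF3 line(s) (fewer than 9 fields) at line ",
          paste(idx[nf < 9][1:min(3, sum(nf < 9))], collapse = ", "))
  }
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) abort("non-numeric coordinates at line ", idx[bad[1]])
  bad <- which(end1 < start1)
  if (length(bad)) abort("end < start at line ", idx[bad[1]])
  at <- lapply(m[, 9], parse_gff_attributes)
  pick <- function(a, key) if (key %in% names(a)) a[[key]] else NA_character_
  ids <- vapply(at, function(a) {
    v <- pick(a, "ID")
    if (is.na(v)) pick(a, "gene_id") else v
  }, character(1))
  if (anyNA(ids)) abort("missing ID attribute at line ", idx[which(is.na(ids))[1]])
  if (anyDuplicated(ids))
    abort("duplicate gene_id: ", ids[duplicated(ids)][1])
  get_at <- function(key) vapply(at, pick, character(1), key)
  gene_catalog(data.frame(
    gene_id = ids,
    scaffold = m[, 1],
    start = as.integer(start1 - 1),   # GFF 1-based closed -> 0-based half-open
    end = as.integer(end1),
    strand = m[, 7],
    family = get_at("family"),
    frameshift = !is.na(get_at("frameshift")) & get_at("frameshift") %in% c("1", "true", "TRUE"),
    provenance = get_at("provenance"),
    stringsAsFactors = FALSE
  ))
}

#' Write a gene catalog as GFF3
#' @param catalog a [gene_catalog()].
#' @param path output file path.
#' @export
write_gene_models <- function(catalog, path) {
  at <- paste0("ID=", catalog$gene_id)
  at <- ifelse(is.na(catalog$family), at, paste0(at, ";family=", catalog$family))
  at <- ifelse(catalog$frameshift, paste0(at, ";frameshift=1"), at)
  at <- ifelse(is.na(catalog$provenance), at, paste0(at, ";provenance=", catalog$provenance))
  lines <- paste(catalog$scaffold, "immunexpand", "gene",
                 catalog$start + 1L, catalog$end, ".", catalog$strand, ".", at,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Parse a 12-column homology hit table and map subjects to phylostrata
#'
#' Subjects are mapped to integer stratum levels 1..10 via `stratum_map`
#' (columns `subject`, `level`); the match is on the full subject id, falling
#' back to the organism prefix before the first `|`. Rows whose subject is
#' absent from the map are dropped and counted (attribute `n_dropped`).
#'
#' @param path tabular file (12 columns, no header), or `text=` lines.
#' @param stratum_map data frame with columns `subject` and `level` (1..10).
#' @param text optional character lines.
#' @param clamp_zero_evalue if `TRUE`, E-values of exactly 0 are clamped to
#'   1e-180 instead of raising an error.
#' @return Data frame of hits with columns `query`, `subject`, `evalue`,
#'   `level`, plus the raw outfmt-6 columns; attribute `n_dropped`.
#' @export
parse_hit_table <- function(path = NULL, stratum_map, text = NULL,
                            clamp_zero_evalue = FALSE) {
  df <- if (!is.null(text)) {
    read.delim(text = paste(text, collapse = "\n"), header = FALSE,
               stringsAsFactors = FALSE, colClasses = "character")
  } else {
    read.delim(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character")
  }
  if (ncol(df) != 12)
    abort("hit table must have 12 columns, found ", ncol(df))
  names(df) <- OUTFMT6_COLS
  ev <- suppressWarnings(as.numeric(df$evalue))
  if (anyNA(ev))
    abort("non-numeric E-value at row ", which(is.na(ev))[1])
  zero <- which(ev == 0)
  if (length(zero)) {
    if (!clamp_zero_evalue)
      abort("E-value of 0 at row ", zero[1],
            " (treat as underflow; set clamp_zero_evalue = TRUE to clamp to 1e-180)")
    ev[zero] <- 1e-180
  }
  if (any(ev < 0)) abort("negative E-value at row ", which(ev < 0)[1])
  stopifnot(all(c("subject", "level") %in% names(stratum_map)))
  lvl <- stratum_map$level[match(df$sseqid, stratum_map$subject)]
  pref <- sub("\\|.*$", "", df$sseqid)
  lvl2 <- stratum_map$level[match(pref, stratum_map$subject)]
  lvl[is.na(lvl)] <- lvl2[is.na(lvl)]
  keep <- !is.na(lvl)
  out <- data.frame(query = df$qseqid[keep], subject = df$sseqid[keep],
                    evalue = ev[keep], level = as.integer(lvl[keep]),
                    stringsAsFactors = FALSE)
  if (length(out$level) && any(out$level < 1 | out$level > 10))
    abort("mapped stratum level outside 1..10")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a hit table in the 12-column dialect
#' @param hits data frame with outfmt-6 columns (as written by the simulator).
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- intersect(OUTFMT6_COLS, names(hits))
  if (length(cols) != 12) abort("hits lack the 12 outfmt-6 columns")
  write.table(hits[, OUTFMT6_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Integer split supports stored in `tree$node.label` are emitted as internal
#' node labels; a round-trip through [read_newick()] preserves topology,
#' branch lengths (to 1e-9) and supports.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#' @param path input path.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read an alignment FASTA into a character matrix
#' @param path FASTA path.
#' @return Matrix (sequences x columns) of upper-case single characters.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1)
    abort("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, lapply(seqs, function(s) toupper(as.character(s))))
  rownames(m) <- names(seqs)
  m
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Write a data frame as a UTF-8 TSV with header
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
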