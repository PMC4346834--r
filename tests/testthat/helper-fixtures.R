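# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  gene_catalog(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    scaffold = c("s1", "s1", "s1", "s1", "s2", "s2"),
    start = c(0L, 2000L, 4000L, 6000L, 0L, 3000L),
    end = c(1500L, 3500L, 5500L, 7500L, 1200L, 4200L),
    strand = c("+", "-", "+", "+", "-", "+"),
    family = c("TLR", "TLR", NA, "TLR", "C1qDC", "C1qDC"),
    stringsAsFactors = FALSE))
}

tiny_expression <- function(counts = NULL) {
  design <- data.frame(
    condition = c("ctrl", "PBS", "trtA", "trtB"),
    axis = "biotic", time_h = NA_real_,
    control = c(TRUE, TRUE, FALSE, FALSE))
  if (is.null(counts)) {
    counts <- matrix(c(100, 100, 800, 100,
                       100, 110, 90, 100,
                       0, 0, 0, 0), nrow = 3, byrow = TRUE,
                     dimnames = list(c("gA", "gB", "gC"), design$condition))
  }
  expression_matrix(counts, design,
                    lib_sizes = setNames(rep(1e7, 4), design$condition),
                    gene_length = setNames(rep(1000, nrow(counts)),
                                           rownames(counts)))
}

small_sim_config <- function(seed = 1, n_genes = 300, ...) {
  simulation_config(
    seed = seed, n_genes = n_genes, n_scaffolds = 10,
    family_spec = data.frame(family = c("TLR", "MyD88"), size = c(30L, 10L)),
    subtype_mix = list(TLR = c(V = 5L, P = 5L, sPP = 5L, Ls = 5L, sP = 10L),
                       MyD88 = c(death_tir = 6L, tir_only = 4L)),
    tandem_spec = data.frame(family = c("TLR", "TLR", "MyD88"),
                             size = c(8L, 3L, 2L),
                             scaffold = c("s599", NA, NA)),
    de_spec = data.frame(axis = "biotic", n_de = 20L, lfc = 3),
    tc_spec = NULL,
    specific_spec = data.frame(axis = "tissue", n = 25L, lfc_drop = 5),
    ...)
}
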