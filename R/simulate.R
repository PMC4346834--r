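## Synthetic-data generators. Every input the workflow consumes can be
## simulated with recorded ground truth, so each downstream stage is testable
## by parameter recovery. Defaults emulate the study design of the bivalve
## immune-gene survey: a multi-scaffold catalog with planted gene families and
## tandem arrays (including an eight-member TLR array on scaffold "s599"),
## half-depth allelic twins reflecting haplotype-inflated assembly (genome
## coverage 105x, twins at half of that, CV 10%), replicate-free pooled count
## libraries across biotic/abiotic/developmental/tissue axes, homology-hit
## tables with planted phylostratum ages, and codon alignments with planted
## positively selected sites.

#' Simulation configuration
#'
#' One object holds every knob of the synthetic study; all randomness flows
#' from the single `seed` through stage-specific derived seeds, so identical
#' configurations reproduce identical datasets byte for byte.
#'
#' @param seed master integer seed.
#' @param n_scaffolds number of scaffolds.
#' @param n_genes total number of gene models (allelic twins included).
#' @param family_spec data frame (`family`, `size`) of planted family sizes.
#' @param subtype_mix named list: per family, a named integer vector of
#'   subtype counts summing to the family size.
#' @param tandem_spec data frame (`family`, `size`, `scaffold`) of planted
#'   tandem arrays; `scaffold` may be `NA` for a random placement.
#' @param duplicate_fraction fraction of gene models that are planted
#'   half-depth allelic twins of another gene.
#' @param pseudogene_fraction fraction of genes flagged with a frameshift.
#' @param depth list: `mean` (normal gene coverage), `duplicate_ratio`
#'   (twin coverage relative to normal) and `cv` (coefficient of variation).
#' @param design condition design data frame (see [default_design()]).
#' @param de_spec data frame (`axis`, `n_de`, `lfc`) of planted differential
#'   expression per axis (signed log2 fold-changes of magnitude `lfc`).
#' @param tc_spec data frame (`class`, `n`) of planted time-course response
#'   classes on the infection time course.
#' @param specific_spec data frame (`axis`, `n`, `lfc_drop`): genes planted
#'   with condition-specific expression on an axis (expression suppressed by
#'   `2^lfc_drop` everywhere on the axis except one peak condition).
#' @param nb list: `mean` and `dispersion` of the count model (gene-level
#'   baselines are Gamma so that counts are marginally negative binomial;
#'   condition-level draws are Poisson, matching a replicate-free pooled
#'   library design).
#' @param silent_fraction fraction of genes planted as untranscribed.
#' @param silent_mean count mean for untranscribed genes.
#' @param library_size nominal mapped reads per condition library.
#' @param library_cv lognormal CV of library sizes across conditions.
#' @param age_spec probability vector over phylostratum levels 1..10.
#' @param homology list: `detection_prob` (chance a stratum younger than the
#'   true age yields a hit), `decoy_fraction` (chance of an above-cutoff decoy
#'   hit per level), `orgs_per_level` subject organisms per stratum.
#' @param selection list: `n_sequences`, `n_codons`, `selected_sites`,
#'   `multiplier` (nonsynonymous rate multiplier at planted sites),
#'   `ns_accept` (baseline nonsynonymous acceptance probability) and
#'   `events_per_codon` (expected mutation proposals per codon per lineage).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    n_scaffolds = 40L,
    n_genes = 1405L,
    family_spec = default_family_spec(),
    subtype_mix = default_subtype_mix(),
    tandem_spec = default_tandem_spec(),
    duplicate_fraction = 0.10,
    pseudogene_fraction = 0.02,
    depth = list(mean = 105, duplicate_ratio = 0.5, cv = 0.10),
    design = default_design(),
    de_spec = data.frame(axis = c("biotic", "abiotic", "development", "tissue"),
                         n_de = c(150L, 100L, 40L, 40L),
                         lfc = c(3, 3, 3, 3)),
    tc_spec = data.frame(class = c("early", "late", "early_and_late", "down"),
                         n = c(10L, 10L, 5L, 8L)),
    specific_spec = data.frame(axis = c("tissue", "development"),
                               n = c(320L, 70L), lfc_drop = c(5, 5)),
    nb = list(mean = 200, dispersion = 0.1),
    silent_fraction = 0.031,
    silent_mean = 2,
    library_size = 2e7,
    library_cv = 0.05,
    age_spec = rep(0.1, 10),
    homology = list(detection_prob = 0.8, decoy_fraction = 0.05, orgs_per_level = 3L),
    selection = list(n_sequences = 20L, n_codons = 100L,
                     selected_sites = c(10L, 30L, 50L, 70L, 90L),
                     multiplier = 10, ns_accept = 0.03, events_per_codon = 6.0)) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              n_genes = as.integer(n_genes), family_spec = family_spec,
              subtype_mix = subtype_mix, tandem_spec = tandem_spec,
              duplicate_fraction = duplicate_fraction,
              pseudogene_fraction = pseudogene_fraction, depth = depth,
              design = design, de_spec = de_spec, tc_spec = tc_spec,
              specific_spec = specific_spec, nb = nb,
              silent_fraction = silent_fraction, silent_mean = silent_mean,
              library_size = library_size, library_cv = library_cv,
              age_spec = age_spec, homology = homology, selection = selection)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  n_dup <- round(cfg$duplicate_fraction * cfg$n_genes)
  n_primary <- cfg$n_genes - n_dup
  if (sum(cfg$family_spec$size) > n_primary)
    abort("configuration error: family sizes (", sum(cfg$family_spec$size),
          ") exceed available gene models (", n_primary, ")")
  for (f in names(cfg$subtype_mix)) {
    sz <- cfg$family_spec$size[cfg$family_spec$family == f]
    if (length(sz) && sum(cfg$subtype_mix[[f]]) != sz)
      abort("configuration error: subtype mix for ", f,
            " sums to ", sum(cfg$subtype_mix[[f]]), ", family size is ", sz)
  }
  if (nrow(cfg$tandem_spec) > 0) {
    ts <- merge(aggregate(size ~ family, cfg$tandem_spec, sum),
                cfg$family_spec, by = "family", all.x = TRUE,
                suffixes = c("_tandem", "_family"))
    if (any(is.na(ts$size_family)))
      abort("configuration error: tandem_spec names unknown family ",
            ts$family[is.na(ts$size_family)][1])
    if (any(ts$size_tandem > ts$size_family))
      abort("configuration error: tandem members exceed family size for ",
            ts$family[ts$size_tandem > ts$size_family][1])
  }
  if (cfg$duplicate_fraction < 0 || cfg$duplicate_fraction > 0.5)
    abort("configuration error: duplicate_fraction outside [0, 0.5]")
  if (cfg$nb$mean <= 0 || cfg$nb$dispersion <= 0)
    abort("configuration error: nonpositive count mean or dispersion")
  if (length(cfg$age_spec) != 10 || any(cfg$age_spec < 0) || sum(cfg$age_spec) <= 0)
    abort("configuration error: age_spec must be 10 nonnegative weights")
  sel <- cfg$selection
  if (sel$n_codons < 10)
    abort("configuration error: n_codons must be >= 10")
  if (length(sel$selected_sites) && any(sel$selected_sites > sel$n_codons))
    abort("configuration error: selected-site index beyond n_codons")
  invisible(cfg)
}

#' Default planted family sizes
#'
#' Mirrors the headline family sizes of the survey the workflow emulates
#' (83 TLRs, 321 C1qDCs, 10 MyD88-like adaptors, and smaller families).
#' @return Data frame (`family`, `size`).
#' @export
default_family_spec <- function() {
  data.frame(family = c("TLR", "C1qDC", "MyD88", "TNF", "TRAF", "RIG1",
                        "IAP", "Defensin"),
             size = c(83L, 321L, 10L, 23L, 15L, 11L, 48L, 20L))
}

#' Default subtype composition per family
#' @return Named list of named integer vectors.
#' @export
default_subtype_mix <- function() {
  list(TLR = c(V = 6L, P = 8L, sPP = 2L, Ls = 12L, sP = 55L),
       MyD88 = c(death_tir = 6L, tir_only = 4L),
       C1qDC = c(c1q_collagen = 1L, c1q_only = 320L))
}

#' Default planted tandem arrays
#'
#' 57 of the 83 TLRs sit in arrays, headed by an eight-member array pinned to
#' scaffold "s599"; smaller families carry pairs and triplets.
#' @return Data frame (`family`, `size`, `scaffold`).
#' @export
default_tandem_spec <- function() {
  data.frame(
    family = c(rep("TLR", 15), "MyD88", "C1qDC", "C1qDC", "C1qDC", "C1qDC",
               "TNF", "TNF", "TRAF", "TRAF", "RIG1", "RIG1", "RIG1"),
    size = c(8L, 7L, 6L, 5L, 5L, 4L, 4L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L,
             2L, 4L, 3L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L),
    scaffold = c("s599", rep(NA_character_, 26)),
    stringsAsFactors = FALSE
  )
}

#' Default condition design
#'
#' Replicate-free pooled libraries: biotic challenges (five Vibrio strains,
#' M. luteus, LPS, a herpesvirus, with untreated and PBS controls and a mixed
#' Vibrio infection time course), abiotic stresses, developmental stages and
#' adult organs.
#' @return Data frame (`condition`, `axis`, `time_h`, `control`).
#' @export
default_design <- function() {
  df <- rbind(
    data.frame(condition = c("untreated", "PBS"), axis = "biotic",
               time_h = NA_real_, control = TRUE),
    data.frame(condition = c("Vibrio_anguillarum", "Vibrio_tubiashii",
                             "Vibrio_aestuarianus", "Vibrio_alginolyticus1",
                             "Vibrio_alginolyticus2", "M_luteus", "LPS", "OsHV1"),
               axis = "biotic", time_h = NA_real_, control = FALSE),
    data.frame(condition = paste0("Vibrio_mix_", c(0, 6, 12, 24, 48), "h"),
               axis = "biotic", time_h = c(0, 6, 12, 24, 48), control = FALSE),
    data.frame(condition = "normal", axis = "abiotic", time_h = NA_real_,
               control = TRUE),
    data.frame(condition = c("heat", "cold", "salinity_low", "salinity_high",
                             "air_exposure"),
               axis = "abiotic", time_h = NA_real_, control = FALSE),
    data.frame(condition = "egg", axis = "development", time_h = NA_real_,
               control = TRUE),
    data.frame(condition = c("morula", "blastula", "gastrula", "trochophore",
                             "D_larva", "umbo", "spat", "juvenile"),
               axis = "development", time_h = NA_real_, control = FALSE),
    data.frame(condition = "whole_body", axis = "tissue", time_h = NA_real_,
               control = TRUE),
    data.frame(condition = c("gill", "hemocyte", "mantle", "gonad",
                             "adductor_muscle", "digestive_gland", "labial_palp"),
               axis = "tissue", time_h = NA_real_, control = FALSE)
  )
  rownames(df) <- NULL
  df
}

## ---- architecture grammar ---------------------------------------------------

#' Sample a TLR domain architecture of a given subtype
#'
#' The generator draws from the same grammar the subtype classifier
#' operationalises, so planted subtypes are exactly recoverable.
#'
#' @param subtype one of `"V"`, `"P"`, `"sP"`, `"sPP"`, `"Ls"`.
#' @param lrr_long_threshold boundary between short and long ectodomains
#'   (LRR count), default 8.
#' @return Character vector of ordered domain tokens (N to C).
#' @export
sample_tlr_architecture <- function(subtype, lrr_long_threshold = 8) {
  sp <- if (runif(1) < 0.7) "SP" else character()
  tail <- c("TM", "TIR")
  thr <- lrr_long_threshold
  ecto <- switch(subtype,
    V = c("LRRNT", rep("LRR", sample(thr:(thr + 17), 1)), "LRRCT"),
    P = {
      total <- sample(thr:(thr + 12), 1)
      a <- sample(seq_len(total - 1), 1)
      c("LRRNT", rep("LRR", a), "LRRCT", "LRRNT", rep("LRR", total - a), "LRRCT")
    },
    sPP = {
      total <- sample(2:(thr - 1), 1)
      a <- sample(seq_len(total - 1), 1)
      c("LRRNT", rep("LRR", a), "LRRCT", "LRRNT", rep("LRR", total - a), "LRRCT")
    },
    sP = c(rep("LRR", sample(1:(thr - 1), 1)),
           if (runif(1) < 0.5) "LRRCT" else character()),
    Ls = "LRRCT",
    abort("unknown TLR subtype: ", subtype)
  )
  c(sp, ecto, tail)
}

sample_architecture <- function(family, subtype) {
  if (family == "TLR") return(sample_tlr_architecture(subtype))
  switch(family,
    MyD88 = if (identical(subtype, "tir_only")) "TIR" else c("DEATH", "TIR"),
    C1qDC = if (identical(subtype, "c1q_collagen")) c("COLLAGEN", "C1Q") else "C1Q",
    paste0(family, "_domain")
  )
}

## ---- catalog ----------------------------------------------------------------

#' Simulate a gene catalog with planted families, tandem arrays and twins
#'
#' Genes are laid on scaffolds as non-overlapping 0-based half-open intervals.
#' Planted tandem arrays are runs of consecutive same-family genes; scattered
#' same-family genes are kept at least six gene models away from any other
#' member of their family so arrays are exactly recoverable. A fraction of
#' gene models are allelic twins ("-D" suffix) whose read depth is drawn
#' around half the normal coverage; twins are planted on family-unlabelled
#' genes so family ground truth is unaffected. Each gene carries a domain
#' architecture consistent with its planted subtype; a fraction carry a
#' frameshift (pseudogene) flag.
#'
#' @param config a [simulation_config()].
#' @return List with elements `catalog` ([gene_catalog()]), `depths`
#'   (data frame `gene_id`, `depth`), `domains` (data frame `gene_id`,
#'   `tokens` comma-joined, `frameshift`) and `truth` (subtypes, tandem
#'   arrays, duplicate pairs, pseudogene ids).
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "catalog"), {
    n_dup <- round(config$duplicate_fraction * config$n_genes)
    n_primary <- config$n_genes - n_dup

    scaffolds <- c("s599", sprintf("s%03d", seq_len(config$n_scaffolds - 1)))
    scaf_of <- sort(rep_len(seq_len(config$n_scaffolds), n_primary))
    slot_family <- rep(NA_character_, n_primary)
    slot_array <- rep(NA_integer_, n_primary)

    ts <- config$tandem_spec
    ts <- ts[order(-ts$size), , drop = FALSE]  # big arrays first
    for (i in seq_len(nrow(ts))) {
      fam <- ts$family[i]; k <- ts$size[i]
      want <- ts$scaffold[i]
      sc_idx <- if (!is.na(want)) match(want, scaffolds) else NA_integer_
      placed <- FALSE
      for (try in 1:2000) {
        sc <- if (!is.na(sc_idx)) sc_idx else sample.int(config$n_scaffolds, 1)
        slots <- which(scaf_of == sc)
        if (length(slots) < k) next
        s0 <- slots[sample.int(length(slots) - k + 1, 1)]
        run <- s0:(s0 + k - 1)
        if (any(!is.na(slot_family[run]))) next
        slot_family[run] <- fam
        slot_array[run] <- i
        placed <- TRUE
        break
      }
      if (!placed) abort("could not place tandem array of size ", k,
                         " for family ", fam, "; too crowded")
    }

    fs <- config$family_spec
    for (i in seq_len(nrow(fs))) {
      fam <- fs$family[i]
      n_rest <- fs$size[i] - sum(slot_family %in% fam)
      if (n_rest < 0) abort("tandem members exceed family size for ", fam)
      if (n_rest > 0) {
        free <- which(is.na(slot_family))
        if (n_rest > length(free)) abort("could not scatter family ", fam)
        slot_family[free[sample.int(length(free), n_rest)]] <- fam
      }
    }

    ## gene ids: five-digit codes
    codes <- sprintf("Cg%05d", sample.int(99999, n_primary))
    ## twins: planted on family-unlabelled genes only
    free_idx <- which(is.na(slot_family))
    if (n_dup > length(free_idx))
      abort("configuration error: not enough unlabelled genes to host ",
            n_dup, " allelic twins")
    twin_partner <- sort(sample(free_idx, n_dup))

    ## build final ordered gene list with twins inserted after partners
    ord <- data.frame(slot = seq_len(n_primary), twin = FALSE,
                      partner = NA_integer_)
    if (n_dup > 0) {
      tw <- data.frame(slot = twin_partner + 0.5, twin = TRUE,
                       partner = twin_partner)
      ord <- rbind(ord, tw)
    }
    ord <- ord[order(ord$slot), , drop = FALSE]
    n_all <- nrow(ord)

    base_slot <- floor(ord$slot)
    gene_id <- ifelse(ord$twin, paste0(codes[ord$partner], "-D"), codes[base_slot])
    scaffold <- scaffolds[scaf_of[base_slot]]
    family <- ifelse(ord$twin, NA_character_, slot_family[base_slot])

    ## coordinates: sequential non-overlapping intervals per scaffold
    len <- sample(seq(900L, 3000L, 3L), n_all, replace = TRUE)
    gap <- sample(500:5000, n_all, replace = TRUE)
    start <- numeric(n_all); end <- numeric(n_all)
    pos <- 0; cur <- ""
    for (i in seq_len(n_all)) {
      if (scaffold[i] != cur) { pos <- 0; cur <- scaffold[i] }
      start[i] <- pos
      end[i] <- pos + len[i]
      pos <- end[i] + gap[i]
    }

    ## keep planted arrays the ONLY tandem-linked runs: any same-family pair
    ## not in one array is pushed beyond the 100 kb linkage distance by
    ## inflating an intergenic gap between them (never inside an array)
    fam_all <- ifelse(ord$twin, NA_character_, slot_family[base_slot])
    arr_all <- ifelse(ord$twin, NA_integer_, slot_array[base_slot])
    linkage_gap <- 1e5; linkage_intervening <- 5L
    for (sc in unique(scaffold)) {
      idx <- which(scaffold == sc)
      arr_first <- !is.na(arr_all[idx]) &
        !duplicated(arr_all[idx]) | is.na(arr_all[idx])
      for (jj in seq_along(idx)) {
        f <- fam_all[idx[jj]]
        if (is.na(f) || jj == 1) next
        prev <- rev(which(fam_all[idx[seq_len(jj - 1)]] %in% f))
        if (!length(prev)) next
        ii <- prev[1]
        if (!is.na(arr_all[idx[jj]]) && !is.na(arr_all[idx[ii]]) &&
            arr_all[idx[jj]] == arr_all[idx[ii]]) next
        between <- if (jj - ii > 1) (ii + 1):(jj - 1) else integer()
        n_interv <- sum(!(fam_all[idx[between]] %in% f))
        if (n_interv > linkage_intervening) next
        if (start[idx[jj]] - start[idx[ii]] > linkage_gap) next
        q <- max(which(arr_first[(ii + 1):jj])) + ii
        delta <- start[idx[ii]] + linkage_gap + 10000 - start[idx[q]]
        shift <- idx[q:length(idx)]
        start[shift] <- start[shift] + delta
        end[shift] <- end[shift] + delta
      }
    }
    start <- as.integer(start); end <- as.integer(end)

    strand <- sample(c("+", "-"), n_all, replace = TRUE)
    frameshift <- runif(n_all) < config$pseudogene_fraction
    prov <- vapply(seq_len(n_all), function(i) {
      paste(sort(sample(EVIDENCE_SETS[-1], sample(1:3, 1))), collapse = ",")
    }, character(1))

    ## depth: normal genes around full coverage, twins around half
    dp <- config$depth
    mu <- ifelse(ord$twin, dp$mean * dp$duplicate_ratio, dp$mean)
    depth <- pmax(1, rnorm(n_all, mu, mu * dp$cv))

    ## subtypes and architectures
    subtype <- rep(NA_character_, n_all)
    for (f in names(config$subtype_mix)) {
      idx <- which(family == f)
      mix <- config$subtype_mix[[f]]
      labs <- sample(rep(names(mix), mix))
      subtype[idx] <- labs[seq_along(idx)]
    }
    tokens <- vapply(seq_len(n_all), function(i) {
      fam <- family[i]
      if (is.na(fam)) return("other_domain")
      paste(sample_architecture(fam, subtype[i]), collapse = ",")
    }, character(1))

    catalog <- gene_catalog(data.frame(
      gene_id = gene_id, scaffold = scaffold, start = start, end = end,
      strand = strand, family = family, frameshift = frameshift,
      provenance = prov, stringsAsFactors = FALSE))

    depths <- data.frame(gene_id = gene_id, depth = depth)
    domains <- data.frame(gene_id = gene_id, family = family, tokens = tokens,
                          frameshift = frameshift, stringsAsFactors = FALSE)

    arrays <- lapply(sort(unique(slot_array[!is.na(slot_array)])), function(a) {
      idx <- which(!ord$twin & slot_array[base_slot] %in% a)
      list(family = ts$family[a], scaffold = scaffolds[scaf_of[floor(ord$slot[idx])][1]],
           members = sort(gene_id[idx]))
    })
    truth <- list(
      subtypes = data.frame(gene_id = gene_id, family = family,
                            subtype = subtype, stringsAsFactors = FALSE),
      tandem_arrays = arrays,
      duplicate_pairs = if (n_dup > 0) {
        data.frame(gene_id = codes[twin_partner],
                   twin_id = paste0(codes[twin_partner], "-D"),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = character(), twin_id = character())
      },
      pseudogenes = gene_id[frameshift]
    )
    list(catalog = catalog, depths = depths, domains = domains, truth = truth)
  })
}

## ---- counts -----------------------------------------------------------------

#' Simulate a pooled-library count matrix with planted differential expression
#'
#' Gene baselines are Gamma-distributed (so counts are marginally negative
#' binomial at the configured mean and dispersion); given its baseline, each
#' single-library condition draws a Poisson count, matching the technical
#' noise of a replicate-free pooled design. Planted DE genes have their mean
#' multiplied by `2^lfc` in one target condition of their axis; planted
#' time-course genes follow an early/late/both/down response pattern on the
#' infection time course; a fraction of genes are planted untranscribed.
#'
#' @param catalog a [gene_catalog()] supplying gene ids and lengths.
#' @param config a [simulation_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth`
#'   (`de`: gene/condition/lfc; `response`: gene/class; `silent`: ids).
#' @export
simulate_counts <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  axes <- unique(design$axis)
  for (ax in axes) {
    if (!any(design$control[design$axis == ax]))
      abort("design must have at least one control condition per axis (", ax, ")")
  }
  with_seed(derive_seed(config$seed, "counts"), {
    genes <- catalog$gene_id
    n <- length(genes)
    nc <- nrow(design)
    disp <- config$nb$dispersion
    mu <- config$nb$mean

    n_silent <- round(config$silent_fraction * n)
    silent <- sort(sample.int(n, n_silent))
    base <- rgamma(n, shape = 1 / disp, rate = 1 / (mu * disp))
    base[silent] <- rgamma(n_silent, shape = 1 / disp,
                           rate = 1 / (config$silent_mean * disp))

    lfc_mat <- matrix(0, n, nc, dimnames = list(genes, design$condition))
    de_rows <- list()
    expressed <- setdiff(seq_len(n), silent)

    tc_conds <- design$condition[!is.na(design$time_h) & design$time_h > 0]
    tc_by_time <- setNames(tc_conds, design$time_h[match(tc_conds, design$condition)])
    avail <- expressed
    resp_rows <- list()
    if (!is.null(config$tc_spec) && length(tc_conds) == 4) {
      for (i in seq_len(nrow(config$tc_spec))) {
        cls <- config$tc_spec$class[i]
        k <- config$tc_spec$n[i]
        g <- avail[sample.int(length(avail), k)]; avail <- setdiff(avail, g)
        target <- switch(cls,
          early = tc_by_time[c("6", "12")],
          late = tc_by_time[c("24", "48")],
          early_and_late = tc_by_time[c("6", "48")],
          down = tc_by_time[c("6", "12", "24", "48")])
        sgn <- if (cls == "down") -1 else 1
        for (cond in target) lfc_mat[g, cond] <- sgn * 3
        for (gg in g) for (cond in target)
          de_rows[[length(de_rows) + 1L]] <-
            data.frame(gene_id = genes[gg], condition = cond, lfc = sgn * 3)
        resp_rows[[length(resp_rows) + 1L]] <-
          data.frame(gene_id = genes[g], class = cls)
      }
    }

    ## DE genes may overlap across axes (a gene can respond to both biotic
    ## and abiotic challenge), but not within one axis
    de_pool <- avail
    de_used <- integer()
    for (i in seq_len(nrow(config$de_spec))) {
      ax <- config$de_spec$axis[i]
      k <- config$de_spec$n_de[i]
      mag <- config$de_spec$lfc[i]
      targets <- design$condition[design$axis == ax & !design$control &
                                    (is.na(design$time_h))]
      if (!length(targets) || k == 0) next
      g <- de_pool[sample.int(length(de_pool), k)]
      de_used <- union(de_used, g)
      cond <- sample(targets, k, replace = TRUE)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      for (j in seq_len(k)) {
        lfc_mat[g[j], cond[j]] <- sgn[j] * mag
        de_rows[[length(de_rows) + 1L]] <-
          data.frame(gene_id = genes[g[j]], condition = cond[j], lfc = sgn[j] * mag)
      }
    }

    spec_rows <- list()
    avail <- setdiff(avail, de_used)
    if (!is.null(config$specific_spec)) {
      for (i in seq_len(nrow(config$specific_spec))) {
        ax <- config$specific_spec$axis[i]
        k <- min(config$specific_spec$n[i], length(avail))
        drop <- config$specific_spec$lfc_drop[i]
        conds <- design$condition[design$axis == ax & !design$control]
        if (!length(conds) || k == 0) next
        g <- avail[sample.int(length(avail), k)]
        avail <- setdiff(avail, g)
        peak <- conds[sample.int(length(conds), k, replace = TRUE)]
        for (j in seq_len(k)) {
          lfc_mat[g[j], setdiff(conds, peak[j])] <- -drop
          spec_rows[[length(spec_rows) + 1L]] <-
            data.frame(gene_id = genes[g[j]], axis = ax, peak = peak[j])
        }
      }
    }

    lib <- round(config$library_size *
                   exp(rnorm(nc, -config$library_cv^2 / 2, config$library_cv)))
    libfac <- lib / config$library_size
    lambda <- (base %o% libfac) * 2^lfc_mat
    counts <- matrix(rpois(n * nc, lambda), n, nc,
                     dimnames = list(genes, design$condition))

    expr <- expression_matrix(counts, design, setNames(lib, design$condition),
                              setNames(catalog$end - catalog$start, genes))
    truth <- list(de = rbind_dfs(de_rows) %||%
                    data.frame(gene_id = character(), condition = character(),
                               lfc = numeric()),
                  response = rbind_dfs(resp_rows),
                  specific = rbind_dfs(spec_rows),
                  silent = genes[silent],
                  base_mean = setNames(base, genes))
    list(expr = expr, truth = truth)
  })
}

## ---- homology ---------------------------------------------------------------

#' Simulate a homology-hit table with planted phylostratum ages
#'
#' Each gene draws a true age over levels 1..10; it receives one guaranteed
#' below-cutoff hit at its true level, hits at younger levels (greater than
#' the true age) with the configured detection probability, no below-cutoff
#' hits at older levels, and above-cutoff decoy hits at any level with the
#' configured decoy probability.
#'
#' @param catalog a [gene_catalog()] or character vector of gene ids.
#' @param config a [simulation_config()].
#' @param evalue_cutoff the cutoff decoys must exceed (default 1e-3).
#' @return List with `hits` (12-column outfmt-6 data frame), `stratum_map`
#'   (`subject`, `level`) and `truth` (`gene_id`, `age`).
#' @export
simulate_homology <- function(catalog, config, evalue_cutoff = 1e-3) {
  stopifnot(inherits(config, "sim_config"))
  genes <- if (is.character(catalog)) catalog else catalog$gene_id
  hm <- config$homology
  with_seed(derive_seed(config$seed, "homology"), {
    orgs <- expand.grid(org = seq_len(hm$orgs_per_level), level = 1:10)
    orgs$subject <- sprintf("lvl%02d_org%d", orgs$level, orgs$org)
    age <- sample(1:10, length(genes), replace = TRUE,
                  prob = config$age_spec / sum(config$age_spec))
    rows <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      lv_true <- age[i]
      younger <- if (lv_true < 10) (lv_true + 1):10 else integer()
      lv_hit <- c(lv_true, younger[runif(length(younger)) < hm$detection_prob])
      ev <- 10^-runif(length(lv_hit), 4, 60)
      lv_decoy <- which(runif(10) < hm$decoy_fraction)
      ev_decoy <- 10^runif(length(lv_decoy), log10(evalue_cutoff * 1.5), 1)
      lv_all <- c(lv_hit, lv_decoy)
      ev_all <- c(ev, ev_decoy)
      subj <- vapply(lv_all, function(l) {
        o <- orgs$subject[orgs$level == l]
        paste0(o[sample.int(length(o), 1)], "|p", sample.int(99999, 1))
      }, character(1))
      rows[[i]] <- data.frame(
        qseqid = genes[i], sseqid = subj,
        pident = round(runif(length(lv_all), 25, 95), 1),
        length = sample(80:400, length(lv_all), replace = TRUE),
        mismatch = sample(5:200, length(lv_all), replace = TRUE),
        gapopen = sample(0:5, length(lv_all), replace = TRUE),
        qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
        evalue = signif(ev_all, 3),
        bitscore = round(runif(length(lv_all), 40, 500), 1),
        stringsAsFactors = FALSE)
    }
    list(hits = rbind_dfs(rows),
         stratum_map = orgs[, c("subject", "level")],
         truth = data.frame(gene_id = genes, age = age, stringsAsFactors = FALSE))
  })
}

## ---- codon alignments -------------------------------------------------------

#' Simulate a codon alignment with planted positively selected sites
#'
#' Sequences evolve independently from one stop-free ancestor (a star
#' phylogeny). Per codon, mutation proposals arrive at the configured rate;
#' proposals creating a stop codon are rejected, synonymous proposals are
#' always accepted, and nonsynonymous proposals are accepted with the baseline
#' probability times the planted multiplier at selected sites (capped at 1).
#'
#' @param config a [simulation_config()]; fields under `selection` are used.
#' @return A `codon_alignment`: list with `codons` (matrix sequences x sites
#'   of codon strings), `ancestor`, and `truth$selected_sites`.
#' @export
simulate_codon_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sel <- config$selection
  code <- codon_table()
  sense <- names(code)[code != "*"]
  with_seed(derive_seed(config$seed, "codon"), {
    anc <- sample(sense, sel$n_codons, replace = TRUE)
    mult <- rep(1, sel$n_codons)
    mult[sel$selected_sites] <- sel$multiplier
    p_acc <- pmin(1, sel$ns_accept * mult)
    m <- matrix("", sel$n_sequences, sel$n_codons,
                dimnames = list(sprintf("seq%02d", seq_len(sel$n_sequences)), NULL))
    for (s in seq_len(sel$n_sequences)) {
      cod <- anc
      n_ev <- rpois(sel$n_codons, sel$events_per_codon)
      for (j in which(n_ev > 0)) {
        nt <- strsplit(cod[j], "")[[1]]
        for (e in seq_len(n_ev[j])) {
          pos <- sample.int(3, 1)
          b <- sample(setdiff(DNA_BASES, nt[pos]), 1)
          cand <- nt; cand[pos] <- b
          cand_cod <- paste0(cand, collapse = "")
          if (code[[cand_cod]] == "*") next
          if (code[[cand_cod]] == code[[paste0(nt, collapse = "")]]) {
            nt <- cand
          } else if (runif(1) < p_acc[j]) {
            nt <- cand
          }
        }
        cod[j] <- paste0(nt, collapse = "")
      }
      m[s, ] <- cod
    }
    structure(list(codons = m, ancestor = anc,
                   truth = list(selected_sites = sort(sel$selected_sites))),
              class = "codon_alignment")
  })
}

#' Collapse a codon alignment to DNA strings
#' @param aln a `codon_alignment`.
#' @return Named character vector of nucleotide sequences.
#' @export
codon_alignment_strings <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  setNames(apply(aln$codons, 1, paste0, collapse = ""), rownames(aln$codons))
}
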