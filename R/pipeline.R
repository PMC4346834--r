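## End-to-end orchestration over a simulated study: catalog -> classify ->
## expression -> expansion -> selection -> strata, with per-stage tables, a
## run manifest (config hash, seed, package version) and a machine-readable
## summary. Re-running with an identical configuration reproduces identical
## outputs.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with every analysis threshold.
#' Defaults equal the workflow's canonical values: depth 80x, RPKM > 1,
#' P < 0.001 with fold-change >= 2, E-value 1e-3, tau 0.90, tandem linkage
#' (5 intervening genes / 100 kb), and site-scan alpha 0.05.
#'
#' @param seed master seed (also seeds the simulation unless `sim` is given).
#' @param sim a [simulation_config()].
#' @param depth_threshold,rpkm_threshold,p_threshold,fc_threshold thresholds.
#' @param evalue_cutoff,tau_threshold,alpha more thresholds.
#' @param max_intervening,max_gap_bp tandem linkage knobs.
#' @param bootstrap_B bootstrap replicates for the family tree.
#' @param stages character vector of stages to run, in dependency order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = simulation_config(seed = seed),
                            depth_threshold = 80,
                            rpkm_threshold = 1,
                            p_threshold = 0.001,
                            fc_threshold = 2,
                            evalue_cutoff = 1e-3,
                            tau_threshold = 0.90,
                            alpha = 0.05,
                            max_intervening = 5,
                            max_gap_bp = 1e5,
                            bootstrap_B = 100,
                            stages = c("catalog", "classify", "expression",
                                       "expansion", "selection", "strata")) {
  known <- c("catalog", "classify", "expression", "expansion", "selection", "strata")
  bad <- setdiff(stages, known)
  if (length(bad)) abort("unknown stage: ", bad[1])
  structure(list(seed = as.integer(seed), sim = sim,
                 depth_threshold = depth_threshold,
                 rpkm_threshold = rpkm_threshold, p_threshold = p_threshold,
                 fc_threshold = fc_threshold, evalue_cutoff = evalue_cutoff,
                 tau_threshold = tau_threshold, alpha = alpha,
                 max_intervening = max_intervening, max_gap_bp = max_gap_bp,
                 bootstrap_B = bootstrap_B, stages = stages),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis over a simulated study
#'
#' Simulates every input from `config$sim`, executes the enabled stages in
#' dependency order and returns the per-stage results, a ground-truth
#' recovery section, and a summary. With `out_dir`, per-stage TSV/JSON files
#' and a run manifest are written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A `pipeline_result` list: `manifest`, `data`, `stages`, `summary`,
#'   `recovery`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  needs <- function(s) s %in% stages
  res <- list()
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(packageVersion("immunexpand")),
                   stages = stages)

  sim_cat <- simulate_catalog(config$sim)
  sim_cnt <- simulate_counts(sim_cat$catalog, config$sim)
  sim_hom <- simulate_homology(sim_cat$catalog, config$sim,
                               evalue_cutoff = config$evalue_cutoff)
  sim_aln <- simulate_codon_alignment(config$sim)
  data <- list(catalog = sim_cat, counts = sim_cnt, homology = sim_hom,
               alignment = sim_aln)

  catalog <- sim_cat$catalog
  if (needs("catalog")) {
    df <- depth_filter(catalog, sim_cat$depths, config$depth_threshold)
    catalog <- df$catalog
    fun <- functional_filter(sim_cnt$expr, catalog, config$rpkm_threshold)
    res$catalog <- list(filter_report = df$report, functional = fun)
  }

  if (needs("classify")) {
    dom <- sim_cat$domains[sim_cat$domains$gene_id %in% catalog$gene_id, ]
    calls <- classify_catalog(dom)
    fam_counts <- table(calls$family[!is.na(calls$family)])
    ## expansion versus a reference repertoire; both genomes taken at a
    ## nominal 22k protein-coding genes
    genome_size <- 22000
    comparator <- list(TLR = 10, C1qDC = 30, MyD88 = 3)
    exp_tests <- lapply(names(comparator), function(f) {
      if (!(f %in% names(fam_counts))) return(NULL)
      ft <- family_expansion_test(fam_counts[[f]], genome_size,
                                  comparator[[f]][1], genome_size)
      data.frame(family = f, n_focal = fam_counts[[f]],
                 n_reference = comparator[[f]],
                 chi2 = ft$statistic, p = ft$p.value)
    })
    res$classify <- list(calls = calls, expansion = rbind_dfs(exp_tests))
  }

  if (needs("expression")) {
    em <- sim_cnt$expr
    des <- em$design
    biotic_controls <- des$condition[des$axis == "biotic" & des$control]
    challenges <- des$condition[des$axis == "biotic" & !des$control &
                                  is.na(des$time_h)]
    de <- lapply(challenges, function(ch) {
      call_de(em, ch, biotic_controls, config$p_threshold, config$fc_threshold)
    })
    names(de) <- challenges
    de_sets <- lapply(de, function(d) d$gene_id[d$direction != "ns"])
    venn <- condition_specific_sets(de_sets)

    abiotic <- des$condition[des$axis == "abiotic" & !des$control]
    ab_ctrl <- des$condition[des$axis == "abiotic" & des$control]
    de_ab <- lapply(abiotic, function(ch) {
      call_de(em, ch, ab_ctrl, config$p_threshold, config$fc_threshold)
    })
    biotic_flag <- rownames(em$counts) %in% unique(unlist(de_sets))
    abiotic_flag <- rownames(em$counts) %in%
      unique(unlist(lapply(de_ab, function(d) d$gene_id[d$direction != "ns"])))
    stress <- stress_category(biotic_flag, abiotic_flag)

    ## time-course response classes on the infection time course
    tc <- des[!is.na(des$time_h), ]
    resp <- NULL
    if (nrow(tc) == 5) {
      t0 <- tc$condition[tc$time_h == 0]
      calls <- rbind_dfs(lapply(tc$condition[tc$time_h > 0], function(cc) {
        d <- call_de(em, cc, t0, config$p_threshold, config$fc_threshold)
        d$time_h <- tc$time_h[tc$condition == cc]
        d
      }))
      names(calls)[names(calls) == "gene_id"] <- "gene_id"
      resp <- response_classify(calls[, c("gene_id", "time_h", "direction")])
    }

    ## organ- and stage-specificity
    tau_axis <- function(axis) {
      conds <- des$condition[des$axis == axis & !des$control]
      rp <- em$rpkm[, conds, drop = FALSE]
      vapply(seq_len(nrow(rp)), function(i) {
        si <- specificity_index(rp[i, ], config$tau_threshold)
        isTRUE(si$specific)
      }, logical(1))
    }
    organ_specific <- tau_axis("tissue")
    stage_specific <- tau_axis("development")

    res$expression <- list(de = de, venn = venn, stress = stress,
                           response = resp,
                           organ_specific_frac = mean(organ_specific),
                           stage_specific_frac = mean(stage_specific))
  }

  if (needs("expansion")) {
    fams <- unique(config$sim$tandem_spec$family)
    arrays <- unlist(lapply(fams, function(f) {
      tandem_clusters(catalog, f, config$max_intervening, config$max_gap_bp)
    }), recursive = FALSE)
    n_tlr <- sum(catalog$family %in% "TLR")
    tlr_tandem <- sum(lengths(lapply(
      Filter(function(a) a$family == "TLR", arrays), `[[`, "members")))
    res$expansion <- list(arrays = arrays,
                          tlr_tandem_fraction = if (n_tlr) tlr_tandem / n_tlr else NA)
  }

  if (needs("selection")) {
    scan <- site_selection_scan(sim_aln, alpha = config$alpha)
    strs <- codon_alignment_strings(sim_aln)
    dnds <- ng86_dnds(strs[1], strs[2])
    res$selection <- list(scan = scan, pair_dnds = dnds)
  }

  if (needs("strata")) {
    ages <- assign_age(data.frame(query = sim_hom$hits$qseqid,
                                  subject = sim_hom$hits$sseqid,
                                  evalue = sim_hom$hits$evalue,
                                  level = stratum_level(sim_hom)),
                       catalog$gene_id, config$evalue_cutoff)
    res$strata <- list(ages = ages)
  }

  recovery <- pipeline_recovery(res, data, catalog, config)
  summary <- pipeline_summary(res, catalog)
  out <- structure(list(manifest = manifest, data = data, stages = res,
                        summary = summary, recovery = recovery),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

stratum_level <- function(sim_hom) {
  pref <- sub("\\|.*$", "", sim_hom$hits$sseqid)
  sim_hom$stratum_map$level[match(pref, sim_hom$stratum_map$subject)]
}

pipeline_recovery <- function(res, data, catalog, config) {
  rec <- list()
  truth <- data$catalog$truth
  if (!is.null(res$catalog)) {
    removed <- res$catalog$filter_report$removed_ids
    twins <- truth$duplicate_pairs$twin_id
    tp <- length(intersect(removed, twins))
    fp <- length(setdiff(removed, twins))
    fn <- length(setdiff(twins, removed))
    rec$depth_filter_f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA
    rec$functional_fraction <- mean(res$catalog$functional$functional)
  }
  if (!is.null(res$classify)) {
    tr <- truth$subtypes
    m <- merge(res$classify$calls, tr, by = "gene_id",
               suffixes = c("_called", "_true"))
    m <- m[!is.na(m$subtype_true), ]
    rec$subtype_accuracy <- if (nrow(m)) mean(m$subtype_called == m$subtype_true) else NA
  }
  if (!is.null(res$expression)) {
    de_truth <- data$counts$truth$de
    called <- unlist(lapply(names(res$expression$de), function(ch) {
      d <- res$expression$de[[ch]]
      paste(d$gene_id[d$direction != "ns"], ch)
    }))
    keys <- paste(de_truth$gene_id, de_truth$condition)
    keys <- keys[de_truth$condition %in% names(res$expression$de)]
    if (length(keys)) {
      rec$de_sensitivity <- mean(keys %in% called)
      rec$de_fdr <- if (length(called)) mean(!(called %in% keys)) else 0
    }
    tr_resp <- data$counts$truth$response
    if (!is.null(res$expression$response) && !is.null(tr_resp)) {
      m <- merge(res$expression$response, tr_resp, by = "gene_id",
                 suffixes = c("_called", "_true"))
      if (nrow(m)) rec$response_class_accuracy <-
          mean(m$class_called == m$class_true)
    }
  }
  if (!is.null(res$expansion)) {
    ## recovery is judged on the unfiltered catalog: the depth filter may
    ## legitimately remove array members before the workflow's own detection
    fams <- unique(vapply(truth$tandem_arrays, `[[`, "", "family"))
    raw <- unlist(lapply(fams, function(f) {
      tandem_clusters(data$catalog$catalog, f, config$max_intervening,
                      config$max_gap_bp)
    }), recursive = FALSE)
    got <- lapply(raw, function(a) sort(a$members))
    want <- lapply(truth$tandem_arrays, function(a) sort(a$members))
    rec$tandem_exact <- setequal_lists(got, want)
  }
  if (!is.null(res$selection)) {
    st <- res$selection$scan$sites
    planted <- data$alignment$truth$selected_sites
    called <- st$site[st$selected]
    rec$site_scan_sensitivity <-
      if (length(planted)) mean(planted %in% called) else NA
    rec$site_scan_fdr <-
      if (length(called)) mean(!(called %in% planted)) else 0
  }
  if (!is.null(res$strata)) {
    tr <- data$homology$truth
    m <- merge(res$strata$ages, tr, by = "gene_id")
    rec$age_accuracy <- mean(m$age.x == m$age.y)
  }
  rec
}

setequal_lists <- function(a, b) {
  key <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
  identical(key(a), key(b))
}

pipeline_summary <- function(res, catalog) {
  s <- list(n_genes = nrow(catalog))
  if (!is.null(res$catalog)) {
    s$n_removed_depth <- res$catalog$filter_report$n_removed_depth
    s$pct_functional <- 100 * mean(res$catalog$functional$functional)
  }
  if (!is.null(res$classify)) {
    calls <- res$classify$calls
    tlr <- calls[calls$family %in% "TLR", ]
    s$tlr_subtype_counts <- as.list(table(tlr$subtype))
  }
  if (!is.null(res$expression)) {
    s$n_de_per_challenge <- lapply(res$expression$de, function(d)
      sum(d$direction != "ns"))
    s$stress_category_counts <- as.list(table(res$expression$stress))
    s$organ_specific_frac <- res$expression$organ_specific_frac
    s$stage_specific_frac <- res$expression$stage_specific_frac
  }
  if (!is.null(res$expansion)) {
    s$n_tandem_arrays <- length(res$expansion$arrays)
    s$tlr_tandem_fraction <- res$expansion$tlr_tandem_fraction
  }
  if (!is.null(res$selection)) {
    s$n_selected_sites <- sum(res$selection$scan$sites$selected, na.rm = TRUE)
  }
  if (!is.null(res$strata)) {
    s$age_distribution <- as.list(table(factor(res$strata$ages$age, levels = 1:10)))
  }
  s
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- result$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_gene_models(result$data$catalog$catalog, file.path(out_dir, "catalog.gff3"))
  write_tsv(result$data$catalog$depths, file.path(out_dir, "depths.tsv"))
  if (!is.null(result$stages$classify))
    write_tsv(result$stages$classify$calls, file.path(out_dir, "subtypes.tsv"))
  if (!is.null(result$stages$strata))
    write_tsv(result$stages$strata$ages, file.path(out_dir, "ages.tsv"))
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(result$recovery, file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run (config", substr(x$manifest$config_hash, 1, 8), "):",
      length(x$stages), "stages\n")
  str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}
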