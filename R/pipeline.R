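#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis chain with defaults
#' equal to the reference study design: LOQ cutoffs 0.03 (FA) / 0.4 (AA)
#' nmol/mg, detection in more than 100 samples, 1000 permutations for
#' transgression and heritability, 100 permuted panels for the scan
#' threshold at q = 0.05, interaction FDR 0.1 with a 50-marker
#' separation, and a 1.5-drop confidence interval.
#'
#' @param ... Overrides of the defaults listed below.
#' @param path Optional YAML file of flat key-value overrides (applied
#'   before `...`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., path = NULL) {
  cfg <- list(
    loq_fa = 0.03, loq_aa = 0.4, min_samples = 100,
    outlier_k = 2, sd_type = "sample",
    n_perm_stats = 1000, n_perm_scan = 100,
    q = 0.05, fdr_q = 0.1, min_sep = 50, drop = 1.5,
    threshold = NULL,       # override; NULL -> permutation-derived
    default_t = 3.7,
    seed = 1,
    # synthetic-data defaults (used when no input paths are given)
    n_strains = 199, n_markers = 729, switch_prob = 0.03,
    genotypes_path = NULL, metabolites_path = NULL, il_panel_path = NULL
  )
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$q >= 0, cfg$q <= 1, cfg$fdr_q >= 0, cfg$fdr_q <= 1,
            cfg$drop > 0, cfg$min_sep >= 0, cfg$loq_fa >= 0,
            cfg$loq_aa >= 0, cfg$n_perm_stats >= 0, cfg$n_perm_scan >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Chains the stages on either user-supplied TSV inputs (paths in the
#' config) or freshly simulated data, writes all result tables plus a
#' machine-readable run manifest to `out_dir`, and returns the results.
#' Stage failures abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run, in order, from:
#'   `"simulate"`, `"preprocess"`, `"transgression"`, `"heritability"`,
#'   `"correlate"`, `"map"`, `"interact"`, `"power"`.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param qtl Optional [qtl_spec()] passed to the simulate stage.
#' @param batches Optional [batch_spec()] for the simulate stage.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "preprocess",
                                    "transgression", "heritability",
                                    "correlate", "map", "interact"),
                         out_dir = NULL, qtl = NULL, batches = NULL) {
  res <- list()
  emit <- function(name, tab, params = list()) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_table(tab, file.path(out_dir, paste0(name, ".tsv")),
                  c(list(seed = config$seed), params))
    }
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs: read or simulate -----------------------------------------
  if (!is.null(config$genotypes_path)) {
    res$genotypes <- run_stage("read", read_genotypes(config$genotypes_path))
  } else if ("simulate" %in% stages) {
    res$genotypes <- run_stage("simulate", simulate_ril_genotypes(
      config$n_strains, default_marker_map(config$n_markers),
      switch_prob = config$switch_prob, seed = config$seed))
  }
  if (!is.null(config$metabolites_path)) {
    res$raw <- run_stage("read", read_metabolites(config$metabolites_path))
  } else if ("simulate" %in% stages) {
    res$raw <- run_stage("simulate", simulate_traits(
      add_parents(res$genotypes), qtl = qtl,
      batches = if (is.null(batches)) batch_spec() else batches,
      replicates = ril_study_design(strains(res$genotypes)),
      seed = config$seed + 1))
    emit("simulated_metabolites", res$raw)
  }

  if ("preprocess" %in% stages) {
    res$norm <- run_stage("preprocess", normalize_metabolites(
      res$raw, loq_fa = config$loq_fa, loq_aa = config$loq_aa,
      min_samples = config$min_samples, k = config$outlier_k,
      sd_type = config$sd_type))
    emit("zscores", res$norm$zscores)
  }

  z <- res$norm$zscores
  is_parent <- z$strain %in% c("N2", "CB")
  parents_long <- tibble::tibble(strain = z$strain[is_parent],
                                 metabolite = z$metabolite[is_parent],
                                 value = z$value[is_parent])
  ril_traits <- {
    tt <- res$norm$traits
    keep <- setdiff(rownames(tt$mean), c("N2", "CB"))
    trait_table(tt$mean[keep, , drop = FALSE], tt$n[keep, , drop = FALSE])
  }
  res$traits <- ril_traits

  if ("transgression" %in% stages) {
    res$transgression <- run_stage("transgression", transgression_test(
      ril_traits$mean, parents_long, n_perm = config$n_perm_stats,
      seed = config$seed + 2))
    emit("transgression", res$transgression,
         list(n_perm = config$n_perm_stats))
  }
  if ("heritability" %in% stages) {
    zr <- z[!is_parent, ]
    n_per_strain <- table(unique(zr[c("strain", "sample_id")])$strain)
    rep_strains <- names(n_per_strain)[n_per_strain >= 3]
    reps <- tibble::tibble(strain = zr$strain, metabolite = zr$metabolite,
                           value = zr$value)[zr$strain %in% rep_strains, ]
    res$heritability <- run_stage("heritability", broad_heritability(
      reps, n_perm = config$n_perm_stats, seed = config$seed + 3))
    res$heritability_parental <- run_stage(
      "heritability", parental_heritability(
        parents_long, n_perm = config$n_perm_stats,
        seed = config$seed + 4))
    emit("heritability", res$heritability,
         list(n_perm = config$n_perm_stats))
    emit("heritability_parental", res$heritability_parental,
         list(n_perm = config$n_perm_stats))
  }
  if ("correlate" %in% stages) {
    res$correlation <- run_stage("correlate",
                                 correlation_matrix(ril_traits))
    emit("correlation",
         as.data.frame(res$correlation) |>
           tibble::rownames_to_column("metabolite"))
  }
  if ("map" %in% stages) {
    res$scan <- run_stage("map", single_marker_scan(ril_traits,
                                                    res$genotypes))
    res$threshold <- run_stage("map", if (!is.null(config$threshold)) {
      structure(list(T = config$threshold, q = config$q, m = NA_integer_,
                     n_perm = 0L, trace = NULL),
                class = "threshold_result")
    } else {
      permutation_threshold(ril_traits, res$genotypes,
                            n_perm = config$n_perm_scan, q = config$q,
                            seed = config$seed + 5,
                            default_t = config$default_t)
    })
    res$peaks <- run_stage("map", call_peaks(res$scan, res$threshold$T,
                                             drop = config$drop))
    emit("scan", res$scan, list(threshold = res$threshold$T))
    emit("peaks", res$peaks, list(threshold = res$threshold$T,
                                  drop = config$drop))
  }
  if ("interact" %in% stages) {
    res$interactions <- run_stage("interact", interaction_scan(
      ril_traits, res$genotypes, min_sep = config$min_sep,
      fdr_q = config$fdr_q))
    emit("interactions", res$interactions$tests,
         list(min_sep = config$min_sep, fdr_q = config$fdr_q))
  }
  if ("power" %in% stages) {
    res$power <- run_stage("power", simulate_power(
      res$genotypes, threshold = if (!is.null(config$threshold))
        config$threshold else config$default_t,
      drop = config$drop, seed = config$seed + 6))
    emit("power", res$power$summary)
  }

  if (!is.null(out_dir)) {
    manifest <- list(
      package = "metaboqtl",
      version = as.character(utils::packageVersion("metaboqtl")),
      seed = config$seed,
      stages = stages,
      parameters = unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
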