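#' Apply limit-of-quantification cutoffs
#'
#' Concentrations strictly below the class-specific limit of
#' quantification are treated as unreliable and set to missing: 0.03
#' nmol/mg protein for fatty acids (FA) and 0.4 nmol/mg for amino acids
#' (AA) by default. Boundary values are kept. The number of detected
#' (non-missing) samples per metabolite is attached as the `n_detected`
#' attribute.
#'
#' @param raw Long metabolite table (see [validate_metabolites()]).
#' @param loq_fa,loq_aa Class-specific cutoffs in nmol/mg protein.
#' @return The table with below-LOQ values set to `NA`.
#' @export
apply_detection_limits <- function(raw, loq_fa = 0.03, loq_aa = 0.4) {
  validate_metabolites(raw)
  loq <- ifelse(raw$class == "FA", loq_fa, loq_aa)
  raw$concentration[!is.na(raw$concentration) & raw$concentration < loq] <-
    NA_real_
  n_det <- tapply(!is.na(raw$concentration), raw$metabolite, sum)
  attr(raw, "n_detected") <- n_det
  raw
}

#' Drop unreliably detected metabolites
#'
#' Keeps only metabolites detected (non-missing after LOQ filtering) in
#' strictly more than `min_samples` samples.
#'
#' @param raw Long metabolite table, LOQ-filtered.
#' @param min_samples Detection-count cutoff (strict; default 100).
#' @return The table restricted to reliably detected metabolites.
#' @export
filter_detected <- function(raw, min_samples = 100) {
  n_det <- tapply(!is.na(raw$concentration), raw$metabolite, sum)
  keep <- names(n_det)[n_det > min_samples]
  dropped <- setdiff(names(n_det), keep)
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " metabolite(s) detected in <= ", min_samples, " samples: ",
            paste(dropped, collapse = ", "))
  }
  raw[raw$metabolite %in% keep, , drop = FALSE]
}

#' Express concentrations as within-class composition ratios
#'
#' Because FA and AA panels are measured on the same sample, each
#' concentration is expressed as a fraction of the summed composition of
#' its own class within the sample:
#' `R = M_i / sum_i M` over the non-missing metabolites of the class.
#'
#' @param raw Long metabolite table.
#' @return A ratio table: same keys, `value` column in `[0, 1]`,
#'   `stage = "ratio"`. A (sample, class) group whose total is zero or
#'   all-missing yields missing ratios and is reported.
#' @export
compute_ratios <- function(raw) {
  validate_metabolites(raw)
  out <- raw |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::mutate(.total = sum(.data$concentration, na.rm = TRUE),
                  value = dplyr::if_else(.data$.total > 0,
                                         .data$concentration / .data$.total,
                                         NA_real_)) |>
    dplyr::ungroup()
  n_zero <- out |>
    dplyr::filter(.data$.total <= 0) |>
    dplyr::distinct(.data$sample_id, .data$class) |>
    nrow()
  if (n_zero > 0) {
    message(n_zero, " (sample, class) group(s) with zero total; ",
            "ratios set to missing")
  }
  out$stage <- "ratio"
  out[c("sample_id", "strain", "batch", "replicate", "metabolite", "class",
        "value", "stage")]
}

# Internal: which column carries the measurement in a given table.
.value_col <- function(tab) {
  if ("value" %in% names(tab)) "value" else if
  ("concentration" %in% names(tab)) "concentration" else
    stop("table has neither `value` nor `concentration`", call. = FALSE)
}

#' Remove additive batch effects
#'
#' Per metabolite, subtracts the difference between the batch mean and
#' the grand mean: `v_cor = v - (mean_batch - mean_total)`, equalizing
#' every batch's mean to the grand mean. Works on ratio tables (`value`
#' column) and on raw concentration tables (`concentration` column; used
#' for fold-difference evaluation of absolute abundances).
#'
#' @param tab Ratio or raw metabolite table with a `batch` column.
#' @return Table of the same shape with corrected values; ratio tables
#'   advance to `stage = "corrected"`.
#' @export
batch_correct <- function(tab) {
  col <- .value_col(tab)
  v <- tab[[col]]
  key_m <- tab$metabolite
  key_mb <- paste(tab$metabolite, tab$batch, sep = "\r")
  grand <- tapply(v, key_m, mean, na.rm = TRUE)
  bmean <- tapply(v, key_mb, mean, na.rm = TRUE)
  nb <- tapply(!is.na(v), key_mb, sum)
  if (any(nb == 0)) {
    warning("metabolite/batch cell(s) with no observations pass through ",
            "uncorrected")
  }
  shift <- bmean[key_mb] - grand[key_m]
  shift[is.na(shift)] <- 0
  tab[[col]] <- as.vector(v - shift)
  if ("stage" %in% names(tab)) tab$stage <- "corrected"
  tab
}

#' Standardize metabolite values to z-scores
#'
#' Per metabolite across all samples: `Z = (v - mu) / sigma`. The sample
#' standard deviation (n - 1 denominator) is the default; metabolites
#' with zero variance carry no mappable variation and are dropped with a
#' message.
#'
#' @param tab Ratio table (typically batch-corrected).
#' @param sd_type `"sample"` (n - 1) or `"population"` (n) denominator.
#' @return Table with `stage = "zscore"`; per metabolite mean 0, sd 1.
#' @export
zscore_transform <- function(tab, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  col <- .value_col(tab)
  v <- tab[[col]]
  mu <- tapply(v, tab$metabolite, mean, na.rm = TRUE)
  sig <- tapply(v, tab$metabolite, stats::sd, na.rm = TRUE)
  if (sd_type == "population") {
    n <- tapply(!is.na(v), tab$metabolite, sum)
    sig <- sig * sqrt((n - 1) / n)
  }
  flat <- names(sig)[!is.na(sig) & sig == 0]
  if (length(flat)) {
    message("dropping constant metabolite(s): ", paste(flat, collapse = ", "))
    keep <- !(tab$metabolite %in% flat)
    tab <- tab[keep, , drop = FALSE]
    v <- v[keep]
  }
  tab[[col]] <- as.vector((v - mu[tab$metabolite]) / sig[tab$metabolite])
  if ("stage" %in% names(tab)) tab$stage <- "zscore"
  tab
}

#' Remove per-strain outlier replicates
#'
#' Within each (strain, metabolite), replicate values that exceed the
#' strain mean by more than `k` strain standard deviations (strictly
#' outside `mu +/- k * sigma`, both computed over all replicates
#' including the candidate) are set to missing. Strains with fewer than 3
#' non-missing replicates are left untouched (sigma is degenerate).
#'
#' @param tab Z-scored ratio table.
#' @param k Envelope half-width in strain SDs (default 2).
#' @return Table with outliers set to `NA`.
#' @export
remove_outliers <- function(tab, k = 2) {
  col <- .value_col(tab)
  v <- tab[[col]]
  key <- paste(tab$strain, tab$metabolite, sep = "\r")
  n <- tapply(!is.na(v), key, sum)
  mu <- tapply(v, key, mean, na.rm = TRUE)
  sig <- tapply(v, key, stats::sd, na.rm = TRUE)
  eligible <- n[key] >= 3 & !is.na(sig[key]) & sig[key] > 0
  out <- eligible & !is.na(v) & abs(v - mu[key]) > k * sig[key]
  v[out] <- NA_real_
  tab[[col]] <- v
  tab
}

#' Per-strain trait means
#'
#' Averages the (z-scored) replicate values per strain and metabolite,
#' keeping the replicate count behind each mean. This is the mapping
#' phenotype.
#'
#' @param tab Z-scored ratio table.
#' @return A [trait_table()].
#' @export
strain_means <- function(tab) {
  col <- .value_col(tab)
  sids <- sort(unique(tab$strain))
  mets <- unique(tab$metabolite)
  v <- tab[[col]]
  i <- match(tab$strain, sids)
  j <- match(tab$metabolite, mets)
  sum_m <- matrix(0, length(sids), length(mets),
                  dimnames = list(sids, mets))
  n_m <- sum_m
  ok <- !is.na(v)
  for (r in which(ok)) {
    sum_m[i[r], j[r]] <- sum_m[i[r], j[r]] + v[r]
    n_m[i[r], j[r]] <- n_m[i[r], j[r]] + 1
  }
  mean_m <- ifelse(n_m > 0, sum_m / n_m, NA_real_)
  trait_table(mean_m, n_m)
}

#' Fold differences in absolute abundance between extreme strains
#'
#' On batch-corrected absolute concentrations, computes per metabolite
#' the ratio of the highest to the lowest strain mean over the supplied
#' strains (RILs only, typically). Undefined when the minimum is not
#' positive.
#'
#' @param tab Batch-corrected raw concentration table.
#' @param strains_use Strain ids to include (default: all in the table).
#' @return Tibble with `metabolite`, `min_strain`, `max_strain`, `fold`.
#' @export
fold_differences <- function(tab, strains_use = unique(tab$strain)) {
  tab <- tab[tab$strain %in% strains_use, , drop = FALSE]
  tt <- strain_means(tab)
  mets <- colnames(tt$mean)
  res <- lapply(mets, function(m) {
    v <- tt$mean[, m]
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(tibble::tibble(metabolite = m, min_strain = NA_character_,
                            max_strain = NA_character_, fold = NA_real_))
    }
    lo <- which.min(v); hi <- which.max(v)
    fold <- if (v[lo] > 0) unname(v[hi] / v[lo]) else NA_real_
    tibble::tibble(metabolite = m, min_strain = names(v)[lo],
                   max_strain = names(v)[hi], fold = fold)
  })
  dplyr::bind_rows(res)
}

#' Run the full normalization chain
#'
#' LOQ filtering, detection filtering, composition ratios, batch
#' correction, z-scoring, per-strain outlier removal and strain
#' averaging, in that order.
#'
#' @param raw Long metabolite table.
#' @param loq_fa,loq_aa LOQ cutoffs (see [apply_detection_limits()]).
#' @param min_samples Detection cutoff (see [filter_detected()]).
#' @param k Outlier envelope width (see [remove_outliers()]).
#' @param sd_type Passed to [zscore_transform()].
#' @return List with `zscores` (long table after outlier removal) and
#'   `traits` (a [trait_table()]).
#' @export
normalize_metabolites <- function(raw, loq_fa = 0.03, loq_aa = 0.4,
                                  min_samples = 100, k = 2,
                                  sd_type = "sample") {
  z <- raw |>
    apply_detection_limits(loq_fa = loq_fa, loq_aa = loq_aa) |>
    filter_detected(min_samples = min_samples) |>
    compute_ratios() |>
    batch_correct() |>
    zscore_transform(sd_type = sd_type) |>
    remove_outliers(k = k)
  list(zscores = z, traits = strain_means(z))
}
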