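# Index of the FDR = 0.05 cutoff in a permutation null: the 50th highest
# of 1000 null statistics, scaling as ceil(0.05 * n_perm) for other n_perm.
.perm_cutoff_index <- function(n_perm, q = 0.05) max(1L, ceiling(q * n_perm))

.nth_highest <- function(x, k) {
  x <- sort(x, decreasing = TRUE)
  x[min(k, length(x))]
}

#' Test for transgressive segregation
#'
#' For each metabolite, counts RILs whose mean trait value falls strictly
#' outside the parental envelope `[mu_low - 2*sigma, mu_high + 2*sigma]`,
#' where `mu_low`/`mu_high` are the parental means and `sigma` is the
#' pooled parental standard deviation (square root of the mean of the two
#' parental variances). Significance is assessed by permuting the trait
#' values over the strain designations (parents and RILs jointly),
#' recomputing the count `n_perm` times, and taking the FDR = 0.05
#' cutoff as the 50th highest null count (for `n_perm = 1000`).
#'
#' @param ril_means Numeric matrix RIL strains x metabolites of per-strain
#'   mean z-scores (e.g. `trait_table$mean` restricted to RILs).
#' @param parents Long tibble of parental replicate z-scores with columns
#'   `strain` (`"N2"`/`"CB"`), `metabolite`, `value`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param k Envelope half-width in pooled SDs (default 2).
#' @return Tibble per metabolite: `n_transgressive`, `low`, `high`,
#'   `perm_cutoff`, `significant`. Metabolites where either parent has
#'   fewer than 2 replicates are skipped.
#' @export
transgression_test <- function(ril_means, parents, n_perm = 1000, seed = 1,
                               k = 2) {
  set.seed(seed)
  mets <- colnames(ril_means)
  kidx <- .perm_cutoff_index(n_perm)
  count_fun <- function(pn2, pcb, rils) {
    mu <- c(mean(pn2), mean(pcb))
    sig <- sqrt(mean(c(stats::var(pn2), stats::var(pcb))))
    lo <- min(mu) - k * sig
    hi <- max(mu) + k * sig
    c(sum(rils < lo | rils > hi, na.rm = TRUE), lo, hi)
  }
  res <- lapply(mets, function(m) {
    pn2 <- parents$value[parents$strain == "N2" & parents$metabolite == m]
    pcb <- parents$value[parents$strain == "CB" & parents$metabolite == m]
    pn2 <- pn2[!is.na(pn2)]; pcb <- pcb[!is.na(pcb)]
    if (length(pn2) < 2 || length(pcb) < 2) {
      return(tibble::tibble(metabolite = m, n_transgressive = NA_integer_,
                            low = NA_real_, high = NA_real_,
                            perm_cutoff = NA_real_, significant = NA))
    }
    rils <- ril_means[, m]
    obs <- count_fun(pn2, pcb, rils)
    pool <- c(pn2, pcb, rils[!is.na(rils)])
    n1 <- length(pn2); n2 <- length(pcb)
    null_counts <- vapply(seq_len(n_perm), function(p) {
      s <- sample(pool)
      count_fun(s[seq_len(n1)], s[n1 + seq_len(n2)], s[-seq_len(n1 + n2)])[1]
    }, numeric(1))
    cutoff <- .nth_highest(null_counts, kidx)
    tibble::tibble(metabolite = m, n_transgressive = as.integer(obs[1]),
                   low = obs[2], high = obs[3], perm_cutoff = cutoff,
                   significant = obs[1] > cutoff)
  })
  dplyr::bind_rows(res)
}

# One-way ANOVA variance components by expected mean squares with the
# unbalanced-design effective replicate number
# n_bar = (N - sum(n_i^2)/N) / (k - 1).
.anova_components <- function(value, group) {
  ok <- !is.na(value)
  value <- value[ok]; group <- group[ok]
  n_i <- table(group)
  n_i <- n_i[n_i > 0]
  k <- length(n_i); N <- sum(n_i)
  if (k < 2 || N - k < 1) return(c(V_strain = NA, V_res = NA))
  gm <- mean(value)
  m_i <- tapply(value, group, mean)
  ssb <- sum(n_i * (m_i[names(n_i)] - gm)^2)
  ssw <- sum((value - m_i[as.character(group)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n_bar <- (N - sum(n_i^2) / N) / (k - 1)
  c(V_strain = max(0, (msb - msw) / n_bar), V_res = msw)
}

.h2_one <- function(value, group, method = "ems") {
  if (method == "ss") {
    ok <- !is.na(value)
    value <- value[ok]; group <- group[ok]
    m_i <- tapply(value, group, mean)
    ssb <- sum((m_i[as.character(group)] - mean(value))^2)
    sst <- sum((value - mean(value))^2)
    if (sst == 0) return(NA_real_)
    return(min(1, max(0, ssb / sst)))
  }
  vc <- .anova_components(value, group)
  if (anyNA(vc) || sum(vc) == 0) return(NA_real_)
  min(1, max(0, vc[["V_strain"]] / (vc[["V_strain"]] + vc[["V_res"]])))
}

#' Broad-sense heritability from replicated RIL measurements
#'
#' One-way ANOVA over strains per metabolite, with variance components
#' from expected mean squares: `V_res = MS_within` and
#' `V_strain = max(0, (MS_between - MS_within) / n_bar)` using the
#' unbalanced-design effective replicate number. The broad-sense
#' heritability is `H2 = V_strain / (V_strain + V_res)`. Significance is
#' assessed by permuting values over strains; the FDR = 0.05 cutoff is
#' the 50th highest of 1000 permuted H2 values.
#'
#' @param reps Long tibble with `strain`, `metabolite`, `value`: replicate
#'   z-scores for the replicated strain subset (e.g. 51 RILs, n >= 3).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param method `"ems"` (expected mean squares, default) or `"ss"`
#'   (between-strain over total sum of squares).
#' @return Tibble per metabolite: `H2`, `perm_cutoff`, `significant`.
#' @export
broad_heritability <- function(reps, n_perm = 1000, seed = 1,
                               method = c("ems", "ss")) {
  method <- match.arg(method)
  set.seed(seed)
  kidx <- .perm_cutoff_index(n_perm)
  mets <- unique(reps$metabolite)
  res <- lapply(mets, function(m) {
    sub <- reps[reps$metabolite == m & !is.na(reps$value), ]
    h2 <- .h2_one(sub$value, sub$strain, method)
    if (is.na(h2)) {
      return(tibble::tibble(metabolite = m, H2 = NA_real_,
                            perm_cutoff = NA_real_, significant = NA))
    }
    null_h2 <- vapply(seq_len(n_perm), function(p) {
      h <- .h2_one(sample(sub$value), sub$strain, method)
      if (is.na(h)) 0 else h
    }, numeric(1))
    cutoff <- .nth_highest(null_h2, kidx)
    tibble::tibble(metabolite = m, H2 = h2, perm_cutoff = cutoff,
                   significant = h2 > cutoff)
  })
  dplyr::bind_rows(res)
}

#' Heritability from parental strains
#'
#' Two-group ANOVA between the parental strains; the factor 0.5 corrects
#' for the overestimation of additive variance in inbred lines:
#' `h2 = 0.5 * V_parent / (0.5 * V_parent + V_res)`. `V_parent` is the
#' population variance of the two parental genotype effects (`d^2/4` for
#' a parental mean difference `d`), the genotypic variance a balanced
#' segregant population of those alleles would show. Permutation FDR as
#' in [broad_heritability()].
#'
#' @param parents Long tibble with `strain` (`"N2"`/`"CB"`), `metabolite`,
#'   `value`: parental replicate z-scores (the study design has n = 11
#'   per parent).
#' @param n_perm,seed,method As in [broad_heritability()].
#' @return Tibble per metabolite: `h2_parental`, `perm_cutoff`,
#'   `significant`.
#' @export
parental_heritability <- function(parents, n_perm = 1000, seed = 1,
                                  method = c("ems", "ss")) {
  method <- match.arg(method)
  set.seed(seed)
  kidx <- .perm_cutoff_index(n_perm)
  h2p <- function(value, group) {
    if (method == "ss") {
      h <- .h2_one(value, group, "ss")
      return(h)  # SS ratio has no component form for the 0.5 factor
    }
    vc <- .anova_components(value, group)
    if (anyNA(vc)) return(NA_real_)
    # V_parent is the population variance of the two parental genotype
    # effects (sum over k = 2 effects divided by k, i.e. d^2/4 for a mean
    # difference d) — the genotypic variance a balanced RIL population
    # segregating those alleles would show.
    k <- length(unique(group))
    vparent <- vc[["V_strain"]] * (k - 1) / k
    vp <- 0.5 * vparent
    if (vp + vc[["V_res"]] == 0) return(NA_real_)
    min(1, max(0, vp / (vp + vc[["V_res"]])))
  }
  mets <- unique(parents$metabolite)
  res <- lapply(mets, function(m) {
    sub <- parents[parents$metabolite == m & !is.na(parents$value), ]
    if (length(unique(sub$strain)) < 2) {
      return(tibble::tibble(metabolite = m, h2_parental = NA_real_,
                            perm_cutoff = NA_real_, significant = NA))
    }
    h2 <- h2p(sub$value, sub$strain)
    null_h2 <- vapply(seq_len(n_perm), function(p) {
      h <- h2p(sample(sub$value), sub$strain)
      if (is.na(h)) 0 else h
    }, numeric(1))
    cutoff <- .nth_highest(null_h2, kidx)
    tibble::tibble(metabolite = m, h2_parental = h2, perm_cutoff = cutoff,
                   significant = !is.na(h2) && h2 > cutoff)
  })
  dplyr::bind_rows(res)
}

#' Metabolite-metabolite Pearson correlation
#'
#' Pairwise-complete Pearson correlation between metabolites over strain
#' means, computed per class (FAs and AAs independently) or over a
#' supplied subset. Cells with fewer than 3 complete pairs are missing.
#'
#' @param traits A [trait_table()] or a strains x metabolites matrix.
#' @param metabolites Optional metabolite subset (e.g. all FAs).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(traits, metabolites = NULL) {
  m <- if (inherits(traits, "trait_table")) traits$mean else as.matrix(traits)
  if (!is.null(metabolites)) m <- m[, metabolites, drop = FALSE]
  r <- stats::cor(m, use = "pairwise.complete.obs")
  ok <- !is.na(m)
  npairs <- crossprod(ok)  # complete pairs per metabolite pair
  r[npairs < 3] <- NA_real_
  diag(r) <- 1
  r
}
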