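# -log10(p) values are capped here to avoid floating underflow artifacts
# from perfect or near-perfect associations.
NEGLOGP_CAP <- 300

# Internal fast single-trait scan. y: numeric per strain (NA allowed);
# A0: strains x markers allele matrix with NA -> 0; V: validity (0/1).
# Equivalent to the two-sample pooled-variance t-test per marker.
.scan_core <- function(y, A0, V) {
  mask <- !is.na(y)
  yv <- y[mask]
  Av <- A0[mask, , drop = FALSE]
  Vv <- V[mask, , drop = FALSE]
  n <- colSums(Vv)
  n1 <- colSums(Av)
  n0 <- n - n1
  s1 <- drop(crossprod(Av, yv))
  s <- drop(crossprod(Vv, yv))
  sq <- drop(crossprod(Vv, yv^2))
  m1 <- ifelse(n1 > 0, s1 / n1, NA_real_)
  m0 <- ifelse(n0 > 0, (s - s1) / n0, NA_real_)
  sse <- sq - ifelse(n1 > 0, n1 * m1^2, 0) - ifelse(n0 > 0, n0 * m0^2, 0)
  sse <- pmax(sse, 0)
  df <- n - 2
  poly <- n1 > 0 & n0 > 0 & df > 0
  s2 <- ifelse(poly, sse / df, NA_real_)
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  tval <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tval), df)
  sst <- sq - s^2 / n
  r2 <- ifelse(poly & sst > 0, 1 - sse / sst, NA_real_)
  neglogp <- -log10(p)
  neglogp[poly & (is.infinite(neglogp) | neglogp > NEGLOGP_CAP)] <- NEGLOGP_CAP
  neglogp[!poly] <- NA_real_
  list(n = unname(n), effect = unname(m1 - m0), r2 = unname(r2),
       p = unname(p), neglogp = unname(neglogp))
}

# Internal batched variant of .scan_core: Y is a complete (no NA)
# strains x traits matrix; returns the markers x traits -log10(p) matrix.
# Used to scan many permuted copies of a trait in one set of products.
.scan_neglogp_mat <- function(Y, A0, V) {
  n <- colSums(V)
  n1 <- colSums(A0)
  n0 <- n - n1
  S1 <- crossprod(A0, Y)            # markers x traits
  S <- crossprod(V, Y)
  SQ <- crossprod(V, Y^2)
  m1 <- S1 / n1
  m0 <- (S - S1) / n0
  sse <- pmax(SQ - n1 * m1^2 - n0 * m0^2, 0)
  df <- n - 2
  poly <- n1 > 0 & n0 > 0 & df > 0
  s2 <- sse / df
  tval <- (m1 - m0) / sqrt(s2 * (1 / n1 + 1 / n0))
  p <- 2 * stats::pt(-abs(tval), df)
  neglogp <- -log10(p)
  neglogp[is.infinite(neglogp) | neglogp > NEGLOGP_CAP] <- NEGLOGP_CAP
  neglogp[!poly, ] <- NA_real_
  neglogp
}

# Internal: align a trait matrix with a genotype matrix and pre-mask
# alleles. Returns list(Y, A0, V, markers).
.align_scan_inputs <- function(traits, genotypes, min_shared = 20) {
  Y <- if (inherits(traits, "trait_table")) traits$mean else as.matrix(traits)
  shared <- intersect(rownames(Y), strains(genotypes))
  if (length(shared) < min_shared) {
    stop("only ", length(shared),
         " strains shared between traits and genotypes (need >= ",
         min_shared, ")", call. = FALSE)
  }
  A <- genotypes$alleles[shared, , drop = FALSE]
  V <- (!is.na(A)) * 1
  A0 <- A
  A0[is.na(A0)] <- 0L
  list(Y = Y[shared, , drop = FALSE], A0 = A0, V = V,
       markers = genotypes$markers)
}

#' Single-marker genome scan
#'
#' Fits, per metabolite and marker, the one-predictor linear model
#' `Z = x + e` of the strain-mean z-score on the biallelic genotype —
#' numerically identical to the two-sample pooled-variance t-test between
#' allele groups. Strains missing either the trait or the genotype are
#' dropped pairwise per marker; monomorphic markers yield missing
#' results.
#'
#' @param traits A [trait_table()] (or strains x metabolites matrix).
#' @param genotypes A [geno_matrix()].
#' @param min_shared Minimum shared strains required (default 20).
#' @return A tibble of class `scan_result` with one row per
#'   (metabolite, marker): `neglogp` (capped at 300), `effect`
#'   (CB-group mean minus N2-group mean, so positive means the CB allele
#'   raises the trait), `r2`, `n`.
#' @export
single_marker_scan <- function(traits, genotypes, min_shared = 20) {
  inp <- .align_scan_inputs(traits, genotypes, min_shared)
  res <- lapply(colnames(inp$Y), function(met) {
    sc <- .scan_core(inp$Y[, met], inp$A0, inp$V)
    tibble::tibble(metabolite = met,
                   marker = inp$markers$marker,
                   chrom = inp$markers$chrom,
                   pos = inp$markers$pos,
                   n = sc$n, effect = sc$effect, r2 = sc$r2,
                   neglogp = sc$neglogp)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("scan_result", class(out))
  out
}

#' Genome-wide threshold by permutation under dependency
#'
#' Permutes each metabolite's trait values over strains (never the
#' genotypes), rescans, and determines the smallest threshold `t` on a
#' 0.1-step grid of -log10(p) for which
#' `FDS(t) / RDS(t) <= (m0 / m) * q * log(m)`, where `RDS(t)` is the
#' number of metabolites with at least one marker above `t` in the real
#' scan, `FDS(t)` the mean of the same count over permutations,
#' `m` the number of metabolites tested and `m0 = m - RDS(t)` the
#' estimated number of true nulls. `log` is the natural logarithm (the
#' multiple-testing-under-dependency constant).
#'
#' @param traits A [trait_table()] (or matrix).
#' @param genotypes A [geno_matrix()].
#' @param n_perm Number of permuted panels (default 100). With
#'   `n_perm = 0` no permutations are run and the default threshold
#'   `default_t` is returned with a warning.
#' @param q FDR level (default 0.05).
#' @param seed RNG seed.
#' @param grid_step Threshold grid step in -log10(p) units.
#' @param default_t Fallback threshold when `n_perm = 0`; 3.7 is the
#'   genome-wide value this procedure yields on the reference 199-RIL,
#'   56-metabolite panel.
#' @param fds_stat `"mean"` (default) or `"median"` summary of the
#'   per-permutation false-discovery counts.
#' @return List of class `threshold_result`: `T` (the threshold, `Inf`
#'   when nothing passes), `q`, `m`, `n_perm`, and `trace` (tibble of
#'   RDS/FDS per candidate threshold).
#' @export
permutation_threshold <- function(traits, genotypes, n_perm = 100, q = 0.05,
                                  seed = 1, grid_step = 0.1,
                                  default_t = 3.7,
                                  fds_stat = c("mean", "median")) {
  fds_stat <- match.arg(fds_stat)
  if (n_perm == 0) {
    warning("n_perm = 0: skipping permutations, using default threshold ",
            default_t)
    return(structure(list(T = default_t, q = q, m = NA_integer_,
                          n_perm = 0L, trace = NULL),
                     class = "threshold_result"))
  }
  inp <- .align_scan_inputs(traits, genotypes)
  mets <- colnames(inp$Y)
  m <- length(mets)
  ns <- nrow(inp$Y)
  max_real <- vapply(mets, function(met) {
    v <- .scan_core(inp$Y[, met], inp$A0, inp$V)$neglogp
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  }, numeric(1))
  set.seed(seed)
  max_perm <- matrix(NA_real_, n_perm, m)
  for (j in seq_len(m)) {
    y <- inp$Y[, j]
    if (!anyNA(y)) {
      # complete trait: scan all permuted copies in one batched call
      Yp <- vapply(seq_len(n_perm), function(p) y[sample.int(ns)],
                   numeric(ns))
      v <- .scan_neglogp_mat(Yp, inp$A0, inp$V)
      max_perm[, j] <- apply(v, 2, function(col) {
        if (all(is.na(col))) -Inf else max(col, na.rm = TRUE)
      })
    } else {
      for (p in seq_len(n_perm)) {
        v <- .scan_core(y[sample.int(ns)], inp$A0, inp$V)$neglogp
        max_perm[p, j] <- if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
      }
    }
  }
  hi <- max(c(max_real, max_perm[is.finite(max_perm)]), 0)
  grid <- seq(grid_step, ceiling(hi / grid_step) * grid_step + grid_step,
              by = grid_step)
  fds_fun <- if (fds_stat == "mean") mean else stats::median
  trace <- lapply(grid, function(t) {
    rds <- sum(max_real > t)
    fds <- fds_fun(rowSums(max_perm > t))
    m0 <- m - rds
    bound <- (m0 / m) * q * log(m)
    tibble::tibble(threshold = t, RDS = rds, FDS = fds, m0 = m0,
                   bound = bound,
                   ok = rds > 0 && fds / rds <= bound)
  })
  trace <- dplyr::bind_rows(trace)
  T_hat <- if (any(trace$ok)) min(trace$threshold[trace$ok]) else Inf
  if (is.infinite(T_hat)) {
    message("no threshold satisfies the FDS/RDS inequality; returning Inf")
  }
  structure(list(T = T_hat, q = q, m = m, n_perm = as.integer(n_perm),
                 trace = trace), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> T =", x$T, "at q =", x$q, "over m =", x$m,
      "metabolites,", x$n_perm, "permutations\n")
  invisible(x)
}

#' Call QTL peaks and 1.5-drop confidence intervals
#'
#' Per metabolite and chromosome: the marker with the highest -log10(p)
#' (leftmost on ties) is a peak if it exceeds the threshold `T`; its
#' confidence interval is the maximal contiguous run of markers around
#' the peak whose -log10(p) stays above `peak - drop`, truncated at the
#' chromosome ends, reported as the bp positions of the run's flanking
#' markers.
#'
#' @param scan A `scan_result` from [single_marker_scan()].
#' @param T Genome-wide significance threshold in -log10(p).
#' @param drop Drop defining the interval (default 1.5).
#' @return Tibble: `metabolite`, `chrom`, `peak_marker`, `peak_pos`,
#'   `peak_neglogp`, `peak_effect`, `peak_r2`, `ci_start`, `ci_end`.
#' @export
call_peaks <- function(scan, T, drop = 1.5) {
  out <- scan |>
    dplyr::group_by(.data$metabolite, .data$chrom) |>
    dplyr::group_map(function(g, key) {
      v <- g$neglogp
      if (all(is.na(v))) return(NULL)
      pk <- which.max(ifelse(is.na(v), -Inf, v))  # leftmost maximum
      if (is.na(v[pk]) || v[pk] <= T) return(NULL)
      lim <- v[pk] - drop
      lo <- pk
      while (lo > 1 && !is.na(v[lo - 1]) && v[lo - 1] > lim) lo <- lo - 1
      hi <- pk
      while (hi < length(v) && !is.na(v[hi + 1]) && v[hi + 1] > lim) hi <- hi + 1
      tibble::tibble(metabolite = key$metabolite, chrom = key$chrom,
                     peak_marker = g$marker[pk], peak_pos = g$pos[pk],
                     peak_neglogp = v[pk], peak_effect = g$effect[pk],
                     peak_r2 = g$r2[pk],
                     ci_start = g$pos[lo], ci_end = g$pos[hi])
    }, .keep = TRUE)
  dplyr::bind_rows(out)
}

#' Additive multi-marker model for multi-peak traits
#'
#' Joint linear fit `Z = x1 + x2 + ... + xn + e` over up to three peak
#' markers from the single-marker scan, used to verify that multiple
#' peaks for one trait are independent rather than linked. Duplicated
#' (identical) genotype columns are dropped with a warning.
#'
#' @param traits A [trait_table()] (or matrix).
#' @param metabolite Metabolite to fit.
#' @param markers Character vector of 1-3 peak marker ids.
#' @param genotypes A [geno_matrix()].
#' @return List: `fit` (the `lm`), `terms` (tibble of per-marker effects
#'   and partial p-values), `r2`, `adj_r2`.
#' @export
multi_marker_model <- function(traits, metabolite, markers, genotypes) {
  Y <- if (inherits(traits, "trait_table")) traits$mean else as.matrix(traits)
  shared <- intersect(rownames(Y), strains(genotypes))
  y <- Y[shared, metabolite]
  idx <- match(markers, genotypes$markers$marker)
  if (anyNA(idx)) stop("unknown marker: ",
                       paste(markers[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  X <- genotypes$alleles[shared, idx, drop = FALSE]
  colnames(X) <- markers
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("dropping duplicated genotype column(s): ",
            paste(markers[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
  }
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- tibble::tibble(marker = rownames(co)[-1],
                          effect = co[-1, "Estimate"],
                          p = co[-1, "Pr(>|t|)"])
  list(fit = fit, terms = terms, r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared)
}

#' Two-locus epistasis genome scan
#'
#' For every marker pair more than `min_sep` markers apart (or on
#' different chromosomes) fits the full two-locus interaction model
#' `Z = x1 + x2 + x1:x2 + e` and tests the interaction term; identical,
#' in the saturated binary two-way layout, to testing the interaction
#' contrast `m11 - m10 - m01 + m00` against the pooled within-cell
#' variance. P-values are Benjamini-Hochberg adjusted across all
#' eligible (pair, metabolite) tests. Pairs with fewer than
#' `min_class_n` strains in any of the four genotype classes are
#' skipped. For metabolites with a significant pair, the trait variance
#' is decomposed into additive and interaction fractions by sequential
#' ANOVA of the full model.
#'
#' @param traits A [trait_table()] (or matrix).
#' @param genotypes A [geno_matrix()].
#' @param min_sep Minimum marker-index separation within a chromosome
#'   (default 50).
#' @param fdr_q FDR level on the adjusted interaction p (default 0.1).
#' @param min_class_n Minimum strains per two-locus genotype class.
#' @return List of class `interaction_result`: `tests` (tibble with
#'   `metabolite`, `marker1`, `marker2`, `p`, `q`, `significant`) and
#'   `decomposition` (per significant (metabolite, pair): additive and
#'   interaction variance fractions).
#' @export
interaction_scan <- function(traits, genotypes, min_sep = 50, fdr_q = 0.1,
                             min_class_n = 5) {
  inp <- .align_scan_inputs(traits, genotypes, min_shared = 20)
  mk <- inp$markers
  M <- nrow(mk)
  idx <- seq_len(M)
  elig <- outer(mk$chrom, mk$chrom, "!=") |
    abs(outer(idx, idx, "-")) > min_sep
  elig <- elig & upper.tri(elig)
  if (!any(elig)) {
    return(structure(list(tests = tibble::tibble(
      metabolite = character(), marker1 = character(),
      marker2 = character(), p = numeric(), q = numeric(),
      significant = logical()), decomposition = NULL),
      class = "interaction_result"))
  }
  tests <- lapply(colnames(inp$Y), function(met) {
    y <- inp$Y[, met]
    mask <- !is.na(y)
    yv <- y[mask]
    Av <- inp$A0[mask, , drop = FALSE]
    Vv <- inp$V[mask, , drop = FALSE]
    N <- crossprod(Vv)
    n1dot <- crossprod(Av, Vv)   # [j,k]: allele-1 count at j among (j,k)-valid
    n11 <- crossprod(Av)
    Vy <- Vv * yv
    Ay <- Av * yv
    Sy <- crossprod(Vv, Vy)
    S1dot <- crossprod(Av, Vy)   # [j,k]: sum of y with allele 1 at j
    S11 <- crossprod(Av, Ay)
    SQ <- crossprod(Vv, Vv * yv^2)
    n10 <- n1dot - n11
    n01 <- t(n1dot) - n11
    n00 <- N - n1dot - t(n1dot) + n11
    S10 <- S1dot - S11
    S01 <- t(S1dot) - S11
    S00 <- Sy - S1dot - t(S1dot) + S11
    okn <- elig & n11 >= min_class_n & n10 >= min_class_n &
      n01 >= min_class_n & n00 >= min_class_n & (N - 4) > 0
    if (!any(okn)) return(NULL)
    sq0 <- function(S, n) ifelse(n > 0, S^2 / n, 0)
    rss <- SQ - sq0(S11, n11) - sq0(S10, n10) - sq0(S01, n01) -
      sq0(S00, n00)
    rss <- pmax(rss, 0)
    df <- N - 4
    sigma2 <- rss / df
    est <- S11 / n11 - S10 / n10 - S01 / n01 + S00 / n00
    se <- sqrt(sigma2 * (1 / n11 + 1 / n10 + 1 / n01 + 1 / n00))
    tval <- est / se
    pmat <- 2 * stats::pt(-abs(tval), df)
    w <- which(okn, arr.ind = TRUE)
    tibble::tibble(metabolite = met,
                   marker1 = mk$marker[w[, 1]],
                   marker2 = mk$marker[w[, 2]],
                   interaction_effect = est[w],
                   p = pmat[w])
  })
  tests <- dplyr::bind_rows(tests)
  if (!nrow(tests)) {
    return(structure(list(tests = tibble::tibble(
      metabolite = character(), marker1 = character(),
      marker2 = character(), interaction_effect = numeric(),
      p = numeric(), q = numeric(), significant = logical()),
      decomposition = NULL), class = "interaction_result"))
  }
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$q < fdr_q
  sig <- tests[tests$significant, , drop = FALSE]
  decomp <- NULL
  if (nrow(sig)) {
    decomp <- lapply(seq_len(nrow(sig)), function(i) {
      ve <- variance_explained(
        inp$Y[, sig$metabolite[i]], genotypes,
        markers = c(sig$marker1[i], sig$marker2[i]),
        interactions = list(c(sig$marker1[i], sig$marker2[i])))
      addv <- sum(ve$terms$fraction[!grepl(":", ve$terms$term)])
      intv <- sum(ve$terms$fraction[grepl(":", ve$terms$term)])
      tibble::tibble(metabolite = sig$metabolite[i],
                     marker1 = sig$marker1[i], marker2 = sig$marker2[i],
                     additive_fraction = addv, interaction_fraction = intv,
                     r2 = ve$r2, adj_r2 = ve$adj_r2)
    })
    decomp <- dplyr::bind_rows(decomp)
  }
  structure(list(tests = tibble::as_tibble(tests), decomposition = decomp),
            class = "interaction_result")
}

#' Variance explained by a marker model
#'
#' R-squared, adjusted R-squared, and per-term sequential (type-I)
#' variance fractions for a linear model of a trait on marker genotypes,
#' optionally with interaction terms.
#'
#' @param trait Named numeric vector of per-strain trait values (names
#'   are strain ids), or a [trait_table()] plus `metabolite`.
#' @param genotypes A [geno_matrix()].
#' @param markers Character vector of marker ids entering additively.
#' @param interactions Optional list of length-2 character vectors of
#'   marker ids whose products enter as interaction terms.
#' @param metabolite Metabolite name when `trait` is a [trait_table()].
#' @return List: `r2`, `adj_r2`, `terms` (tibble of `term`, `fraction` —
#'   sequential sum-of-squares fractions of total).
#' @export
variance_explained <- function(trait, genotypes, markers,
                               interactions = NULL, metabolite = NULL) {
  y <- if (inherits(trait, "trait_table")) {
    stopifnot(!is.null(metabolite))
    trait$mean[, metabolite]
  } else trait
  shared <- intersect(names(y), strains(genotypes))
  y <- y[shared]
  idx <- match(markers, genotypes$markers$marker)
  if (anyNA(idx)) stop("unknown marker: ",
                       paste(markers[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  X <- as.data.frame(genotypes$alleles[shared, idx, drop = FALSE])
  names(X) <- markers
  rhs <- markers
  if (!is.null(interactions)) {
    rhs <- c(rhs, vapply(interactions, function(pr) {
      paste0("`", pr[1], "`:`", pr[2], "`")
    }, character(1)))
  }
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", markers), collapse = " + "),
    if (!is.null(interactions))
      paste("+", paste(vapply(interactions, function(pr)
        paste0("`", pr[1], "`:`", pr[2], "`"), character(1)),
        collapse = " + "))
    else ""))
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(fml, data = dat)
  av <- stats::anova(fit)
  sst <- sum(av$`Sum Sq`)
  terms <- tibble::tibble(term = rownames(av), fraction = av$`Sum Sq` / sst)
  terms <- terms[terms$term != "Residuals", ]
  terms$term <- gsub("`", "", terms$term)
  sm <- summary(fit)
  list(r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, terms = terms)
}
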