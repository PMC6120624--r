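test_that("scan equals the pooled two-sample t-test per marker", {
  g <- simulate_ril_genotypes(60, tiny_map(6), seed = 40)
  set.seed(41)
  y <- rnorm(60)
  names(y) <- strains(g)
  y[c(3, 10)] <- NA
  geno_na <- g
  geno_na$alleles[5, 2] <- NA_integer_
  sc <- scan_vector(y, geno_na)
  for (j in seq_len(ncol(geno_na$alleles))) {
    x <- geno_na$alleles[, j]
    ok <- !is.na(y) & !is.na(x)
    tt <- t.test(y[ok][x[ok] == 1], y[ok][x[ok] == 0], var.equal = TRUE)
    expect_equal(sc$neglogp[j], -log10(tt$p.value), tolerance = 1e-10)
    expect_equal(sc$effect[j],
                 mean(y[ok][x[ok] == 1]) - mean(y[ok][x[ok] == 0]),
                 tolerance = 1e-12)
  }
})

test_that("perfect association caps -log10(p) and gives R2 = 1", {
  g <- simulate_ril_genotypes(100, tiny_map(4), seed = 42)
  y <- as.numeric(g$alleles[, 3]) - 0.5
  names(y) <- strains(g)
  sc <- scan_vector(y, g)
  expect_equal(sc$neglogp[3], 300)      # documented cap
  expect_equal(sc$r2[3], 1)
})

test_that("monomorphic markers give missing results", {
  map <- tiny_map(3, chroms = "I")
  al <- cbind(M0001 = c(0L, 0L, 0L, 0L), M0002 = c(0L, 1L, 0L, 1L),
              M0003 = c(1L, 0L, 1L, 0L))
  rownames(al) <- sprintf("S%d", 1:4)
  # pad to >= 20 strains for the shared-strain contract
  al <- al[rep(1:4, 6), ]
  rownames(al) <- sprintf("S%02d", 1:24)
  g <- geno_matrix(al, map)
  y <- rnorm(24)
  names(y) <- rownames(al)
  sc <- scan_vector(y, g)
  expect_true(is.na(sc$neglogp[1]))
  expect_false(anyNA(sc$neglogp[2:3]))
})

test_that("null per-marker p-values are uniform", {
  g <- simulate_ril_genotypes(199, tiny_map(5, chroms = "I"), seed = 43)
  set.seed(44)
  pvals <- vapply(1:800, function(i) {
    y <- rnorm(199)
    names(y) <- strains(g)
    10^(-scan_vector(y, g)$neglogp[3])
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a strong planted QTL is localized at (or beside) its marker", {
  g <- simulate_ril_genotypes(199, default_marker_map(729), seed = 45)
  set.seed(46)
  js <- sample(729, 200, replace = TRUE)
  hits <- vapply(seq_along(js), function(i) {
    j <- js[i]
    y <- additive_effect(0.5) * (g$alleles[, j] - 0.5) + rnorm(199)
    names(y) <- strains(g)
    sc <- scan_vector(y, g)
    which.max(sc$neglogp) - j
  }, numeric(1))
  # tightly linked flanking markers (r ~ 0.94) occasionally win the argmax
  expect_gte(mean(hits == 0), 0.95)
  expect_gte(mean(abs(hits) <= 2), 0.99)
})

test_that("permutation threshold: limits and determinism", {
  g <- simulate_ril_genotypes(60, tiny_map(8), seed = 47)
  set.seed(48)
  Y <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(strains(g), sprintf("m%d", 1:4)))
  th1 <- permutation_threshold(Y, g, n_perm = 20, seed = 7)
  th2 <- permutation_threshold(Y, g, n_perm = 20, seed = 7)
  expect_identical(th1$trace, th2$trace)
  # q = 0 -> nothing can pass
  th0 <- permutation_threshold(Y, g, n_perm = 10, q = 0, seed = 7)
  expect_identical(th0$T, Inf)
  # n_perm = 0 -> default threshold with a warning
  expect_warning(thd <- permutation_threshold(Y, g, n_perm = 0),
                 "default threshold")
  expect_equal(thd$T, 3.7)
})

test_that("RDS trace is non-increasing in the threshold", {
  g <- simulate_ril_genotypes(80, tiny_map(10), seed = 49)
  set.seed(50)
  Y <- matrix(rnorm(80 * 5), 80, 5,
              dimnames = list(strains(g), sprintf("m%d", 1:5)))
  Y[, 1] <- Y[, 1] + 1.2 * g$alleles[, 4]   # one real signal
  th <- permutation_threshold(Y, g, n_perm = 20, seed = 8)
  expect_true(all(diff(th$trace$RDS) <= 0))
  expect_true(all(diff(th$trace$FDS) <= 1e-12))
})

test_that("peak calling and 1.5-drop intervals follow the profile walk", {
  map <- tiny_map(9, chroms = "I")
  scan <- tibble::tibble(metabolite = "m", marker = map$marker,
                         chrom = "I", pos = map$pos, n = 100,
                         effect = 1, r2 = 0.1,
                         neglogp = c(1, 2, 3.2, 4.5, 6, 4.6, 3, 5.9, 1))
  pk <- call_peaks(scan, T = 3.7, drop = 1.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_pos, map$pos[5])
  # brute-force walk oracle: markers with neglogp > 6 - 1.5 = 4.5
  # contiguous around the peak are 4..6 is wrong: 4.5 not > 4.5; run is 5..5
  # extended to neighbours strictly above 4.5: left 4.5 (no), right 4.6 (yes)
  expect_equal(pk$ci_start, map$pos[5])
  expect_equal(pk$ci_end, map$pos[6])

  # single significant marker -> CI is that marker's position
  scan2 <- scan
  scan2$neglogp <- c(0, 0, 0, 5, 0, 0, 0, 0, 0)
  pk2 <- call_peaks(scan2, T = 3.7)
  expect_equal(c(pk2$ci_start, pk2$ci_end), rep(map$pos[4], 2))

  # peaks on two chromosomes are both reported
  map2 <- tiny_map(5, chroms = c("I", "II"))
  scan3 <- tibble::tibble(metabolite = "m", marker = map2$marker,
                          chrom = map2$chrom, pos = map2$pos, n = 100,
                          effect = 1, r2 = 0.1,
                          neglogp = c(1, 5, 1, 1, 1, 1, 1, 6, 1, 1))
  expect_equal(nrow(call_peaks(scan3, T = 3.7)), 2L)
  # ties break to the leftmost marker
  scan4 <- scan
  scan4$neglogp <- c(1, 1, 5, 5, 1, 1, 1, 1, 1)
  expect_equal(call_peaks(scan4, T = 3.7)$peak_pos, map$pos[3])
})

test_that("additive multi-marker model: joint variance and consistency", {
  g <- simulate_ril_genotypes(199, tiny_map(10, chroms = c("I", "II")),
                              seed = 51)
  # two unlinked planted QTL, each explaining 15% of the *total* variance
  # (a^2/4 = 0.15/0.70 sigma^2 apiece) -> joint explained ~ 30%
  a <- 2 * sqrt(0.15 / 0.70)
  r2j <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    y <- a * (g$alleles[, 3] - 0.5) +
      a * (g$alleles[, 15] - 0.5) + rnorm(199)
    names(y) <- strains(g)
    Y <- matrix(y, dimnames = list(names(y), "m"))
    multi_marker_model(Y, "m", c("M0003", "M0015"), g)$r2
  }, numeric(1))
  expect_lt(abs(mean(r2j) - 0.30), 0.05)

  set.seed(52)
  y <- rnorm(199) + g$alleles[, 3]
  names(y) <- strains(g)
  Y <- matrix(y, dimnames = list(names(y), "m"))
  # duplicated marker dropped, fit unchanged
  expect_warning(
    fit_dup <- multi_marker_model(Y, "m", c("M0003", "M0003"), g),
    "duplicated")
  fit1 <- multi_marker_model(Y, "m", "M0003", g)
  expect_equal(fit_dup$r2, fit1$r2)
  # single-marker fit agrees with the scan exactly
  sc <- scan_vector(y, g)
  expect_equal(-log10(fit1$terms$p), sc$neglogp[3], tolerance = 1e-10)
  expect_equal(fit1$terms$effect, sc$effect[3], tolerance = 1e-12)
})

test_that("interaction scan recovers planted epistasis, controls the null", {
  map <- default_marker_map(300)
  g <- simulate_ril_genotypes(199, map, seed = 53)
  j1 <- 40; j2 <- 200   # different chromosomes
  # planted product-coded epistasis, interaction fraction 0.3
  hits <- vapply(1:100, function(i) {
    set.seed(8000 + i)
    u <- (2 * g$alleles[, j1] - 1) * (2 * g$alleles[, j2] - 1)
    y <- additive_effect(0.3) * u / 2 + rnorm(199)
    names(y) <- strains(g)
    Y <- matrix(y, dimnames = list(names(y), "m"))
    res <- interaction_scan(Y, g, min_sep = 50, fdr_q = 0.1)
    sig <- res$tests[res$tests$significant, ]
    if (!nrow(sig)) return(FALSE)
    i1 <- match(sig$marker1, map$marker)
    i2 <- match(sig$marker2, map$marker)
    any((abs(i1 - j1) <= 5 & abs(i2 - j2) <= 5) |
          (abs(i1 - j2) <= 5 & abs(i2 - j1) <= 5))
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  # purely additive trait -> expected significant-pair count ~ 0
  n_sig <- vapply(1:50, function(i) {
    set.seed(9000 + i)
    y <- additive_effect(0.3) * (g$alleles[, j1] - 0.5) + rnorm(199)
    names(y) <- strains(g)
    Y <- matrix(y, dimnames = list(names(y), "m"))
    sum(interaction_scan(Y, g, min_sep = 50, fdr_q = 0.1)$tests$significant)
  }, numeric(1))
  # under LD, false rejections arrive in correlated clusters, so the
  # FDR guarantee is on the family-level rate, not the mean count
  expect_equal(median(n_sig), 0)
  expect_lte(mean(n_sig > 0), 0.2)

  # min_sep larger than the genome -> no eligible pairs
  g2 <- simulate_ril_genotypes(30, tiny_map(5, chroms = "I"), seed = 54)
  Y2 <- matrix(rnorm(30), dimnames = list(strains(g2), "m"))
  empty <- interaction_scan(Y2, g2, min_sep = 10)
  expect_equal(nrow(empty$tests), 0L)
})

test_that("interaction-term p matches the lm interaction coefficient", {
  g <- simulate_ril_genotypes(199, tiny_map(30, chroms = c("I", "II")),
                              seed = 55)
  set.seed(56)
  y <- rnorm(199)
  names(y) <- strains(g)
  Y <- matrix(y, dimnames = list(names(y), "m"))
  res <- interaction_scan(Y, g, min_sep = 5, fdr_q = 0.1)
  # oracle: refit a handful of pairs with lm
  pick <- res$tests[c(1, 25, 100), ]
  for (i in seq_len(nrow(pick))) {
    x1 <- g$alleles[, pick$marker1[i]]
    x2 <- g$alleles[, pick$marker2[i]]
    co <- summary(stats::lm(y ~ x1 * x2))$coefficients
    expect_equal(pick$p[i], co["x1:x2", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(pick$interaction_effect[i], co["x1:x2", "Estimate"],
                 tolerance = 1e-10)
  }
})

test_that("variance_explained matches lm and recovers planted fractions", {
  g <- simulate_ril_genotypes(199, tiny_map(10, chroms = c("I", "II")),
                              seed = 57)
  # deterministic limit
  y <- as.numeric(g$alleles[, 4])
  names(y) <- strains(g)
  # base R warns about the (intentionally) perfect fit
  ve <- suppressWarnings(variance_explained(y, g, markers = "M0004"))
  expect_equal(ve$r2, 1)
  # null traits: adjusted R2 centred at 0
  adj <- vapply(1:500, function(i) {
    set.seed(10000 + i)
    y <- rnorm(199)
    names(y) <- strains(g)
    variance_explained(y, g, markers = "M0004")$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.01)
  # planted R2 = 0.34
  est <- vapply(1:200, function(i) {
    set.seed(11000 + i)
    y <- additive_effect(0.34) * (g$alleles[, 4] - 0.5) + rnorm(199)
    names(y) <- strains(g)
    variance_explained(y, g, markers = "M0004")$r2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.34), 0.06)
})
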