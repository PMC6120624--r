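test_that("LOQ cutoffs remove strictly-below values per class", {
  tab <- make_metab(list(fa = c(0.02, 0.03, 1), aa = c(0.39, 0.4, 2)),
                    class = c("FA", "AA"))
  out <- apply_detection_limits(tab)
  fa <- out$concentration[out$metabolite == "fa"]
  aa <- out$concentration[out$metabolite == "aa"]
  expect_equal(is.na(fa), c(TRUE, FALSE, FALSE))   # 0.03 kept (boundary)
  expect_equal(is.na(aa), c(TRUE, FALSE, FALSE))   # 0.39 removed
  # all-above table unchanged
  ok <- make_metab(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(apply_detection_limits(ok)$concentration,
               ok$concentration, ignore_attr = TRUE)
})

test_that("detection filter is strict: 'more than' min_samples", {
  v100 <- c(rep(1, 100), rep(NA, 10))
  v101 <- c(rep(1, 101), rep(NA, 9))
  tab <- make_metab(list(just100 = v100, just101 = v101))
  suppressMessages(out <- filter_detected(tab, min_samples = 100))
  expect_false("just100" %in% out$metabolite)
  expect_true("just101" %in% out$metabolite)
  expect_equal(filter_detected(tab, min_samples = 0), tab)
})

test_that("composition ratios normalize within (sample, class)", {
  tab <- make_metab(list(a = 1, b = 1, c = 2))
  r <- compute_ratios(tab)
  expect_equal(sort(r$value), c(0.25, 0.25, 0.5))
  # one metabolite alone in its class -> ratio 1
  one <- make_metab(list(solo = c(3, 7)))
  expect_equal(compute_ratios(one)$value, c(1, 1))
  # mixed FA + AA: each class sums to 1 independently (brute force)
  set.seed(20)
  mixed <- make_metab(stats::setNames(
    lapply(1:6, function(i) runif(15, 1, 5)),
    sprintf("m%d", 1:6)), class = rep(c("FA", "AA"), each = 3))
  rr <- compute_ratios(mixed)
  sums <- tapply(rr$value, paste(rr$sample_id, rr$class), sum)
  expect_true(all(abs(sums - 1) < 1e-10))
})

test_that("batch correction equalizes batch means to the grand mean", {
  tab <- make_metab(list(m = c(0.3, 0.5, 0.5, 0.7)),
                    batch = c(1, 1, 2, 2))
  out <- batch_correct(tab)
  bm <- tapply(out$concentration, out$batch, mean)
  expect_equal(as.vector(bm), c(0.5, 0.5))
  # single batch -> identity
  one <- make_metab(list(m = c(1, 2, 3)))
  expect_equal(batch_correct(one)$concentration, one$concentration)
  # equal batch sizes preserve the grand mean to 1e-12
  set.seed(21)
  rnd <- make_metab(list(a = rnorm(40), b = abs(rnorm(40)) + 5),
                    batch = rep(1:4, each = 10))
  cor_ <- batch_correct(rnd)
  for (m in c("a", "b")) {
    expect_equal(mean(cor_$concentration[cor_$metabolite == m]),
                 mean(rnd$concentration[rnd$metabolite == m]),
                 tolerance = 1e-12)
  }
})

test_that("planted additive batch offsets are removed exactly", {
  g <- simulate_ril_genotypes(60, tiny_map(4, chroms = "I"), seed = 22)
  bs <- batch_spec(3, offsets = c(-1, 0, 2.5), assign = "round_robin")
  tab <- simulate_traits(g, qtl = NULL, batches = bs,
                         replicates = stats::setNames(rep(3L, 60),
                                                      strains(g)),
                         metabolites = c("a", "b"), seed = 23)
  out <- batch_correct(tab)
  spread <- tapply(out$concentration,
                   paste(out$metabolite, out$batch), mean)
  for (m in c("a", "b")) {
    bm <- spread[grep(paste0("^", m), names(spread))]
    expect_lt(diff(range(bm)), 1e-10)
  }
})

test_that("z-scoring gives mean 0, sd 1, and is idempotent", {
  tab <- make_metab(list(m = c(1, 2, 3), k = c(2, 2, 2)))
  r <- compute_ratios(tab)  # two metabolites -> non-degenerate ratios
  expect_message(z <- zscore_transform(r), NA)
  zm <- z$value[z$metabolite == "m"]
  expect_equal(zm, (r$value[r$metabolite == "m"] -
                      mean(r$value[r$metabolite == "m"])) /
                 sd(r$value[r$metabolite == "m"]))
  expect_equal(mean(zm), 0, tolerance = 1e-10)
  expect_equal(sd(zm), 1, tolerance = 1e-10)
  # plain values (1,2,3) standardize to (-1, 0, 1)
  plain <- make_metab(list(m = c(1, 2, 3)))
  z2 <- zscore_transform(plain)
  expect_equal(z2$concentration, c(-1, 0, 1))
  # idempotence
  z3 <- zscore_transform(z2)
  expect_equal(z3$concentration, z2$concentration, tolerance = 1e-10)
  # constant metabolite dropped
  const <- make_metab(list(flat = c(5, 5, 5), var = c(1, 2, 3)))
  expect_message(zc <- zscore_transform(const), "constant")
  expect_false("flat" %in% zc$metabolite)
})

test_that("per-strain outlier rule uses all replicates incl. candidate", {
  # (0,0,0,10): mu = 2.5, s = 5, bound mu + 2s = 12.5 -> 10 is kept
  tab <- make_metab(list(m = c(0, 0, 0, 10)), strain = rep("A", 4))
  expect_equal(remove_outliers(tab)$concentration, c(0, 0, 0, 10))
  # with 7 replicates a gross outlier is removable: arithmetic oracle
  v <- c(0, 0, 0, 0, 0, 0, 10)
  expect_gt(abs(10 - mean(v)), 2 * sd(v))
  tab7 <- make_metab(list(m = v), strain = rep("A", 7))
  out7 <- remove_outliers(tab7)
  expect_true(is.na(out7$concentration[7]))
  expect_equal(out7$concentration[1:6], rep(0, 6))
  # single replicate and constant strains untouched
  single <- make_metab(list(m = 4), strain = "A")
  expect_equal(remove_outliers(single)$concentration, 4)
  const <- make_metab(list(m = c(2, 2, 2, 2)), strain = rep("A", 4))
  expect_equal(remove_outliers(const)$concentration, rep(2, 4))
})

test_that("strain means match a grouped brute-force oracle", {
  set.seed(24)
  tab <- make_metab(stats::setNames(lapply(1:3, function(i) rnorm(30)),
                                    c("a", "b", "c")),
                    strain = rep(sprintf("S%d", 1:10), each = 3))
  tab$concentration[c(3, 17)] <- NA
  tt <- strain_means(tab)
  brute <- tapply(tab$concentration, list(tab$strain, tab$metabolite),
                  mean, na.rm = TRUE)
  expect_equal(tt$mean[rownames(brute), colnames(brute)], brute,
               tolerance = 1e-12)
  one <- make_metab(list(m = 7), strain = "A")
  expect_equal(unname(strain_means(one)$mean["A", "m"]), 7)
  two <- make_metab(list(m = c(-1, 1)), strain = c("A", "A"))
  expect_equal(unname(strain_means(two)$mean["A", "m"]), 0)
})

test_that("fold differences are max over min strain means", {
  tab <- make_metab(list(m = c(2, 13)), strain = c("A", "B"))
  fd <- fold_differences(batch_correct(tab))
  expect_equal(fd$fold, 6.5)
  flat <- make_metab(list(m = c(3, 3, 3)))
  expect_equal(fold_differences(flat)$fold, 1)
  # non-positive minimum -> undefined
  neg <- make_metab(list(m = c(0, 5)), strain = c("A", "B"))
  expect_true(is.na(fold_differences(neg)$fold))
})

test_that("the full normalization chain is deterministic", {
  g <- simulate_ril_genotypes(50, tiny_map(4, chroms = "I"), seed = 25)
  tab <- simulate_traits(g, qtl_spec(c("a", "b"), c(1, 3), c(0.2, 0.3)),
                         metabolites = c("a", "b", "c", "d"),
                         replicates = stats::setNames(rep(3L, 50),
                                                      strains(g)),
                         batches = batch_spec(3, c(0, 1, -1),
                                              assign = "round_robin"),
                         seed = 26)
  n1 <- normalize_metabolites(tab, min_samples = 0)
  n2 <- normalize_metabolites(tab, min_samples = 0)
  expect_identical(n1$traits$mean, n2$traits$mean)
  # ratios at the z stage came from a table whose per-class ratios sum to 1
  expect_s3_class(n1$zscores, "tbl_df")
})
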