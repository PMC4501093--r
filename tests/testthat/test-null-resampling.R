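test_that("global-frequency bins use half-open 0.1 intervals", {
  f <- c(0.16, 0.34, 1.0, 0.1, 0.0, 0.95)
  m <- matrix(f, ncol = 1, dimnames = list(sprintf("s%d", 1:6), "p1"))
  bins <- bin_by_global_frequency(freq_matrix(m))
  expect_equal(unname(bins$bin), c(2L, 4L, 10L, 2L, 1L, 10L))
  expect_equal(sum(lengths(bins$pools)), 6)
  # every SNP in exactly one pool
  expect_setequal(unlist(bins$pools), rownames(m))
})

test_that("global frequency is the unweighted mean over populations", {
  m <- random_matrix(50, 7, seed = 12)
  bins <- bin_by_global_frequency(m)
  expect_equal(bins$global_freq, rowMeans(unclass(m)))
  eur <- colnames(m)[1:3]
  bins_eur <- bin_by_global_frequency(m, eur)
  expect_equal(bins_eur$global_freq, rowMeans(unclass(m)[, eur]))
})

test_that("resampled sets are matched, distinct and exclude the risk panel", {
  w <- shared_world()
  set <- make_risk_sets(w$matrix, 20, seed = 6)[[1]]
  bins <- w$bins
  set.seed(1)
  for (k in 1:200) {
    ids <- resample_set(set, bins)
    expect_length(ids, 20)
    expect_equal(anyDuplicated(ids), 0L)
    expect_length(intersect(ids, set$snp_id), 0)
    # bin-matched per draw
    expect_equal(unname(bins$bin[ids]), unname(bins$bin[set$snp_id]))
  }
})

test_that("a one-alternative pool makes resampling deterministic", {
  # two SNPs per bin with identical rows: the only legal replacement of
  # each risk SNP is its twin
  m <- rbind(r1 = rep(0.15, 4), t1 = rep(0.15, 4),
             r2 = rep(0.55, 4), t2 = rep(0.55, 4))
  colnames(m) <- paste0("p", 1:4)
  fm <- freq_matrix(m)
  bins <- bin_by_global_frequency(fm)
  set <- risk_set("d", c("r1", "r2"))
  set.seed(2)
  expect_identical(resample_set(set, bins), c("t1", "t2"))

  lonely <- risk_set("d", c("r1", "t1", "r2"))  # bin 2 pool exhausted
  expect_error(resample_set(lonely, bins), "exhausted")
})

test_that("draws within a bin pool are uniform", {
  w <- shared_world()
  set <- make_risk_sets(w$matrix, 10, seed = 8)[[1]]
  bins <- w$bins
  set.seed(3)
  draws <- replicate(10000, resample_set(set, bins))
  # pick the risk SNP in the largest bin and tabulate its replacements
  counts <- table(unlist(draws))
  b <- bins$bin[set$snp_id]
  big <- names(which.max(table(b)))
  pool <- setdiff(bins$pools[[as.integer(big)]], set$snp_id)
  n_in_bin <- sum(b == as.integer(big))
  obs <- as.numeric(counts[pool])
  obs[is.na(obs)] <- 0
  chi <- suppressWarnings(chisq.test(obs))
  expect_gt(chi$p.value, 0.001)
  expect_equal(sum(obs), 10000 * n_in_bin)
})

test_that("empirical p counts strictly higher null samples", {
  null <- c(0.1, 0.2, 0.3)
  expect_equal(empirical_p(0.35, null), 0)
  expect_equal(empirical_p(0.05, null), 1)
  expect_equal(empirical_p(0.2, null), 1 / 3)  # tie counts as not higher
  # 300 of 10,000 higher -> 0.03
  big <- c(rep(0.9, 300), rep(0.1, 9700))
  expect_equal(empirical_p(0.5, big), 0.03)
  expect_equal(empirical_p(0.35, null, plus_one = TRUE), 1 / 4)
  expect_error(empirical_p(0.5, numeric(0)), "empty")
})

test_that("vectorised null R-squared equals a per-set lm oracle", {
  w <- shared_world()
  set <- make_risk_sets(w$matrix, 12, seed = 9)[[1]]
  set.seed(4)
  ids <- vapply(1:50, function(i) resample_set(set, w$bins),
                character(12))
  m <- unclass(w$matrix)
  H <- 2 * m * (1 - m)
  X <- as.matrix(w$predictors[, setdiff(names(w$predictors), "population")])
  fast <- alleleclim:::null_r2_from_ids(ids, m, H, w$baseline, X, chunk = 7L)
  for (s in c(1, 17, 50)) {
    sel <- ids[, s]
    adj_h <- colMeans(H[sel, ]) - w$baseline$avg_het_all
    adj_f <- colMeans(m[sel, ]) - w$baseline$avg_freq_all
    for (v in colnames(X)) {
      expect_equal(unname(fast$het[s, v]),
                   summary(lm(adj_h ~ X[, v]))$r.squared, tolerance = 1e-10)
      expect_equal(unname(fast$frq[s, v]),
                   summary(lm(adj_f ~ X[, v]))$r.squared, tolerance = 1e-10)
    }
  }
})

test_that("build_null is reproducible and its shape matches the design", {
  w <- shared_world()
  set <- make_risk_sets(w$matrix, 8, seed = 10)[[1]]
  a <- build_null(set, w$matrix, w$predictors, bins = w$bins,
                  baseline = w$baseline, n_sets = 100, seed = 5)
  b <- build_null(set, w$matrix, w$predictors, bins = w$bins,
                  baseline = w$baseline, n_sets = 100, seed = 5)
  expect_identical(a$heterozygosity, b$heterozygosity)
  expect_identical(a$risk_freq, b$risk_freq)
  expect_equal(dim(a$heterozygosity), c(100L, 10L))
  expect_true(all(a$heterozygosity >= 0 & a$heterozygosity <= 1))
})

test_that("a twin-pool null reproduces the observed R-squared exactly", {
  # matrix in which every risk SNP has an identical twin as its only legal
  # replacement: the null sample must equal the observed statistic
  set.seed(6)
  base <- matrix(runif(5 * 6, 0.3, 0.4), 5, 6)
  filler <- matrix(runif(8 * 6, 0.7, 0.8), 8, 6)  # other bin, never drawn
  m2 <- rbind(base, base, filler)  # each risk SNP's twin is identical
  rownames(m2) <- c(sprintf("r%d", 1:5), sprintf("t%d", 1:5),
                    sprintf("f%d", 1:8))
  colnames(m2) <- sprintf("p%d", 1:6)
  fm <- freq_matrix(m2)
  bins <- bin_by_global_frequency(fm)
  set <- risk_set("d", sprintf("r%d", 1:5))
  pred <- data.frame(population = colnames(m2), distance_km = 1:6,
                     climate1 = c(0.3, -1, 2, 0.1, -0.4, 1))
  null <- build_null(set, fm, pred, bins = bins, n_sets = 1, seed = 7)
  prof <- allelic_profile(fm, set)
  obs <- regress_panel(prof, pred, "heterozygosity", adjusted = TRUE)
  expect_equal(null$heterozygosity[1, obs$predictor],
               setNames(obs$r_squared, obs$predictor), tolerance = 1e-12)
})

test_that("multiplicity flags follow Bonferroni and a manual BH walk-through", {
  p <- c(0.001, 0.002, 0.0026, 0.01, 0.04, rep(0.5, 15))
  res <- data.frame(disease = "d", statistic = "het",
                    predictor = sprintf("v%02d", 1:20), empirical_p = p)
  out <- correct_multiplicity(res)
  # Bonferroni at 0.05/20 = 0.0025, strict <
  expect_equal(out$bonferroni_significant, p < 0.0025)
  expect_equal(sum(out$bonferroni_significant), 2)
  # manual BH at q = 0.2: sorted p_(i) <= 0.2 * i / 20 holds through i = 5
  expect_equal(sum(out$fdr_significant), 5)
  expect_equal(which(out$fdr_significant), 1:5)

  ones <- res; ones$empirical_p <- rep(1, 20)
  none <- correct_multiplicity(ones)
  expect_false(any(none$bonferroni_significant))
  expect_false(any(none$fdr_significant))

  expect_warning(correct_multiplicity(res[1:5, ]), "expected")
  # boundary: p = 0.0024 is Bonferroni-significant at 20 tests
  b <- res; b$empirical_p <- c(0.0024, rep(1, 19))
  expect_true(correct_multiplicity(b)$bonferroni_significant[1])
})

test_that("test_against_null ties observed statistics to their nulls", {
  w <- shared_world()
  set <- make_risk_sets(w$matrix, 10, seed = 11)[[1]]
  res <- test_against_null(set, w$matrix, w$predictors,
                           bins = w$bins, baseline = w$baseline,
                           n_sets = 200, seed = 8)
  expect_equal(nrow(res), 20)  # 10 predictors x 2 statistics
  expect_true(all(res$empirical_p >= 0 & res$empirical_p <= 1))
  expect_setequal(unique(res$statistic), c("heterozygosity", "risk_freq"))
})
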