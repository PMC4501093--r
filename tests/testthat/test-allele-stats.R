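test_that("average heterozygosity matches direct substitution", {
  m <- tiny_matrix()
  one <- risk_set("d1", "snpA", "A")
  expect_equal(unname(average_heterozygosity(m, one, "p2")), 0.5)  # p = 0.5
  fixed <- risk_set("d2", "snpC", "G")
  expect_equal(unname(average_heterozygosity(m, fixed, "p1")), 0)  # p = 0
  expect_equal(unname(average_heterozygosity(m, fixed, "p2")), 0)  # p = 1
  pair <- risk_set("d3", c("snpA", "snpB"), c("A", "C"))
  # p = (0.2, 0.4): (2*0.2*0.8 + 2*0.4*0.6)/2 = (0.32 + 0.48)/2
  expect_equal(unname(average_heterozygosity(m, pair, "p1")), 0.40)
})

test_that("average risk frequency honours risk-allele orientation", {
  m <- tiny_matrix()  # designated alleles A, C, G, T
  des <- risk_set("d", "snpA", "A")
  expect_equal(unname(average_risk_frequency(m, des, "p1")), 0.2)
  flipped <- risk_set("d", "snpA", "G")  # non-designated risk allele
  expect_equal(unname(average_risk_frequency(m, flipped, "p1")), 0.8)
  trio <- risk_set("d", c("snpA", "snpB", "snpD"), c("A", "C", "T"))
  # population p2 frequencies: snpA 0.5, snpB 0.5, snpD 0.3 (all designated)
  expect_equal(unname(average_risk_frequency(m, trio, "p2")),
               mean(c(0.5, 0.5, 0.3)))
})

test_that("heterozygosity is flip-invariant while frequency complements", {
  m <- random_matrix(50, 8, seed = 3)
  ids <- rownames(m)[1:10]
  straight <- risk_set("d", ids, rep("A", 10))
  flipped <- risk_set("d", ids, rep("T", 10))
  expect_equal(average_heterozygosity(m, straight),
               average_heterozygosity(m, flipped))
  expect_equal(average_risk_frequency(m, straight) +
                 average_risk_frequency(m, flipped),
               setNames(rep(1, 8), colnames(m)))
})

test_that("genome-wide baseline equals brute-force column means", {
  m <- random_matrix(200, 6, seed = 9)
  b <- genomewide_baseline(m)
  raw <- unclass(m)
  for (j in seq_len(ncol(raw))) {
    expect_equal(b$avg_het_all[j], mean(2 * raw[, j] * (1 - raw[, j])))
    expect_equal(b$avg_freq_all[j], mean(raw[, j]))
  }
  # degenerate cases
  one <- freq_matrix(matrix(0.5, 1, 2, dimnames = list("s", c("a", "b"))))
  expect_equal(genomewide_baseline(one)$avg_het_all, c(0.5, 0.5))
  two <- freq_matrix(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                            dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_equal(genomewide_baseline(two)$avg_het_all, c(0, 0))
  expect_equal(genomewide_baseline(two)$avg_freq_all, c(0.5, 0.5))
})

test_that("adjusted statistics subtract the genome-wide baseline", {
  m <- tiny_matrix()
  whole <- risk_set("all", rownames(m), unname(designated_alleles(m)))
  prof <- allelic_profile(m, whole)
  expect_equal(prof$adj_heterozygosity, rep(0, 3))
  expect_equal(prof$adj_risk_freq, rep(0, 3))

  sub <- risk_set("d", c("snpA", "snpB"), c("A", "C"))
  prof2 <- allelic_profile(m, sub)
  # hand arithmetic for population p1
  base_het <- mean(2 * c(0.2, 0.4, 0.0, 0.9) * (1 - c(0.2, 0.4, 0.0, 0.9)))
  expect_equal(prof2$adj_heterozygosity[1], 0.40 - base_het)
  base_frq <- mean(c(0.2, 0.4, 0.0, 0.9))
  expect_equal(prof2$adj_risk_freq[1], mean(c(0.2, 0.4)) - base_frq)

  # zero baseline (all SNPs fixed) leaves statistics unadjusted
  fixed <- freq_matrix(matrix(c(1, 0, 1, 0), 2, 2, dimnames =
                                list(c("s1", "s2"), c("a", "b"))))
  pf <- allelic_profile(fixed, risk_set("d", "s1", "A"))
  expect_equal(pf$adj_risk_freq, pf$avg_risk_freq - 0.5)
  expect_equal(pf$adj_heterozygosity, pf$avg_heterozygosity)
})

test_that("adjusted_profile rejects mismatched population sets", {
  m <- tiny_matrix()
  prof <- allelic_profile(m, risk_set("d", "snpA", "A"))
  bad <- genomewide_baseline(m)
  bad$population <- c("x", "y", "z")
  expect_error(adjusted_profile(prof, bad), "population")
})

test_that("variance of the mean frequency matches a two-pass oracle", {
  m <- tiny_matrix()
  pair <- risk_set("d", c("snpA", "snpB"), c("A", "C"))
  # equal frequencies give zero variance
  eq <- freq_matrix(matrix(0.3, 2, 2, dimnames =
                             list(c("s1", "s2"), c("a", "b"))))
  v0 <- population_variance_of_mean_freq(eq, risk_set("d", c("s1", "s2")))
  expect_equal(unname(v0), c(0, 0))
  # p = (0, 1): sample variance 0.5, variance of the mean 0.25
  pm <- freq_matrix(matrix(c(0, 1), 2, 1, dimnames =
                             list(c("s1", "s2"), "a")))
  rs <- risk_set("d", c("s1", "s2"))
  expect_equal(unname(population_variance_of_mean_freq(pm, rs)), 0.25)
  expect_equal(unname(population_variance_of_mean_freq(pm, rs,
                                                       type = "sample")), 0.5)
  # random panel vs brute force
  rm <- random_matrix(20, 5, seed = 17)
  ids <- rownames(rm)[1:7]
  set7 <- risk_set("d", ids)
  v <- population_variance_of_mean_freq(rm, set7)
  raw <- unclass(rm)[ids, ]
  for (j in 1:5) {
    mu <- mean(raw[, j])
    expect_equal(unname(v[j]), sum((raw[, j] - mu)^2) / (7 - 1) / 7)
  }
  expect_error(population_variance_of_mean_freq(m, risk_set("d", "snpA")),
               "at least 2")
})

test_that("empty or unresolvable panels raise errors", {
  m <- tiny_matrix()
  expect_error(risk_set("d", character(0)), "at least one")
  ghost <- risk_set("d", "snpZ", "A")
  expect_error(average_heterozygosity(m, ghost), "snpZ")
})

test_that("baseline heterozygosity declines with distance on founder-chain data", {
  w <- shared_world()
  fit <- ols(w$baseline$avg_het_all, w$predictors$distance_km,
             "baseline_het", "distance_km")
  expect_lt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.9)
})
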