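test_that("founder_config validates its parameters", {
  expect_error(founder_config(n_populations = 1), "n_populations")
  expect_error(founder_config(n_snps = 0), "n_snps")
  expect_error(founder_config(effective_size = 1), "effective_size")
  expect_error(founder_config(inter_population_distance_km = 0), "positive")
})

test_that("the simulator is deterministic and bounded", {
  cfg <- founder_config(n_populations = 10, n_snps = 500,
                        effective_size = 50, seed = 99)
  a <- simulate_serial_founder(cfg)
  b <- simulate_serial_founder(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$panel, b$panel)
  expect_true(all(unclass(a$matrix) >= 0 & unclass(a$matrix) <= 1))
})

test_that("a fixed ancestral allele stays fixed along the chain", {
  cfg <- founder_config(n_populations = 2, n_snps = 1, effective_size = 5,
                        ancestral_freq_range = c(1, 1), seed = 1)
  sim <- simulate_serial_founder(cfg)
  expect_true(all(unclass(sim$matrix) == 1))
})

test_that("huge effective size approaches the no-drift limit", {
  cfg <- founder_config(n_populations = 12, n_snps = 300,
                        effective_size = 5e6, seed = 3)
  sim <- simulate_serial_founder(cfg)
  m <- unclass(sim$matrix)
  expect_lt(max(abs(m - m[, 1])), 0.005)
  het <- colMeans(2 * m * (1 - m))
  fit <- ols(het, sim$panel$distance_km)
  expect_lt(abs(fit$slope) * max(sim$panel$distance_km), 0.001)
})

test_that("heterozygosity decays at the closed-form binomial-drift rate", {
  cfg <- founder_config(n_populations = 30, n_snps = 4000,
                        effective_size = 500, seed = 42)
  sim <- simulate_serial_founder(cfg)
  m <- unclass(sim$matrix)
  het <- 2 * m * (1 - m)
  k <- ncol(m) - 1L
  expected <- mean(het[, 1]) * (1 - 1 / (2 * 500))^k
  se <- sd(het[, ncol(m)]) / sqrt(nrow(m))
  expect_lt(abs(mean(het[, ncol(m)]) - expected), 3 * se)
  fit <- ols(colMeans(het), sim$panel$distance_km)
  expect_lt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.9)
})

test_that("climate variables follow their distance loadings", {
  w <- shared_world()
  spec <- data.frame(variable = c("pure", "noisefree", "indep"),
                     distance_loading = c(1, 1, 0),
                     noise_sd = c(0.05, 0, 1))
  cl <- generate_climate(w$panel, spec, seed = 8)
  d <- w$panel$distance_km
  expect_equal(abs(cor(cl$noisefree, d)), 1, tolerance = 1e-12)
  expect_gt(abs(cor(cl$pure, d)), 0.98)
  expect_lt(abs(cor(cl$indep, d)), 0.5)
  # two strongly distance-loaded variables are mutually collinear
  expect_gt(cor(cl$pure, cl$noisefree), 0.98)

  # a zero-loading variable decorrelates from distance as n grows
  big <- data.frame(population = sprintf("p%04d", 1:2000),
                    distance_km = seq(0, 2e4, length.out = 2000))
  cl2 <- generate_climate(big, data.frame(variable = "x",
                                          distance_loading = 0,
                                          noise_sd = 1), seed = 9)
  expect_lt(abs(cor(cl2$x, big$distance_km)), 0.08)

  # default spec carries the nine standard variable labels
  expect_identical(default_climate_spec()$variable,
                   c("latitude", "longitude", "winter_temp_min",
                     "summer_temp_max", "winter_precip", "summer_precip",
                     "winter_radiation", "winter_humidity",
                     "summer_humidity"))
})

test_that("cline injection is the identity at beta 0 and clamps when saturated", {
  w <- shared_world()
  ids <- rownames(w$matrix)[1:5]
  none <- inject_cline(w$matrix, w$climate,
                       cline_spec(ids, "latitude", 0, noise_sd = 0), seed = 1)
  expect_identical(unclass(none), unclass(w$matrix))

  sat <- inject_cline(w$matrix, w$climate,
                      cline_spec(ids, "latitude", 50, noise_sd = 0), seed = 1)
  z <- as.numeric(scale(w$climate$latitude))
  extreme <- unclass(sat)[ids, abs(z) > 0.5]
  expect_true(all(extreme %in% c(0, 1)))

  expect_error(inject_cline(w$matrix, w$climate,
                            cline_spec("nope", "latitude", 0.1)), "nope")
  expect_error(inject_cline(w$matrix, w$climate,
                            cline_spec(ids, "marsquake", 0.1)), "marsquake")
})

test_that("an injected cline makes its driving variable the best predictor", {
  w <- shared_world()
  zero_load <- c("winter_precip", "summer_precip", "winter_humidity")
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    ids <- rownames(w$matrix)[(5 * s):(5 * s + 14)]
    injected <- inject_cline(w$matrix, w$climate,
                             cline_spec(ids, "summer_precip", 0.1), seed = s)
    set <- risk_set("cline", ids)
    prof <- allelic_profile(injected, set,
                            baseline = genomewide_baseline(injected))
    res <- regress_panel(prof, w$predictors, "risk_freq", adjusted = TRUE)
    r2 <- setNames(res$r_squared, res$predictor)
    if (r2[["summer_precip"]] > max(r2[setdiff(zero_load, "summer_precip")]))
      hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("risk panels are disjoint, sized and labelled", {
  w <- shared_world()
  sets <- make_risk_sets(w$matrix, c(15, 7), seed = 2)
  expect_length(sets, 2)
  expect_equal(sets[[1]]$d, 15)
  expect_equal(sets[[2]]$d, 7)
  expect_length(intersect(sets[[1]]$snp_id, sets[[2]]$snp_id), 0)
  expect_false(attr(sets[[1]], "cline"))

  expect_error(make_risk_sets(w$matrix, nrow(w$matrix) + 1, seed = 1),
               "exceed")

  sizes <- disease_panel_sizes()
  expect_length(sizes, 21)
  expect_equal(range(sizes), c(7L, 41L))
  all21 <- make_risk_sets(w$matrix, sizes, labels = names(sizes), seed = 3)
  expect_length(all21, 21)
  ids <- unlist(lapply(all21, `[[`, "snp_id"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(all21$type_2_diabetes$d, 15L)

  ids5 <- rownames(w$matrix)[1:5]
  tagged <- make_risk_sets(w$matrix, c(5, 8), labels = c("cl", "neutral"),
                           cline_assignments = list(cl = ids5), seed = 4)
  expect_true(attr(tagged$cl, "cline"))
  expect_identical(tagged$cl$snp_id, ids5)
  expect_length(intersect(tagged$neutral$snp_id, ids5), 0)
})
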