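#' Configuration for the serial-founder simulator
#'
#' Validated parameter bundle for [simulate_serial_founder()]. Identical
#' configuration and seed give bit-identical output.
#'
#' @param n_populations Number of populations along the founder chain
#'   (>= 2).
#' @param n_snps Number of independent biallelic SNPs (>= 1).
#' @param effective_size Diploid effective size per founding event (>= 2);
#'   each event resamples `2 * effective_size` gametes binomially.
#' @param n_founding_events_per_step Founding events between consecutive
#'   populations (default 1).
#' @param ancestral_freq_range Range of the uniform law for ancestral
#'   frequencies (default `c(0.05, 0.95)`, avoiding immediate fixation).
#' @param inter_population_distance_km Spacing of consecutive populations
#'   along the migration path (default 400 km, giving a chain span on the
#'   order of the out-of-Africa expansion).
#' @param seed Integer seed.
#' @return An object of class `founder_config`.
#' @export
founder_config <- function(n_populations = 60L, n_snps = 20000L,
                           effective_size = 500L,
                           n_founding_events_per_step = 1L,
                           ancestral_freq_range = c(0.05, 0.95),
                           inter_population_distance_km = 400,
                           seed = 1L) {
  if (n_populations < 2L) stop("n_populations must be >= 2", call. = FALSE)
  if (n_snps < 1L) stop("n_snps must be >= 1", call. = FALSE)
  if (effective_size < 2L) stop("effective_size must be >= 2", call. = FALSE)
  if (n_founding_events_per_step < 1L) {
    stop("n_founding_events_per_step must be >= 1", call. = FALSE)
  }
  if (inter_population_distance_km <= 0) {
    stop("inter_population_distance_km must be positive", call. = FALSE)
  }
  stopifnot(length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1L] >= 0, ancestral_freq_range[2L] <= 1,
            ancestral_freq_range[1L] <= ancestral_freq_range[2L])
  structure(list(n_populations = as.integer(n_populations),
                 n_snps = as.integer(n_snps),
                 effective_size = as.integer(effective_size),
                 n_founding_events_per_step = as.integer(n_founding_events_per_step),
                 ancestral_freq_range = as.numeric(ancestral_freq_range),
                 inter_population_distance_km = as.numeric(inter_population_distance_km),
                 seed = as.integer(seed)),
            class = "founder_config")
}

#' Simulate a serial-founder allele-frequency matrix
#'
#' Pure binomial drift along a chain of founding events: population 1 draws
#' ancestral frequencies from the configured uniform law; each subsequent
#' population resamples `2 * effective_size` gametes from its predecessor
#' (repeated for each founding event per step). Expected heterozygosity
#' decays by the factor `1 - 1/(2 * effective_size)` per event, producing
#' the declining-heterozygosity cline that distance regressions detect.
#' There is no mutation, migration or selection.
#'
#' @param config A [founder_config()].
#' @return List with `matrix` (a [freq_matrix()]) and `panel` (data frame
#'   with `population`, `region`, `distance_km`).
#' @export
simulate_serial_founder <- function(config) {
  stopifnot(inherits(config, "founder_config"))
  set.seed(config$seed)
  n <- config$n_snps
  k <- config$n_populations
  gametes <- 2L * config$effective_size
  f <- matrix(0, nrow = n, ncol = k)
  f[, 1L] <- stats::runif(n, config$ancestral_freq_range[1L],
                          config$ancestral_freq_range[2L])
  for (j in seq_len(k - 1L)) {
    p <- f[, j]
    for (e in seq_len(config$n_founding_events_per_step)) {
      p <- stats::rbinom(n, gametes, p) / gametes
    }
    f[, j + 1L] <- p
  }
  pops <- sprintf("pop%02d", seq_len(k))
  rownames(f) <- sprintf("snp%05d", seq_len(n))
  colnames(f) <- pops
  panel <- data.frame(population = pops, region = "synthetic",
                      distance_km = (seq_len(k) - 1L) *
                        config$inter_population_distance_km,
                      stringsAsFactors = FALSE)
  list(matrix = freq_matrix(f), panel = panel)
}

#' Default climate-variable generation spec
#'
#' The nine climate variables with their loadings on standardized distance
#' and residual noise standard deviations. Longitude loads strongly on
#' distance (migration ran mostly across longitudes), latitude and the
#' temperature variables moderately, and the precipitation/humidity
#' variables little or not at all, so that both distance-confounded and
#' distance-independent predictors are available downstream. All variables
#' are on standardized (unitless) scales.
#'
#' @return Data frame with columns `variable`, `distance_loading`,
#'   `noise_sd`.
#' @export
default_climate_spec <- function() {
  data.frame(
    variable = c("latitude", "longitude", "winter_temp_min",
                 "summer_temp_max", "winter_precip", "summer_precip",
                 "winter_radiation", "winter_humidity", "summer_humidity"),
    distance_loading = c(0.4, 0.8, -0.5, 0.3, 0, 0, 0.1, 0, 0.2),
    noise_sd = c(1, 0.6, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic climate table
#'
#' Each variable is `distance_loading * z(distance) + N(0, noise_sd)` per
#' population, where `z(distance)` is the standardized migration distance.
#' A zero loading gives a distance-independent variable.
#'
#' @param panel Data frame with `population` and `distance_km`.
#' @param spec Data frame as returned by [default_climate_spec()].
#' @param seed Integer seed.
#' @return Data frame: `population` plus one column per variable.
#' @export
generate_climate <- function(panel, spec = default_climate_spec(), seed = 1L) {
  if (!all(c("population", "distance_km") %in% names(panel))) {
    stop("panel must have population and distance_km columns", call. = FALSE)
  }
  set.seed(as.integer(seed))
  z <- as.numeric(scale(panel$distance_km))
  out <- data.frame(population = panel$population, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(spec))) {
    noise <- if (spec$noise_sd[i] > 0) {
      stats::rnorm(length(z), 0, spec$noise_sd[i])
    } else 0
    out[[spec$variable[i]]] <- spec$distance_loading[i] * z + noise
  }
  out
}

#' Specify a frequency cline coupled to one climate variable
#'
#' @param snp_ids SNPs to shift.
#' @param variable_name Climate variable driving the cline.
#' @param beta Frequency shift per standard deviation of the variable.
#' @param noise_sd Additional per-SNP, per-population Gaussian noise in
#'   frequency units (default 0.02).
#' @return An object of class `cline_spec`.
#' @export
cline_spec <- function(snp_ids, variable_name, beta, noise_sd = 0.02) {
  structure(list(snp_ids = as.character(snp_ids),
                 variable_name = as.character(variable_name),
                 beta = as.numeric(beta), noise_sd = as.numeric(noise_sd)),
            class = "cline_spec")
}

#' Inject an environmental frequency cline into a matrix
#'
#' For each listed SNP and population j the frequency becomes
#' `clamp(p_ij + beta * z_j + eps, 0, 1)` with `z` the standardized climate
#' variable and `eps ~ N(0, noise_sd)`. Unlisted SNPs are untouched. This is
#' an additive effect generator, not a population-genetic selection model:
#' downstream statistics only see the induced frequency/environment
#' correlation.
#'
#' @param matrix A [freq_matrix()].
#' @param climate Climate table (from [generate_climate()]).
#' @param cline A [cline_spec()].
#' @param seed Integer seed.
#' @return A new [freq_matrix()].
#' @export
inject_cline <- function(matrix, climate, cline, seed = 1L) {
  stopifnot(inherits(matrix, "freq_matrix"), inherits(cline, "cline_spec"))
  if (!cline$variable_name %in% names(climate)) {
    stop("unknown climate variable: ", cline$variable_name, call. = FALSE)
  }
  missing <- setdiff(cline$snp_ids, rownames(matrix))
  if (length(missing)) {
    stop("unknown SNP(s): ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(climate$population), colnames(matrix))) {
    stop("climate populations must match the matrix columns", call. = FALSE)
  }
  set.seed(as.integer(seed))
  z <- as.numeric(scale(climate[[cline$variable_name]]))
  m <- unclass(matrix)
  sub <- sweep(m[cline$snp_ids, , drop = FALSE], 2L, z * cline$beta, "+")
  if (cline$noise_sd > 0) {
    sub <- sub + stats::rnorm(length(sub), 0, cline$noise_sd)
  }
  m[cline$snp_ids, ] <- pmin(pmax(sub, 0), 1)
  freq_matrix(m, designated_alleles(matrix))
}

#' Draw disjoint risk-SNP panels from a matrix
#'
#' Samples disjoint SNP panels of the requested sizes (the risk allele being
#' the designated allele), optionally labelling some panels as coupled to an
#' injected cline via `cline_assignments`.
#'
#' @param matrix A [freq_matrix()].
#' @param sizes Integer vector of panel sizes.
#' @param labels Optional disease labels (default `disease01`, ...).
#' @param cline_assignments Optional named list mapping a disease label to a
#'   character vector of SNP ids that must make up that panel (e.g. the SNPs
#'   given to [inject_cline()]); such panels are marked `cline = TRUE`.
#' @param seed Integer seed.
#' @return Named list of [risk_set()]s; each carries a logical `cline`
#'   attribute.
#' @export
make_risk_sets <- function(matrix, sizes, labels = NULL,
                           cline_assignments = NULL, seed = 1L) {
  stopifnot(inherits(matrix, "freq_matrix"))
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("panel sizes must be positive", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("disease%02d", seq_along(sizes))
  if (length(labels) != length(sizes)) {
    stop("labels must match sizes in length", call. = FALSE)
  }
  fixed <- unlist(cline_assignments, use.names = FALSE)
  pool <- setdiff(rownames(matrix), fixed)
  need <- sum(sizes[!(labels %in% names(cline_assignments))])
  if (need > length(pool)) {
    stop("requested panel sizes exceed the available SNP pool", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- vector("list", length(sizes))
  names(out) <- labels
  for (i in seq_along(sizes)) {
    lab <- labels[i]
    if (!is.null(cline_assignments) && lab %in% names(cline_assignments)) {
      ids <- cline_assignments[[lab]]
      if (length(ids) != sizes[i]) {
        stop("cline assignment for ", lab, " has ", length(ids),
             " SNPs but size ", sizes[i], " was requested", call. = FALSE)
      }
      is_cline <- TRUE
    } else {
      ids <- sample(pool, sizes[i])
      pool <- setdiff(pool, ids)
      is_cline <- FALSE
    }
    rs <- risk_set(lab, ids, unname(designated_alleles(matrix)[ids]))
    attr(rs, "cline") <- is_cline
    out[[lab]] <- rs
  }
  out
}

#' Panel sizes of the 21 disease risk-SNP sets
#'
#' The number of risk SNPs per disease in the 21-disease study design, from
#' biliary liver cirrhosis (41) down to pancreatic cancer (7). Useful for
#' generating synthetic panels with realistic sizes.
#'
#' @return Named integer vector of length 21.
#' @export
disease_panel_sizes <- function() {
  c(biliary_liver_cirrhosis = 41L, alopecia_areata = 41L,
    prostate_cancer = 39L, systemic_lupus_erythematosus = 33L,
    ulcerative_colitis = 32L, type_1_diabetes = 27L, celiac_disease = 26L,
    parkinsons_disease = 25L, crohns_disease = 24L,
    membranous_nephropathy = 20L, systemic_sclerosis = 19L,
    primary_biliary_cirrhosis = 15L, colorectal_cancer = 15L,
    type_2_diabetes = 15L, breast_cancer = 14L, melanoma = 14L,
    rheumatoid_arthritis = 14L, asthma = 13L, neuroblastoma = 10L,
    polycystic_ovary_syndrome = 10L, pancreatic_cancer = 7L)
}
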