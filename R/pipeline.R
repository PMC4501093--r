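# Deterministic per-stage seed substreams from one master seed, kept in
# 32-bit integer range so stages can be rerun independently.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 131 + stage * 7919) %% 2147483647
}

#' Assemble the predictor table (distance plus climate)
#'
#' @param panel Data frame with `population` and `distance_km`.
#' @param climate Climate table (`population` plus variable columns).
#' @return Data frame: `population`, `distance_km`, then the climate
#'   variables.
#' @export
predictor_table <- function(panel, climate) {
  if (!all(c("population", "distance_km") %in% names(panel))) {
    stop("panel must have population and distance_km", call. = FALSE)
  }
  cl <- climate[match(panel$population, climate$population), ]
  if (anyNA(cl$population)) {
    stop("climate rows missing for some populations", call. = FALSE)
  }
  cbind(panel[, c("population", "distance_km")],
        cl[, setdiff(names(cl), "population"), drop = FALSE],
        row.names = NULL)
}

#' Run the full analysis pipeline on in-memory inputs
#'
#' Orchestrates the stages in order: predictor assembly and collinearity
#' report, genome-wide baselines, per-disease allelic profiles, raw
#' regressions on distance (all populations and any requested subsets),
#' adjusted regressions on every predictor, frequency-matched resampling
#' nulls with empirical p-values and multiple-testing flags, per-SNP
#' environmental scores (supplied or surrogate) with ranked p-values, and
#' tail-enrichment permutation tests. Deterministic given `seed`
#' (per-stage substreams are derived from it); when `out_dir` is given
#' every stage's table is written as TSV together with a run manifest, and
#' per-disease null distributions are cached there and reused on rerun.
#'
#' @param matrix A [freq_matrix()].
#' @param panel Population data frame with `population` and `distance_km`
#'   (see [assign_distances()] for computing distances from coordinates).
#' @param climate Climate table.
#' @param risk_sets Named list of [risk_set()]s.
#' @param scores Optional [score_table()]; if `NULL`, surrogate scores are
#'   computed from the matrix and climate via [surrogate_scores()].
#' @param subsets Optional named list of population subsets for additional
#'   raw-on-distance regressions (e.g. excluding a continent).
#' @param n_sets Resampled sets per disease null (default 10000).
#' @param n_perm Permutation sets per enrichment test (default 50000).
#' @param tail_threshold Low-p tail threshold (default 0.05).
#' @param enrichment_cutoff Bonferroni cutoff on permutation p (default
#'   0.00026).
#' @param alpha,fdr_q Passed to [correct_multiplicity()].
#' @param resample_mode `"global"` or `"european"` frequency matching.
#' @param european_populations Population ids used when
#'   `resample_mode = "european"`.
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for TSVs, null cache and
#'   manifest.
#' @return List with `predictors`, `collinearity`, `baseline`, `profiles`,
#'   `distance_regressions`, `empirical_results`, `ranked_pvalues`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(matrix, panel, climate, risk_sets, scores = NULL,
                         subsets = NULL, n_sets = 10000L, n_perm = 50000L,
                         tail_threshold = 0.05, enrichment_cutoff = 0.00026,
                         alpha = 0.05, fdr_q = 0.2,
                         resample_mode = c("global", "european"),
                         european_populations = NULL, seed = 1L,
                         out_dir = NULL) {
  resample_mode <- match.arg(resample_mode)
  t0 <- Sys.time()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "nulls"), showWarnings = FALSE)
  }

  predictors <- predictor_table(panel, climate)
  collin <- predictor_correlations(predictors)
  baseline <- genomewide_baseline(matrix)
  bins <- if (resample_mode == "european") {
    if (is.null(european_populations)) {
      stop("european_populations required for resample_mode = 'european'",
           call. = FALSE)
    }
    bin_by_global_frequency(matrix, european_populations)
  } else {
    bin_by_global_frequency(matrix)
  }

  profiles <- list()
  dist_reg <- list()
  emp <- list()
  for (i in seq_along(risk_sets)) {
    set <- risk_sets[[i]]
    prof <- allelic_profile(matrix, set, baseline = baseline)
    profiles[[set$disease]] <- cbind(disease = set$disease, prof)

    dl <- list(cbind(subset = "all",
                     regress_panel(prof, predictors[, c("population", "distance_km")],
                                   statistic = "heterozygosity",
                                   adjusted = FALSE)),
               cbind(subset = "all",
                     regress_panel(prof, predictors[, c("population", "distance_km")],
                                   statistic = "risk_freq", adjusted = FALSE)))
    for (nm in names(subsets)) {
      dl[[length(dl) + 1L]] <-
        cbind(subset = nm,
              regress_panel(prof, predictors[, c("population", "distance_km")],
                            statistic = "heterozygosity", adjusted = FALSE,
                            subset = subsets[[nm]]))
    }
    dist_reg[[set$disease]] <- cbind(disease = set$disease, do.call(rbind, dl))

    null_seed <- stage_seed(seed, i)
    null <- pipeline_null(set, matrix, predictors, bins, baseline, n_sets,
                          null_seed, out_dir)
    emp[[set$disease]] <- test_against_null(set, matrix, predictors,
                                            baseline = baseline, null = null)
  }
  empirical_results <- correct_multiplicity(do.call(rbind, emp),
                                            alpha = alpha, fdr_q = fdr_q)

  if (is.null(scores)) scores <- surrogate_scores(matrix, climate)
  rp <- ranked_pvalues(scores)
  enr <- enrichment_grid(rp, risk_sets,
                         variables = setdiff(colnames(rp), "distance_km"),
                         n_perm = n_perm, threshold = tail_threshold,
                         seed = stage_seed(seed, length(risk_sets) + 1L))
  enr <- correct_enrichment(enr, cutoff = enrichment_cutoff)

  manifest <- list(seed = as.integer(seed), n_sets = as.integer(n_sets),
                   n_perm = as.integer(n_perm),
                   tail_threshold = tail_threshold,
                   enrichment_cutoff = enrichment_cutoff, alpha = alpha,
                   fdr_q = fdr_q, resample_mode = resample_mode,
                   n_snps = nrow(matrix), n_populations = ncol(matrix),
                   diseases = vapply(risk_sets, `[[`, "", "disease"),
                   r_version = as.character(getRversion()),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))

  out <- list(predictors = predictors, collinearity = collin,
              baseline = baseline,
              profiles = do.call(rbind, c(profiles, make.row.names = FALSE)),
              distance_regressions = do.call(rbind, c(dist_reg,
                                                      make.row.names = FALSE)),
              empirical_results = empirical_results,
              ranked_pvalues = rp, enrichment = enr, manifest = manifest)

  if (!is.null(out_dir)) {
    write_tsv(out$predictors, file.path(out_dir, "predictors.tsv"))
    write_tsv(out$profiles, file.path(out_dir, "allelic_profiles.tsv"))
    write_tsv(out$distance_regressions,
              file.path(out_dir, "distance_regressions.tsv"))
    write_tsv(out$empirical_results,
              file.path(out_dir, "empirical_results.tsv"))
    write_tsv(out$enrichment, file.path(out_dir, "enrichment.tsv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}

# Build (or load from cache) one disease's null distribution. The cache is
# a pair of full-precision TSVs per disease under <out_dir>/nulls/.
pipeline_null <- function(set, matrix, predictors, bins, baseline, n_sets,
                          null_seed, out_dir) {
  if (!is.null(out_dir)) {
    base_path <- file.path(out_dir, "nulls", set$disease)
    het_p <- paste0(base_path, "_heterozygosity.tsv")
    frq_p <- paste0(base_path, "_risk_freq.tsv")
    if (file.exists(het_p) && file.exists(frq_p)) {
      return(structure(list(heterozygosity = read_null_tsv(het_p),
                            risk_freq = read_null_tsv(frq_p),
                            disease = set$disease, n_sets = n_sets,
                            seed = null_seed),
                       class = "null_distribution"))
    }
  }
  null <- build_null(set, matrix, predictors, bins = bins,
                     baseline = baseline, n_sets = n_sets, seed = null_seed)
  if (!is.null(out_dir)) {
    write_null_tsv(null$heterozygosity, het_p)
    write_null_tsv(null$risk_freq, frq_p)
  }
  null
}

write_null_tsv <- function(m, path) {
  df <- as.data.frame(format(m, digits = 17, scientific = TRUE,
                             trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_null_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  as.matrix(df)
}
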