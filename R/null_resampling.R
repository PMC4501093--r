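#' Bin SNPs by global allele frequency
#'
#' Groups every SNP of the matrix into half-open frequency bins
#' \[0, 0.1), ..., \[0.9, 1.0\] by its global allele frequency, the
#' unweighted mean of the designated-allele frequency over populations
#' (optionally a subset, e.g. European populations). The bin pools are the
#' sampling frames for frequency-matched resampling.
#'
#' @param matrix A [freq_matrix()].
#' @param populations Optional population ids over which to average
#'   (default: all populations).
#' @return An object of class `freq_bins`: list with `global_freq` (named
#'   vector), `bin` (integer bin index 1..10 per SNP) and `pools` (list of
#'   SNP-id vectors per bin).
#' @export
bin_by_global_frequency <- function(matrix, populations = NULL) {
  stopifnot(inherits(matrix, "freq_matrix"))
  m <- unclass(matrix)
  if (!is.null(populations)) {
    missing <- setdiff(populations, colnames(m))
    if (length(missing)) {
      stop("unknown population(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- m[, populations, drop = FALSE]
  }
  g <- rowMeans(m)
  edges <- seq(0, 1, by = 0.1)
  bin <- findInterval(g, edges, rightmost.closed = TRUE)
  pools <- split(rownames(m), factor(bin, levels = 1:10))
  structure(list(global_freq = g, bin = stats::setNames(bin, rownames(m)),
                 pools = pools),
            class = "freq_bins")
}

#' Draw one frequency-matched resampled SNP set
#'
#' Replaces each risk SNP by a SNP drawn uniformly from the same global-
#' frequency bin, excluding the disease's own risk SNPs and without
#' duplicates within the set.
#'
#' @param set A [risk_set()].
#' @param bins A [bin_by_global_frequency()] object (built in `global` or
#'   European mode as desired).
#' @return Character vector of `set$d` distinct SNP ids, none in the risk
#'   set, each in the same bin as the risk SNP it replaces.
#' @export
resample_set <- function(set, bins) {
  stopifnot(inherits(set, "risk_set"), inherits(bins, "freq_bins"))
  b <- bins$bin[set$snp_id]
  if (anyNA(b)) {
    stop("risk SNP(s) not present in the binned matrix: ",
         paste(set$snp_id[is.na(b)], collapse = ", "), call. = FALSE)
  }
  out <- character(set$d)
  for (bb in unique(b)) {
    idx <- which(b == bb)
    pool <- setdiff(bins$pools[[bb]], set$snp_id)
    if (length(pool) < length(idx)) {
      stop(sprintf("bin [%0.1f, %0.1f) pool exhausted for disease '%s'",
                   (bb - 1) / 10, bb / 10, set$disease), call. = FALSE)
    }
    out[idx] <- pool[sample.int(length(pool), length(idx))]
  }
  out
}

#' Build frequency-matched null distributions of regression R-squared
#'
#' Draws `n_sets` frequency-matched resampled SNP sets for a disease and,
#' for each set, computes the baseline-adjusted average heterozygosity and
#' average frequency per population and their R-squared against every
#' predictor — the same pipeline applied to the observed panel. The same
#' resampled sets serve all predictors and both allelic statistics, so the
#' per-predictor null distributions are deliberately not independent of one
#' another (they share resampled sets), while nulls for different diseases
#' are built independently.
#'
#' @param set A [risk_set()].
#' @param matrix A [freq_matrix()].
#' @param predictors Data frame: `population` plus one numeric column per
#'   predictor (distance and climate variables).
#' @param bins Optional precomputed [bin_by_global_frequency()] (global or
#'   European mode); computed from `matrix` if omitted.
#' @param baseline Optional precomputed [genomewide_baseline()].
#' @param n_sets Number of resampled sets (default 10000).
#' @param seed Integer seed.
#' @return An object of class `null_distribution`: list with per-statistic
#'   matrices of R-squared values (`n_sets` rows, one column per predictor)
#'   plus `disease`, `n_sets`, `seed`.
#' @export
build_null <- function(set, matrix, predictors, bins = NULL, baseline = NULL,
                       n_sets = 10000L, seed = 1L) {
  stopifnot(inherits(set, "risk_set"), inherits(matrix, "freq_matrix"))
  if (is.null(bins)) bins <- bin_by_global_frequency(matrix)
  if (is.null(baseline)) baseline <- genomewide_baseline(matrix)
  pops <- colnames(matrix)
  pred <- predictors[match(pops, predictors$population), ]
  if (anyNA(pred$population)) {
    stop("predictors missing for some matrix populations", call. = FALSE)
  }
  vars <- setdiff(names(pred), "population")
  X <- as.matrix(pred[, vars, drop = FALSE])

  m <- unclass(matrix)
  H <- 2 * m * (1 - m)
  n_sets <- as.integer(n_sets)
  set.seed(as.integer(seed))
  ids <- vapply(seq_len(n_sets), function(s) resample_set(set, bins),
                character(set$d))
  ids <- if (set$d == 1L) base::matrix(ids, nrow = 1L) else ids  # d x n_sets

  r2 <- null_r2_from_ids(ids, m, H, baseline, X)
  structure(list(heterozygosity = r2$het, risk_freq = r2$frq,
                 disease = set$disease, n_sets = n_sets,
                 seed = as.integer(seed)),
            class = "null_distribution")
}

# Vectorised R^2 of adjusted panel statistics for many SNP sets at once.
# ids: d x n_sets matrix of SNP ids; returns n_sets x n_predictor matrices.
null_r2_from_ids <- function(ids, m, H, baseline, X, chunk = 2000L) {
  d <- nrow(ids); n_sets <- ncol(ids)
  het <- frq <- base::matrix(NA_real_, n_sets, ncol(X),
                             dimnames = list(NULL, colnames(X)))
  for (start in seq(1L, n_sets, by = chunk)) {
    end <- min(start + chunk - 1L, n_sets)
    sel <- as.vector(ids[, start:end, drop = FALSE])  # stacks set by set
    grp <- rep(seq_len(end - start + 1L), each = d)
    ph <- rowsum(H[sel, , drop = FALSE], grp, reorder = TRUE) / d
    pf <- rowsum(m[sel, , drop = FALSE], grp, reorder = TRUE) / d
    adj_h <- sweep(ph, 2L, baseline$avg_het_all)
    adj_f <- sweep(pf, 2L, baseline$avg_freq_all)
    het[start:end, ] <- stats::cor(t(adj_h), X)^2
    frq[start:end, ] <- stats::cor(t(adj_f), X)^2
  }
  list(het = het, frq = frq)
}

#' Empirical p-value of an observed R-squared against its null
#'
#' The fraction of null samples strictly greater than the observed value;
#' ties count as not higher, and 0 is a possible output. Set
#' `plus_one = TRUE` for the (k+1)/(n+1) estimator, which cannot return 0
#' (off by default).
#'
#' @param observed Observed R-squared.
#' @param null Numeric vector of null R-squared samples.
#' @param plus_one Use the (k+1)/(n+1) estimator? Default `FALSE`.
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_p <- function(observed, null, plus_one = FALSE) {
  if (!length(null)) stop("null distribution is empty", call. = FALSE)
  k <- sum(null > observed)
  if (plus_one) (k + 1) / (length(null) + 1) else k / length(null)
}

#' Test one disease's panel against its resampling null
#'
#' Computes the observed adjusted R-squared of both allelic statistics on
#' every predictor and the empirical p-value against a frequency-matched
#' null built by [build_null()].
#'
#' @inheritParams build_null
#' @param null Optional precomputed [build_null()] result (built here if
#'   omitted).
#' @param plus_one Passed to [empirical_p()].
#' @return Data frame with columns `disease`, `statistic`, `predictor`,
#'   `observed_r_squared`, `empirical_p`.
#' @export
test_against_null <- function(set, matrix, predictors, bins = NULL,
                              baseline = NULL, n_sets = 10000L, seed = 1L,
                              null = NULL, plus_one = FALSE) {
  if (is.null(baseline)) baseline <- genomewide_baseline(matrix)
  if (is.null(null)) {
    null <- build_null(set, matrix, predictors, bins = bins,
                       baseline = baseline, n_sets = n_sets, seed = seed)
  }
  profile <- allelic_profile(matrix, set, baseline = baseline)
  out <- list()
  for (statistic in c("heterozygosity", "risk_freq")) {
    obs <- regress_panel(profile, predictors, statistic = statistic,
                         adjusted = TRUE)
    nl <- null[[statistic]]
    p <- vapply(seq_len(nrow(obs)), function(i) {
      empirical_p(obs$r_squared[i], nl[, obs$predictor[i]],
                  plus_one = plus_one)
    }, numeric(1))
    out[[statistic]] <- data.frame(disease = set$disease,
                                   statistic = statistic,
                                   predictor = obs$predictor,
                                   observed_r_squared = obs$r_squared,
                                   empirical_p = p,
                                   stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag significance under Bonferroni and FDR corrections
#'
#' Within each disease, the Bonferroni flag marks empirical p-values below
#' `alpha / m` where `m` is the number of tests for that disease (10
#' predictors x 2 statistics = 20 in the standard design, giving the
#' threshold 0.0025), and the FDR flag applies Benjamini-Hochberg at
#' `fdr_q` across the disease's tests. A disease with a test count other
#' than `expected_tests` raises a warning but is still processed.
#'
#' @param results Data frame from [test_against_null()] (possibly several
#'   diseases stacked).
#' @param alpha Family-wise error rate for Bonferroni (default 0.05).
#' @param fdr_q Benjamini-Hochberg false discovery rate (default 0.2).
#' @param bonferroni_threshold Optional fixed threshold overriding
#'   `alpha / m`.
#' @param expected_tests Expected tests per disease (default 20).
#' @return `results` with logical columns `bonferroni_significant` and
#'   `fdr_significant` added.
#' @export
correct_multiplicity <- function(results, alpha = 0.05, fdr_q = 0.2,
                                 bonferroni_threshold = NULL,
                                 expected_tests = 20L) {
  stopifnot(all(c("disease", "empirical_p") %in% names(results)))
  parts <- split(results, results$disease)
  parts <- lapply(parts, function(g) {
    m <- nrow(g)
    if (m != expected_tests) {
      warning("disease '", g$disease[1L], "' has ", m, " tests, expected ",
              expected_tests, call. = FALSE)
    }
    thr <- if (is.null(bonferroni_threshold)) alpha / m else bonferroni_threshold
    g$bonferroni_significant <- g$empirical_p < thr
    g$fdr_significant <- stats::p.adjust(g$empirical_p, "BH") <= fdr_q
    g
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
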