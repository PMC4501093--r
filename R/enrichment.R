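#' Tail counts of risk and non-risk SNPs
#'
#' Counts SNPs with ranked p-value strictly below the threshold for one
#' variable, partitioned into risk and non-risk SNPs.
#'
#' @param pvals Matrix of ranked p-values from [ranked_pvalues()].
#' @param risk_ids SNP ids of the disease's risk panel (must be scored).
#' @param variable Variable (column) to use.
#' @param threshold Tail threshold on the empirical p-value (default 0.05,
#'   strict `<`).
#' @return Named list with `n_r`, `n_nr` (risk / non-risk SNPs in the
#'   tail) and `N_r`, `N_nr` (risk / non-risk totals among scored SNPs).
#' @export
tail_counts <- function(pvals, risk_ids, variable, threshold = 0.05) {
  if (!is.matrix(pvals) || !nrow(pvals)) {
    stop("empty score table", call. = FALSE)
  }
  if (!variable %in% colnames(pvals)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  missing <- setdiff(risk_ids, rownames(pvals))
  if (length(missing)) {
    stop("risk SNP(s) not scored: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- pvals[, variable]
  is_risk <- rownames(pvals) %in% risk_ids
  in_tail <- p < threshold
  list(n_r = sum(in_tail & is_risk), n_nr = sum(in_tail & !is_risk),
       N_r = sum(is_risk), N_nr = sum(!is_risk))
}

#' Tail enrichment statistic
#'
#' The ratio of the risk/non-risk composition inside the low-p tail to the
#' overall composition: `(n_r / n_nr) / (N_r / N_nr)`. A value of 1 means
#' the tail composition is proportional to the overall composition. When a
#' denominator is zero (`n_nr = 0`, `N_r = 0` or `N_nr = 0`) the statistic
#' is undefined and `NA` is returned rather than an error.
#'
#' @param n_r,n_nr Risk / non-risk SNPs in the tail.
#' @param N_r,N_nr Risk / non-risk totals.
#' @return The enrichment ratio (scale-free), or `NA` when undefined.
#' @examples
#' enrichment_statistic(5, 95, 20, 980)  # ~2.58
#' @export
enrichment_statistic <- function(n_r, n_nr, N_r, N_nr) {
  if (n_nr == 0 || N_r == 0 || N_nr == 0) return(NA_real_)
  (n_r / n_nr) / (N_r / N_nr)
}

#' Permutation test for tail over-representation
#'
#' Draws `n_perm` random SNP sets of the same size as the risk panel
#' (without replacement within a set, from all scored SNPs including the
#' risk SNPs) and reports the fraction of sets containing strictly more
#' low-p SNPs than the observed risk panel.
#'
#' @inheritParams tail_counts
#' @param n_perm Number of permutation sets (default 50000).
#' @param seed Integer seed.
#' @return List with `perm_p`, the observed counts (`n_r`, `n_nr`, `N_r`,
#'   `N_nr`) and `enrichment`.
#' @export
permutation_test <- function(pvals, risk_ids, variable, n_perm = 50000L,
                             threshold = 0.05, seed = 1L) {
  tc <- tail_counts(pvals, risk_ids, variable, threshold)
  n_total <- nrow(pvals)
  if (n_total <= tc$N_r) {
    stop("scored SNP pool must be larger than the risk panel", call. = FALSE)
  }
  in_tail <- pvals[, variable] < threshold
  set.seed(as.integer(seed))
  n_perm <- as.integer(n_perm)
  counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    counts[i] <- sum(in_tail[sample.int(n_total, tc$N_r)])
  }
  list(perm_p = sum(counts > tc$n_r) / n_perm,
       n_r = tc$n_r, n_nr = tc$n_nr, N_r = tc$N_r, N_nr = tc$N_nr,
       enrichment = enrichment_statistic(tc$n_r, tc$n_nr, tc$N_r, tc$N_nr))
}

#' Enrichment grid over diseases and variables
#'
#' Runs [permutation_test()] for every disease x variable combination and
#' returns a tidy results table.
#'
#' @param pvals Matrix of ranked p-values from [ranked_pvalues()].
#' @param risk_sets Named list of [risk_set()]s.
#' @param variables Variables to test (default all columns of `pvals`).
#' @param n_perm,threshold,seed Passed to [permutation_test()]; the seed is
#'   advanced deterministically per combination.
#' @return Data frame: `disease`, `variable`, `n_r`, `n_nr`, `N_r`,
#'   `N_nr`, `enrichment`, `perm_p`.
#' @export
enrichment_grid <- function(pvals, risk_sets, variables = colnames(pvals),
                            n_perm = 50000L, threshold = 0.05, seed = 1L) {
  rows <- list()
  k <- 0L
  for (set in risk_sets) {
    for (v in variables) {
      k <- k + 1L
      pt <- permutation_test(pvals, set$snp_id, v, n_perm = n_perm,
                             threshold = threshold,
                             seed = as.integer(seed) + k)
      rows[[k]] <- data.frame(disease = set$disease, variable = v,
                              n_r = pt$n_r, n_nr = pt$n_nr, N_r = pt$N_r,
                              N_nr = pt$N_nr, enrichment = pt$enrichment,
                              perm_p = pt$perm_p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag significant enrichment after Bonferroni correction
#'
#' Marks grid cells with permutation p strictly below the cutoff. The
#' default cutoff 0.00026 corresponds to a Bonferroni correction over a
#' 21-disease x 9-variable grid (~0.05/189); override for other designs.
#'
#' @param results Data frame from [enrichment_grid()].
#' @param cutoff Significance cutoff on `perm_p` (default 0.00026).
#' @return `results` with a logical `significant` column added.
#' @export
correct_enrichment <- function(results, cutoff = 0.00026) {
  stopifnot("perm_p" %in% names(results))
  results$significant <- results$perm_p < cutoff
  results
}
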