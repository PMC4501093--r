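# Risk-allele-oriented frequencies for a panel: flip p -> 1 - p where the
# risk allele is not the matrix's designated allele. Unknown orientation
# (NA risk allele) is treated as designated.
risk_frequencies <- function(matrix, set) {
  stopifnot(inherits(matrix, "freq_matrix"), inherits(set, "risk_set"))
  missing <- setdiff(set$snp_id, rownames(matrix))
  if (length(missing)) {
    stop("risk SNP(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(matrix)[set$snp_id, , drop = FALSE]
  des <- designated_alleles(matrix)[set$snp_id]
  flip <- !is.na(set$risk_allele) & set$risk_allele != des
  if (any(flip)) p[flip, ] <- 1 - p[flip, ]
  p
}

#' Average heterozygosity of a risk-SNP panel per population
#'
#' For a panel of d SNPs, the mean over SNPs of `2 * p * (1 - p)`, where p is
#' the risk-allele frequency in the population (orientation does not affect
#' 2pq). Values lie in \[0, 0.5\].
#'
#' @param matrix A [freq_matrix()].
#' @param set A [risk_set()].
#' @param population Optional population id(s); default all populations.
#' @return Named numeric vector of average heterozygosities.
#' @export
average_heterozygosity <- function(matrix, set, population = NULL) {
  p <- risk_frequencies(matrix, set)
  if (!is.null(population)) p <- p[, population, drop = FALSE]
  colMeans(2 * p * (1 - p))
}

#' Average risk-allele frequency of a panel per population
#'
#' The mean over the panel's d SNPs of the risk-allele frequency
#' (complemented where the risk allele is the non-designated allele).
#'
#' @inheritParams average_heterozygosity
#' @return Named numeric vector of average risk-allele frequencies.
#' @export
average_risk_frequency <- function(matrix, set, population = NULL) {
  p <- risk_frequencies(matrix, set)
  if (!is.null(population)) p <- p[, population, drop = FALSE]
  colMeans(p)
}

#' Genome-wide baseline statistics per population
#'
#' Means over ALL SNPs in the matrix of `2pq` and of the designated-allele
#' frequency, per population. These baselines capture the drift signature of
#' population structure and are subtracted from panel statistics by
#' [allelic_profile()].
#'
#' @param matrix A [freq_matrix()].
#' @return Data frame with columns `population`, `avg_het_all`,
#'   `avg_freq_all`.
#' @export
genomewide_baseline <- function(matrix) {
  stopifnot(inherits(matrix, "freq_matrix"))
  if (!nrow(matrix)) stop("empty matrix", call. = FALSE)
  m <- unclass(matrix)
  data.frame(population = colnames(m),
             avg_het_all = colMeans(2 * m * (1 - m)),
             avg_freq_all = colMeans(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-population allelic profile of a risk-SNP panel
#'
#' Computes average heterozygosity and average risk-allele frequency of the
#' panel, and their baseline-adjusted versions (panel statistic minus the
#' genome-wide statistic from all SNPs). The subtraction removes the
#' variance accounted for by drift, so adjusted statistics can be regressed
#' on environmental variables.
#'
#' @param matrix A [freq_matrix()].
#' @param set A [risk_set()].
#' @param baseline Optional precomputed [genomewide_baseline()] (computed
#'   from `matrix` if omitted).
#' @return Data frame with columns `population`, `avg_heterozygosity`,
#'   `avg_risk_freq`, `adj_heterozygosity`, `adj_risk_freq`.
#' @export
allelic_profile <- function(matrix, set, baseline = NULL) {
  if (is.null(baseline)) baseline <- genomewide_baseline(matrix)
  het <- average_heterozygosity(matrix, set)
  frq <- average_risk_frequency(matrix, set)
  if (!identical(names(het), as.character(baseline$population))) {
    stop("baseline populations do not match the matrix", call. = FALSE)
  }
  data.frame(population = names(het),
             avg_heterozygosity = unname(het),
             avg_risk_freq = unname(frq),
             adj_heterozygosity = unname(het) - baseline$avg_het_all,
             adj_risk_freq = unname(frq) - baseline$avg_freq_all,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjust a profile against a genome-wide baseline
#'
#' @param profile Data frame with `population`, `avg_heterozygosity`,
#'   `avg_risk_freq` (e.g. the raw columns of [allelic_profile()]).
#' @param baseline A [genomewide_baseline()] data frame.
#' @return `profile` with `adj_heterozygosity` and `adj_risk_freq` columns
#'   (re)computed.
#' @export
adjusted_profile <- function(profile, baseline) {
  if (!setequal(profile$population, baseline$population) ||
      nrow(profile) != nrow(baseline)) {
    stop("profile and baseline population sets differ", call. = FALSE)
  }
  b <- baseline[match(profile$population, baseline$population), ]
  profile$adj_heterozygosity <- profile$avg_heterozygosity - b$avg_het_all
  profile$adj_risk_freq <- profile$avg_risk_freq - b$avg_freq_all
  profile
}

#' Variance of the panel-mean risk-allele frequency per population
#'
#' Sample variance across the panel's d risk-allele frequencies; by default
#' divided by d to give the variance of the mean, whose inverses serve as
#' weights in [wls()] regressions. Set `type = "sample"` for the raw sample
#' variance.
#'
#' @inheritParams average_heterozygosity
#' @param type `"mean"` (sample variance / d, default) or `"sample"`.
#' @return Named numeric vector of variances.
#' @export
population_variance_of_mean_freq <- function(matrix, set, population = NULL,
                                             type = c("mean", "sample")) {
  type <- match.arg(type)
  if (set$d < 2L) stop("panel must contain at least 2 SNPs", call. = FALSE)
  p <- risk_frequencies(matrix, set)
  if (!is.null(population)) p <- p[, population, drop = FALSE]
  v <- apply(p, 2L, stats::var)
  if (type == "mean") v <- v / set$d
  v
}
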