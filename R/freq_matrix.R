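#' Construct a per-population allele-frequency matrix
#'
#' The substrate of every statistic in the package: one row per SNP, one
#' column per population, each cell the frequency of the SNP's designated
#' allele in that population. All frequencies must lie in \[0, 1\] and no
#' cell may be missing; validation fails fast rather than imputing.
#'
#' @param freq Numeric matrix (SNPs x populations) with rownames (SNP ids)
#'   and colnames (population ids).
#' @param designated_allele Character vector, one base label per SNP (the
#'   allele whose frequency is stored). Defaults to `"A"` for every SNP.
#' @return An object of class `freq_matrix` (a numeric matrix with a
#'   `designated_allele` attribute).
#' @export
freq_matrix <- function(freq, designated_allele = NULL) {
  if (!is.matrix(freq) || !is.numeric(freq)) {
    stop("freq must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(freq)) || is.null(colnames(freq))) {
    stop("freq must have SNP rownames and population colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(freq))) {
    stop("duplicate SNP ids in matrix", call. = FALSE)
  }
  if (anyNA(freq)) stop("missing frequencies are not allowed", call. = FALSE)
  if (any(freq < 0 | freq > 1)) {
    bad <- which(freq < 0 | freq > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("frequency out of [0, 1] at SNP '%s', population '%s'",
                 rownames(freq)[bad[1L]], colnames(freq)[bad[2L]]),
         call. = FALSE)
  }
  if (is.null(designated_allele)) {
    designated_allele <- rep("A", nrow(freq))
  }
  if (length(designated_allele) != nrow(freq)) {
    stop("designated_allele must have one entry per SNP", call. = FALSE)
  }
  structure(freq,
            designated_allele = stats::setNames(as.character(designated_allele),
                                                rownames(freq)),
            class = c("freq_matrix", "matrix", "array"))
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix> %d SNPs x %d populations\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Designated alleles of a frequency matrix
#' @param x A [freq_matrix()].
#' @return Named character vector, one allele label per SNP.
#' @export
designated_alleles <- function(x) {
  stopifnot(inherits(x, "freq_matrix"))
  attr(x, "designated_allele")
}

#' Read a frequency matrix from TSV
#'
#' Expected header: `snp_id`, `designated_allele`, then one column per
#' population. Frequencies are validated to \[0, 1\]; population order is
#' preserved.
#'
#' @param path Path to a tab-separated file.
#' @return A [freq_matrix()].
#' @export
read_frequency_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "designated_allele")
  if (!all(need %in% names(df)[1:2])) {
    stop("frequency matrix file must start with columns snp_id, designated_allele",
         call. = FALSE)
  }
  pops <- setdiff(names(df), need)
  if (!length(pops)) stop("no population columns found", call. = FALSE)
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id in ", path, ": ",
         df$snp_id[anyDuplicated(df$snp_id)], call. = FALSE)
  }
  m <- as.matrix(df[, pops, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric frequency cell in ", path, call. = FALSE)
  bad <- which(m < 0 | m > 1 | is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid frequency at row %d (snp '%s'), column '%s' in %s",
                 bad[1L, 1L], df$snp_id[bad[1L, 1L]], pops[bad[1L, 2L]], path),
         call. = FALSE)
  }
  rownames(m) <- df$snp_id
  freq_matrix(m, df$designated_allele)
}

#' Write a frequency matrix to TSV
#' @param x A [freq_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(x, path) {
  stopifnot(inherits(x, "freq_matrix"))
  df <- data.frame(snp_id = rownames(x),
                   designated_allele = unname(designated_alleles(x)),
                   as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a disease risk-SNP set
#'
#' One disease's risk SNPs with their risk-allele orientation. When the risk
#' allele differs from the matrix's designated allele the frequency used for
#' that SNP is `1 - p`.
#'
#' @param disease Disease label.
#' @param snp_id Character vector of SNP ids.
#' @param risk_allele Character vector of risk-allele base labels (same
#'   length as `snp_id`).
#' @return An object of class `risk_set` with fields `disease`, `snp_id`,
#'   `risk_allele` and panel size `d`.
#' @export
risk_set <- function(disease, snp_id, risk_allele = NULL) {
  snp_id <- as.character(snp_id)
  if (!length(snp_id)) stop("risk set must contain at least one SNP", call. = FALSE)
  if (anyDuplicated(snp_id)) stop("duplicate SNP in risk set", call. = FALSE)
  if (is.null(risk_allele)) risk_allele <- rep(NA_character_, length(snp_id))
  if (length(risk_allele) != length(snp_id)) {
    stop("risk_allele must match snp_id in length", call. = FALSE)
  }
  structure(list(disease = as.character(disease), snp_id = snp_id,
                 risk_allele = as.character(risk_allele),
                 d = length(snp_id)),
            class = "risk_set")
}

#' @export
print.risk_set <- function(x, ...) {
  cat(sprintf("<risk_set> %s: %d SNPs\n", x$disease, x$d))
  invisible(x)
}

#' Read risk-SNP sets from TSV
#'
#' Expected columns: `disease`, `snp_id`, `risk_allele`. Rows are grouped
#' into one [risk_set()] per disease. If a matrix is supplied, risk SNPs
#' absent from it are dropped with a warning (mirroring the exclusion of
#' SNPs not present in both data sets).
#'
#' @param path Path to a tab-separated file.
#' @param matrix Optional [freq_matrix()] used to drop unknown SNPs.
#' @return Named list of [risk_set()]s.
#' @export
read_risk_sets <- function(path, matrix = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("disease", "snp_id", "risk_allele")
  if (!all(need %in% names(df))) {
    stop("risk set file must have columns disease, snp_id, risk_allele",
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("disease", "snp_id")])) {
    stop("duplicate (disease, snp_id) row in ", path, call. = FALSE)
  }
  if (!is.null(matrix)) {
    known <- df$snp_id %in% rownames(matrix)
    if (any(!known)) {
      warning(sum(!known), " risk SNP(s) absent from the frequency matrix ",
              "were excluded: ",
              paste(utils::head(df$snp_id[!known], 5L), collapse = ", "),
              call. = FALSE)
      df <- df[known, , drop = FALSE]
    }
  }
  out <- lapply(split(df, df$disease), function(g) {
    risk_set(g$disease[1L], g$snp_id, g$risk_allele)
  })
  out[order(names(out))]
}

#' Write risk-SNP sets to TSV
#' @param sets List of [risk_set()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(disease = s$disease, snp_id = s$snp_id,
               risk_allele = s$risk_allele, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population panel (coordinates and regions) from TSV
#'
#' Expected columns: `population`, `region`, `latitude`, `longitude`;
#' an optional `distance_km` column is kept if present.
#' @param path Path to a tab-separated file.
#' @return Data frame.
#' @export
read_populations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "region", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("population file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a climate table from TSV
#'
#' Expected columns: `population` then one numeric column per climate
#' variable.
#' @param path Path to a tab-separated file.
#' @return Data frame.
#' @export
read_climate <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"population" %in% names(df)) {
    stop("climate file must have a population column", call. = FALSE)
  }
  df
}

#' Write a plain data frame to TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
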