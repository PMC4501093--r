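#' Construct a per-SNP environmental-association score table
#'
#' Bayes-factor-style scores, one row per SNP and one column per
#' environmental variable. Scores must be non-negative and finite.
#'
#' @param scores Numeric matrix (SNPs x variables) with rownames (SNP ids)
#'   and colnames (variable labels).
#' @param panel Optional ascertainment-panel label.
#' @param run Optional run identifier.
#' @return An object of class `score_table`.
#' @export
score_table <- function(scores, panel = NA_character_, run = NA_character_) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("scores must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores must have SNP rownames and variable colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(scores))) {
    stop("duplicate SNP ids in score table", call. = FALSE)
  }
  if (anyNA(scores) || any(!is.finite(scores)) || any(scores < 0)) {
    stop("scores must be non-negative and finite", call. = FALSE)
  }
  structure(list(scores = scores, panel = as.character(panel),
                 run = as.character(run)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d SNPs x %d variables (panel %s, run %s)\n",
              nrow(x$scores), ncol(x$scores), x$panel, x$run))
  invisible(x)
}

#' Read a whitespace-delimited score table with a SNP-id sidecar
#'
#' The score file carries one row per SNP and one numeric column per
#' variable (no header), as produced by Bayes-factor scans; SNP identifiers
#' come from a sidecar file with one id per line, in row order.
#'
#' @param path Path to the whitespace-delimited score file.
#' @param snp_ids_path Path to the sidecar SNP-id list.
#' @param variables Optional variable labels (default `var1`, `var2`, ...).
#' @param panel,run Labels stored on the table.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, snp_ids_path, variables = NULL,
                             panel = NA_character_, run = NA_character_) {
  if (missing(snp_ids_path) || is.null(snp_ids_path)) {
    stop("a SNP-id sidecar file is required", call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(fields)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("ragged score row at line ", bad, " of ", path, call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1L] / lens[1L])
    stop("non-numeric score cell at line ", bad, " of ", path, call. = FALSE)
  }
  m <- base::matrix(vals, nrow = length(fields), byrow = TRUE)
  ids <- readLines(snp_ids_path)
  ids <- ids[nzchar(trimws(ids))]
  if (length(ids) != nrow(m)) {
    stop("sidecar has ", length(ids), " ids but score file has ", nrow(m),
         " rows", call. = FALSE)
  }
  if (is.null(variables)) variables <- paste0("var", seq_len(ncol(m)))
  rownames(m) <- ids
  colnames(m) <- variables
  score_table(m, panel = panel, run = run)
}

#' Write a score table plus SNP-id sidecar
#' @param x A [score_table()].
#' @param path Output path for the whitespace-delimited scores.
#' @param snp_ids_path Output path for the SNP-id sidecar.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x, path, snp_ids_path) {
  stopifnot(inherits(x, "score_table"))
  utils::write.table(x$scores, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(rownames(x$scores), snp_ids_path)
  invisible(path)
}

#' Average score tables over runs
#'
#' Element-wise arithmetic mean of two or more runs over the same SNPs and
#' variables (run this before combining panels and ranking).
#'
#' @param tables List of [score_table()]s with identical SNP ids and
#'   variables.
#' @return A [score_table()].
#' @export
average_runs <- function(tables) {
  if (length(tables) < 2L) stop("need at least 2 runs", call. = FALSE)
  ref <- tables[[1L]]$scores
  for (t in tables[-1L]) {
    if (!identical(dimnames(t$scores), dimnames(ref))) {
      stop("runs differ in SNP ids or variables", call. = FALSE)
    }
  }
  avg <- Reduce(`+`, lapply(tables, `[[`, "scores")) / length(tables)
  score_table(avg, panel = tables[[1L]]$panel, run = "averaged")
}

#' Combine score tables from disjoint ascertainment panels
#'
#' Row-concatenates tables with identical variables and disjoint SNP sets
#' into one table (run after [average_runs()], before [ranked_pvalues()]).
#'
#' @param tables List of [score_table()]s.
#' @return A [score_table()].
#' @export
combine_panels <- function(tables) {
  if (length(tables) < 2L) stop("need at least 2 panels", call. = FALSE)
  vars <- colnames(tables[[1L]]$scores)
  for (t in tables[-1L]) {
    if (!identical(colnames(t$scores), vars)) {
      stop("panels differ in variables", call. = FALSE)
    }
  }
  ids <- unlist(lapply(tables, function(t) rownames(t$scores)))
  if (anyDuplicated(ids)) {
    stop("duplicate SNP id across panels: ", ids[anyDuplicated(ids)],
         call. = FALSE)
  }
  score_table(do.call(rbind, lapply(tables, `[[`, "scores")),
              panel = "combined", run = tables[[1L]]$run)
}

#' Ranked empirical p-values from a score table
#'
#' Per variable, a SNP's p-value is the fraction of SNPs whose score is at
#' least as large: `p_i = #\{k : score_k >= score_i\} / N`. Ties share the
#' larger count (the conservative convention), the top SNP gets `1/N`, and
#' the result is invariant under any strictly increasing transform of the
#' scores.
#'
#' @param table A [score_table()].
#' @return Numeric matrix (SNPs x variables) of p-values in (0, 1\].
#' @export
ranked_pvalues <- function(table) {
  stopifnot(inherits(table, "score_table"))
  s <- table$scores
  n <- nrow(s)
  apply(s, 2L, function(x) rank(-x, ties.method = "max") / n)
}

#' Correlation-based surrogate environmental scores
#'
#' A per-SNP, per-variable association score for synthetic data: the
#' absolute Pearson correlation of the SNP's frequencies with the climate
#' variable across populations, mapped monotonically onto a positive
#' Bayes-factor-like scale `(1 + |r|) / (1 - |r| + eps)`. A SNP with
#' constant frequencies scores 0. Only the ranks matter downstream, so the
#' choice of monotone map is immaterial.
#'
#' @param matrix A [freq_matrix()].
#' @param climate Climate table (`population` plus variable columns) with
#'   populations matching the matrix.
#' @return A [score_table()].
#' @export
surrogate_scores <- function(matrix, climate) {
  stopifnot(inherits(matrix, "freq_matrix"))
  if (!identical(as.character(climate$population), colnames(matrix))) {
    stop("climate populations must match the matrix columns", call. = FALSE)
  }
  vars <- setdiff(names(climate), "population")
  m <- unclass(matrix)
  X <- as.matrix(climate[, vars, drop = FALSE])
  r <- suppressWarnings(stats::cor(t(m), X))  # NA for constant SNP rows
  a <- abs(r)
  s <- (1 + a) / (1 - a + .Machine$double.eps)
  s[is.na(s)] <- 0
  dimnames(s) <- list(rownames(m), vars)
  score_table(s, panel = "surrogate", run = "surrogate")
}
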