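#' Load gene intervals from refFlat or BED
#'
#' Parses gene records into 0-based half-open intervals. refFlat columns
#' follow the published layout (geneName, name, chrom, strand, txStart,
#' txEnd, ...; txStart/txEnd already 0-based half-open); BED is read as
#' chrom, start, end, name(, score, strand). Multiple isoforms of one
#' symbol are merged to the min-start/max-end envelope per (symbol,
#' chromosome). Chromosome names are normalized by stripping a leading
#' "chr".
#'
#' @param path Path to the gene file.
#' @param format `"refFlat"` or `"BED"`.
#' @return Data frame with columns `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
load_genes <- function(path, format = c("refFlat", "BED")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  min_cols <- if (format == "refFlat") 6L else 4L
  lens <- lengths(fields)
  if (any(lens < min_cols)) {
    stop("malformed ", format, " line ", which(lens < min_cols)[1L], " in ",
         path, call. = FALSE)
  }
  if (format == "refFlat") {
    df <- data.frame(symbol = vapply(fields, `[[`, "", 1L),
                     chrom = vapply(fields, `[[`, "", 3L),
                     strand = vapply(fields, `[[`, "", 4L),
                     start = as.numeric(vapply(fields, `[[`, "", 5L)),
                     end = as.numeric(vapply(fields, `[[`, "", 6L)),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(symbol = vapply(fields, `[[`, "", 4L),
                     chrom = vapply(fields, `[[`, "", 1L),
                     strand = vapply(fields, function(f)
                       if (length(f) >= 6L) f[[6L]] else "*", ""),
                     start = as.numeric(vapply(fields, `[[`, "", 2L)),
                     end = as.numeric(vapply(fields, `[[`, "", 3L)),
                     stringsAsFactors = FALSE)
  }
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("non-numeric coordinate in ", path, " line ",
         which(is.na(df$start) | is.na(df$end))[1L], call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    stop("start >= end at line ", which(df$start >= df$end)[1L], " in ",
         path, call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  # merge isoforms to one envelope interval per (symbol, chromosome)
  key <- paste(df$symbol, df$chrom, sep = "\r")
  merged <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(symbol = g$symbol[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start), ]
  rownames(merged) <- NULL
  merged
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Map SNPs to nearby genes
#'
#' A SNP is genic if it lies within `window` bp of a gene's merged
#' interval, i.e. inside `[start - window, end + window)` in 0-based
#' half-open coordinates; `window = 0` reduces to strict gene-body
#' overlap. Strand is ignored. Chromosome naming conventions ("chr1" vs
#' "1") are normalized, with a warning when the two inputs differ.
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `position`
#'   (1-based base-pair position, as in common SNP tables).
#' @param genes Data frame from [load_genes()].
#' @param window Flanking distance in bp (default 10000).
#' @return Named list mapping each `snp_id` to a character vector of gene
#'   symbols (empty vector = intergenic).
#' @export
genic_snps <- function(snps, genes, window = 10000) {
  need <- c("snp_id", "chrom", "position")
  miss <- setdiff(need, names(snps))
  if (length(miss)) {
    stop("snps missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(snps$position < 1)) stop("positions must be >= 1", call. = FALSE)
  snp_chr <- normalize_chrom(snps$chrom)
  if (!identical(sort(unique(as.character(snps$chrom))),
                 sort(unique(snp_chr))) ||
      !identical(sort(unique(as.character(genes$chrom))),
                 sort(unique(normalize_chrom(genes$chrom))))) {
    warning("chromosome names normalized (leading 'chr' stripped)",
            call. = FALSE)
  }
  gene_chr <- normalize_chrom(genes$chrom)
  # 0-based half-open [start - w, end + w) -> 1-based closed [start-w+1, end+w]
  g <- GenomicRanges::GRanges(
    seqnames = gene_chr,
    ranges = IRanges::IRanges(start = genes$start - window + 1,
                              end = genes$end + window))
  s <- GenomicRanges::GRanges(
    seqnames = snp_chr,
    ranges = IRanges::IRanges(start = snps$position, width = 1))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(s, g))
  out <- stats::setNames(vector("list", nrow(snps)), snps$snp_id)
  for (i in seq_len(nrow(snps))) out[[i]] <- character(0)
  if (length(hits)) {
    byq <- split(genes$symbol[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    for (q in names(byq)) out[[as.integer(q)]] <- unique(byq[[q]])
  }
  out
}

#' Tidy table of SNP-to-gene assignments
#'
#' @inheritParams genic_snps
#' @return Data frame with `snp_id`, `genic` (logical) and `genes`
#'   (semicolon-joined symbols, empty for intergenic SNPs).
#' @export
genic_table <- function(snps, genes, window = 10000) {
  mp <- genic_snps(snps, genes, window)
  data.frame(snp_id = names(mp),
             genic = lengths(mp) > 0L,
             genes = vapply(mp, paste, "", collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}
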