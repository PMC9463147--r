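# Readers/writers for the tabular formats the pipeline touches, plus the
# coordinate and missing-value conventions used throughout.
#
# Conventions: internal segment coordinates are 0-based half-open; the
# canonical on-disk dialect is tab-separated UTF-8 with a header row and "."
# for missing values. VCF positions stay 1-based (the format owns them).

.MISSING <- "."

#' Read a tab-separated table in the canonical dialect
#'
#' Missing values are encoded as "." on disk.
#'
#' @param path file path.
#' @param colClasses optional named colClasses vector passed through.
#' @return data.frame with character NA for missing fields.
#' @export
read_tsv_canonical <- function(path, colClasses = NA) {
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = .MISSING,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", colClasses = colClasses)
}

#' Write a table in the canonical dialect (tab-separated, "." for missing)
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tsv_canonical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = .MISSING,
                     row.names = FALSE)
  invisible(path)
}

#' Read somatic mutation calls
#'
#' Reads simple somatic mutations (SSMs) from a VCF 4.x file (allelic depths
#' taken from the per-sample \code{AD} field) or from a canonical TSV with
#' columns \code{sample_id, chrom, pos, ref, alt, ref_depth, alt_depth, gene,
#' impact} (and optionally \code{vaf}). The variant allele fraction (VAF) is
#' recomputed from depths whenever depths are present; a TSV row carrying an
#' explicit \code{vaf} but no depths keeps the given value. Records whose
#' depths cannot be parsed or whose total depth is zero are dropped with a
#' warning giving the count.
#'
#' @param path path to a VCF or TSV file.
#' @param format "auto" (by extension), "vcf" or "tsv".
#' @param sample_id sample id to assign when the file carries none
#'   (single-sample VCF without a meaningful column name, or TSV without a
#'   sample_id column).
#' @return data.frame of mutation calls, one row per (sample, chrom, pos,
#'   ref, alt), with columns sample_id, chrom, pos (1-based), ref, alt,
#'   ref_depth, alt_depth, gene, impact (logical), vaf.
#' @export
read_mutations <- function(path, format = c("auto", "vcf", "tsv"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    calls <- .read_mutations_vcf(path, sample_id)
  } else {
    calls <- .read_mutations_tsv(path, sample_id)
  }
  .validate_mutations(calls)
}

.read_mutations_vcf <- function(path, sample_id = NULL) {
  if (file.size(path) == 0L) {
    warning("empty mutation file: ", path)
    return(.empty_mutations())
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warning("no variant records in ", path)
    return(.empty_mutations())
  }
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad)) stop("VCF has no AD (allelic depth) field: ", path)
  samples <- colnames(ad)
  gene <- .vcf_info_field(vcf, "GENE")
  impact <- .vcf_info_field(vcf, "IMPACT")
  out <- do.call(rbind, lapply(seq_along(samples), function(j) {
    parts <- strsplit(ad[, j], ",", fixed = TRUE)
    rd <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    adp <- suppressWarnings(as.integer(vapply(parts, function(x)
      if (length(x) >= 2L) x[2L] else NA_character_, "")))
    data.frame(
      sample_id = if (is.null(sample_id)) samples[j] else sample_id,
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      ref_depth = rd, alt_depth = adp,
      gene = if (is.null(gene)) NA_character_ else gene,
      impact = if (is.null(impact)) NA else toupper(impact) %in%
        c("1", "TRUE", "HIGH", "MODERATE"),
      stringsAsFactors = FALSE)
  }))
  n_bad <- sum(is.na(out$ref_depth) | is.na(out$alt_depth) |
                 (out$ref_depth + out$alt_depth) <= 0L)
  if (n_bad > 0L) {
    warning(n_bad, " record(s) dropped: unparseable or zero depth")
    out <- out[!(is.na(out$ref_depth) | is.na(out$alt_depth) |
                   (out$ref_depth + out$alt_depth) <= 0L), , drop = FALSE]
  }
  out$vaf <- out$alt_depth / (out$ref_depth + out$alt_depth)
  out
}

.vcf_info_field <- function(vcf, key) {
  val <- tryCatch(vcfR::extract.info(vcf, element = key),
                  error = function(e) NULL)
  if (is.null(val) || all(is.na(val))) NULL else val
}

.read_mutations_tsv <- function(path, sample_id = NULL) {
  if (file.size(path) == 0L) {
    warning("empty mutation file: ", path)
    return(.empty_mutations())
  }
  # ref/alt must never be type-sniffed ("T" is a base, not a logical)
  df <- read_tsv_canonical(path,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character"))
  if (nrow(df) == 0L) {
    warning("no mutation records in ", path)
    return(.empty_mutations())
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
  if (!"sample_id" %in% names(df))
    df$sample_id <- if (is.null(sample_id)) "sample" else sample_id
  for (col in c("ref_depth", "alt_depth", "gene", "impact", "vaf"))
    if (!col %in% names(df)) df[[col]] <- NA
  df$pos <- as.integer(df$pos)
  df$ref_depth <- suppressWarnings(as.integer(df$ref_depth))
  df$alt_depth <- suppressWarnings(as.integer(df$alt_depth))
  df$impact <- as.logical(df$impact)
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  have_depth <- !is.na(df$ref_depth) & !is.na(df$alt_depth)
  bad <- have_depth & (df$ref_depth + df$alt_depth) <= 0L
  no_info <- !have_depth & is.na(df$vaf)
  if (any(bad | no_info)) {
    warning(sum(bad | no_info),
            " record(s) dropped: zero depth or no depth/VAF information")
    df <- df[!(bad | no_info), , drop = FALSE]
    have_depth <- have_depth[!(bad | no_info)]
  }
  df$vaf[have_depth] <- df$alt_depth[have_depth] /
    (df$ref_depth[have_depth] + df$alt_depth[have_depth])
  df[, c("sample_id", "chrom", "pos", "ref", "alt", "ref_depth",
         "alt_depth", "gene", "impact", "vaf")]
}

.empty_mutations <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), ref_depth = integer(),
             alt_depth = integer(), gene = character(), impact = logical(),
             vaf = numeric(), stringsAsFactors = FALSE)
}

.validate_mutations <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  key <- paste(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate mutation record(s) removed")
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls
}

#' Write mutation calls to the canonical TSV dialect
#' @param calls data.frame as returned by \code{read_mutations}.
#' @param path output path.
#' @export
write_mutations <- function(calls, path) write_tsv_canonical(calls, path)

#' Discretize a log2 copy-number ratio into an event call
#'
#' @param log2_ratio numeric vector of log2 ratios; NA gives a neutral call.
#' @param amp_threshold amplification cut-off (call +1 when
#'   \code{log2_ratio >= amp_threshold}); boundary inclusive.
#' @param del_threshold deletion cut-off (call -1 when
#'   \code{log2_ratio <= del_threshold}); boundary inclusive.
#' @return integer vector in \{-1, 0, +1\}.
#' @export
call_from_log2 <- function(log2_ratio, amp_threshold = 0.3,
                           del_threshold = -0.3) {
  stopifnot(is.finite(amp_threshold), is.finite(del_threshold),
            del_threshold < amp_threshold)
  out <- integer(length(log2_ratio))
  out[!is.na(log2_ratio) & log2_ratio >= amp_threshold] <- 1L
  out[!is.na(log2_ratio) & log2_ratio <= del_threshold] <- -1L
  out
}

#' Read copy-number segments
#'
#' Reads a SEG/BED-like TSV with columns \code{chrom, start, end} plus at
#' least one of \code{log2_ratio} / \code{total_cn}, and optionally
#' \code{sample_id} and \code{call}. Coordinates are normalized to 0-based
#' half-open internally; SEG files are conventionally 1-based inclusive, so
#' that is the default input convention. When \code{call} is absent it is
#' derived from \code{total_cn} (sign of \code{total_cn - 2}) or, failing
#' that, from \code{log2_ratio} via \code{\link{call_from_log2}}. Rows with
#' \code{start >= end} (after conversion) are rejected with a warning.
#'
#' @param path file path.
#' @param coords "one_based" (SEG-style inclusive; the default) or
#'   "zero_based" (already half-open).
#' @param sample_id fallback sample id when the file has no sample column.
#' @param amp_threshold,del_threshold passed to \code{call_from_log2}.
#' @return data.frame with columns sample_id, chrom, start, end (0-based
#'   half-open), log2_ratio, total_cn, call.
#' @export
read_segments <- function(path, coords = c("one_based", "zero_based"),
                          sample_id = NULL, amp_threshold = 0.3,
                          del_threshold = -0.3) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("segment file not found: ", path)
  df <- read_tsv_canonical(path)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  if (!"sample_id" %in% names(df))
    df$sample_id <- if (is.null(sample_id)) "sample" else sample_id
  for (col in c("log2_ratio", "total_cn", "call"))
    if (!col %in% names(df)) df[[col]] <- NA
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (coords == "one_based") df$start <- df$start - 1
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end
  if (any(bad)) {
    warning(sum(bad), " segment(s) rejected: invalid coordinates")
    df <- df[!bad, , drop = FALSE]
  }
  df$log2_ratio <- suppressWarnings(as.numeric(df$log2_ratio))
  df$total_cn <- suppressWarnings(as.integer(df$total_cn))
  df$call <- suppressWarnings(as.integer(df$call))
  derive <- is.na(df$call)
  from_cn <- derive & !is.na(df$total_cn)
  df$call[from_cn] <- sign(df$total_cn[from_cn] - 2L)
  rest <- is.na(df$call)
  df$call[rest] <- call_from_log2(df$log2_ratio[rest], amp_threshold,
                                  del_threshold)
  keep <- c("sample_id", "chrom", "start", "end", "log2_ratio",
            "total_cn", "call",
            intersect("cellular_fraction", names(df)))
  df <- df[, keep]
  rownames(df) <- NULL
  df
}

#' Write copy-number segments in the canonical (0-based half-open) dialect
#' @param segments data.frame as returned by \code{read_segments}.
#' @param path output path.
#' @export
write_segments <- function(segments, path) write_tsv_canonical(segments, path)

#' Retain samples passing the tumor-purity filter
#'
#' A sample is retained only when its purity strictly exceeds
#' \code{min_purity} (the filter is "purity > 0.4", not ">="). Samples with
#' missing purity are excluded with a warning.
#'
#' @param metas data.frame of sample metadata with columns \code{sample_id}
#'   and \code{purity}.
#' @param min_purity purity threshold, default 0.4.
#' @return character vector of retained sample ids.
#' @export
filter_samples_by_purity <- function(metas, min_purity = 0.4) {
  stopifnot(is.data.frame(metas), all(c("sample_id", "purity") %in% names(metas)))
  missing <- is.na(metas$purity)
  if (any(missing))
    warning(sum(missing), " sample(s) excluded: missing purity")
  metas$sample_id[!missing & metas$purity > min_purity]
}

#' Read sample metadata
#'
#' Expects columns \code{sample_id, purity} and optionally \code{ploidy},
#' \code{tissue} (primary/metastasis), \code{pair_id} and arbitrary group
#' label columns (CMS, MSI, sidedness, relapse, ...).
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv_canonical(path)
  if (!all(c("sample_id", "purity") %in% names(df)))
    stop("sample metadata must have sample_id and purity columns")
  df$purity <- as.numeric(df$purity)
  if (!"tissue" %in% names(df)) df$tissue <- "primary"
  df
}

#' Read a cell-type fraction matrix
#'
#' Samples in rows, cell types in columns; the first column is the sample
#' id. Rows are renormalized to sum to one at load time; negative entries
#' are fatal.
#'
#' @param path file path.
#' @return numeric matrix, rownames = sample ids, colnames = cell types.
#' @export
read_cell_fractions <- function(path) {
  df <- read_tsv_canonical(path)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE)) stop("negative cell fractions in ", path)
  m[is.na(m)] <- 0
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("all-zero cell-fraction row(s) in ", path)
  sweep(m, 1L, rs, "/")
}

#' Read a gene panel (one symbol per line)
#' @param path plain-text file, one gene symbol per line; blank lines and
#'   lines starting with '#' are skipped.
#' @return character vector of unique symbols in file order.
#' @export
read_gene_panel <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read a UCSC-style cytoband table
#'
#' Columns chrom, start (0-based), end, band name, stain (stain optional).
#' Headerless UCSC files are accepted.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, band (e.g. "8q24.21"),
#'   band_id ("chr8:8q24.21" style unique key).
#' @export
read_cytobands <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) {
    names(df)[1:4] <- c("chrom", "start", "end", "band")
  }
  names(df) <- tolower(names(df))
  if ("name" %in% names(df) && !"band" %in% names(df)) df$band <- df$name
  stopifnot(all(c("chrom", "start", "end", "band") %in% names(df)))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$band_id <- paste0(df$chrom, ":", df$band)
  df[, c("chrom", "start", "end", "band", "band_id")]
}
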