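# Cancer cell fraction (CCF) estimation from VAF under purity and local
# copy number, clonal/subclonal classification via the Clopper-Pearson
# confidence interval on the VAF, and a one-dimensional Gaussian-mixture
# subclone caller (a deliberately simple stand-in for SSM/CNV co-occurrence
# tools such as Expands or PhyloWGS; external compositions can be supplied
# instead wherever a CloneComposition is consumed).

.CCF_CEILING <- 1.5

#' Estimate mutant-allele multiplicity
#'
#' \code{m = round(vaf * (purity * CT + (1 - purity) * 2) / purity)} clipped
#' to \code{[1, CT]}, with CT the local tumor copy number.
#'
#' @param vaf variant allele fraction(s).
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn local tumor copy number (>= 1), recycled.
#' @return integer vector of multiplicities.
#' @export
estimate_multiplicity <- function(vaf, purity, tumor_cn) {
  stopifnot(purity > 0, purity <= 1, all(tumor_cn >= 1))
  m <- round(vaf * (purity * tumor_cn + (1 - purity) * 2) / purity)
  as.integer(pmin(pmax(m, 1L), tumor_cn))
}

#' Estimate the cancer cell fraction of a variant
#'
#' \code{ccf = vaf * (purity * CT + (1 - purity) * 2) / (purity * m)},
#' clipped to [0, 1.5] (the ceiling retains super-clonal artifacts without
#' letting them dominate diversity estimates).
#'
#' @param vaf variant allele fraction(s).
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn local tumor copy number, recycled.
#' @param multiplicity mutant-allele multiplicity, recycled.
#' @return numeric vector of CCFs.
#' @export
estimate_ccf <- function(vaf, purity, tumor_cn = 2L, multiplicity = 1L) {
  if (any(purity <= 0)) stop("purity must be > 0")
  ccf <- vaf * (purity * tumor_cn + (1 - purity) * 2) / (purity * multiplicity)
  pmin(pmax(ccf, 0), .CCF_CEILING)
}

# exact (Clopper-Pearson) 95% binomial interval on the success probability
.clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lo, hi)
}

#' Classify mutation clonality from the CCF confidence interval
#'
#' The 95% Clopper-Pearson interval on the VAF is mapped through the CCF
#' relation; a mutation is clonal when the interval's upper bound reaches 1
#' (the data cannot exclude presence in every tumor cell), subclonal
#' otherwise. The alternative point-estimate rule (\code{ccf >= 0.9}) is
#' available via \code{rule = "point"}.
#'
#' @param alt_depth,depth alt-supporting and total read counts (vectors).
#' @param purity tumor purity in (0, 1].
#' @param tumor_cn local tumor copy number, recycled.
#' @param multiplicity mutant-allele multiplicity, recycled.
#' @param rule "ci" (default) or "point".
#' @param conf confidence level of the interval.
#' @return data.frame with columns ccf, ci_low, ci_high, multiplicity,
#'   clonality ("clonal"/"subclonal").
#' @export
classify_clonality <- function(alt_depth, depth, purity, tumor_cn = 2L,
                               multiplicity = 1L, rule = c("ci", "point"),
                               conf = 0.95) {
  rule <- match.arg(rule)
  stopifnot(all(depth > 0), all(alt_depth >= 0), all(alt_depth <= depth))
  vaf <- alt_depth / depth
  ccf <- estimate_ccf(vaf, purity, tumor_cn, multiplicity)
  ci <- .clopper_pearson(alt_depth, depth, conf)
  ci_low <- estimate_ccf(ci[, 1], purity, tumor_cn, multiplicity)
  ci_high <- estimate_ccf(ci[, 2], purity, tumor_cn, multiplicity)
  clonality <- if (rule == "ci") ifelse(ci_high >= 1, "clonal", "subclonal")
               else ifelse(ccf >= 0.9, "clonal", "subclonal")
  data.frame(ccf = ccf, ci_low = ci_low, ci_high = ci_high,
             multiplicity = as.integer(rep_len(multiplicity, length(ccf))),
             clonality = clonality, stringsAsFactors = FALSE)
}

#' Classify copy-number event clonality from its cellular fraction
#'
#' @param cellular_fraction fraction of tumor cells carrying the event (as
#'   reported by absolute copy-number callers or the simulator); NA gives NA.
#' @param threshold clonal when \code{cellular_fraction >= threshold}
#'   (boundary inclusive).
#' @return character vector "clonal"/"subclonal" (NA propagated with a
#'   warning).
#' @export
classify_cnv_clonality <- function(cellular_fraction, threshold = 0.9) {
  if (any(is.na(cellular_fraction)))
    warning(sum(is.na(cellular_fraction)),
            " segment(s) without cellular fraction: clonality missing")
  ifelse(is.na(cellular_fraction), NA_character_,
         ifelse(cellular_fraction >= threshold, "clonal", "subclonal"))
}

#' Infer a subclone composition from CCF values
#'
#' Fits one-dimensional Gaussian mixtures (equal- and unequal-variance
#' families) with 1 to \code{max_clusters} components to the CCFs, picks the
#' model and component number by BIC (mclust's deterministic agglomerative
#' initialization makes the fit reproducible without a seed), merges
#' clusters holding fewer than
#' \code{min_cluster_fraction} of the variants into their nearest neighbor,
#' and reports cluster means as cellular prevalences renormalized to sum 1.
#'
#' @param ccfs numeric vector of per-variant CCFs (>= 1 value).
#' @param min_cluster_fraction minimum share of variants a cluster must
#'   hold.
#' @param max_clusters largest number of mixture components tried.
#' @param sample_id label carried into the result.
#' @return object of class \code{clone_composition}: list with
#'   \code{sample_id}, \code{clusters} (data.frame cluster, prevalence,
#'   n_variants), \code{n_clones}.
#' @export
infer_subclones <- function(ccfs, min_cluster_fraction = 0.05,
                            max_clusters = 8L, sample_id = "sample") {
  stopifnot(length(ccfs) >= 1, all(is.finite(ccfs)))
  uniq <- sort(unique(ccfs))
  if (length(uniq) == 1L || length(ccfs) < 3L) {
    means <- mean(ccfs)
    sizes <- length(ccfs)
  } else if (length(uniq) <= max_clusters) {
    # degenerate (noise-free) input: each distinct value is its own cluster
    means <- uniq
    sizes <- as.integer(table(factor(ccfs, levels = uniq)))
  } else {
    fit <- suppressWarnings(
      Mclust(ccfs, G = seq_len(max_clusters), modelNames = c("E", "V"),
             verbose = FALSE))
    if (is.null(fit)) {  # degenerate data; fall back to one cluster
      means <- mean(ccfs)
      sizes <- length(ccfs)
    } else {
      cls <- fit$classification
      means <- as.numeric(tapply(ccfs, cls, mean))
      sizes <- as.integer(table(cls))
    }
  }
  # merge clusters below the minimum fraction into the nearest neighbor
  repeat {
    frac <- sizes / sum(sizes)
    small <- which(frac < min_cluster_fraction)
    if (length(small) == 0L || length(means) == 1L) break
    i <- small[which.min(sizes[small])]
    j <- setdiff(order(abs(means - means[i])), i)[1L]
    means[j] <- (means[i] * sizes[i] + means[j] * sizes[j]) /
      (sizes[i] + sizes[j])
    sizes[j] <- sizes[j] + sizes[i]
    means <- means[-i]; sizes <- sizes[-i]
  }
  o <- order(means, decreasing = TRUE)
  means <- pmax(means[o], 1e-12)
  sizes <- sizes[o]
  clone_composition(sample_id,
                    prevalence = means / sum(means),
                    n_variants = sizes)
}

#' Construct a subclone composition
#'
#' Also the entry point for compositions produced by external tools
#' (Expands/PhyloWGS-style tables of cluster prevalences): prevalences are
#' renormalized to sum 1, as the Shannon index requires a probability
#' vector.
#'
#' @param sample_id sample label.
#' @param prevalence positive cluster cellular prevalences.
#' @param n_variants member variant count per cluster (optional).
#' @return object of class \code{clone_composition}.
#' @export
clone_composition <- function(sample_id, prevalence,
                              n_variants = rep(NA_integer_, length(prevalence))) {
  stopifnot(length(prevalence) >= 1, all(prevalence > 0))
  prevalence <- prevalence / sum(prevalence)
  structure(list(sample_id = sample_id,
                 clusters = data.frame(cluster = seq_along(prevalence),
                                       prevalence = prevalence,
                                       n_variants = n_variants),
                 n_clones = length(prevalence)),
            class = "clone_composition")
}

#' @export
print.clone_composition <- function(x, ...) {
  cat("Subclone composition for", x$sample_id, "-", x$n_clones, "clone(s)\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Count clonal and subclonal mutation and copy-number burdens
#'
#' @param ccf_records data.frame with a \code{clonality} column (SSMs).
#' @param cnv_labels character vector of CNV clonality labels (NAs are
#'   excluded from the counts).
#' @return named integer vector: clonal_ssm, subclonal_ssm, clonal_cnv,
#'   subclonal_cnv.
#' @export
burden_summary <- function(ccf_records = NULL, cnv_labels = NULL) {
  ssm <- if (is.null(ccf_records)) character() else ccf_records$clonality
  cnv <- if (is.null(cnv_labels)) character() else cnv_labels[!is.na(cnv_labels)]
  c(clonal_ssm = sum(ssm == "clonal"),
    subclonal_ssm = sum(ssm == "subclonal"),
    clonal_cnv = sum(cnv == "clonal"),
    subclonal_cnv = sum(cnv == "subclonal"))
}

#' Run the full CCF/clonality stage for one or more samples
#'
#' Joins mutation calls with sample purity, annotates each variant with the
#' local tumor copy number from overlapping segments (2 where no segment
#' covers it), estimates multiplicity and CCF, and classifies clonality.
#'
#' @param mutations mutation calls (format of \code{\link{read_mutations}}).
#' @param meta sample metadata with sample_id and purity.
#' @param segments optional copy-number segments with a total_cn column.
#' @param rule clonality rule passed to \code{\link{classify_clonality}}.
#' @return the mutation data.frame with added columns tumor_cn,
#'   multiplicity, ccf, ci_low, ci_high, clonality.
#' @export
ccf_pipeline <- function(mutations, meta, segments = NULL,
                         rule = c("ci", "point")) {
  rule <- match.arg(rule)
  stopifnot(all(c("sample_id", "purity") %in% names(meta)))
  purity <- stats::setNames(meta$purity, meta$sample_id)
  missing <- setdiff(unique(mutations$sample_id), meta$sample_id)
  if (length(missing) > 0L)
    stop("no purity for sample(s): ", paste(missing, collapse = ", "))
  ct <- rep(2L, nrow(mutations))
  if (!is.null(segments) && nrow(segments) > 0L &&
      any(!is.na(segments$total_cn))) {
    segs <- segments[!is.na(segments$total_cn), , drop = FALSE]
    mg <- GenomicRanges::GRanges(
      paste0(mutations$sample_id, ":", mutations$chrom),
      IRanges::IRanges(mutations$pos, mutations$pos))
    sg <- GenomicRanges::GRanges(
      paste0(segs$sample_id, ":", segs$chrom),
      IRanges::IRanges(segs$start + 1L, segs$end))
    hit <- suppressWarnings(GenomicRanges::findOverlaps(mg, sg,
                                                        select = "first"))
    ct[!is.na(hit)] <- segs$total_cn[hit[!is.na(hit)]]
    ct <- pmax(ct, 1L)
  }
  p <- purity[mutations$sample_id]
  depth <- mutations$ref_depth + mutations$alt_depth
  m <- estimate_multiplicity(mutations$vaf, p, ct)
  out <- mutations
  out$tumor_cn <- ct
  cl <- classify_clonality(mutations$alt_depth, depth, p, ct, m, rule = rule)
  out$multiplicity <- cl$multiplicity
  out$ccf <- cl$ccf
  out$ci_low <- cl$ci_low
  out$ci_high <- cl$ci_high
  out$clonality <- cl$clonality
  out
}
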