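# Cohort-level statistics: consensus molecular subtype voting, per-cytoband
# copy-number carrier frequencies and Fisher enrichment, logistic models of
# metastatic potential, burden correlations, masked Spearman correlation
# matrices and the pro/anti-metastatic cell-ratio stratification.

.CMS_LEVELS <- c("CMS1", "CMS2", "CMS3", "CMS4")

#' Consensus molecular subtype by majority vote of three classifiers
#'
#' The final label is the subtype called consistently by at least two of
#' the three classifiers, "Unknown" otherwise. A classifier's own unknown
#' token (anything outside CMS1..CMS4, or NA) never votes.
#'
#' @param labels character matrix or data.frame, samples x 3 classifier
#'   calls, or three character vectors via \code{...}.
#' @param ... alternative: three equal-length character vectors.
#' @return character vector of consensus labels.
#' @export
consensus_cms <- function(labels = NULL, ...) {
  if (is.null(labels)) labels <- cbind(...)
  labels <- as.matrix(labels)
  stopifnot(ncol(labels) == 3L)
  apply(labels, 1L, function(v) {
    v <- v[!is.na(v) & v %in% .CMS_LEVELS]
    if (length(v) == 0L) return("Unknown")
    tab <- table(v)
    top <- names(tab)[which.max(tab)]
    if (max(tab) >= 2L) top else "Unknown"
  })
}

#' Per-cytoband copy-number carrier frequencies by group
#'
#' A sample carries an amplification on a band iff any of its call +1
#' segments overlaps the band (likewise deletions with call -1); the
#' frequency is carriers divided by group size.
#'
#' @param segments segment data.frame (0-based half-open) for all samples.
#' @param cytobands cytoband table (\code{\link{read_cytobands}} format).
#' @param groups named vector mapping sample_id to group label (all samples
#'   counted, with or without segments).
#' @return data.frame: band_id, event, group, n_carriers, n_group,
#'   frequency.
#' @export
cnv_band_frequencies <- function(segments, cytobands, groups) {
  stopifnot(!is.null(names(groups)))
  samples <- names(groups)
  bg <- GenomicRanges::GRanges(cytobands$chrom,
                               IRanges::IRanges(cytobands$start + 1L,
                                                cytobands$end))
  carrier <- function(sgn) {
    s <- segments[!is.na(segments$call) & segments$call == sgn &
                    segments$sample_id %in% samples, , drop = FALSE]
    m <- matrix(FALSE, length(samples), length(bg),
                dimnames = list(samples, cytobands$band_id))
    if (nrow(s) > 0L) {
      sg <- GenomicRanges::GRanges(s$chrom,
                                   IRanges::IRanges(s$start + 1L, s$end))
      hits <- GenomicRanges::findOverlaps(sg, bg)
      if (length(hits) > 0L)
        m[cbind(s$sample_id[S4Vectors::queryHits(hits)],
                cytobands$band_id[S4Vectors::subjectHits(hits)])] <- TRUE
    }
    m
  }
  out <- do.call(rbind, lapply(c(amp = 1L, del = -1L), function(sgn) {
    m <- carrier(sgn)
    do.call(rbind, lapply(unique(groups), function(gr) {
      rows <- samples[groups == gr]
      data.frame(band_id = cytobands$band_id,
                 event = if (sgn == 1L) "amp" else "del",
                 group = gr,
                 n_carriers = colSums(m[rows, , drop = FALSE]),
                 n_group = length(rows),
                 stringsAsFactors = FALSE)
    }))
  }))
  out$frequency <- out$n_carriers / out$n_group
  rownames(out) <- NULL
  out
}

#' Fisher enrichment of copy-number events between two groups
#'
#' Two-sided Fisher exact test on the carrier / non-carrier 2x2 table per
#' band and event. P values are deliberately left uncorrected; the
#' -log10(p) column is the plotting scale used for genome-wide enrichment
#' tracks.
#'
#' @param freqs data.frame from \code{\link{cnv_band_frequencies}} computed
#'   on exactly two groups.
#' @param group1,group2 group labels to compare (default: the two groups
#'   present).
#' @return data.frame: band_id, event, freq_group1, freq_group2, the 2x2
#'   counts, p_uncorrected, neg_log10_p.
#' @export
band_enrichment <- function(freqs, group1 = NULL, group2 = NULL) {
  grs <- unique(freqs$group)
  if (is.null(group1)) group1 <- grs[1L]
  if (is.null(group2)) group2 <- grs[2L]
  stopifnot(all(c(group1, group2) %in% grs))
  f1 <- freqs[freqs$group == group1, ]
  f2 <- freqs[freqs$group == group2, ]
  key <- paste(f1$band_id, f1$event)
  f2 <- f2[match(key, paste(f2$band_id, f2$event)), ]
  p <- vapply(seq_len(nrow(f1)), function(i) {
    tab <- matrix(c(f1$n_carriers[i], f1$n_group[i] - f1$n_carriers[i],
                    f2$n_carriers[i], f2$n_group[i] - f2$n_carriers[i]),
                  nrow = 2L)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(band_id = f1$band_id, event = f1$event,
             freq_group1 = f1$frequency, freq_group2 = f2$frequency,
             a = f1$n_carriers, b = f1$n_group - f1$n_carriers,
             c = f2$n_carriers, d = f2$n_group - f2$n_carriers,
             p_uncorrected = p, neg_log10_p = -log10(p),
             stringsAsFactors = FALSE)
}

#' Logistic model of metastatic potential
#'
#' Logistic regression of a binary relapse/metastasis outcome on
#' standardized covariates (z-scores), with intercept; coefficients are
#' log-odds per covariate SD. Complete or quasi-complete separation is
#' detected (fitted probabilities numerically 0/1 or exploding standard
#' errors) and flagged, with estimates withheld.
#'
#' @param covariates data.frame of numeric per-sample covariates.
#' @param relapse binary outcome (0/1 or logical), same length.
#' @return object of class \code{glm_result}: data.frame with covariate,
#'   log_odds, std_error, p, plus attributes \code{separation} (logical)
#'   and \code{model}.
#' @export
metastasis_glm <- function(covariates, relapse) {
  covariates <- as.data.frame(covariates)
  relapse <- as.integer(relapse)
  stopifnot(nrow(covariates) == length(relapse),
            all(relapse %in% c(0L, 1L)))
  if (nrow(covariates) < 10L)
    stop("need at least 10 samples to fit a metastatic-potential model")
  if (length(unique(relapse)) < 2L)
    stop("outcome has a single class: model undefined")
  z <- as.data.frame(lapply(covariates, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) stop("constant covariate cannot be standardized")
    (x - mean(x)) / s
  }))
  dat <- cbind(z, .outcome = relapse)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  if (any(sm[, "Std. Error"] > 100)) separation <- TRUE
  out <- data.frame(covariate = rownames(sm),
                    log_odds = sm[, "Estimate"],
                    std_error = sm[, "Std. Error"],
                    p = sm[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (separation) out[, c("log_odds", "std_error", "p")] <- NA_real_
  structure(out, separation = separation, model = fit,
            class = c("glm_result", "data.frame"))
}

#' Pearson correlation between alteration burdens
#'
#' SSM counts are conventionally displayed on a log10 scale;
#' \code{log_x = TRUE} applies \code{log10(x + 1)} to the first burden
#' before correlating.
#'
#' @param x,y non-negative counts per sample (length >= 3).
#' @param log_x log10-transform the first vector.
#' @return data.frame: pearson_r, p_value, n (NA with a warning when either
#'   vector is constant).
#' @export
burden_correlation <- function(x, y, log_x = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(x >= 0), all(y >= 0))
  if (log_x) x <- log10(x + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(data.frame(pearson_r = NA_real_, p_value = NA_real_,
                      n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(pearson_r = unname(ct$estimate), p_value = ct$p.value,
             n = length(x))
}

#' Masked Spearman correlation matrix
#'
#' Pairwise Spearman rho over the columns of a sample x measure table, with
#' Benjamini-Hochberg adjustment across all tested (off-diagonal) pairs;
#' cells whose adjusted p is not below \code{alpha} are masked to NA. The
#' diagonal is 1 and never masked.
#'
#' @param variables numeric data.frame or matrix, samples x measures.
#' @param alpha significance level for the mask.
#' @return list: rho (masked matrix), rho_all (unmasked), p_adj.
#' @export
correlation_matrix <- function(variables, alpha = 0.05) {
  m <- as.matrix(variables)
  stopifnot(nrow(m) >= 3)
  k <- ncol(m)
  rho <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(colnames(m), colnames(m))
  pairs <- utils::combn(k, 2L)
  pvals <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    ct <- suppressWarnings(stats::cor.test(m[, i1], m[, i2],
                                           method = "spearman"))
    rho[i1, i2] <- rho[i2, i1] <- unname(ct$estimate)
    pvals[j] <- ct$p.value
  }
  padj <- stats::p.adjust(pvals, method = "BH")
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    p[i1, i2] <- p[i2, i1] <- padj[j]
  }
  masked <- rho
  masked[!is.na(p) & p >= alpha] <- NA_real_
  diag(masked) <- 1
  list(rho = masked, rho_all = rho, p_adj = p)
}

#' Pro/anti-metastatic cell-ratio stratification
#'
#' Ratio of summed pro-metastatic to summed anti-metastatic cell fractions
#' (pseudocount-stabilized), dichotomized at the cohort median. Defaults
#' follow the pro-metastatic myofibroblast / pro-inflammatory macrophage
#' and anti-metastatic stalk-like endothelial / dendritic cell
#' compartments.
#'
#' @param cell_fractions matrix samples x cell types (rows sum to 1).
#' @param pro_types,anti_types cell-type names to sum.
#' @param pseudo pseudocount added to both sums.
#' @return data.frame: sample_id, ratio, group ("high"/"low" vs the cohort
#'   median; values equal to the median go to "low").
#' @export
prognostic_ratio <- function(cell_fractions,
                             pro_types = c("myofibroblasts",
                                           "pro_inflammatory_macrophages"),
                             anti_types = c("stalk_like_endothelial",
                                            "dendritic_cells"),
                             pseudo = 1e-3) {
  missing <- setdiff(c(pro_types, anti_types), colnames(cell_fractions))
  if (length(missing) > 0L)
    stop("cell type(s) not in profile: ", paste(missing, collapse = ", "))
  pro <- rowSums(cell_fractions[, pro_types, drop = FALSE])
  anti <- rowSums(cell_fractions[, anti_types, drop = FALSE])
  ratio <- (pro + pseudo) / (anti + pseudo)
  med <- stats::median(ratio)
  data.frame(sample_id = rownames(cell_fractions), ratio = ratio,
             group = ifelse(ratio > med, "high", "low"),
             stringsAsFactors = FALSE, row.names = NULL)
}
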