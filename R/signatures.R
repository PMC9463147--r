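# Feature encodings (binary SSM presence/absence, ternary CNV, logCPM
# expression) over a cancer-gene panel, cross-validated lasso signatures of
# ITH with entry-order reporting, and within/cross-cohort evaluation.

#' Encode SSMs as a binary presence/absence matrix
#'
#' Entry (sample, gene) is 1 iff the sample carries at least one SSM in
#' that panel gene with VAF strictly above \code{min_vaf} and (when
#' \code{require_impact}) a predicted functional impact. Multiple hits in a
#' gene still give 1: hypermutated genes are not over-represented.
#'
#' @param calls mutation data.frame with sample_id, gene, vaf, impact.
#' @param panel character vector of candidate genes (column order).
#' @param samples sample ids (row order); defaults to those seen in
#'   \code{calls}.
#' @param min_vaf VAF threshold (strict ">", default 0.05).
#' @param require_impact keep only impact-flagged SSMs.
#' @return integer matrix samples x genes in \{0, 1\} with attribute
#'   \code{encoding = "binary"}.
#' @export
encode_ssm_features <- function(calls, panel, samples = NULL,
                                min_vaf = 0.05, require_impact = TRUE) {
  stopifnot(length(panel) > 0)
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  keep <- !is.na(calls$gene) & calls$gene %in% panel &
    !is.na(calls$vaf) & calls$vaf > min_vaf
  if (require_impact) keep <- keep & !is.na(calls$impact) & calls$impact
  x <- matrix(0L, length(samples), length(panel),
              dimnames = list(samples, panel))
  hits <- calls[keep & calls$sample_id %in% samples, c("sample_id", "gene")]
  if (nrow(hits) > 0L)
    x[cbind(hits$sample_id, hits$gene)] <- 1L
  attr(x, "encoding") <- "binary"
  x
}

#' Encode CNVs as a ternary gene-level matrix
#'
#' Entry (sample, gene) is the call sign (-1 deletion, +1 amplification, 0
#' none) of the segment overlapping the gene. When a gene overlaps both an
#' amplified and a deleted segment, the sign covering the larger fraction
#' of the gene wins; exact ties give 0.
#'
#' @param segments segment data.frame with sample_id, chrom, start, end,
#'   call (0-based half-open).
#' @param panel_intervals data.frame gene, chrom, start, end (0-based
#'   half-open gene intervals).
#' @param samples sample ids (row order).
#' @return integer matrix samples x genes in \{-1, 0, 1\} with attribute
#'   \code{encoding = "ternary"}.
#' @export
encode_cnv_features <- function(segments, panel_intervals, samples = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(panel_intervals)))
  if (is.null(samples)) samples <- sort(unique(segments$sample_id))
  x <- matrix(0L, length(samples), nrow(panel_intervals),
              dimnames = list(samples, panel_intervals$gene))
  segs <- segments[!is.na(segments$call) & segments$call != 0L &
                     segments$sample_id %in% samples, , drop = FALSE]
  if (nrow(segs) > 0L) {
    gg <- GenomicRanges::GRanges(panel_intervals$chrom,
                                 IRanges::IRanges(panel_intervals$start + 1L,
                                                  panel_intervals$end))
    sg <- GenomicRanges::GRanges(segs$chrom,
                                 IRanges::IRanges(segs$start + 1L, segs$end))
    hits <- GenomicRanges::findOverlaps(gg, sg)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(gg[qi], sg[si]))
      frac <- ov / GenomicRanges::width(gg[qi])
      df <- data.frame(sample = segs$sample_id[si], gene = qi,
                       call = segs$call[si], frac = frac)
      agg <- stats::aggregate(frac ~ sample + gene + call, df, FUN = sum)
      for (key in split(agg, paste(agg$sample, agg$gene))) {
        amp <- sum(key$frac[key$call == 1L])
        del <- sum(key$frac[key$call == -1L])
        val <- if (amp > del) 1L else if (del > amp) -1L else 0L
        x[key$sample[1L], key$gene[1L]] <- val
      }
    }
  }
  attr(x, "encoding") <- "ternary"
  x
}

#' Encode expression counts as logCPM features
#'
#' Counts-per-million with pseudocount: \code{log2(count * 1e6 /
#' library_size + pseudocount)}.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param pseudocount added inside the log.
#' @return numeric matrix samples x genes with attribute
#'   \code{encoding = "continuous"}.
#' @export
encode_expression_features <- function(counts, pseudocount = 1) {
  stopifnot(all(counts >= 0, na.rm = TRUE))
  libsize <- colSums(counts)
  if (any(libsize <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libsize <= 0], collapse = ", "))
  cpm <- sweep(counts, 2L, libsize, "/") * 1e6
  x <- t(log2(cpm + pseudocount))
  attr(x, "encoding") <- "continuous"
  x
}

# stratified fold assignment: samples are binned by outcome quartile and
# folds filled per bin, so every fold spans the outcome range
.stratified_folds <- function(y, n_folds, seed) {
  .with_seed(seed, {
    qs <- stats::quantile(y, probs = seq(0, 1, 0.25), type = 7)
    bin <- findInterval(y, unique(qs), rightmost.closed = TRUE)
    foldid <- integer(length(y))
    for (b in unique(bin)) {
      idx <- sample(which(bin == b))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    foldid
  })
}

#' Fit a cross-validated lasso signature of ITH
#'
#' Covariates are standardized (zero mean, unit sd; zero-variance columns
#' dropped with a message), the lasso path is fitted from lambda_max (the
#' smallest lambda with an all-zero solution) downward, and lambda is
#' chosen by tenfold cross-validated mean squared error (CV minimum by
#' default; the 1-SE rule via \code{lambda_rule = "1se"}). The entry order
#' of each selected gene is the rank of the largest lambda at which its
#' coefficient first becomes nonzero along the path (ties broken by
#' absolute coefficient at the chosen lambda) - lower numbers entered
#' earlier and carry more of the signal.
#'
#' @param X feature matrix, samples x genes (any encoding).
#' @param y numeric ITH values, one per row of X.
#' @param n_folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule "min" or "1se".
#' @return object of class \code{signature_model}: list with selected
#'   coefficients (standardized scale), entry_order, lambda_opt,
#'   lambda_max, intercept, standardization parameters, cv_folds, seed,
#'   train_r2 and the glmnet fit.
#' @export
fit_lasso_signature <- function(X, y, n_folds = 10L, seed = 1L,
                                lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < n_folds) stop("fewer samples than CV folds")
  if (stats::sd(y) == 0) stop("constant outcome: nothing to model")
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0L)
    message("dropping ", length(dropped), " zero-variance feature(s): ",
            paste(utils::head(dropped, 10L), collapse = ", "))
  X <- X[, sds > 0, drop = FALSE]
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  Xs <- scale(X, center = center, scale = scale_)
  foldid <- .stratified_folds(y, n_folds, seed)
  cv <- glmnet::cv.glmnet(Xs, y, foldid = foldid, standardize = FALSE,
                          alpha = 1)
  lambda_opt <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  fit <- cv$glmnet.fit
  beta <- as.matrix(fit$beta)
  coef_opt <- as.numeric(glmnet::coef.glmnet(fit, s = lambda_opt))
  names(coef_opt) <- c("(Intercept)", rownames(beta))
  selected <- coef_opt[-1L][coef_opt[-1L] != 0]
  # first lambda index (largest lambda) at which each coefficient is nonzero
  first_idx <- apply(beta != 0, 1L, function(nz)
    if (any(nz)) which(nz)[1L] else NA_integer_)
  sel_idx <- first_idx[names(selected)]
  ord <- order(sel_idx, -abs(selected))
  entry_order <- stats::setNames(seq_along(selected), names(selected)[ord])
  entry_order <- entry_order[names(selected)]
  pred <- as.numeric(coef_opt[1L] + Xs[, names(selected), drop = FALSE] %*%
                       selected)
  train_r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(list(selected = selected, entry_order = entry_order,
                 lambda_opt = lambda_opt, lambda_max = max(fit$lambda),
                 intercept = unname(coef_opt[1L]),
                 center = center, scale = scale_,
                 features = colnames(X), cv_folds = n_folds, seed = seed,
                 train_r2 = train_r2, cv = cv),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Lasso ITH signature:", length(x$selected), "gene(s) selected",
      sprintf("(lambda = %.4g, %d-fold CV, train R2 = %.3f)\n",
              x$lambda_opt, x$cv_folds, x$train_r2))
  if (length(x$selected) > 0L) {
    df <- data.frame(gene = names(x$selected),
                     coefficient = unname(x$selected),
                     entry_order = unname(x$entry_order[names(x$selected)]))
    print(df[order(df$entry_order), ], row.names = FALSE)
  }
  invisible(x)
}

#' Predict ITH from a fitted signature
#'
#' Applies the stored standardization (training center/scale) and linear
#' predictor to new samples. Every training feature must be present.
#'
#' @param model a \code{signature_model}.
#' @param X feature matrix, samples x genes, same encoding rules as
#'   training.
#' @return named numeric vector of predictions.
#' @export
predict_ith <- function(model, X) {
  missing <- setdiff(model$features, colnames(X))
  if (length(missing) > 0L)
    stop("feature(s) missing from the new matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  Xs <- scale(X[, model$features, drop = FALSE],
              center = model$center, scale = model$scale)
  sel <- names(model$selected)
  out <- as.numeric(model$intercept +
                      Xs[, sel, drop = FALSE] %*% model$selected)
  stats::setNames(out, rownames(X))
}

#' Evaluate observed vs predicted ITH
#'
#' Pearson correlation with two-sided p value and the explained variance
#' \code{R2 = 1 - SS_res / SS_tot}. A constant prediction vector leaves the
#' correlation undefined (NA, with a warning); R2 is still reported.
#'
#' @param y_obs,y_pred numeric vectors of equal length >= 3.
#' @return data.frame: pearson_r, p_value, r2, n.
#' @export
evaluate_predictions <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  if (stats::sd(y_obs) == 0) stop("observed values have zero variance")
  r2 <- 1 - sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  if (stats::sd(y_pred) == 0) {
    warning("constant predictions: correlation undefined")
    return(data.frame(pearson_r = NA_real_, p_value = NA_real_, r2 = r2,
                      n = length(y_obs)))
  }
  ct <- stats::cor.test(y_obs, y_pred, method = "pearson")
  data.frame(pearson_r = unname(ct$estimate), p_value = ct$p.value,
             r2 = r2, n = length(y_obs))
}

#' Cross-cohort evaluation of a signature
#'
#' Applies a model trained on one cohort to a second cohort encoded with
#' the same rules and panel, and reports the transfer performance
#' separately from the training fit.
#'
#' @param model a \code{signature_model} trained on cohort A.
#' @param X_b feature matrix of cohort B (same panel and encoding).
#' @param y_b observed ITH of cohort B.
#' @return data.frame as \code{\link{evaluate_predictions}}.
#' @export
transfer_evaluation <- function(model, X_b, y_b) {
  evaluate_predictions(y_b, predict_ith(model, X_b))
}

#' Serialize a signature model to JSON
#' @param model a \code{signature_model}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_signature_model <- function(model, path) {
  obj <- model[c("selected", "entry_order", "lambda_opt", "lambda_max",
                 "intercept", "center", "scale", "features", "cv_folds",
                 "seed", "train_r2")]
  for (nm in c("selected", "entry_order", "center", "scale"))
    obj[[nm]] <- as.list(obj[[nm]])   # keep names as JSON object keys
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature model back from JSON
#' @param path path written by \code{\link{write_signature_model}}.
#' @return a \code{signature_model} (without the CV object).
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$selected <- unlist(obj$selected)
  obj$entry_order <- unlist(obj$entry_order)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  structure(obj, class = "signature_model")
}

#' Simulate two matched feature cohorts with a planted linear signal
#'
#' Binary mutation features for \code{panel_size} genes (mutation
#' probability \code{mut_prob}); the outcome is the planted linear
#' combination of the first \code{length(beta)} genes plus Gaussian noise.
#' Used to exercise signature fitting and cross-cohort transfer without a
#' full cohort simulation.
#'
#' @param n samples per cohort.
#' @param panel_size candidate genes.
#' @param beta planted coefficients (assigned to the first genes).
#' @param noise_sd outcome noise sd.
#' @param mut_prob mutation probability per gene.
#' @param seed integer seed.
#' @return list with X, y (cohort A), X_b, y_b (independent cohort B),
#'   planted gene names.
#' @export
simulate_feature_cohort <- function(n = 150L, panel_size = 50L,
                                    beta = rep(0.8, 5L), noise_sd = 0.5,
                                    mut_prob = 0.4, seed = 1L) {
  genes <- sprintf("G%02d", seq_len(panel_size))
  planted <- genes[seq_along(beta)]
  draw <- function(s) .with_seed(s, {
    X <- matrix(stats::rbinom(n * panel_size, 1L, mut_prob), n, panel_size,
                dimnames = list(sprintf("S%03d", seq_len(n)), genes))
    y <- as.numeric(X[, planted, drop = FALSE] %*% beta) +
      stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
  a <- draw(seed)
  b <- draw(.child_seed(seed, 7L))
  list(X = a$X, y = a$y, X_b = b$X, y_b = b$y, planted = planted)
}
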