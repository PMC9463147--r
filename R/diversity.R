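# Shannon-index intra-tumor heterogeneity: genetic (over subclone
# prevalences) and microenvironmental (over cell-type fractions), plus
# quantile rank stratification.

#' Shannon diversity index
#'
#' Zero entries are dropped (the limit of p*log(p) is 0, so no smoothing is
#' applied), the remainder renormalized to sum 1, and
#' \code{H = -sum(p * log(p, base))} returned. Natural log by default, the
#' ecology convention.
#'
#' @param fractions non-negative numeric vector with at least one positive
#'   entry.
#' @param base logarithm base.
#' @return non-negative scalar; 0 for a single component, at most
#'   \code{log(k)} for k components.
#' @export
shannon_index <- function(fractions, base = exp(1)) {
  stopifnot(is.numeric(fractions), all(!is.na(fractions)),
            all(fractions >= 0))
  p <- fractions[fractions > 0]
  if (length(p) == 0L) stop("all-zero fraction vector")
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Genetic intra-tumor heterogeneity of a subclone composition
#'
#' Shannon index over the composition's cluster prevalences.
#'
#' @param composition a \code{\link{clone_composition}}.
#' @param base logarithm base.
#' @return one-row data.frame: sample_id, index_kind ("genetic"), shannon,
#'   n_components.
#' @export
genetic_ith <- function(composition, base = exp(1)) {
  stopifnot(inherits(composition, "clone_composition"))
  data.frame(sample_id = composition$sample_id, index_kind = "genetic",
             shannon = shannon_index(composition$clusters$prevalence, base),
             n_components = composition$n_clones,
             stringsAsFactors = FALSE)
}

.SUBSET_CLASSES <- list(
  epithelial_only = "epithelial",
  epithelial_stromal = c("epithelial", "stromal"),
  all = NULL)

#' Microenvironmental intra-tumor heterogeneity of a cell-fraction profile
#'
#' Restricts the profile to the requested compartment subset, renormalizes,
#' and applies the Shannon index.
#'
#' @param fractions named non-negative vector of cell-type fractions for one
#'   sample (or one row of a cell-fraction matrix).
#' @param subset "epithelial_only", "epithelial_stromal" or "all".
#' @param type_map data.frame with columns cell_type, class covering every
#'   cell type in \code{fractions}; defaults to
#'   \code{\link{default_cell_types}}.
#' @param sample_id label carried into the result.
#' @param base logarithm base.
#' @return one-row data.frame: sample_id, index_kind, shannon,
#'   n_components; NA shannon with a warning when the subset is empty.
#' @export
microenv_ith <- function(fractions,
                         subset = c("all", "epithelial_only",
                                    "epithelial_stromal"),
                         type_map = default_cell_types(),
                         sample_id = "sample", base = exp(1)) {
  subset <- match.arg(subset)
  stopifnot(!is.null(names(fractions)))
  unmapped <- setdiff(names(fractions), type_map$cell_type)
  if (length(unmapped) > 0L)
    stop("cell type(s) missing from type_map: ",
         paste(unmapped, collapse = ", "))
  kind <- switch(subset, all = "microenv_all",
                 epithelial_only = "microenv_epithelial",
                 epithelial_stromal = "microenv_epithelial_stromal")
  keep_classes <- .SUBSET_CLASSES[[subset]]
  if (!is.null(keep_classes)) {
    cls <- type_map$class[match(names(fractions), type_map$cell_type)]
    fractions <- fractions[cls %in% keep_classes]
  }
  if (length(fractions) == 0L || sum(fractions) <= 0) {
    warning("empty compartment subset for ", sample_id)
    return(data.frame(sample_id = sample_id, index_kind = kind,
                      shannon = NA_real_, n_components = 0L,
                      stringsAsFactors = FALSE))
  }
  data.frame(sample_id = sample_id, index_kind = kind,
             shannon = shannon_index(fractions, base),
             n_components = sum(fractions > 0),
             stringsAsFactors = FALSE)
}

#' Stratify samples into ordinal heterogeneity ranks
#'
#' Quantile bins (quartiles by default) labelled from very_low to
#' very_high; a value tied with an internal bin boundary falls in the lower
#' rank.
#'
#' @param values numeric vector (needs at least \code{n_ranks} distinct
#'   values).
#' @param n_ranks number of ranks.
#' @return ordered factor of length \code{length(values)}.
#' @export
ith_ranks <- function(values, n_ranks = 4L) {
  stopifnot(is.numeric(values), all(!is.na(values)))
  if (length(unique(values)) < n_ranks)
    stop("need at least ", n_ranks, " distinct values to form ", n_ranks,
         " ranks")
  breaks <- stats::quantile(values, probs = seq(0, 1, length.out = n_ranks + 1))
  breaks <- unique(as.numeric(breaks))
  if (length(breaks) < n_ranks + 1L)
    stop("quantile boundaries collapse: values too heavily tied for ",
         n_ranks, " ranks")
  labels <- if (n_ranks == 4L) c("very_low", "low", "high", "very_high")
            else paste0("rank", seq_len(n_ranks))
  cut(values, breaks = breaks, labels = labels, include.lowest = TRUE,
      right = TRUE, ordered_result = TRUE)
}
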