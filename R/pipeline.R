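# End-to-end wiring: purity filter -> CCF/clonality -> subclone inference
# -> Shannon ITH -> signatures -> cohort statistics, with a JSON config, a
# run manifest and per-stage seeds.

#' Recover per-sample genetic ITH from mutation calls
#'
#' The core analysis chain: retain samples passing the purity filter,
#' estimate CCFs and clonality (\code{\link{ccf_pipeline}}), infer each
#' sample's subclone composition from its CCFs and compute the genetic
#' Shannon index, plus clonal/subclonal burden counts.
#'
#' @param mutations mutation calls for the cohort.
#' @param meta sample metadata (sample_id, purity).
#' @param segments optional segments with total_cn and cellular_fraction.
#' @param min_purity purity threshold (strict ">").
#' @param min_vaf VAF filter applied before CCF estimation (strict ">").
#' @param rule clonality rule, see \code{\link{classify_clonality}}.
#' @param max_clusters passed to \code{\link{infer_subclones}}.
#' @return data.frame per retained sample: sample_id, shannon, n_clones,
#'   clonal_ssm, subclonal_ssm, clonal_cnv, subclonal_cnv, n_ssm_used.
#' @export
recover_genetic_ith <- function(mutations, meta, segments = NULL,
                                min_purity = 0.4, min_vaf = 0.05,
                                rule = "ci", max_clusters = 8L) {
  keep <- filter_samples_by_purity(meta, min_purity)
  mut <- mutations[mutations$sample_id %in% keep &
                     mutations$vaf > min_vaf, , drop = FALSE]
  ccf <- ccf_pipeline(mut, meta, segments, rule = rule)
  cnv_lab <- NULL
  if (!is.null(segments) && "cellular_fraction" %in% names(segments))
    cnv_lab <- data.frame(sample_id = segments$sample_id,
                          lab = classify_cnv_clonality(segments$cellular_fraction),
                          stringsAsFactors = FALSE)
  out <- lapply(keep, function(s) {
    cc <- ccf[ccf$sample_id == s, , drop = FALSE]
    if (nrow(cc) == 0L) return(NULL)
    comp <- infer_subclones(cc$ccf, max_clusters = max_clusters,
                            sample_id = s)
    div <- genetic_ith(comp)
    bl <- burden_summary(cc, if (is.null(cnv_lab)) NULL
                         else cnv_lab$lab[cnv_lab$sample_id == s])
    data.frame(sample_id = s, shannon = div$shannon,
               n_clones = div$n_components,
               clonal_ssm = bl[["clonal_ssm"]],
               subclonal_ssm = bl[["subclonal_ssm"]],
               clonal_cnv = bl[["clonal_cnv"]],
               subclonal_cnv = bl[["subclonal_cnv"]],
               n_ssm_used = nrow(cc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Microenvironmental ITH for every sample of a cell-fraction matrix
#'
#' @param cell_fractions matrix samples x cell types.
#' @param subsets which compartment subsets to compute.
#' @param type_map cell-type to class map.
#' @return data.frame: sample_id, index_kind, shannon, n_components.
#' @export
microenv_ith_matrix <- function(cell_fractions,
                                subsets = c("all", "epithelial_only",
                                            "epithelial_stromal"),
                                type_map = default_cell_types()) {
  do.call(rbind, lapply(subsets, function(sub) {
    do.call(rbind, lapply(rownames(cell_fractions), function(s)
      microenv_ith(cell_fractions[s, ], subset = sub, type_map = type_map,
                   sample_id = s)))
  }))
}

.stage_seed <- function(seed, stage) {
  .child_seed(seed, match(stage, c("simulate", "clonality", "diversity",
                                   "seeding", "signature", "cohort")))
}

#' Run the full analysis pipeline from a JSON config
#'
#' Stage blocks are optional; providing only a \code{simulate} block writes
#' the synthetic cohort and stops there. With input files (or a simulated
#' cohort) present, the clonality/diversity stage produces \code{ith.tsv},
#' the signature stage \code{model.json} and \code{evaluation.tsv}, and the
#' cohort stage \code{glm.tsv} and \code{band_enrichment.tsv}. A manifest
#' with the config hash, per-stage seeds and output checksums is written to
#' \code{manifest.json}.
#'
#' @param config path to a JSON config, or an equivalent list. Recognized
#'   blocks: \code{seed}; \code{simulate} (arguments of
#'   \code{\link{cohort_design}}); \code{input} (paths: mutations,
#'   segments, meta, cell_fractions, panel); \code{clonality} (min_purity,
#'   min_vaf, rule); \code{signature} (n_folds); \code{cohort} (glm
#'   covariates).
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else config_path <- NULL
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  manifest <- list(tool = "tumorith",
                   version = as.character(utils::packageVersion("tumorith")),
                   seed = seed, stage_seeds = list(), outputs = list())
  cfg_file <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))

  bundle <- NULL
  if (!is.null(config$simulate)) {
    s <- .stage_seed(seed, "simulate")
    manifest$stage_seeds$simulate <- s
    args <- config$simulate
    args$seed <- s
    design <- do.call(cohort_design, args)
    bundle <- simulate_cohort(design)
    cdir <- file.path(out_dir, "cohort")
    write_cohort(bundle, cdir)
    manifest$outputs$cohort <- cdir
  } else if (!is.null(config$input)) {
    inp <- config$input
    bundle <- list(
      mutations = read_mutations(inp$mutations),
      segments = if (!is.null(inp$segments))
        read_segments(inp$segments, coords = "zero_based") else NULL,
      meta = read_sample_meta(inp$meta),
      cell_fractions = if (!is.null(inp$cell_fractions))
        read_cell_fractions(inp$cell_fractions) else NULL,
      panel = if (!is.null(inp$panel)) read_gene_panel(inp$panel) else NULL,
      cytobands = if (!is.null(inp$cytobands))
        read_cytobands(inp$cytobands) else NULL)
  }
  if (is.null(bundle)) {
    .finish_manifest(manifest, out_dir)
    return(invisible(manifest))
  }
  if (!"purity" %in% names(bundle$meta))
    stop("pipeline halted at the purity filter: sample metadata has no ",
         "purity column")

  run_downstream <- !is.null(config$clonality) || !is.null(config$signature) ||
    !is.null(config$cohort) || is.null(config$simulate)
  if (is.null(config$clonality) && is.null(config$signature) &&
      is.null(config$cohort) && !is.null(config$simulate)) {
    .finish_manifest(manifest, out_dir)
    return(invisible(manifest))
  }

  cl_cfg <- if (is.null(config$clonality)) list() else config$clonality
  min_purity <- if (is.null(cl_cfg$min_purity)) 0.4 else cl_cfg$min_purity
  min_vaf <- if (is.null(cl_cfg$min_vaf)) 0.05 else cl_cfg$min_vaf
  ith <- recover_genetic_ith(bundle$mutations, bundle$meta, bundle$segments,
                             min_purity = min_purity, min_vaf = min_vaf,
                             rule = if (is.null(cl_cfg$rule)) "ci" else cl_cfg$rule)
  write_tsv_canonical(ith, file.path(out_dir, "ith.tsv"))
  manifest$outputs$ith <- "ith.tsv"
  if (!is.null(bundle$cell_fractions)) {
    micro <- microenv_ith_matrix(bundle$cell_fractions)
    write_tsv_canonical(micro, file.path(out_dir, "microenv_ith.tsv"))
    manifest$outputs$microenv_ith <- "microenv_ith.tsv"
  }

  if (!is.null(config$signature) && !is.null(bundle$panel)) {
    s <- .stage_seed(seed, "signature")
    manifest$stage_seeds$signature <- s
    n_folds <- if (is.null(config$signature$n_folds)) 10L
               else as.integer(config$signature$n_folds)
    X <- encode_ssm_features(bundle$mutations, bundle$panel,
                             samples = ith$sample_id, min_vaf = min_vaf)
    model <- fit_lasso_signature(X, ith$shannon, n_folds = n_folds, seed = s)
    write_signature_model(model, file.path(out_dir, "model.json"))
    ev <- evaluate_predictions(ith$shannon, predict_ith(model, X))
    write_tsv_canonical(ev, file.path(out_dir, "evaluation.tsv"))
    manifest$outputs$model <- "model.json"
  }

  if (!is.null(config$cohort) && "relapse" %in% names(bundle$meta)) {
    meta_kept <- bundle$meta[match(ith$sample_id, bundle$meta$sample_id), ]
    covs <- data.frame(genetic_ith = ith$shannon,
                       ssm_burden = ith$clonal_ssm + ith$subclonal_ssm,
                       cnv_burden = ith$clonal_cnv + ith$subclonal_cnv)
    if (!is.null(bundle$cell_fractions)) {
      mh <- microenv_ith_matrix(bundle$cell_fractions, subsets = "all")
      covs$microenv_ith <- mh$shannon[match(ith$sample_id, mh$sample_id)]
    }
    glm_res <- metastasis_glm(covs, meta_kept$relapse)
    write_tsv_canonical(as.data.frame(glm_res), file.path(out_dir, "glm.tsv"))
    manifest$outputs$glm <- "glm.tsv"
    if (!is.null(bundle$segments) && !is.null(bundle$cytobands)) {
      groups <- stats::setNames(ifelse(meta_kept$relapse == 1L, "relapse",
                                       "no_relapse"), meta_kept$sample_id)
      freqs <- cnv_band_frequencies(bundle$segments, bundle$cytobands, groups)
      if (length(unique(groups)) == 2L) {
        enr <- band_enrichment(freqs, "relapse", "no_relapse")
        write_tsv_canonical(enr, file.path(out_dir, "band_enrichment.tsv"))
        manifest$outputs$band_enrichment <- "band_enrichment.tsv"
      }
    }
  }
  .finish_manifest(manifest, out_dir)
  invisible(manifest)
}

.finish_manifest <- function(manifest, out_dir) {
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest$checksums <- stats::setNames(as.list(unname(sums)), files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
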