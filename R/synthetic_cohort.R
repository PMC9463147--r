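# Ground-truth tumor simulator: clone trees with nested cancer cell
# fractions, binomial read sampling under purity and coverage,
# primary-metastasis pairs with known seeding mode, and full cohorts with
# planted gene-ITH effects and a logistic relapse model.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# child seed derivation: one global seed fans out per stage via a counter
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483629)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a clone tree with known subclone fractions
#'
#' Clones are labelled C1..Ck with C1 the founder (root). Topology priors:
#' \code{"random"} attaches each new clone to a uniformly chosen existing
#' clone; \code{"chain"} gives a linear sequence of nested expansions (all
#' clone CCFs distinct); \code{"star"} makes every subclone a direct child
#' of the founder (branched evolution at bulk resolution). Clone fractions
#' (the proportion of tumor cells belonging exactly to each clone) are a
#' flat Dirichlet draw, resampled until every fraction reaches
#' \code{min_clone_fraction}; the cancer cell fraction (CCF) of a clone is
#' the sum of clone fractions over its subtree, so the root has CCF 1 and
#' CCF never increases from parent to child.
#'
#' @param n_clones number of clones (>= 1).
#' @param min_clone_fraction smallest admissible clone fraction.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param topology tree prior, see Details.
#' @param fractions optional explicit clone-fraction vector (must sum to 1);
#'   overrides the Dirichlet draw.
#' @return object of class \code{clone_tree}: list with elements
#'   \code{clones}, \code{parent} (named, NA for the root),
#'   \code{clone_fraction}, \code{ccf}, \code{n_clones}.
#' @export
simulate_clone_tree <- function(n_clones, min_clone_fraction = 0.05,
                                seed = NULL,
                                topology = c("random", "chain", "star"),
                                fractions = NULL) {
  topology <- match.arg(topology)
  stopifnot(n_clones >= 1)
  if (is.null(fractions) && min_clone_fraction * n_clones > 1)
    stop("infeasible: min_clone_fraction * n_clones > 1")
  .with_seed(seed, {
    clones <- paste0("C", seq_len(n_clones))
    parent <- rep(NA_character_, n_clones)
    if (n_clones > 1) {
      for (i in 2:n_clones) {
        parent[i] <- switch(topology,
          random = clones[sample.int(i - 1L, 1L)],
          chain  = clones[i - 1L],
          star   = clones[1L])
      }
    }
    if (is.null(fractions)) {
      repeat {
        fractions <- .rdirichlet1(rep(1, n_clones))
        if (all(fractions >= min_clone_fraction)) break
      }
    } else {
      stopifnot(length(fractions) == n_clones,
                abs(sum(fractions) - 1) < 1e-6, all(fractions >= 0))
      fractions <- fractions / sum(fractions)
    }
    names(parent) <- clones
    names(fractions) <- clones
    # subtree sums, children always have larger index than their parent
    ccf <- fractions
    if (n_clones > 1) {
      for (i in n_clones:2) ccf[parent[i]] <- ccf[parent[i]] + ccf[i]
    }
    structure(list(clones = clones, parent = parent,
                   clone_fraction = fractions, ccf = ccf,
                   n_clones = n_clones),
              class = "clone_tree")
  })
}

#' Clones on the path from the root to a clone (inclusive)
#' @param tree a \code{clone_tree}.
#' @param clone clone id.
#' @return character vector of clone ids, root first.
#' @export
clone_lineage <- function(tree, clone) {
  path <- clone
  while (!is.na(tree$parent[[clone]])) {
    clone <- tree$parent[[clone]]
    path <- c(clone, path)
  }
  unname(path)
}

#' Assign ground-truth variants to clones
#'
#' Each variant is placed on the root with probability \code{clonal_bias},
#' otherwise uniformly on a non-root clone. The variant's true CCF equals
#' its clone's CCF; SSM multiplicity is drawn in \{1, 2\}; a variant is
#' labelled clonal iff it sits on the root.
#'
#' @param tree a \code{clone_tree}.
#' @param n_ssm,n_cnv numbers of simple somatic mutations and copy-number
#'   events to plant.
#' @param panel character vector of gene symbols to draw from.
#' @param clonal_bias probability of assignment to the root clone.
#' @param seed integer seed.
#' @param p_multiplicity_2 probability that an SSM has multiplicity 2.
#' @return data.frame with columns id, type ("ssm"/"cnv"), clone, gene,
#'   true_ccf, multiplicity, clonality ("clonal"/"subclonal").
#' @export
assign_variants <- function(tree, n_ssm, n_cnv = 0, panel,
                            clonal_bias = 0.5, seed = NULL,
                            p_multiplicity_2 = 0.2) {
  stopifnot(length(panel) > 0)
  n <- n_ssm + n_cnv
  if (n == 0L) {
    return(data.frame(id = character(), type = character(),
                      clone = character(), gene = character(),
                      true_ccf = numeric(), multiplicity = integer(),
                      clonality = character(), stringsAsFactors = FALSE))
  }
  .with_seed(seed, {
    root <- tree$clones[1L]
    nonroot <- setdiff(tree$clones, root)
    clone <- if (length(nonroot) == 0L) rep(root, n) else {
      is_root <- stats::runif(n) < clonal_bias
      cl <- rep(root, n)
      cl[!is_root] <- sample(nonroot, sum(!is_root), replace = TRUE)
      cl
    }
    type <- rep(c("ssm", "cnv"), c(n_ssm, n_cnv))
    mult <- ifelse(type == "ssm",
                   1L + stats::rbinom(n, 1L, p_multiplicity_2), 1L)
    data.frame(
      id = paste0(type, "_", c(seq_len(n_ssm), seq_len(max(n_cnv, 0L)))[seq_len(n)]),
      type = type, clone = clone,
      gene = sample(panel, n, replace = TRUE),
      true_ccf = unname(tree$ccf[clone]),
      multiplicity = as.integer(mult),
      clonality = ifelse(clone == root, "clonal", "subclonal"),
      stringsAsFactors = FALSE)
  })
}

#' Simulate read counts for ground-truth SSMs
#'
#' Sequencing depth per site is zero-truncated Poisson with the given mean;
#' the expected variant allele fraction follows the purity / copy-number
#' relation \code{vaf = purity * ccf * m / (purity * CT + (1 - purity) * 2)}
#' with CT the local tumor copy number, and alt reads are Binomial(depth,
#' expected vaf). Expected VAFs above 1 are clipped with a warning.
#'
#' @param truth data.frame from \code{\link{assign_variants}} (rows with
#'   type "ssm" are used) or any data.frame with columns id, gene, true_ccf,
#'   multiplicity.
#' @param purity tumor purity in (0, 1].
#' @param mean_coverage mean sequencing depth.
#' @param seed integer seed.
#' @param tumor_cn local tumor copy number per variant (recycled; default 2).
#' @param sample_id sample id for the output calls.
#' @param chrom chromosome label(s) for the synthetic positions (recycled).
#' @param pos optional 1-based positions (default: 1000, 2000, ...).
#' @return data.frame of mutation calls (columns of
#'   \code{\link{read_mutations}}) plus variant_id, true_ccf, true_clonality.
#' @export
simulate_read_counts <- function(truth, purity, mean_coverage, seed = NULL,
                                 tumor_cn = 2L, sample_id = "S1",
                                 chrom = "chr1", pos = NULL) {
  stopifnot(purity > 0, purity <= 1, mean_coverage > 0)
  ssm <- if ("type" %in% names(truth)) truth[truth$type == "ssm", , drop = FALSE] else truth
  n <- nrow(ssm)
  if (n == 0L) return(.empty_mutations())
  ct <- rep_len(as.numeric(tumor_cn), n)
  chrom <- rep_len(chrom, n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  evaf <- purity * ssm$true_ccf * ssm$multiplicity /
    (purity * ct + (1 - purity) * 2)
  if (any(evaf > 1)) {
    warning(sum(evaf > 1), " expected VAF(s) > 1 clipped to 1")
    evaf <- pmin(evaf, 1)
  }
  .with_seed(seed, {
    depth <- stats::rpois(n, mean_coverage)
    while (any(depth == 0L))
      depth[depth == 0L] <- stats::rpois(sum(depth == 0L), mean_coverage)
    alt <- stats::rbinom(n, depth, evaf)
    data.frame(
      sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
      ref = "A", alt = "T",
      ref_depth = depth - alt, alt_depth = alt,
      gene = ssm$gene, impact = TRUE, vaf = alt / depth,
      variant_id = ssm$id, true_ccf = ssm$true_ccf,
      true_clonality = if ("clonality" %in% names(ssm)) ssm$clonality else NA_character_,
      tumor_cn = ct,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a primary-metastasis pair with known seeding mode
#'
#' Every clone of the primary tree carries \code{variants_per_clone} lineage
#' SSMs. The metastasis is founded by \code{n_seeding_clones} clones
#' (exactly 1 for monoclonal seeding, >= 2 for polyclonal) and inherits the
#' union of the seeding clones' lineage variants (root-to-clone paths); it
#' then acquires \code{n_private_met} new private variants, while the
#' primary acquires \code{n_private_primary} private variants the metastasis
#' never sees. Metastasis clone fractions are the seeding clones' primary
#' fractions renormalized to sum 1, so inherited variants get a metastasis
#' CCF equal to the summed fractions of the seeding clones carrying them.
#'
#' @param tree a \code{clone_tree} for the primary tumor.
#' @param mode "monoclonal" or "polyclonal".
#' @param n_seeding_clones number of disseminating clones.
#' @param n_private_primary,n_private_met private variant counts.
#' @param seed integer seed.
#' @param variants_per_clone lineage SSMs acquired by each clone.
#' @return list with data.frames \code{primary} and \code{met} (columns id,
#'   clone, gene, true_ccf, multiplicity, clonality), \code{mode},
#'   \code{seeding_clones} and the input \code{tree}.
#' @export
simulate_met_pair <- function(tree, mode = c("monoclonal", "polyclonal"),
                              n_seeding_clones = if (mode == "monoclonal") 1L else 2L,
                              n_private_primary = 0L, n_private_met = 0L,
                              seed = NULL, variants_per_clone = 30L) {
  mode <- match.arg(mode)
  nonroot <- setdiff(tree$clones, tree$clones[1L])
  if (mode == "monoclonal" && n_seeding_clones != 1L)
    stop("monoclonal seeding requires exactly one seeding clone")
  if (mode == "polyclonal") {
    if (n_seeding_clones < 2L)
      stop("polyclonal seeding requires >= 2 seeding clones")
    if (length(nonroot) < 2L)
      stop("polyclonal seeding requires a tree with >= 2 non-root clones")
  }
  .with_seed(seed, {
    root <- tree$clones[1L]
    # lineage variants: each clone acquires its own block of SSMs
    vars <- do.call(rbind, lapply(tree$clones, function(cl) {
      data.frame(id = paste0(cl, "_v", seq_len(variants_per_clone)),
                 clone = cl, stringsAsFactors = FALSE)
    }))
    vars$gene <- vars$id
    vars$multiplicity <- 1L
    pool <- if (length(nonroot) > 0L) nonroot else root
    seeds <- if (mode == "monoclonal") sample(pool, 1L)
             else sample(nonroot, n_seeding_clones)
    # primary: all tree variants at their clone CCFs, plus privates
    primary <- vars
    primary$true_ccf <- unname(tree$ccf[primary$clone])
    if (n_private_primary > 0L) {
      pp <- data.frame(id = paste0("privP_", seq_len(n_private_primary)),
                       clone = sample(tree$clones, n_private_primary,
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
      pp$gene <- pp$id
      pp$multiplicity <- 1L
      pp$true_ccf <- unname(tree$ccf[pp$clone])
      primary <- rbind(primary, pp)
    }
    primary$clonality <- ifelse(primary$clone == root, "clonal", "subclonal")
    # metastasis: union of seeding lineages, fractions renormalized
    met_frac <- tree$clone_fraction[seeds] / sum(tree$clone_fraction[seeds])
    lineages <- lapply(seeds, function(s) clone_lineage(tree, s))
    inherited_clones <- unique(unlist(lineages))
    met <- vars[vars$clone %in% inherited_clones, , drop = FALSE]
    met$true_ccf <- vapply(met$clone, function(cl) {
      sum(met_frac[vapply(seq_along(seeds), function(i)
        cl %in% lineages[[i]], logical(1))])
    }, numeric(1))
    if (n_private_met > 0L) {
      pm <- data.frame(id = paste0("privM_", seq_len(n_private_met)),
                       clone = sample(seeds, n_private_met, replace = TRUE),
                       stringsAsFactors = FALSE)
      pm$gene <- pm$id
      pm$multiplicity <- 1L
      pm$true_ccf <- vapply(pm$clone, function(cl)
        sum(met_frac[vapply(seq_along(seeds), function(i)
          cl %in% lineages[[i]], logical(1))]), numeric(1))
      met <- rbind(met, pm)
    }
    met$clonality <- ifelse(met$true_ccf >= 1 - 1e-9, "clonal", "subclonal")
    rownames(primary) <- rownames(met) <- NULL
    list(primary = primary, met = met, mode = mode,
         seeding_clones = seeds, tree = tree)
  })
}

#' Variant keys observed in a simulated sample after read-level detection
#'
#' A variant is called present when its observed VAF exceeds \code{min_vaf}
#' and it has at least \code{min_alt} supporting reads.
#'
#' @param calls data.frame from \code{\link{simulate_read_counts}}.
#' @param min_vaf detection VAF threshold (strict).
#' @param min_alt minimum alt read count.
#' @return character vector of variant ids.
#' @export
observed_variant_keys <- function(calls, min_vaf = 0.05, min_alt = 3L) {
  calls$variant_id[calls$vaf > min_vaf & calls$alt_depth >= min_alt]
}

# solve for a clone-fraction vector of k clones whose Shannon index equals
# the target: one-parameter family (a, (1-a)/(k-1), ...), a in [1/k, 1)
.fractions_for_shannon <- function(k, target_h) {
  if (k == 1L) return(1)
  h_of <- function(a) {
    p <- c(a, rep((1 - a) / (k - 1), k - 1))
    -sum(p * log(p))
  }
  if (target_h >= log(k) - 1e-12) return(rep(1 / k, k))
  a <- stats::uniroot(function(a) h_of(a) - target_h,
                      lower = 1 / k, upper = 1 - 1e-9, tol = 1e-12)$root
  c(a, rep((1 - a) / (k - 1), k - 1))
}

#' Default cell types and classes for microenvironment profiles
#'
#' Nine RNA-deconvolution cell signatures covering the epithelial
#' (CMS-like), stromal, myeloid and lymphoid compartments used throughout
#' the simulator and the microenvironment diversity subsets.
#'
#' @return data.frame with columns cell_type, class.
#' @export
default_cell_types <- function() {
  data.frame(
    cell_type = c("CMS1_like", "CMS2_like", "CMS3_like",
                  "myofibroblasts", "stalk_like_endothelial",
                  "pro_inflammatory_macrophages", "dendritic_cells",
                  "T_cells", "B_cells"),
    class = c("epithelial", "epithelial", "epithelial",
              "stromal", "stromal",
              "myeloid", "myeloid",
              "lymphoid", "lymphoid"),
    stringsAsFactors = FALSE)
}

# group-specific Dirichlet concentrations over default_cell_types();
# echoes subtype biology: CMS1 immune-rich, CMS2/3 epithelial-dominant,
# CMS4 stromal-rich
.default_cell_concentration <- function() {
  ct <- default_cell_types()$cell_type
  conc <- rbind(
    CMS1    = c(8, 2, 2, 2, 1, 3, 3, 8, 4),
    CMS2    = c(2, 14, 3, 2, 1, 1, 1, 3, 2),
    CMS3    = c(2, 3, 14, 2, 1, 1, 1, 3, 2),
    CMS4    = c(2, 3, 2, 10, 4, 4, 1, 4, 2),
    Unknown = c(3, 3, 3, 3, 2, 2, 2, 3, 3))
  colnames(conc) <- ct
  conc
}

#' Construct a cohort design for the synthetic generator
#'
#' Defaults describe a colorectal-cancer-like cohort: CMS group proportions
#' 27/36/12/19/18 (CMS1..CMS4, Unknown), a 50-gene candidate panel with a
#' planted 5-gene ITH signature (coefficient 0.35 per mutated gene, mutation
#' probability 0.4, Gaussian noise sd 0.3 on the Shannon target, sized so
#' the true Shannon index spans the observable range without saturating at
#' the clone-number cap), mean
#' coverage 200x, about 300 passenger SSMs per sample, and a logistic
#' relapse model with log-odds (per SD) 1.0 on genetic ITH, -0.5 on
#' microenvironmental ITH and 0.3 on each mutation burden.
#'
#' @param n_samples cohort size.
#' @param group_proportions named numeric vector, normalized internally.
#' @param panel candidate gene symbols.
#' @param planted_beta named numeric vector of per-gene effects on the
#'   Shannon-ITH target; names must be in \code{panel}.
#' @param planted_mut_prob per-sample mutation probability of planted genes.
#' @param background_mut_prob mutation probability of other panel genes.
#' @param base_ith intercept of the Shannon-ITH target.
#' @param noise_sd Gaussian noise sd on the target.
#' @param max_clones largest admissible clone number.
#' @param mean_ssm mean passenger SSM count per sample.
#' @param mean_cnv mean CNV segment count per sample.
#' @param mean_coverage mean sequencing depth.
#' @param purity_range sampling range for tumor purity.
#' @param relapse_intercept,relapse_coefs logistic relapse model:
#'   intercept plus log-odds per SD of (genetic ITH, microenv ITH, SSM
#'   burden, CNV burden).
#' @param amp_band_relapse_probs amplification probability of the planted
#'   relapse-associated band (chr8 band q-arm stand-in) given relapse
#'   status, c(relapse, no_relapse).
#' @param cell_concentration group x cell-type Dirichlet concentrations.
#' @param seed integer seed for the whole cohort.
#' @return list of class \code{cohort_design}.
#' @export
cohort_design <- function(n_samples = 100L,
                          group_proportions = c(CMS1 = 27, CMS2 = 36,
                                                CMS3 = 12, CMS4 = 19,
                                                Unknown = 18),
                          panel = sprintf("G%02d", 1:50),
                          planted_beta = stats::setNames(rep(0.35, 5), sprintf("G%02d", 1:5)),
                          planted_mut_prob = 0.4,
                          background_mut_prob = 0.05,
                          base_ith = 0.2,
                          noise_sd = 0.3,
                          max_clones = 4L,
                          mean_ssm = 300,
                          mean_cnv = 8,
                          mean_coverage = 200,
                          purity_range = c(0.5, 0.95),
                          relapse_intercept = -1.2,
                          relapse_coefs = c(genetic_ith = 1.0,
                                            microenv_ith = -0.5,
                                            ssm_burden = 0.3,
                                            cnv_burden = 0.3),
                          amp_band_relapse_probs = c(0.6, 0.2),
                          cell_concentration = .default_cell_concentration(),
                          seed = 1L) {
  stopifnot(n_samples >= 1, noise_sd > 0, all(group_proportions >= 0),
            all(names(planted_beta) %in% panel))
  group_proportions <- group_proportions / sum(group_proportions)
  structure(list(n_samples = as.integer(n_samples),
                 group_proportions = group_proportions, panel = panel,
                 planted_beta = planted_beta,
                 planted_mut_prob = planted_mut_prob,
                 background_mut_prob = background_mut_prob,
                 base_ith = base_ith, noise_sd = noise_sd,
                 max_clones = as.integer(max_clones),
                 mean_ssm = mean_ssm, mean_cnv = mean_cnv,
                 mean_coverage = mean_coverage,
                 purity_range = purity_range,
                 relapse_intercept = relapse_intercept,
                 relapse_coefs = relapse_coefs,
                 amp_band_relapse_probs = amp_band_relapse_probs,
                 cell_concentration = cell_concentration,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Synthetic cytoband table matching the simulator's genome
#'
#' A reduced genome of 22 chromosomes, each divided into eight 10-Mb bands
#' (p1..p4, q1..q4).
#' @return data.frame in the format of \code{\link{read_cytobands}}.
#' @export
synthetic_cytobands <- function() {
  bands <- c(paste0("p", 4:1), paste0("q", 1:4))
  df <- expand.grid(band = bands, chrom = paste0("chr", 1:22),
                    stringsAsFactors = FALSE)[, c("chrom", "band")]
  df$start <- rep(seq(0, 7e7, by = 1e7), times = 22)
  df$end <- df$start + 1e7
  df$band_id <- paste0(df$chrom, ":", df$band)
  df[, c("chrom", "start", "end", "band", "band_id")]
}

#' Simulate a full tumor cohort with known ground truth
#'
#' For each sample a Shannon-ITH target is drawn as \code{base_ith + sum of
#' planted-gene effects + Gaussian noise}; the target is realized exactly by
#' choosing a clone number (the smallest k with log(k) >= target, capped at
#' \code{max_clones}) and solving a one-parameter clone-fraction family for
#' the target entropy. Clone trees use the chain topology so every subclone
#' CCF is distinct (the identifiable regime for one-dimensional CCF
#' clustering). Passenger SSM read counts are simulated under the sample's
#' purity and coverage; planted and background panel-gene mutations are
#' written as clonal, impact-flagged SSMs. CNV segments are drawn on a
#' reduced 22-chromosome genome, with one relapse-associated band
#' ("chr8:q3") amplified preferentially in relapse samples. Cell fractions
#' come from group-specific Dirichlet concentrations, expression counts from
#' a negative binomial with group structure, and relapse labels from the
#' design's logistic model on standardized (genetic ITH, microenvironment
#' ITH, SSM burden, CNV burden).
#'
#' @param design a \code{\link{cohort_design}}.
#' @return list with elements \code{mutations}, \code{segments},
#'   \code{meta}, \code{cell_fractions} (matrix), \code{expression}
#'   (genes x samples counts), \code{truth} (per-sample planted values),
#'   \code{panel}, \code{cytobands}, \code{design}.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  n <- d$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  bands <- synthetic_cytobands()
  ct_tab <- default_cell_types()

  .with_seed(d$seed, {
    group <- sample(names(d$group_proportions), n, replace = TRUE,
                    prob = d$group_proportions)
    purity <- stats::runif(n, d$purity_range[1], d$purity_range[2])

    # planted + background mutation status per panel gene
    mut_status <- matrix(0L, n, length(d$panel),
                         dimnames = list(ids, d$panel))
    for (g in d$panel) {
      p <- if (g %in% names(d$planted_beta)) d$planted_mut_prob
           else d$background_mut_prob
      mut_status[, g] <- stats::rbinom(n, 1L, p)
    }

    effect <- as.numeric(mut_status[, names(d$planted_beta), drop = FALSE] %*%
                           d$planted_beta)
    target_h <- d$base_ith + effect + stats::rnorm(n, 0, d$noise_sd)
    target_h <- pmin(pmax(target_h, 0), log(d$max_clones))

    n_clones <- pmin(pmax(ceiling(exp(target_h) - 1e-9), 1L), d$max_clones)
    true_h <- numeric(n)
    trees <- vector("list", n)
    for (i in seq_len(n)) {
      fr <- .fractions_for_shannon(n_clones[i], target_h[i])
      trees[[i]] <- simulate_clone_tree(n_clones[i], min_clone_fraction = 0,
                                        topology = "chain", fractions = fr)
      p <- fr[fr > 0]
      true_h[i] <- -sum(p * log(p))
    }

    n_ssm <- stats::rpois(n, d$mean_ssm)
    n_ssm[n_ssm < 10L] <- 10L
    n_cnv <- stats::rpois(n, d$mean_cnv)

    # relapse depends on covariates; CNVs are drawn conditional on relapse
    # (planted band enrichment) and read counts then honor local copy number
    cf <- t(vapply(seq_len(n), function(i)
      .rdirichlet1(d$cell_concentration[group[i], ]),
      numeric(ncol(d$cell_concentration))))
    dimnames(cf) <- list(ids, colnames(d$cell_concentration))
    micro_h <- apply(cf, 1L, function(p) { p <- p[p > 0]; -sum(p * log(p)) })

    z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    lin <- d$relapse_intercept +
      d$relapse_coefs[["genetic_ith"]] * z(true_h) +
      d$relapse_coefs[["microenv_ith"]] * z(micro_h) +
      d$relapse_coefs[["ssm_burden"]] * z(n_ssm) +
      d$relapse_coefs[["cnv_burden"]] * z(n_cnv)
    relapse <- stats::rbinom(n, 1L, stats::plogis(lin))

    segments <- vector("list", n)
    relapse_band <- "chr8:q3"
    band_row <- bands[bands$band_id == relapse_band, ]
    for (i in seq_len(n)) {
      segs <- NULL
      if (n_cnv[i] > 0L) {
        chrom <- sample(paste0("chr", 1:22), n_cnv[i], replace = TRUE)
        start <- sample(seq(0, 6e7, by = 5e6), n_cnv[i], replace = TRUE)
        width <- sample(seq(5e6, 2e7, by = 5e6), n_cnv[i], replace = TRUE)
        call <- sample(c(-1L, 1L), n_cnv[i], replace = TRUE)
        segs <- data.frame(sample_id = ids[i], chrom = chrom, start = start,
                           end = pmin(start + width, 8e7),
                           log2_ratio = ifelse(call == 1L, 0.58, -1.0),
                           total_cn = ifelse(call == 1L, 3L, 1L),
                           call = call,
                           cellular_fraction = sample(c(1, 0.5), n_cnv[i],
                                                      replace = TRUE,
                                                      prob = c(0.6, 0.4)),
                           stringsAsFactors = FALSE)
      }
      p_amp <- if (relapse[i] == 1L) d$amp_band_relapse_probs[1]
               else d$amp_band_relapse_probs[2]
      if (stats::runif(1) < p_amp) {
        segs <- rbind(segs, data.frame(
          sample_id = ids[i], chrom = band_row$chrom, start = band_row$start,
          end = band_row$end, log2_ratio = 0.58, total_cn = 3L, call = 1L,
          cellular_fraction = 1, stringsAsFactors = FALSE))
      }
      segments[[i]] <- segs
    }

    # passenger SSMs spread over the genome, read counts honoring the
    # sample's local tumor copy number; panel-gene SSMs (clonal,
    # impact-flagged) sit on chrX, outside the simulated CNV genome
    local_cn <- function(chrom, pos, segs) {
      ct <- rep(2L, length(pos))
      if (!is.null(segs) && nrow(segs) > 0L) {
        for (r in seq_len(nrow(segs))) {
          hit <- chrom == segs$chrom[r] & pos > segs$start[r] &
            pos <= segs$end[r]
          ct[hit] <- segs$total_cn[r]
        }
      }
      pmax(ct, 1L)
    }
    mutations <- vector("list", n)
    for (i in seq_len(n)) {
      si <- .child_seed(d$seed, i)
      truth_i <- assign_variants(trees[[i]], n_ssm[i], 0,
                                 panel = "passenger", clonal_bias = 0.4,
                                 seed = si)
      truth_i$gene <- NA_character_
      pchrom <- .with_seed(.child_seed(d$seed, 3L * n + i), {
        ch <- sample(paste0("chr", 1:22), n_ssm[i], replace = TRUE)
        ps <- sample.int(8e7, n_ssm[i])
        list(ch, ps)
      })
      ct_i <- local_cn(pchrom[[1]], pchrom[[2]], segments[[i]])
      # multiplicity > 1 requires a copy-number gain at the locus; in
      # diploid or deleted regions every SSM is single-copy
      truth_i$multiplicity <- ifelse(ct_i >= 3L, truth_i$multiplicity, 1L)
      truth_i$multiplicity <- pmin(truth_i$multiplicity, ct_i)
      calls <- simulate_read_counts(truth_i, purity[i], d$mean_coverage,
                                    seed = .child_seed(d$seed, n + i),
                                    sample_id = ids[i], tumor_cn = ct_i,
                                    chrom = pchrom[[1]], pos = pchrom[[2]])
      calls$impact <- FALSE
      genes_mut <- d$panel[mut_status[i, ] == 1L]
      if (length(genes_mut) > 0L) {
        gt <- data.frame(id = paste0("gene_", genes_mut), type = "ssm",
                         clone = trees[[i]]$clones[1L], gene = genes_mut,
                         true_ccf = 1, multiplicity = 1L,
                         clonality = "clonal", stringsAsFactors = FALSE)
        gcalls <- simulate_read_counts(gt, purity[i], d$mean_coverage,
                                       seed = .child_seed(d$seed, 2L * n + i),
                                       sample_id = ids[i], chrom = "chrX")
        mutations[[i]] <- rbind(calls, gcalls)
      } else mutations[[i]] <- calls
    }

    # expression: NB counts with group-mean structure over the panel genes
    base_mu <- stats::rlnorm(length(d$panel), log(100), 0.8)
    group_shift <- matrix(stats::rlnorm(length(d$panel) *
                                          length(names(d$group_proportions)),
                                        0, 0.3),
                          nrow = length(d$panel),
                          dimnames = list(d$panel, names(d$group_proportions)))
    expr <- vapply(seq_len(n), function(i)
      stats::rnbinom(length(d$panel), mu = base_mu * group_shift[, group[i]],
                     size = 10),
      numeric(length(d$panel)))
    dimnames(expr) <- list(d$panel, ids)

    truth <- data.frame(sample_id = ids, group = group, purity = purity,
                        n_clones_true = n_clones, target_shannon = target_h,
                        true_shannon = true_h, microenv_shannon = micro_h,
                        n_ssm = n_ssm, n_cnv = n_cnv,
                        relapse_prob = stats::plogis(lin), relapse = relapse,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(mut_status))

    meta <- data.frame(sample_id = ids, purity = purity, ploidy = 2,
                       tissue = "primary", group = group, relapse = relapse,
                       stringsAsFactors = FALSE)

    list(mutations = do.call(rbind, mutations),
         segments = do.call(rbind, segments),
         meta = meta, cell_fractions = cf, expression = expr,
         truth = truth, panel = d$panel, cytobands = bands, design = d)
  })
}

#' Write a simulated cohort bundle to a directory
#'
#' Writes \code{mutations.tsv}, \code{segments.tsv} (0-based half-open),
#' \code{meta.tsv}, \code{cell_fractions.tsv}, \code{expression.tsv},
#' \code{cytobands.tsv}, \code{panel.txt} and \code{truth.tsv} in the
#' canonical dialect \code{\link{read_mutations}} and friends read back.
#'
#' @param bundle list from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_canonical(bundle$mutations, file.path(dir, "mutations.tsv"))
  write_tsv_canonical(bundle$segments, file.path(dir, "segments.tsv"))
  write_tsv_canonical(bundle$meta, file.path(dir, "meta.tsv"))
  cf <- data.frame(sample_id = rownames(bundle$cell_fractions),
                   bundle$cell_fractions, check.names = FALSE)
  write_tsv_canonical(cf, file.path(dir, "cell_fractions.tsv"))
  ex <- data.frame(gene = rownames(bundle$expression), bundle$expression,
                   check.names = FALSE)
  write_tsv_canonical(ex, file.path(dir, "expression.tsv"))
  write_tsv_canonical(bundle$cytobands, file.path(dir, "cytobands.tsv"))
  writeLines(bundle$panel, file.path(dir, "panel.txt"))
  write_tsv_canonical(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
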