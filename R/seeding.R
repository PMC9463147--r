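# Metastatic seeding clonality for primary-metastasis pairs: Jaccard
# similarity over variant sets (SSMs, optionally with reciprocally matched
# CNVs), the polyclonal threshold rule, shared copy-number events per
# cytoband, and a simulation benchmark for the classification rule.

#' Canonical SSM keys for set comparison
#' @param calls mutation data.frame (\code{\link{read_mutations}} format).
#' @return character vector "chrom:pos:ref:alt".
#' @export
ssm_keys <- function(calls) {
  unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"))
}

#' Jaccard similarity between two variant sets
#'
#' \code{jsi = |A intersect B| / |A union B|}; symmetric. When both sets
#' are empty the JSI is undefined and returned as NA with a warning.
#'
#' @param primary_variants,met_variants character vectors of canonical
#'   variant keys.
#' @return list: n_shared, n_private_primary, n_private_met, jsi.
#' @export
jaccard_similarity <- function(primary_variants, met_variants) {
  a <- unique(primary_variants)
  b <- unique(met_variants)
  n_shared <- length(intersect(a, b))
  n_pp <- length(setdiff(a, b))
  n_pm <- length(setdiff(b, a))
  denom <- n_shared + n_pp + n_pm
  if (denom == 0L) {
    warning("both variant sets empty: JSI undefined")
    jsi <- NA_real_
  } else jsi <- n_shared / denom
  list(n_shared = n_shared, n_private_primary = n_pp,
       n_private_met = n_pm, jsi = jsi)
}

#' Classify metastatic seeding from the JSI
#'
#' Polyclonal when \code{jsi > threshold} (strict), monoclonal otherwise;
#' an undefined JSI gives NA.
#'
#' @param jsi Jaccard similarity value(s) in [0, 1].
#' @param threshold polyclonal threshold, default 0.4.
#' @return character vector "monoclonal"/"polyclonal".
#' @export
classify_seeding <- function(jsi, threshold = 0.4) {
  ifelse(is.na(jsi), NA_character_,
         ifelse(jsi > threshold, "polyclonal", "monoclonal"))
}

# match CNV segments across two samples: >= 50% reciprocal overlap and the
# same call sign. Returns indices of matched pairs (greedy, best overlap
# first, one-to-one).
.match_cnvs <- function(seg_a, seg_b, min_reciprocal = 0.5) {
  if (is.null(seg_a) || is.null(seg_b) || nrow(seg_a) == 0L || nrow(seg_b) == 0L)
    return(matrix(integer(), ncol = 2L))
  ga <- GenomicRanges::GRanges(seg_a$chrom,
                               IRanges::IRanges(seg_a$start + 1L, seg_a$end))
  gb <- GenomicRanges::GRanges(seg_b$chrom,
                               IRanges::IRanges(seg_b$start + 1L, seg_b$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  if (length(hits) == 0L) return(matrix(integer(), ncol = 2L))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ga[qi], gb[si]))
  keep <- seg_a$call[qi] == seg_b$call[si] &
    ov >= min_reciprocal * GenomicRanges::width(ga[qi]) &
    ov >= min_reciprocal * GenomicRanges::width(gb[si])
  qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
  o <- order(ov, decreasing = TRUE)
  used_a <- logical(nrow(seg_a)); used_b <- logical(nrow(seg_b))
  out <- matrix(integer(), ncol = 2L)
  for (k in o) {
    if (!used_a[qi[k]] && !used_b[si[k]]) {
      out <- rbind(out, c(qi[k], si[k]))
      used_a[qi[k]] <- TRUE; used_b[si[k]] <- TRUE
    }
  }
  out
}

#' JSI for a primary-metastasis pair over SSMs and CNVs
#'
#' SSMs are matched by exact (chrom, pos, ref, alt) key; CNVs are matched
#' across the two samples by >= 50% reciprocal overlap with the same call
#' sign. The shared count is matched pairs; unmatched segments on either
#' side are private.
#'
#' @param primary_calls,met_calls mutation data.frames (may be NULL).
#' @param primary_segs,met_segs segment data.frames with non-neutral calls
#'   (may be NULL; neutral segments are ignored).
#' @param min_reciprocal reciprocal-overlap fraction for CNV identity.
#' @return list as \code{\link{jaccard_similarity}} plus variant_scope.
#' @export
jsi_with_cnvs <- function(primary_calls, met_calls,
                          primary_segs = NULL, met_segs = NULL,
                          min_reciprocal = 0.5) {
  a <- if (is.null(primary_calls)) character() else ssm_keys(primary_calls)
  b <- if (is.null(met_calls)) character() else ssm_keys(met_calls)
  shared <- length(intersect(a, b))
  pp <- length(setdiff(a, b))
  pm <- length(setdiff(b, a))
  pa <- if (!is.null(primary_segs))
    primary_segs[!is.na(primary_segs$call) & primary_segs$call != 0L, , drop = FALSE]
  pb <- if (!is.null(met_segs))
    met_segs[!is.na(met_segs$call) & met_segs$call != 0L, , drop = FALSE]
  na <- if (is.null(pa)) 0L else nrow(pa)
  nb <- if (is.null(pb)) 0L else nrow(pb)
  matched <- nrow(.match_cnvs(pa, pb, min_reciprocal))
  shared <- shared + matched
  pp <- pp + (na - matched)
  pm <- pm + (nb - matched)
  denom <- shared + pp + pm
  jsi <- if (denom == 0L) NA_real_ else shared / denom
  list(n_shared = shared, n_private_primary = pp, n_private_met = pm,
       jsi = jsi, variant_scope = if (na + nb > 0L) "ssm_and_cnv" else "ssm_only")
}

#' Copy-number events shared by a primary and its paired metastasis
#'
#' A cytoband is shared-amplified when both samples have an overlapping
#' call +1 segment on it (likewise shared-deleted for call -1).
#'
#' @param primary_segs,met_segs segment data.frames for the two samples.
#' @param cytobands cytoband table (\code{\link{read_cytobands}} format).
#' @return data.frame: band_id, event ("amp"/"del"), shared (logical) for
#'   every band x event with at least one overlapping call in either
#'   sample.
#' @export
shared_cnv_events <- function(primary_segs, met_segs, cytobands) {
  bg <- GenomicRanges::GRanges(cytobands$chrom,
                               IRanges::IRanges(cytobands$start + 1L,
                                                cytobands$end))
  covered <- function(segs, call_sign) {
    if (is.null(segs) || nrow(segs) == 0L) return(rep(FALSE, length(bg)))
    s <- segs[!is.na(segs$call) & segs$call == call_sign, , drop = FALSE]
    if (nrow(s) == 0L) return(rep(FALSE, length(bg)))
    sg <- GenomicRanges::GRanges(s$chrom,
                                 IRanges::IRanges(s$start + 1L, s$end))
    GenomicRanges::countOverlaps(bg, sg) > 0L
  }
  out <- do.call(rbind, lapply(c(amp = 1L, del = -1L), function(sgn) {
    p <- covered(primary_segs, sgn)
    m <- covered(met_segs, sgn)
    keep <- p | m
    data.frame(band_id = cytobands$band_id[keep],
               event = rep(if (sgn == 1L) "amp" else "del", sum(keep)),
               shared = (p & m)[keep], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate shared copy-number event frequencies across pairs
#'
#' @param pair_events list of data.frames from
#'   \code{\link{shared_cnv_events}} (one per pair).
#' @return data.frame band_id, event, n_shared, n_pairs, frequency.
#' @export
shared_cnv_frequencies <- function(pair_events) {
  n_pairs <- length(pair_events)
  all_ev <- do.call(rbind, pair_events)
  if (is.null(all_ev) || nrow(all_ev) == 0L)
    return(data.frame(band_id = character(), event = character(),
                      n_shared = integer(), n_pairs = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(shared ~ band_id + event, data = all_ev, FUN = sum)
  names(agg)[3L] <- "n_shared"
  agg$n_pairs <- n_pairs
  agg$frequency <- agg$n_shared / n_pairs
  agg
}

#' Benchmark the JSI seeding rule on simulated pairs
#'
#' For every cell of the parameter grid, simulates \code{n_pairs_per_mode}
#' monoclonal and polyclonal primary-metastasis pairs (branched "star"
#' trees, the regime where single-clone seeding shares only one lineage),
#' generates read counts at the cell's purity and coverage, detects
#' variants (VAF > 5%, >= 3 alt reads), computes the JSI and scores the
#' threshold rule against the simulated truth.
#'
#' @param coverage,purity,private_frac vectors defining the grid
#'   (private_frac = private variants in each tissue as a fraction of the
#'   tree's variant count).
#' @param n_pairs_per_mode pairs per mode per cell.
#' @param n_clones clones per primary tree.
#' @param n_seeding_clones seeding clones for the polyclonal mode.
#' @param min_clone_fraction smallest clone fraction in the simulated
#'   trees; the default keeps every subclone's variants detectable at the
#'   grid's coverage so the JSI reflects seeding, not detection dropout.
#' @param variants_per_clone lineage SSMs per clone.
#' @param threshold JSI threshold for \code{\link{classify_seeding}}.
#' @param seed integer seed.
#' @return data.frame: one row per grid cell with accuracy, sensitivity
#'   (polyclonal recall) and specificity.
#' @export
seeding_mode_benchmark <- function(coverage = 200, purity = 0.8,
                                   private_frac = 0.2,
                                   n_pairs_per_mode = 100L, n_clones = 5L,
                                   n_seeding_clones = 3L,
                                   min_clone_fraction = 0.15,
                                   variants_per_clone = 30L,
                                   threshold = 0.4, seed = 1L) {
  grid <- expand.grid(coverage = coverage, purity = purity,
                      private_frac = private_frac)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    cov <- grid$coverage[g]; pur <- grid$purity[g]
    n_priv <- round(grid$private_frac[g] * n_clones * variants_per_clone)
    truth <- rep(c("monoclonal", "polyclonal"), each = n_pairs_per_mode)
    pred <- character(length(truth))
    for (i in seq_along(truth)) {
      s <- .child_seed(seed, 10000L * g + i)
      tree <- simulate_clone_tree(n_clones,
                                  min_clone_fraction = min_clone_fraction,
                                  seed = s, topology = "star")
      pair <- simulate_met_pair(
        tree, mode = truth[i],
        n_seeding_clones = if (truth[i] == "monoclonal") 1L else n_seeding_clones,
        n_private_primary = n_priv, n_private_met = n_priv,
        seed = .child_seed(s, 1L), variants_per_clone = variants_per_clone)
      pc <- simulate_read_counts(pair$primary, pur, cov,
                                 seed = .child_seed(s, 2L))
      mc <- simulate_read_counts(pair$met, pur, cov,
                                 seed = .child_seed(s, 3L))
      j <- jaccard_similarity(observed_variant_keys(pc),
                              observed_variant_keys(mc))
      pred[i] <- classify_seeding(j$jsi, threshold)
    }
    data.frame(coverage = cov, purity = pur,
               private_frac = grid$private_frac[g],
               accuracy = mean(pred == truth),
               sensitivity = mean(pred[truth == "polyclonal"] == "polyclonal"),
               specificity = mean(pred[truth == "monoclonal"] == "monoclonal"))
  })
  do.call(rbind, res)
}
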