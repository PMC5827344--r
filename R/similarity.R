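#' Class-average patterns over a region, detrended
#'
#' Averages trial patterns within cells and removes a linear trend over
#' voxel index from each averaged vector (which also removes the mean).
#' Two averaging schemes are offered:
#' \describe{
#'   \item{searchlight}{the follow-up to the searchlight analysis: NS and PS
#'     averaged pooled across the analyzed phases, CS+ averaged per phase.}
#'   \item{roi}{the region-of-interest analysis: every class averaged per
#'     phase.}
#' }
#' Conditioning-run trials and shock-delivery CS+ trials are excluded
#' throughout.
#'
#' @param patterns a `trial_patterns` object.
#' @param region_voxels linear voxel indices of the region (nonempty).
#' @param scheme `"searchlight"` or `"roi"`.
#' @param detrend `"linear"` (default: remove best-fit line over voxel
#'   index), `"center"` (remove the mean only), or `"none"` (raw averages,
#'   for exact geometry checks).
#' @return for `"searchlight"`: list with vectors `NS`, `PS` and `CS` (a
#'   per-phase list). For `"roi"`: per-phase list of per-class vectors.
#' @export
average_and_detrend <- function(patterns, region_voxels,
                                scheme = c("searchlight", "roi"),
                                detrend = c("linear", "center", "none")) {
  scheme <- match.arg(scheme)
  detrend <- match.arg(detrend)
  if (length(region_voxels) == 0L) stop("region is empty")
  ev <- patterns$events
  keep <- ev$phase != "conditioning" & !ev$shock
  x <- patterns$patterns[, region_voxels, drop = FALSE]
  phases <- c("baseline", "conditioned", "extinction")
  cell_mean <- function(sel) {
    if (!any(sel)) stop("empty class/phase cell in region averaging")
    detrend_vector(colMeans(x[sel, , drop = FALSE]), detrend)
  }
  if (scheme == "searchlight") {
    cs <- lapply(phases, function(p)
      cell_mean(keep & ev$class == "CS+" & ev$phase == p))
    names(cs) <- phases
    list(NS = cell_mean(keep & ev$class == "NS"),
         PS = cell_mean(keep & ev$class == "PS"),
         CS = cs)
  } else {
    out <- lapply(phases, function(p) {
      cls <- lapply(c("NS", "PS", "CS+"), function(cl)
        cell_mean(keep & ev$class == cl & ev$phase == p))
      names(cls) <- c("NS", "PS", "CS+")
      cls
    })
    names(out) <- phases
    out
  }
}

detrend_vector <- function(v, method = "linear") {
  if (method == "none") return(v)
  if (method == "center") return(v - mean(v))
  idx <- seq_along(v)
  unname(stats::lm.fit(cbind(1, idx), v)$residuals)
}

#' Cosine similarity of two pattern vectors
#'
#' `dot(u, v) / (||u|| ||v||)`: 1 means proportional patterns, 0 orthogonal
#' (independent) patterns, -1 opposed patterns.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return cosine in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero-norm input")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Fisher transform of cosines or probabilities
#'
#' Probabilities in `[0, 1]` are first rescaled to `(-1, 1)` via `2p - 1`;
#' then `atanh` is applied, with inputs clipped to +/-(1 - 1e-7) to keep the
#' transform finite at the boundary.
#'
#' @param values numeric vector.
#' @param kind `"cosine"` (already in `[-1, 1]`) or `"probability"`.
#' @return transformed values.
#' @export
fisher_transform <- function(values, kind = c("cosine", "probability")) {
  kind <- match.arg(kind)
  x <- if (kind == "probability") 2 * values - 1 else values
  out <- atanh(pmin(pmax(as.numeric(x), -(1 - 1e-7)), 1 - 1e-7))
  attributes(out) <- attributes(x)
  out
}

#' Per-participant similarity table for a region
#'
#' For each participant: the cosine between the (detrended) region-average
#' CS+ pattern of each phase and the pooled NS and PS averages.
#'
#' @param cohort list of `trial_patterns` objects.
#' @param region_voxels linear voxel indices of the region.
#' @param detrend passed to [average_and_detrend()].
#' @return data frame with columns `participant`, `phase`, `cos_n`
#'   (NS--CS+ cosine) and `cos_p` (PS--CS+ cosine).
#' @export
similarity_table <- function(cohort, region_voxels, detrend = "linear") {
  phases <- c("baseline", "conditioned", "extinction")
  rows <- lapply(seq_along(cohort), function(i) {
    avg <- average_and_detrend(cohort[[i]], region_voxels,
                               scheme = "searchlight", detrend = detrend)
    data.frame(participant = i, phase = phases,
               cos_n = vapply(phases, function(p)
                 cosine_similarity(avg$NS, avg$CS[[p]]), numeric(1)),
               cos_p = vapply(phases, function(p)
                 cosine_similarity(avg$PS, avg$CS[[p]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjudicate among the representational-change models
#'
#' Estimates, per participant, the conditioning-induced angle changes
#' `delta_theta_n = theta_n(conditioned) - theta_n(baseline)` and
#' `delta_theta_p` likewise (angles recovered as `acos` of the measured
#' cosines), tests each across participants with a one-sample t test, and
#' issues the verdict: `B` if `theta_p` shrinks significantly while
#' `theta_n` does not change, `C` for the converse, `D` if both move in
#' their predicted directions, `A` if neither moves.
#'
#' @param sim_table a [similarity_table()] data frame.
#' @param alpha significance level of the two-sided group tests.
#' @return list with `verdict`, per-change mean estimates in degrees
#'   (`delta_theta_n_deg`, `delta_theta_p_deg`), their p values, and `alpha`.
#' @export
compare_models <- function(sim_table, alpha = 0.05) {
  bl <- sim_table[sim_table$phase == "baseline", ]
  co <- sim_table[sim_table$phase == "conditioned", ]
  bl <- bl[order(bl$participant), ]
  co <- co[order(co$participant), ]
  stopifnot(nrow(bl) == nrow(co), nrow(bl) >= 2L)
  to_deg <- 180 / pi
  d_n <- (acos(co$cos_n) - acos(bl$cos_n)) * to_deg
  d_p <- (acos(co$cos_p) - acos(bl$cos_p)) * to_deg
  p_n <- t.test(d_n)$p.value
  p_p <- t.test(d_p)$p.value
  n_up <- p_n < alpha && mean(d_n) > 0    # NS--CS+ angle widened
  p_down <- p_p < alpha && mean(d_p) < 0  # PS--CS+ angle shrank
  verdict <- if (p_down && n_up) "D" else if (p_down) "B" else
    if (n_up) "C" else "A"
  list(verdict = verdict,
       delta_theta_n_deg = mean(d_n), p_n = p_n,
       delta_theta_p_deg = mean(d_p), p_p = p_p,
       alpha = alpha)
}

#' Correlate similarity with decoding performance
#'
#' Pools participant-by-phase points and computes Pearson correlations
#' between the Fisher-transformed cosines and the Fisher-transformed (after
#' rescaling to (-1, 1)) decoding probabilities, for the NS--CS+ and PS--CS+
#' cosines separately. Significance is declared at a Bonferroni-style
#' family-wise threshold (0.005 default, i.e. 0.05 over ten
#' region-by-cosine tests).
#'
#' @param sim_table a [similarity_table()] data frame.
#' @param decoding data frame with columns `participant`, `phase`, `prob`
#'   (the region's decoding probability for that participant and phase).
#' @param alpha significance threshold for the reported flags.
#' @return list with `r_n`, `p_n`, `sig_n`, `r_p`, `p_p`, `sig_p`, `n`.
#' @export
correlate_similarity_decoding <- function(sim_table, decoding,
                                          alpha = 0.005) {
  merged <- merge(sim_table, decoding, by = c("participant", "phase"))
  if (nrow(merged) < 3L) stop("need at least 3 pooled points")
  fprob <- fisher_transform(merged$prob, "probability")
  if (sd(fprob) == 0 || sd(merged$cos_n) == 0 || sd(merged$cos_p) == 0)
    stop("zero-variance input to correlation")
  ct_n <- cor.test(fisher_transform(merged$cos_n, "cosine"), fprob)
  ct_p <- cor.test(fisher_transform(merged$cos_p, "cosine"), fprob)
  list(r_n = unname(ct_n$estimate), p_n = ct_n$p.value,
       sig_n = ct_n$p.value < alpha,
       r_p = unname(ct_p$estimate), p_p = ct_p$p.value,
       sig_p = ct_p$p.value < alpha,
       n = nrow(merged), alpha = alpha)
}
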