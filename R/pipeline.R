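#' Pipeline configuration
#'
#' Bundles every stage's parameters. Defaults reproduce the study design:
#' 8 runs across four phases, 36/24-trial schedules, a 50-voxel searchlight,
#' TFCE with E = 0.5, H = 2, dh = 0.1, one-tailed inference on negative
#' quadratic coefficients with sign-flip resampling, cluster threshold
#' z = 2.5758 (p < 0.005), and a 0.005 family-wise threshold for the
#' similarity-decoding correlations.
#'
#' @param design a [design_config()] object.
#' @param geometry a [representational_geometry()] object.
#' @param searchlight_n searchlight size in voxels.
#' @param lambda LDA shrinkage constant.
#' @param tfce a [tfce_params()] object.
#' @param n_permutations sign-flip Monte Carlo iterations (desk-scale
#'   default 1000; the full-scale convention is 10,000).
#' @param z_threshold cluster-defining z threshold.
#' @param flip_scheme sign-flip scheme, see [signflip_null()].
#' @param correlation_alpha family-wise threshold for the correlation stage.
#' @param region_value `"peak"` (decoding value at the cluster peak voxel) or
#'   `"mean"` (mean over the region) for the correlation stage.
#' @param max_regions similarity stage analyzes at most this many clusters
#'   (largest first).
#' @param seed integer seed; all pipeline randomness flows from it.
#' @param out_dir optional output directory; when set, stages write NIfTI
#'   maps, TSV tables, JSON verdicts and a run manifest there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            geometry = representational_geometry(),
                            searchlight_n = 50,
                            lambda = 0.01,
                            tfce = tfce_params(),
                            n_permutations = 1000,
                            z_threshold = qnorm(0.995),
                            flip_scheme = "uniform_k",
                            correlation_alpha = 0.005,
                            region_value = c("peak", "mean"),
                            max_regions = 5,
                            seed = 1,
                            out_dir = NULL) {
  structure(list(design = design, geometry = geometry,
                 searchlight_n = as.integer(searchlight_n), lambda = lambda,
                 tfce = tfce, n_permutations = as.integer(n_permutations),
                 z_threshold = z_threshold, flip_scheme = flip_scheme,
                 correlation_alpha = correlation_alpha,
                 region_value = match.arg(region_value),
                 max_regions = as.integer(max_regions),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a synthetic cohort:
#' \describe{
#'   \item{simulate}{event schedules and trial pattern sets for the cohort.}
#'   \item{decode}{searchlight cross-decoding, one probability map per
#'     participant and phase.}
#'   \item{infer}{per-voxel quadratic coefficients, Anderson-Darling
#'     normality screen, one-tailed group t, sign-flip TFCE null, empirical
#'     FWER p values, cluster extraction.}
#'   \item{similarity}{per surviving cluster: cosine similarity table around
#'     the peak, model verdict, correlation of similarity with decoding.}
#'   \item{roi}{control analysis on the informative region: per-phase
#'     CS+ vs PS decoding and CS+/PS cosines, with repeated-measures F tests
#'     across phases.}
#'   \item{report}{summary list (and files, when `out_dir` is set) plus the
#'     run manifest.}
#' }
#' Later stages require earlier ones (either in `stages` or supplied via
#' `state` from a previous call); a missing dependency raises an error
#' naming the absent stage.
#'
#' @param config a [pipeline_config()] object.
#' @param stages `"all"` or a subset of
#'   `c("simulate", "decode", "infer", "similarity", "roi", "report")`.
#' @param state optional result of a previous [run_pipeline()] call to build
#'   on.
#' @return list of class `fear_pipeline` with one element per completed
#'   stage plus `manifest`.
#' @export
run_pipeline <- function(config, stages = "all", state = NULL) {
  all_stages <- c("simulate", "decode", "infer", "similarity", "roi",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  st <- if (is.null(state)) list() else state
  st$config <- config
  need <- function(what, stage) {
    if (is.null(st[[what]]))
      stop("stage '", stage, "' requires missing upstream stage output '",
           what, "'")
    st[[what]]
  }
  set.seed(config$seed)
  t0 <- Sys.time()

  if ("simulate" %in% stages)
    st$cohort <- simulate_cohort(config$design, config$geometry,
                                 seed = config$seed)

  if ("decode" %in% stages) {
    cohort <- need("cohort", "decode")
    mask <- array(TRUE, config$geometry$grid_shape)
    spec <- searchlight_spec(config$searchlight_n, mask)
    st$neighborhoods <- build_neighborhoods(spec)
    st$maps <- lapply(cohort, cross_decode, nbhd = st$neighborhoods,
                      lambda = config$lambda)
  }

  if ("infer" %in% stages) {
    maps <- need("maps", "infer")
    nbhd <- need("neighborhoods", "infer")
    quad <- quadratic_coefficients(maps)
    screen <- anderson_darling_screen(quad$a)
    obs <- group_tfce(quad$a, nbhd$centers, nbhd$dims, config$tfce,
                      tail = "negative")
    null <- signflip_null(quad$a, nbhd$centers, nbhd$dims,
                          m = config$n_permutations, params = config$tfce,
                          tail = "negative", scheme = config$flip_scheme)
    pvals <- empirical_p(obs$tfce, null)
    clusters <- threshold_clusters(pvals, obs$t, nbhd$centers, nbhd$dims,
                                   z_threshold = config$z_threshold,
                                   connectivity = config$tfce$connectivity)
    st$inference <- list(quadratic = quad, normality_screen = screen,
                         t = obs$t, tfce = obs$tfce, dof = obs$dof,
                         null = null, p_fwer = pvals, clusters = clusters)
  }

  if ("similarity" %in% stages) {
    inf <- need("inference", "similarity")
    cohort <- need("cohort", "similarity")
    nbhd <- need("neighborhoods", "similarity")
    maps <- need("maps", "similarity")
    clus <- inf$clusters
    n_regions <- min(nrow(clus), config$max_regions)
    st$similarity <- lapply(seq_len(n_regions), function(i) {
      ijk <- as.numeric(clus[i, c("peak_i", "peak_j", "peak_k")])
      peak <- as.integer(sum((ijk - 1) *
                               c(1, nbhd$dims[1],
                                 nbhd$dims[1] * nbhd$dims[2]))) + 1L
      pos <- match(peak, nbhd$centers)
      region <- nbhd$nb[, pos]
      tab <- similarity_table(cohort, region)
      decoding <- region_decoding_values(maps, nbhd, region, pos,
                                         config$region_value)
      list(cluster_id = clus$cluster_id[i], peak_voxel = peak,
           region_voxels = region, table = tab,
           verdict = compare_models(tab),
           correlation = correlate_similarity_decoding(
             tab, decoding, alpha = config$correlation_alpha))
    })
  }

  if ("roi" %in% stages) {
    cohort <- need("cohort", "roi")
    roi <- which(config$geometry$informative_mask)
    phases <- c("baseline", "conditioned", "extinction")
    acc <- sapply(phases, function(p)
      vapply(cohort, function(pp) as.numeric(roi_decode(pp, roi, p,
                                                        config$lambda)),
             numeric(1)))
    cosines <- t(vapply(cohort, function(pp) {
      avg <- average_and_detrend(pp, roi, scheme = "roi")
      vapply(phases, function(p)
        cosine_similarity(avg[[p]][["CS+"]], avg[[p]][["PS"]]), numeric(1))
    }, numeric(3)))
    acc_t <- lapply(phases, function(p)
      t.test(fisher_transform(acc[, p], "probability"), alternative = "greater"))
    names(acc_t) <- phases
    st$roi <- list(accuracy = acc, cosine = cosines,
                   above_chance = acc_t,
                   accuracy_anova = rm_anova_oneway(
                     fisher_transform(acc, "probability")),
                   cosine_anova = rm_anova_oneway(
                     fisher_transform(cosines, "cosine")))
  }

  if ("report" %in% stages) {
    inf <- need("inference", "report")
    st$report <- list(
      phase_profile = phase_profile_summary(need("maps", "report"),
                                            need("neighborhoods", "report"),
                                            config$geometry),
      clusters = inf$clusters,
      normality_screen = inf$normality_screen,
      verdicts = lapply(st$similarity, function(s)
        c(cluster_id = s$cluster_id, s$verdict)),
      roi = st$roi)
    st$manifest <- write_outputs(st, config, t0)
  }

  structure(st, class = "fear_pipeline")
}

region_decoding_values <- function(maps, nbhd, region, peak_pos,
                                   region_value) {
  phases <- c("baseline", "conditioned", "extinction")
  pos <- if (region_value == "peak") peak_pos else
    match(intersect(region, nbhd$centers), nbhd$centers)
  do.call(rbind, lapply(seq_along(maps), function(i) {
    data.frame(participant = i, phase = phases,
               prob = vapply(phases, function(p)
                 mean(maps[[i]]$prob[p, pos]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
}

# mean decoding probability per phase inside and outside the informative
# region -- the data behind the phase-profile figure
phase_profile_summary <- function(maps, nbhd, geometry) {
  inside <- nbhd$centers %in% which(geometry$informative_mask)
  phases <- c("baseline", "conditioned", "extinction")
  group <- Reduce(`+`, lapply(maps, `[[`, "prob")) / length(maps)
  data.frame(phase = phases,
             informative = rowMeans(group[phases, inside, drop = FALSE]),
             background = rowMeans(group[phases, !inside, drop = FALSE]))
}

write_outputs <- function(st, config, t0) {
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$out_dir, name)
    inf <- st$inference
    nbhd <- st$neighborhoods
    write_volume(vector_to_volume(inf$t, nbhd$centers, nbhd$dims),
                 out("group_t.nii.gz"))
    write_volume(vector_to_volume(inf$tfce, nbhd$centers, nbhd$dims),
                 out("group_tfce.nii.gz"))
    write_volume(vector_to_volume(inf$p_fwer, nbhd$centers, nbhd$dims),
                 out("p_fwer.nii.gz"))
    write.table(as.data.frame(inf$clusters), out("clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(st$similarity)) {
      sim <- do.call(rbind, lapply(st$similarity, function(s)
        cbind(cluster_id = s$cluster_id, s$table)))
      sim$fisher_cos_n <- fisher_transform(sim$cos_n, "cosine")
      sim$fisher_cos_p <- fisher_transform(sim$cos_p, "cosine")
      write.table(sim, out("similarity.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(st$report$verdicts, out("verdicts.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    write.table(st$report$phase_profile, out("phase_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(config$out_dir, full.names = TRUE)
  }
  list(package_version = as.character(packageVersion("fearspace")),
       seed = config$seed,
       started = format(t0), finished = format(Sys.time()),
       files = data.frame(path = files,
                          md5 = if (length(files))
                            unname(tools::md5sum(files)) else character(0)))
}
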