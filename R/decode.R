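#' Train a regularized linear discriminant
#'
#' Two-class LDA with pooled within-class covariance shrunk toward a scaled
#' identity: `S_reg = S + lambda * mean(diag(S)) * I`. The returned decision
#' function is `f(x) = w'x + b` with `w = S_reg^{-1} (mu_pos - mu_neg)` and
#' the bias placing the boundary midway between the class means; `f > 0`
#' labels the positive (phobic) class. Shrinkage keeps the discriminant
#' stable when the 50-voxel searchlight approaches or exceeds the per-class
#' sample count.
#'
#' @param x sample-by-voxel training matrix.
#' @param labels vector of two class labels.
#' @param positive label treated as the positive class (decision value > 0);
#'   defaults to `"PS"` when present, else the second sorted label.
#' @param lambda shrinkage constant, >= 0 (0.01 default).
#' @return object of class `lda_discriminant` with `w`, `b`, `positive`,
#'   `negative`.
#' @export
train_lda <- function(x, labels, positive = NULL, lambda = 0.01) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("train_lda needs exactly two classes, got: ",
         paste(lev, collapse = ", "))
  if (is.null(positive)) positive <- if ("PS" %in% lev) "PS" else lev[2L]
  if (!positive %in% lev) stop("positive class not present in labels")
  negative <- setdiff(lev, positive)
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  mu_pos <- colMeans(x[labels == positive, , drop = FALSE])
  mu_neg <- colMeans(x[labels == negative, , drop = FALSE])
  xc <- x
  xc[labels == positive, ] <- sweep(x[labels == positive, , drop = FALSE],
                                    2, mu_pos)
  xc[labels == negative, ] <- sweep(x[labels == negative, , drop = FALSE],
                                    2, mu_neg)
  s <- crossprod(xc) / (nrow(x) - 2L)
  diag(s) <- diag(s) + lambda * mean(diag(s))
  w <- solve(s, mu_pos - mu_neg)
  b <- -sum(w * (mu_pos + mu_neg) / 2)
  structure(list(w = w, b = b, positive = positive, negative = negative,
                 lambda = lambda), class = "lda_discriminant")
}

#' Decision values and labels of a trained discriminant
#'
#' @param object an `lda_discriminant`.
#' @param newx sample-by-voxel matrix.
#' @param type `"decision"` for signed decision values, `"label"` for class
#'   labels.
#' @param ... unused.
#' @return numeric decision values or character labels.
#' @export
predict.lda_discriminant <- function(object, newx,
                                     type = c("label", "decision"), ...) {
  type <- match.arg(type)
  f <- drop(as.matrix(newx) %*% object$w) + object$b
  if (type == "decision") f else
    ifelse(f > 0, object$positive, object$negative)
}

#' Searchlight cross-decoding of CS+ as phobic
#'
#' The core cross-decoding scheme: in every searchlight and every
#' leave-one-run-out fold over the seven analyzed runs (the conditioning run
#' is never used), an LDA classifier is trained to discriminate NS from PS
#' trials pooled across all phases of the six training runs, then tested on
#' the non-shock CS+ trials of the held-out run. The voxel's value is the
#' fraction of those CS+ test trials labeled PS -- the probability of the
#' classifier calling the conditioned stimulus phobic. Fold maps are averaged
#' within the phase their held-out run belongs to, yielding one probability
#' map per phase.
#'
#' @param patterns a `trial_patterns` object (trial t-maps or pattern maps).
#' @param nbhd a [build_neighborhoods()] object.
#' @param lambda LDA shrinkage constant.
#' @return object of class `phase_maps`: list with `prob` (3 x n-centers
#'   matrix, rows baseline/conditioned/extinction), `centers`, `dims`, and
#'   `folds` (per-fold bookkeeping).
#' @export
cross_decode <- function(patterns, nbhd, lambda = 0.01) {
  ev <- patterns$events
  analyzed <- sort(unique(ev$run[ev$phase != "conditioning"]))
  phases <- c("baseline", "conditioned", "extinction")
  run_phase <- vapply(analyzed,
                      function(r) unique(ev$phase[ev$run == r]), "")
  if (!all(phases %in% run_phase)) stop("a phase has no analyzed run")
  n_centers <- ncol(nbhd$nb)
  fold_maps <- matrix(NA_real_, length(analyzed), n_centers)
  for (f in seq_along(analyzed)) {
    held <- analyzed[f]
    train_runs <- setdiff(analyzed, held)
    tr_idx <- which(ev$class %in% c("NS", "PS") & ev$run %in% train_runs)
    te_idx <- which(ev$class == "CS+" & !ev$shock & ev$run == held)
    stopifnot(length(intersect(tr_idx, te_idx)) == 0L)
    xtr <- patterns$patterns[tr_idx, , drop = FALSE]
    y <- as.integer(ev$class[tr_idx] == "PS")
    mu1 <- colMeans(xtr[y == 1L, , drop = FALSE])
    mu0 <- colMeans(xtr[y == 0L, , drop = FALSE])
    xc <- xtr
    xc[y == 1L, ] <- sweep(xtr[y == 1L, , drop = FALSE], 2, mu1)
    xc[y == 0L, ] <- sweep(xtr[y == 0L, , drop = FALSE], 2, mu0)
    fold_maps[f, ] <- slda_fractions(xc, patterns$patterns[te_idx, ,
                                                           drop = FALSE],
                                     mu1 - mu0, (mu1 + mu0) / 2,
                                     nbhd$nb - 1L, lambda,
                                     nrow(xtr) - 2L)
  }
  prob <- t(sapply(phases,
                   function(p) colMeans(fold_maps[run_phase == p, ,
                                                  drop = FALSE])))
  structure(list(prob = prob, centers = nbhd$centers, dims = nbhd$dims,
                 folds = data.frame(run = analyzed, phase = run_phase)),
            class = "phase_maps")
}

#' Within-phase ROI decoding of CS+ versus PS
#'
#' Control analysis: within one experimental phase, leave-one-run-out
#' classification of (non-shock) CS+ trials against PS trials over a fixed
#' region's voxels, returning the mean accuracy over folds.
#'
#' Because the phases contribute different run counts (2 baseline, 3
#' conditioned, 2 extinction), raw within-phase folds would train on
#' different amounts of data, which by itself shifts accuracy across phases
#' and would masquerade as a phase effect. By default the training set of
#' every fold is therefore subsampled (without replacement, per class) to
#' the largest per-class count achievable in every fold of every analyzed
#' phase, making per-phase accuracies directly comparable. Set
#' `train_per_class = Inf` for raw unbalanced folds.
#'
#' Training-set subsampling uses the current RNG state.
#'
#' @param patterns a `trial_patterns` object.
#' @param roi_voxels linear voxel indices of the region (nonempty).
#' @param phase one of `"baseline"`, `"conditioned"`, `"extinction"`.
#' @param lambda LDA shrinkage constant.
#' @param train_per_class per-class training trials per fold: `NULL`
#'   (default) balances across all analyzed phases, a number caps each
#'   class at that count, `Inf` disables balancing.
#' @return mean accuracy over folds, with per-fold accuracies as attribute
#'   `"folds"`.
#' @export
roi_decode <- function(patterns, roi_voxels, phase, lambda = 0.01,
                       train_per_class = NULL) {
  if (length(roi_voxels) == 0L) stop("ROI is empty")
  ev <- patterns$events
  runs <- sort(unique(ev$run[ev$phase == phase]))
  if (length(runs) < 2L) stop("phase ", phase, " has fewer than 2 runs")
  usable <- (ev$class %in% c("CS+", "PS")) & !ev$shock
  if (is.null(train_per_class))
    train_per_class <- balanced_training_count(ev, usable)
  use <- usable & ev$phase == phase
  acc <- vapply(runs, function(held) {
    tr <- which(use & ev$run != held)
    te <- which(use & ev$run == held)
    if (is.finite(train_per_class))
      tr <- unlist(lapply(c("CS+", "PS"), function(cl) {
        cand <- tr[ev$class[tr] == cl]
        if (length(cand) > train_per_class)
          sample(cand, train_per_class) else cand
      }), use.names = FALSE)
    fit <- train_lda(patterns$patterns[tr, roi_voxels, drop = FALSE],
                     ev$class[tr], positive = "PS", lambda = lambda)
    pred <- predict(fit, patterns$patterns[te, roi_voxels, drop = FALSE])
    mean(pred == ev$class[te])
  }, numeric(1))
  structure(mean(acc), folds = acc)
}

# largest per-class per-fold training count achievable in every
# leave-one-run-out fold of every analyzed phase
balanced_training_count <- function(ev, usable) {
  phases <- setdiff(unique(ev$phase), "conditioning")
  min(unlist(lapply(phases, function(q) {
    runs_q <- unique(ev$run[ev$phase == q])
    vapply(runs_q, function(held) {
      tr <- usable & ev$phase == q & ev$run != held
      min(sum(tr & ev$class == "CS+"), sum(tr & ev$class == "PS"))
    }, numeric(1))
  })))
}
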