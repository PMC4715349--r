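#' Fit the L1 one-class model on training random regions
#'
#' The training set of likely non-SVs defines a centroid `M` (column means in
#' transformed space) and the empirical distribution of training L1 distances
#' from `M`.  The classification region at level `p` is the multidimensional
#' rhombus of points within `t_p` (the empirical p-quantile of training
#' distances) of `M`.
#'
#' @param training An [annotation_table()] of training sites (raw values).
#' @param transform A [fit_transform_model()] fitted on the same training
#'   table (its annotations must all be present).
#' @param min_train Minimum training size (default 100).
#' @return A list of class `oneclass_l1`: `M`, sorted `distances`, `n_train`,
#'   `transform`, `annotations`.
#' @export
fit_l1_model <- function(training, transform, min_train = 100) {
  stopifnot(inherits(training, "annotation_table"),
            inherits(transform, "transform_model"))
  z <- apply_transform(transform, training)$values
  if (nrow(z) < min_train)
    stop("need at least ", min_train, " training sites; got ", nrow(z))
  M <- colMeans(z)
  d <- as.numeric(rowSums(abs(sweep(z, 2, M))))
  structure(list(M = M, distances = sort(d), n_train = length(d),
                 transform = transform, annotations = names(M)),
            class = "oneclass_l1")
}

#' @export
print.oneclass_l1 <- function(x, ...) {
  cat("L1 one-class model:", x$n_train, "training sites,",
      length(x$M), "annotations\n")
  invisible(x)
}

l1_site_distance <- function(model, site_vector) {
  if (length(site_vector) != length(model$M))
    stop("site vector has ", length(site_vector), " values; model expects ",
         length(model$M))
  if (!is.null(names(site_vector))) site_vector <- site_vector[model$annotations]
  sum(abs(site_vector - model$M))
}

#' rho score of a site under the L1 one-class model
#'
#' The proportion of training random sites strictly closer to the centroid
#' than the candidate: high rho means the site's annotations are unlike
#' nearly all random regions, i.e. strong SV evidence.
#'
#' @param model A [fit_l1_model()] object.
#' @param site_vector Transformed annotation vector in the model's space.
#' @return rho in \code{[0, 1]}.
#' @export
rho_score <- function(model, site_vector) {
  d <- l1_site_distance(model, site_vector)
  sum(model$distances < d) / model$n_train
}

#' Empirical threshold t_p of the training distances
#'
#' The smallest training distance with at least `p * n_train` training
#' distances less than or equal to it (order-statistic quantile, no
#' interpolation).
#'
#' @param model A [fit_l1_model()] object.
#' @param p Proportion in (0, 1).
#' @return Threshold distance.
#' @export
l1_threshold <- function(model, p) {
  stopifnot(p > 0, p < 1)
  model$distances[ceiling(p * model$n_train)]
}

#' Classify a site with the L1 one-class rule
#'
#' SV if and only if the site's L1 distance from the centroid strictly
#' exceeds `t_p`; distances at exactly `t_p` are non-SV (conservative).
#'
#' @inheritParams rho_score
#' @param p Training proportion enclosed by the boundary (e.g. 0.95, 0.99).
#' @return `"SV"` or `"non-SV"`.
#' @export
classify_l1 <- function(model, site_vector, p) {
  d <- l1_site_distance(model, site_vector)
  if (d > l1_threshold(model, p)) "SV" else "non-SV"
}

#' Score a table of candidate sites under a one-class model
#'
#' Applies the model's transform and returns one score per row: rho for an
#' `oneclass_l1` model, the smallest-true-negative-rate score for an
#' `oneclass_svm` model.
#'
#' @param model A [fit_l1_model()] or [fit_svm_model()] object.
#' @param table An [annotation_table()] of raw candidate values.
#' @return Named numeric vector of scores in \code{[0, 1]}.
#' @export
score_sites <- function(model, table) {
  z <- apply_transform(model$transform, table)$values
  z <- z[, model$annotations, drop = FALSE]
  if (inherits(model, "oneclass_l1")) {
    d <- as.numeric(rowSums(abs(sweep(z, 2, model$M))))
    setNames(vapply(d, function(di) sum(model$distances < di), 0) / model$n_train,
             rownames(z))
  } else if (inherits(model, "oneclass_svm")) {
    u <- svm_directional_transform(model, z)
    inside <- vapply(model$models,
                     function(m) as.logical(predict(m, u)), logical(nrow(u)))
    if (nrow(u) == 1L) inside <- matrix(inside, nrow = 1L)
    setNames(apply(inside, 1L, function(ins) {
      if (!any(ins)) 1 else 1 - max(model$nu_grid[ins])
    }), rownames(z))
  } else stop("unknown model class")
}

#' Default deviation directions for the one-class SVM transform
#'
#' For a deletion-oriented candidate set: depth below normal is deviant;
#' clipping, discordance, mate-unmapped and insert-size statistics above
#' normal are deviant; the long-read del-ins difference is two-sided
#' (deletions push it up, insertions down).
#'
#' @param annotations Annotation names.
#' @return Named character vector over `{"low", "high", "two_sided"}`.
#' @export
default_deviation_directions <- function(annotations) {
  dir <- setNames(rep("two_sided", length(annotations)), annotations)
  dir[grepl("_Cov$", annotations)] <- "low"
  dir[grepl("_(SoftClip|Discord|MateUnmapped|InsertMean|InsertSd)$",
            annotations)] <- "high"
  dir[grepl("DelInsDiff$", annotations)] <- "two_sided"
  dir
}

# Directional deviation value: larger = more deviant in the direction of
# interest.
deviation_value <- function(z, direction) {
  switch(direction, low = -z, high = z, two_sided = abs(z),
         stop("unknown direction: ", direction))
}

# u = 1 - F(v) with F the strict-less empirical CDF of training deviation
# values: u is in (0, 1] on training values and near 0 for strong deviants.
svm_directional_transform <- function(model, z) {
  u <- matrix(NA_real_, nrow(z), ncol(z), dimnames = dimnames(z))
  for (j in seq_len(ncol(z))) {
    a <- colnames(z)[j]
    v <- deviation_value(z[, j], model$directions[[a]])
    sv <- model$train_dev[[a]]              # sorted training deviations
    u[, j] <- 1 - findInterval(v, sv, left.open = TRUE) / length(sv)
  }
  u
}

#' Fit the one-class SVM variant
#'
#' Each annotation is mapped through a directional empirical-CDF transform
#' (`u = 1 - F(deviation)`, so strong deviation in the direction of interest
#' lands near 0), then a one-class SVM with a linear boundary is trained at
#' each `nu` in the grid; `nu` approximately controls the fraction of
#' training sites left outside the boundary (training true-negative rate
#' about `1 - nu`).
#'
#' @param training An [annotation_table()] of raw training values.
#' @param transform A [fit_transform_model()] for standardization.
#' @param directions Named directions per annotation (see
#'   [default_deviation_directions()]).
#' @param nu_grid Strictly increasing `nu` values in (0, 1).
#' @param seed Seed for the (deterministic in practice) solver.
#' @return A list of class `oneclass_svm`.
#' @export
fit_svm_model <- function(training, transform,
                          directions = NULL,
                          nu_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.32, 0.5),
                          seed = 1) {
  stopifnot(all(nu_grid > 0), all(nu_grid < 1), !is.unsorted(nu_grid, strictly = TRUE))
  z <- apply_transform(transform, training)$values
  ann <- colnames(z)
  if (is.null(directions)) directions <- default_deviation_directions(ann)
  stopifnot(all(ann %in% names(directions)))
  directions <- as.list(directions[ann])
  train_dev <- lapply(ann, function(a)
    sort(deviation_value(z[, a], directions[[a]])))
  names(train_dev) <- ann
  model <- structure(list(directions = directions, train_dev = train_dev,
                          nu_grid = nu_grid, annotations = ann,
                          transform = transform),
                     class = "oneclass_svm")
  u <- svm_directional_transform(model, z)
  model$models <- lapply(nu_grid, function(nu) with_seed(seed,
    e1071::svm(u, y = NULL, type = "one-classification", kernel = "linear",
               nu = nu, scale = FALSE)))
  model
}

#' @export
print.oneclass_svm <- function(x, ...) {
  cat("one-class SVM model:", length(x$annotations), "annotations, nu grid {",
      paste(x$nu_grid, collapse = ", "), "}\n")
  invisible(x)
}

#' Smallest-true-negative-rate score of a site under the one-class SVM
#'
#' The boundaries trained at different `nu` can intersect, so instead of a
#' single distance the score records the smallest training true-negative rate
#' (about `1 - nu`) at which the site still falls inside the boundary — the
#' SVM analogue of rho.  A site outside every boundary scores 1 (maximally
#' SV-like); a site inside even the tightest boundary scores
#' `1 - max(nu_grid)`.
#'
#' @param model A [fit_svm_model()] object.
#' @param site_vector Transformed annotation vector in the model's space.
#' @return Score in \code{[0, 1]}, comparable to [rho_score()].
#' @export
svm_score <- function(model, site_vector) {
  z <- matrix(site_vector, nrow = 1,
              dimnames = list("site", model$annotations))
  unname(score_sites_transformed_svm(model, z))
}

# score already-transformed rows (internal; score_sites() is the public path)
score_sites_transformed_svm <- function(model, z) {
  u <- svm_directional_transform(model, z)
  sapply(seq_len(nrow(u)), function(i) {
    inside <- vapply(model$models,
                     function(m) as.logical(predict(m, u[i, , drop = FALSE])), NA)
    if (!any(inside)) 1 else 1 - max(model$nu_grid[inside])
  })
}

#' k-of-n ensemble vote across datasets
#'
#' A site is an SV when at least `k` of the per-dataset classifiers call it
#' one.
#'
#' @param per_dataset_calls Character vector of `"SV"` / `"non-SV"` calls.
#' @param k Required number of SV votes.
#' @return `"SV"` or `"non-SV"`.
#' @export
ensemble_vote <- function(per_dataset_calls, k) {
  stopifnot(k >= 1, k <= length(per_dataset_calls))
  if (sum(per_dataset_calls == "SV") >= k) "SV" else "non-SV"
}

#' Ensemble rho score: the k-th largest per-dataset rho
#'
#' With per-dataset rule "SV iff rho > p", the k-th largest rho exceeds `p`
#' exactly when at least `k` datasets do, so this single number reproduces
#' the k-of-n vote at every threshold and is what gets stratified.
#'
#' @param rhos Per-dataset rho scores for one site.
#' @param k Ensemble parameter (default 3).
#' @return The k-th largest rho.
#' @export
ensemble_rho <- function(rhos, k = 3) {
  stopifnot(k >= 1, k <= length(rhos))
  sort(rhos, decreasing = TRUE)[k]
}

#' Pre-filter flags from flank statistics
#'
#' Sites in difficult regions are excluded before stratification:
#' `high_flank_coverage` when depth exceeds the threshold in BOTH flanks
#' (likely inside a duplicated region), `low_flank_mapq` when mean mapping
#' quality drops below the threshold in EITHER flank.
#'
#' @param flank_stats Data.frame with columns `L_Cov`, `R_Cov`, `L_MapQ`,
#'   `R_MapQ` for the designated filter dataset.
#' @param max_flank_coverage Coverage threshold (default 300; about 1.5x a
#'   200x dataset's mean).
#' @param min_flank_mapq MAPQ threshold (default 30).
#' @return Data.frame of logicals `high_flank_coverage`, `low_flank_mapq`,
#'   `unfilterable` (missing flank statistics).
#' @export
prefilter_sites <- function(flank_stats, max_flank_coverage = 300,
                            min_flank_mapq = 30) {
  stopifnot(all(c("L_Cov", "R_Cov", "L_MapQ", "R_MapQ") %in% names(flank_stats)))
  unfilterable <- is.na(flank_stats$L_Cov) | is.na(flank_stats$R_Cov) |
    is.na(flank_stats$L_MapQ) | is.na(flank_stats$R_MapQ)
  data.frame(
    high_flank_coverage = !unfilterable &
      flank_stats$L_Cov > max_flank_coverage &
      flank_stats$R_Cov > max_flank_coverage,
    low_flank_mapq = !unfilterable &
      (flank_stats$L_MapQ < min_flank_mapq | flank_stats$R_MapQ < min_flank_mapq),
    unfilterable = unfilterable)
}

DEFAULT_STRATA <- c(0.68, 0.9, 0.97, 0.99, 0.997, 0.999)

#' Stratify rho scores into evidence tiers
#'
#' Half-open bins `[b_i, b_{i+1})`; the top bin is closed at 1.
#'
#' @param rho Scores in \code{[0, 1]}.
#' @param boundaries Sorted stratum boundaries (default the published tiers
#'   0.68 / 0.9 / 0.97 / 0.99 / 0.997 / 0.999).
#' @return Factor of stratum labels (`"<0.68"`, `"0.68-0.9"`, ...,
#'   `">0.999"`).
#' @export
stratify <- function(rho, boundaries = DEFAULT_STRATA) {
  stopifnot(!is.unsorted(boundaries, strictly = TRUE),
            all(boundaries > 0), all(boundaries < 1))
  labels <- c(paste0("<", boundaries[1]),
              if (length(boundaries) > 1)
                paste0(head(boundaries, -1), "-", tail(boundaries, -1)),
              paste0(">", tail(boundaries, 1)))
  idx <- findInterval(rho, boundaries) + 1L
  factor(labels[idx], levels = labels)
}

#' ROC curve from positive and negative scores
#'
#' Sweeps the rule "call SV when score > t" over all observed score values
#' (ties grouped), returning one (fpr, tpr) point per threshold plus the
#' (0,0) and (1,1) endpoints, and the trapezoidal AUC.
#'
#' @param scores_positive Scores of true SV sites.
#' @param scores_negative Scores of non-SV (random) sites.
#' @return A list of class `roc_curve`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc`.
#' @export
roc_curve <- function(scores_positive, scores_negative) {
  stopifnot(length(scores_positive) > 0, length(scores_negative) > 0)
  thresholds <- sort(unique(c(scores_positive, scores_negative)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores_positive > t), 0)
  fpr <- vapply(thresholds, function(t) mean(scores_negative > t), 0)
  pts <- data.frame(threshold = c(Inf, thresholds, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =", round(x$auc, 4), "\n")
  invisible(x)
}
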