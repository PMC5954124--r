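#' P50 sensory gating ratio
#'
#' The suppression of the response to the second of two paired clicks,
#' expressed as \code{(s2 / s1) * 100}. Higher ratios reflect worse gating.
#'
#' @param s1 Amplitude of the response to the first click (uV); must be
#'   non-zero.
#' @param s2 Amplitude of the response to the second click (uV).
#' @return Ratio in percent.
#' @export
p50_ratio <- function(s1, s2) {
  if (any(s1 == 0)) stopf("undefined P50 ratio: S1 amplitude is zero")
  (s2 / s1) * 100
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], `-`)^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], `-`)^2))
  }
  centers
}

#' Fit a K-means model to ERP profiles
#'
#' Standardises each measure to zero mean and unit variance, then runs
#' Lloyd's algorithm from k-means++ starts (\code{n_init} restarts, best
#' inertia kept). Clusters are canonically relabelled by ascending centroid
#' norm so results are invariant to sample order for a fixed seed.
#'
#' @param profiles Data frame or matrix holding the six ERP measures (columns
#'   \code{\link{erp_measures}}, or any all-numeric set of columns).
#' @param k Number of clusters.
#' @param seed Integer seed for the restarts.
#' @param n_init Number of k-means++ restarts.
#' @param impairment_directions Named vector in \{+1, -1\} giving, per
#'   measure, the direction of worse function.
#' @return An object of class \code{cluster_model}: standardisation
#'   parameters, centroids (standardised space), assignments, inertia, and a
#'   slot for the globally impaired label (see
#'   \code{\link{label_globally_impaired}}).
#' @export
fit_kmeans <- function(profiles, k, seed = 1L, n_init = 50L,
                       impairment_directions = default_impairment_directions) {
  x <- as.matrix(profiles[, intersect(colnames(profiles), erp_measures),
                          drop = FALSE])
  if (ncol(x) == 0) x <- as.matrix(profiles)
  if (anyNA(x)) stopf("ERP profiles contain missing measures")
  if (nrow(x) < k) stopf("need at least k samples")
  if (nrow(unique(x)) < k)
    stopf("degenerate input: fewer than k distinct points")
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(x, 2, mu, `-`), 2, sd_, `/`)
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      init <- kmeanspp_centers(z, k)
      fit <- tryCatch(
        stats::kmeans(z, centers = init, iter.max = 300,
                      algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w)
          suppressWarnings(stats::kmeans(z, centers = init, iter.max = 300,
                                         algorithm = "Lloyd")))
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stopf("k-means failed on every restart")
  # canonical relabelling by ascending centroid norm
  ord <- order(rowSums(best$centers^2))
  relabel <- match(seq_len(k), ord)
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  assignments <- relabel[best$cluster]
  structure(list(k = k,
                 standardization = list(mean = mu, sd = sd_),
                 centroids = centroids,
                 assignments = assignments,
                 inertia = best$tot.withinss,
                 impairment_directions =
                   if (!is.null(names(impairment_directions)) &&
                       all(colnames(x) %in% names(impairment_directions)))
                     impairment_directions[colnames(x)]
                   else impairment_directions,
                 gi_cluster = NA_integer_,
                 gi_flag = NULL,
                 gi_fallback = FALSE),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, inertia = %.3f", x$k, x$inertia))
  if (!is.na(x$gi_cluster))
    cat(sprintf(", globally impaired cluster = %d (n = %d)",
                x$gi_cluster, sum(x$gi_flag)))
  cat("\n")
  invisible(x)
}

#' Map standardised centroids back to raw measurement units
#'
#' @param model A \code{cluster_model}.
#' @return Centroid matrix in the original units.
#' @export
centroids_raw <- function(model) {
  sweep(sweep(model$centroids, 2, model$standardization$sd, `*`),
        2, model$standardization$mean, `+`)
}

#' Choose the number of clusters by V-fold cross-validation
#'
#' For each candidate \code{k}, splits the samples into \code{v} folds, fits
#' K-means on the training folds and scores the held-out fold by the mean
#' squared distance of its points to the nearest trained centroid.
#'
#' The raw held-out distance is non-increasing in \code{k} in expectation
#' even for structureless data (more centroids are always nearer), at the
#' quantization rate \code{k^(-2/d)} for \code{d} measures. The selection
#' therefore minimises the dimension-adjusted score
#' \code{error(k) * k^(2/d)}, which is flat under no structure (ties then
#' resolve to the smallest \code{k}) and dips sharply at the true number of
#' well-separated clusters. Raw errors are returned alongside.
#'
#' @param profiles ERP profile table (see \code{\link{fit_kmeans}}).
#' @param k_range Candidate cluster numbers (default 2 to 5).
#' @param v Number of folds.
#' @param seed Integer seed controlling the fold split and restarts.
#' @param n_init Restarts per training fit.
#' @return List of class \code{k_selection}: \code{errors} (named mean
#'   held-out error per k), \code{scores} (dimension-adjusted),
#'   \code{chosen_k}.
#' @export
select_k_vfold <- function(profiles, k_range = 2:5, v = 10L, seed = 1L,
                           n_init = 10L) {
  x <- as.matrix(profiles[, intersect(colnames(profiles), erp_measures),
                          drop = FALSE])
  if (ncol(x) == 0) x <- as.matrix(profiles)
  n <- nrow(x)
  if (v < 2) stopf("v must be at least 2")
  if (n < v * max(k_range))
    stopf("too few samples for %d folds at k = %d", v, max(k_range))
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(x, 2, mu, `-`), 2, sd_, `/`)
  folds <- with_seed(substream_seed(seed, "folds"),
                     sample(rep(seq_len(v), length.out = n)))
  errors <- vapply(k_range, function(k) {
    fold_err <- vapply(seq_len(v), function(f) {
      train <- z[folds != f, , drop = FALSE]
      test <- z[folds == f, , drop = FALSE]
      if (nrow(train) < k) stopf("fold smaller than k = %d", k)
      fit <- fit_kmeans(as.data.frame(train), k,
                        seed = seed + 1000L * k + f, n_init = n_init)
      d2 <- apply(test, 1, function(p)
        min(colSums((t(fit$centroids) - p)^2)))
      mean(d2)
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  names(errors) <- k_range
  scores <- errors * k_range^(2 / ncol(z))
  chosen <- k_range[which.min(scores)]
  structure(list(errors = errors, scores = scores, chosen_k = chosen),
            class = "k_selection")
}

#' Label the globally impaired cluster
#'
#' Multiplies each (standardised) centroid coordinate by its impairment
#' direction; the cluster whose aligned centroid is largest on every one of
#' the six measures is labelled globally impaired. If no cluster dominates on
#' all measures, the cluster with the largest rank-sum across measures is
#' used and the model is flagged (\code{gi_fallback = TRUE}); a rank-sum tie
#' raises an error demanding manual review of the directions.
#'
#' @param model A fitted \code{cluster_model}.
#' @return The model with \code{gi_cluster} and per-sample binary
#'   \code{gi_flag} filled in.
#' @export
label_globally_impaired <- function(model) {
  dir <- model$impairment_directions
  aligned <- sweep(model$centroids, 2, dir, `*`)
  dominates <- vapply(seq_len(model$k), function(i)
    all(vapply(seq_len(ncol(aligned)), function(j)
      aligned[i, j] >= max(aligned[, j]), logical(1))), logical(1))
  if (sum(dominates) == 1) {
    gi <- which(dominates)
    model$gi_fallback <- FALSE
  } else {
    ranksum <- rowSums(apply(aligned, 2, rank))
    if (sum(ranksum == max(ranksum)) > 1)
      stopf(paste("rank-sum tie between clusters: review the impairment",
                  "direction vector manually"))
    gi <- which.max(ranksum)
    model$gi_fallback <- TRUE
  }
  model$gi_cluster <- gi
  model$gi_flag <- as.integer(model$assignments == gi)
  model
}
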