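# Per-pixel feature vectors from DTCWT subband energies, and k-means
# clustering of those features into per-class energies.

#' Extract per-pixel wavelet features
#'
#' For every level and orientation the coefficient magnitude is smoothed
#' over a 3x3 window, square-rooted, and nearest-neighbour upsampled to
#' the source grid; the final channel is the upsampled lowpass residual.
#' The result is a `6*levels + 1` channel feature image whose first
#' `6*levels` channels are non-negative.
#'
#' @param pyramid a `dtcwt_pyramid`.
#' @return object of class `dtcwt_features`: list with `vectors` (matrix,
#'   one row per pixel in column-major order, `6*levels+1` columns),
#'   `shape` (image shape) and `levels`.
#' @export
extract_features <- function(pyramid) {
  .check_pyramid(pyramid)
  nr <- pyramid$source_shape[1]; nc <- pyramid$source_shape[2]
  pr <- pyramid$padded_shape[1]; pc <- pyramid$padded_shape[2]
  J <- pyramid$levels
  chans <- vector("list", 6L * J + 1L)
  k <- 0L
  for (j in seq_len(J)) {
    fac <- 2L^j
    for (o in 1:6) {
      k <- k + 1L
      sm <- .box_mean(Mod(pyramid$subbands[[j]][[o]]), 3L)
      # subbands sit one pixel down-right of the pixel grid
      up <- .circ_shift(.upsample_nn(sqrt(sm), fac, pr, pc), 1L)
      chans[[k]] <- up[seq_len(nr), seq_len(nc), drop = FALSE]
    }
  }
  lp_fac <- 2L^max(J - 1L, 0L)
  # The lowpass is a smooth intensity surface: interpolate it bilinearly
  # (the crisp nearest-neighbour convention is for the magnitude
  # channels) with the residual one-sample-per-level delay compensated.
  shift <- if (J >= 2L) 2 * lp_fac - 2.5 else 0
  lp <- .upsample_bilinear(pyramid$lowpass, lp_fac, pr, pc, shift)
  chans[[6L * J + 1L]] <- lp[seq_len(nr), seq_len(nc), drop = FALSE]
  vectors <- vapply(chans, as.vector, numeric(nr * nc))
  structure(list(vectors = vectors, shape = c(nr, nc), levels = J),
            class = "dtcwt_features")
}

#' Cluster pixels by wavelet features
#'
#' Lloyd's algorithm from a k-means++ initialization on channel-
#' standardized features. Deterministic for a fixed seed.
#'
#' @param features a [extract_features()] result.
#' @param k number of clusters (>= 1, <= number of pixels).
#' @param seed RNG seed for the k-means++ initialization.
#' @param max_iter Lloyd iteration cap.
#' @return object of class `feature_clustering`: `labels` (integer matrix
#'   of cluster ids `0..k-1` in image shape), `centroids` (k x channels,
#'   original feature scale), `energies` (per-class energy, see
#'   [class_energy()]), `k`.
#' @export
cluster_features <- function(features, k, seed = 1L, max_iter = 50L) {
  if (!inherits(features, "dtcwt_features")) .fail("not a dtcwt_features")
  X <- features$vectors
  n <- nrow(X)
  if (k < 1L || k > n) .fail("k must be in [1, number of pixels]")
  sds <- apply(X, 2, sd)
  sds[sds < 1e-12] <- 1
  Z <- sweep(X, 2, sds, "/")
  if (k == 1L) {
    lab <- rep(0L, n)
  } else {
    centers <- with_seed(seed, .kmeanspp_centers(Z, k))
    lab <- tryCatch(
      suppressWarnings(kmeans(Z, centers = centers, iter.max = max_iter,
                              algorithm = "Lloyd")$cluster) - 1L,
      error = function(e) .lloyd(Z, centers, max_iter))  # empty clusters ok
  }
  cents <- t(vapply(0:(k - 1L), function(cl) {
    rows <- lab == cl
    if (!any(rows)) numeric(ncol(X)) else colMeans(X[rows, , drop = FALSE])
  }, numeric(ncol(X))))
  out <- structure(
    list(labels = matrix(lab, features$shape[1], features$shape[2]),
         centroids = cents, k = as.integer(k), energies = NULL),
    class = "feature_clustering")
  out$energies <- vapply(0:(k - 1L), function(cl)
    class_energy(features, out, cl), numeric(1))
  out
}

# plain Lloyd iterations tolerating empty clusters (stats::kmeans errors
# on them); assignment ties break to the lowest centre index
.lloyd <- function(Z, centers, max_iter) {
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(nrow(centers)), function(i)
      rowSums(sweep(Z, 2, centers[i, ])^2), numeric(nrow(Z)))
    lab <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (i in seq_len(nrow(centers)))
      if (any(lab == i)) newc[i, ] <- colMeans(Z[lab == i, , drop = FALSE])
    if (max(abs(newc - centers)) < 1e-12) break
    centers <- newc
  }
  lab - 1L
}

# k-means++ seeding (squared-distance weighted)
.kmeanspp_centers <- function(Z, k) {
  n <- nrow(Z)
  centers <- matrix(0, k, ncol(Z))
  idx <- sample.int(n, 1L)
  centers[1, ] <- Z[idx, ]
  d2 <- rowSums(sweep(Z, 2, centers[1, ])^2)
  for (i in seq_len(k - 1L)) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1L)
            else sample.int(n, 1L, prob = d2 / tot)
    centers[i + 1L, ] <- Z[pick, ]
    d2 <- pmin(d2, rowSums(sweep(Z, 2, centers[i + 1L, ])^2))
  }
  # distinct rows required by stats::kmeans
  if (anyDuplicated(centers))
    centers <- centers + 1e-9 * matrix(rnorm(length(centers)), k)
  centers
}

#' Total feature energy of one cluster
#'
#' The energy of class `class_id` is the sum over its member pixels of the
#' squared L2 norm of the pixel's feature vector; an absent class has
#' energy 0. Summed over all classes this equals the total feature energy
#' of the image.
#'
#' @param features a [extract_features()] result.
#' @param clustering a [cluster_features()] result (or any object with a
#'   `labels` matrix of the same shape).
#' @param class_id integer class id.
#' @return non-negative scalar energy.
#' @export
class_energy <- function(features, clustering, class_id) {
  if (!inherits(features, "dtcwt_features")) .fail("not a dtcwt_features")
  lab <- as.vector(clustering$labels)
  rows <- lab == class_id
  if (!any(rows)) return(0)
  sum(features$vectors[rows, , drop = FALSE]^2)
}
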