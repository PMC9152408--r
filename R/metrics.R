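# Segmentation evaluation metrics: pair-consistency similarity (Rand
# index), information-loss index (normalized variation of information),
# symmetric boundary distance, and F-measure.

.check_pair <- function(reference, result) {
  if (!identical(dim(reference), dim(result)))
    .fail("reference and result must have the same shape")
  if (any(reference < 0) || any(result < 0))
    .fail("labels must be non-negative integers")
  invisible(NULL)
}

#' Pair-consistency sampling function
#'
#' Indicator that two pixels carry the same label in the chosen map: the
#' elementary quantity from which the similarity index is built.
#'
#' @param reference,result integer label matrices of equal shape.
#' @param which `"reference"` or `"result"`.
#' @param i,j pixel indices (1-based, column-major linear index).
#' @return 0 or 1.
#' @export
pair_consistent <- function(reference, result, which = c("reference", "result"),
                            i, j) {
  .check_pair(reference, result)
  which <- match.arg(which)
  m <- if (which == "reference") reference else result
  n <- length(m)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) .fail("pixel index out of range")
  as.integer(m[i] == m[j])
}

#' Pair-consistency similarity index (Rand index)
#'
#' The fraction of unordered pixel pairs whose co-assignment indicator
#' (same class / different class) agrees between the two maps. 1 for
#' identical partitions (up to label permutation); computed exactly via
#' the label contingency table when `sample_pairs = "all"` and the image
#' has at most `exact_limit` pixels, otherwise by seeded Monte-Carlo
#' sampling of `sample_pairs` pixel pairs.
#'
#' @param reference,result integer label matrices of equal shape.
#' @param sample_pairs `"all"` for the exact value, or a pair count for
#'   Monte-Carlo estimation (default 1e6 when the image is too large for
#'   the exact path).
#' @param seed seed for the Monte-Carlo path.
#' @param exact_limit pixel-count cap for the exact path, default 1e4.
#' @return similarity in `[0, 1]`.
#' @export
similarity_index <- function(reference, result, sample_pairs = "all",
                             seed = 1L, exact_limit = 1e4) {
  .check_pair(reference, result)
  N <- length(reference)
  exact_requested <- identical(sample_pairs, "all")
  if (exact_requested && N <= exact_limit) {
    tab <- table(as.vector(reference), as.vector(result))
    nij2 <- sum(choose(tab, 2))
    a2 <- sum(choose(rowSums(tab), 2))
    b2 <- sum(choose(colSums(tab), 2))
    tot <- choose(N, 2)
    return((tot + 2 * nij2 - a2 - b2) / tot)
  }
  n_pairs <- if (exact_requested) 1e6 else as.numeric(sample_pairs)
  with_seed(seed, {
    i <- sample.int(N, n_pairs, replace = TRUE)
    j <- sample.int(N, n_pairs, replace = TRUE)
    keep <- i != j
    mean((reference[i[keep]] == reference[j[keep]]) ==
         (result[i[keep]] == result[j[keep]]))
  })
}

#' Information-loss index (normalized variation of information)
#'
#' `H(F) + H(R) - 2 I(F; R)` from the joint label contingency table
#' (natural logarithms), normalized by `log(N)`. Zero exactly when the two
#' maps are identical up to a label permutation; grows with the amount of
#' label information each map fails to predict about the other.
#'
#' @param reference,result integer label matrices of equal shape.
#' @return non-negative scalar.
#' @export
information_loss <- function(reference, result) {
  .check_pair(reference, result)
  N <- length(reference)
  tab <- table(as.vector(reference), as.vector(result)) / N
  pf <- rowSums(tab); pr <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  joint <- -sum(tab[tab > 0] * log(tab[tab > 0]))
  mi <- ent(pf) + ent(pr) - joint
  vi <- ent(pf) + ent(pr) - 2 * mi
  max(vi, 0) / log(N)
}

# boundary pixels under the crack-edge convention: a pixel is on the
# boundary when its label differs from its right or down neighbour
.boundary_pixels <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  b[-h, ] <- b[-h, ] | (labels[-h, , drop = FALSE] != labels[-1, , drop = FALSE])
  b[, -w] <- b[, -w] | (labels[, -w, drop = FALSE] != labels[, -1, drop = FALSE])
  which(b, arr.ind = TRUE)
}

#' Mean symmetric boundary distance
#'
#' Boundary pixels of each map are extracted (crack-edge convention), the
#' directed mean nearest-neighbour distance is computed in both
#' directions, and the average of the two is normalized by the image
#' diagonal (inter-pixel-centre length `sqrt((h-1)^2 + (w-1)^2)`), giving
#' a dimensionless error in roughly `[0, 1]`.
#'
#' @param reference,result integer label matrices, each with >= 2 labels.
#' @return non-negative scalar; 0 for identical boundaries.
#' @export
boundary_error <- function(reference, result) {
  .check_pair(reference, result)
  if (length(unique(as.vector(reference))) < 2L ||
      length(unique(as.vector(result))) < 2L)
    .fail("boundary undefined: a map contains a single label")
  A <- .boundary_pixels(reference)
  B <- .boundary_pixels(result)
  diag_len <- sqrt((nrow(reference) - 1)^2 + (ncol(reference) - 1)^2)
  (mean(.nn_dist(A, B)) + mean(.nn_dist(B, A))) / 2 / diag_len
}

# directed nearest-neighbour distances from each row of A to the set B
.nn_dist <- function(A, B, chunk = 512L) {
  out <- numeric(nrow(A))
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    d2 <- outer(A[s:e, 1], B[, 1], "-")^2 + outer(A[s:e, 2], B[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' F-measure for one positive class
#'
#' Pixel-level precision and recall of `positive_class`, combined as their
#' harmonic mean; 0 when precision + recall is 0.
#'
#' @param reference,result integer label matrices of equal shape.
#' @param positive_class class id; must occur in `reference`.
#' @return F in `[0, 1]`.
#' @export
f_measure <- function(reference, result, positive_class) {
  .check_pair(reference, result)
  if (!any(reference == positive_class))
    .fail("positive class ", positive_class, " absent from reference")
  tp <- sum(result == positive_class & reference == positive_class)
  fp <- sum(result == positive_class & reference != positive_class)
  fn <- sum(result != positive_class & reference == positive_class)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (pre + rec == 0) return(0)
  2 * pre * rec / (pre + rec)
}

#' Macro-averaged F-measure over all reference classes
#'
#' @param reference,result integer label matrices of equal shape.
#' @return mean per-class F over the classes present in `reference`.
#' @export
f_measure_macro <- function(reference, result) {
  cls <- sort(unique(as.vector(reference)))
  mean(vapply(cls, function(k) f_measure(reference, result, k), numeric(1)))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` between an image and its reference.
#'
#' @param x,ref numeric matrices of equal shape.
#' @param peak signal peak, default 1 (intensity convention).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(x, ref, peak = 1) {
  if (!identical(dim(x), dim(ref))) .fail("shapes differ")
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
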