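# Shared fixtures and independent oracles used across the suite.

# smooth random field (image-like spatial correlation), reproducible
smooth_field <- function(n, corr_len = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  k <- dnorm(seq(-3, 3, length.out = 2 * corr_len + 1))
  k <- k / sum(k)
  csm <- function(m) {
    nn <- nrow(m); c0 <- (length(k) + 1) / 2
    out <- matrix(0, nn, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * m[(((seq_len(nn) - j + c0 - 1) %% nn) + 1), , drop = FALSE]
    out
  }
  t(csm(t(csm(x))))
}

# a simple critically-sampled real DWT (same level-1 filters as the
# package's transform), used only as the shift-invariance comparator
real_dwt_mags <- function(x, J) {
  h0 <- dtcwtseg:::.h0o; h1 <- dtcwtseg:::.h1o
  csm <- function(m, k) {
    nn <- nrow(m); c0 <- (length(k) + 1) / 2
    out <- matrix(0, nn, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * m[(((seq_len(nn) - j + c0 - 1) %% nn) + 1), , drop = FALSE]
    out
  }
  mags <- list(); LL <- x
  for (j in seq_len(J)) {
    f0 <- csm(LL, h0)[seq(1, nrow(LL), 2), , drop = FALSE]
    f1 <- csm(LL, h1)[seq(1, nrow(LL), 2), , drop = FALSE]
    half <- function(m, k) t(csm(t(m), k)[, , drop = FALSE])[, seq(1, ncol(LL), 2), drop = FALSE]
    LLn <- half(f0, h0); LH <- half(f0, h1)
    HL <- half(f1, h0); HH <- half(f1, h1)
    mags <- c(mags, list(abs(LH), abs(HL), abs(HH)))
    LL <- LLn
  }
  mags
}

# relative L2 change of subband magnitudes under a 1-px circular shift
shift_metric <- function(mags1, mags2) {
  num <- sum(unlist(Map(function(a, b) sum((a - b)^2), mags1, mags2)))
  den <- sum(unlist(lapply(mags1, function(a) sum(a^2))))
  sqrt(num / den)
}

dtcwt_mags <- function(x, J) {
  p <- dtcwt_forward(x, J)
  unlist(lapply(p$subbands, function(l) lapply(l, Mod)), recursive = FALSE)
}

# brute-force MAP oracle for the bivariate shrinkage rule: maximize the
# log posterior of the clean pair (a1, a2) given the observed (b1, b2)
# over a grid, then polish with Nelder-Mead
shrink_map_oracle <- function(b1, b2, sigma_n, sigma_local) {
  obj <- function(a) {
    -((b1 - a[1])^2 + (b2 - a[2])^2) / (2 * sigma_n^2) -
      (sqrt(3) / sigma_local) * sqrt(a[1]^2 + a[2]^2)
  }
  m <- sqrt(b1^2 + b2^2)
  g <- seq(-1.05, 1.05, length.out = 61)
  cand <- as.matrix(expand.grid(a1 = g * max(m, 1e-3), a2 = g * max(m, 1e-3)))
  vals <- apply(cand, 1, obj)
  start <- cand[which.max(vals), ]
  opt <- optim(start, function(a) -obj(a), method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  unname(opt$par[1])
}

# brute-force pair-agreement count for the similarity index
rand_index_oracle <- function(A, B) {
  a <- as.vector(A); b <- as.vector(B)
  n <- length(a); agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    agree <- agree + as.integer((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / tot
}

# directed mean nearest-neighbour distance between boundary sets, by
# exhaustive search (oracle for boundary_error)
boundary_oracle <- function(A, B) {
  dAB <- sapply(seq_len(nrow(A)), function(i)
    min(sqrt((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2)))
  mean(dAB)
}

# small noisy phantom sample for segmentation / RL tests
easy_sample <- function(seed, size = 64, n_classes = 4, sigma = 0.05,
                        means = c(0.1, 0.5, 0.9, 1.0)) {
  sp <- phantom_spec(size, size, n_classes, c(1, 1),
                     class_means = means[seq_len(n_classes)],
                     class_texture_sd = 0.02, seed = seed)
  ph <- generate_phantom(sp)
  list(clean = ph$image, truth = ph$truth,
       noisy = add_noise(ph$image, sigma, seed + 1000L), sigma = sigma)
}

# supervised Gaussian/Potts fit at a given depth (the labelled-training
# protocol used for evaluation)
fit_on_truth <- function(img, truth, levels = 2, beta = 2) {
  f <- extract_features(dtcwt_forward(img, levels))
  list(features = f,
       model = fit_segmentation_model(f, truth, beta = beta))
}

# minimal Otsu threshold (histogram method) for the edge-preservation test
otsu_threshold <- function(x, nbins = 128) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts); mids <- h$mids
  w0 <- cumsum(p); mu <- cumsum(p * mids); mt <- mu[length(mu)]
  sb <- (mt * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}
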