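test_that("sigma_n estimator is robust, DC-invariant and zero on silence", {
  z <- dtcwt_forward(matrix(0, 64, 64), 2)
  expect_identical(estimate_sigma_n(z), 0)
  set.seed(5)
  x <- smooth_field(64, 3, seed = 5) * 0.1
  e1 <- estimate_sigma_n(dtcwt_forward(x, 3))
  e2 <- estimate_sigma_n(dtcwt_forward(x + 5, 3))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("sigma_n estimate tracks the wavelet-domain truth", {
  truth <- mean(sapply(1:5, function(s) {
    set.seed(s)
    pn <- dtcwt_forward(matrix(rnorm(96 * 96) * 0.1, 96), 3)
    sd(c(Re(pn$subbands[[1]][[5]]), Re(pn$subbands[[1]][[6]])))
  }))
  est <- median(sapply(1:10, function(s) {
    ph <- generate_phantom(phantom_spec(96, 96, 4, c(1, 1), seed = s))
    estimate_sigma_n(dtcwt_forward(add_noise(ph$image, 0.1, s + 70), 3))
  }))
  expect_lt(abs(est - truth) / truth, 0.15)
})

test_that("local signal SD matches a brute-force sliding window", {
  # constant-magnitude subband with zero noise returns the magnitude
  sb <- matrix(complex(modulus = 0.3, argument = 0.4), 6, 6)
  expect_equal(estimate_sigma_local(sb, 0, 3), matrix(0.3, 6, 6),
               tolerance = 1e-12)
  # noise SD above all magnitudes clamps to the floor
  expect_true(all(estimate_sigma_local(sb, 10, 3) == 1e-8))
  # brute-force oracle on an 8x8 array, window 3
  set.seed(8)
  sb <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  got <- estimate_sigma_local(sb, 0.5, 3)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  for (r in 1:8) for (c in 1:8) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + Mod(sb[refl(r + dr, 8), refl(c + dc, 8)])^2
    expected <- max(sqrt(max(acc / 9 - 0.25, 0)), 1e-8)
    expect_equal(got[r, c], expected, tolerance = 1e-12)
  }
})

test_that("bivariate shrinkage equals its closed form and the MAP oracle", {
  # worked example: m = 5, threshold 2 -> factor 3/5
  out <- shrink_bivariate(3 + 4i, 0 + 0i, sigma_n = sqrt(2 / sqrt(3)),
                          sigma_local = 1)
  expect_equal(out, 1.8 + 2.4i, tolerance = 1e-12)
  expect_equal(shrink_bivariate(3 + 4i, 1i, 0, 1), 3 + 4i)   # no noise
  expect_equal(shrink_bivariate(0.1 + 0i, 0i, 1, 1), 0 + 0i) # threshold zone
  expect_error(shrink_bivariate(NaN + 0i, 0i, 1, 1), "non-finite")
  # MAP-objective oracle on a grid of parameter combinations (real pairs)
  set.seed(12)
  for (i in 1:20) {
    b1 <- runif(1, -3, 3); b2 <- runif(1, -3, 3)
    sn <- runif(1, 0.1, 0.8); sl <- runif(1, 0.3, 2)
    got <- Re(shrink_bivariate(complex(real = b1), complex(real = b2), sn, sl))
    expect_equal(got, shrink_map_oracle(b1, b2, sn, sl), tolerance = 1e-4)
  }
})

test_that("pyramid shrinkage never grows coefficients and spares clean input", {
  ph <- generate_phantom(phantom_spec(64, 64, 2, c(0, 0),
                                      class_texture_sd = 0, seed = 3))
  p <- dtcwt_forward(ph$image, 3)
  dn <- denoise_pyramid(p)
  for (j in 1:3) for (o in 1:6) {
    expect_true(all(Mod(dn$subbands[[j]][[o]]) <=
                    Mod(p$subbands[[j]][[o]]) + 1e-12))
  }
  # a texture-free phantom estimates sigma_n ~ 0: coefficients survive
  expect_lt(max(abs(Mod(unlist(dn$subbands)) - Mod(unlist(p$subbands)))), 1e-6)
  z <- dtcwt_forward(matrix(0, 32, 32), 2)
  dz <- denoise_pyramid(z)
  expect_true(all(Mod(unlist(dz$subbands)) == 0))
  expect_warning(denoise_pyramid(dtcwt_forward(matrix(rnorm(1024), 32), 1)),
                 "depth 1")
})

test_that("anisotropic diffusion is conservative and edge preserving", {
  img <- smooth_field(48, 3, seed = 2)
  expect_identical(diffuse(img, diffusion_config(iterations = 0)), img)
  cst <- matrix(0.4, 32, 32)
  expect_equal(diffuse(cst, diffusion_config(iterations = 7)), cst)
  out <- diffuse(img, diffusion_config(iterations = 50, dt = 0.2))
  expect_lt(abs(mean(out) - mean(img)) / abs(mean(img) + 1e-12), 1e-6)
  expect_error(diffusion_config(dt = 0.3), "stable")
  expect_error(diffusion_config(kappa = -1), "kappa")
  # rational conductance variant also runs and conserves the mean
  out2 <- diffuse(img, diffusion_config(iterations = 10, kappa = 0.1,
                                        conductance = "rational"))
  expect_lt(abs(mean(out2) - mean(img)), 1e-8)
})

test_that("end-to-end denoising lifts PSNR at several noise levels", {
  for (sig in c(0.05, 0.1, 0.2)) {
    gains <- sapply(1:3, function(s) {
      ph <- generate_phantom(phantom_spec(96, 96, 4, c(1, 1), seed = s))
      noisy <- add_noise(ph$image, sig, s + 300)
      out <- denoise_image(noisy, 3)
      expect_true(all(is.finite(out)) && identical(dim(out), dim(noisy)))
      psnr(out, ph$image) - psnr(noisy, ph$image)
    })
    expect_gt(mean(gains), 0)
  }
  # identity composition: clean input, zero sigma, no diffusion
  ph <- generate_phantom(phantom_spec(64, 64, 2, c(0, 0),
                                      class_texture_sd = 0, seed = 1))
  out <- denoise_image(ph$image, 3, diffusion_config(iterations = 0),
                       sigma_n = 0)
  expect_lt(max(abs(out - ph$image)), 1e-6)
})

test_that("denoising does not displace segmentation boundaries", {
  ph <- generate_phantom(phantom_spec(96, 96, 2, c(0, 0),
                                      class_means = c(0.3, 0.7),
                                      class_texture_sd = 0.02, seed = 6))
  noisy <- add_noise(ph$image, 0.1, 61)
  den <- denoise_image(noisy, 3)
  seg_of <- function(img) {
    m <- matrix(as.integer(img > otsu_threshold(img)), nrow(img))
    m
  }
  be_noisy <- boundary_error(ph$truth, seg_of(noisy))
  be_den <- boundary_error(ph$truth, seg_of(den))
  expect_lte(be_den, be_noisy)
})
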