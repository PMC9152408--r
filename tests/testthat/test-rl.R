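test_that("the three elementary loss terms match hand computation", {
  expect_identical(value_loss(1, 1), 0)
  expect_identical(value_loss(1, 0), 0.5)
  expect_identical(value_loss(-2, 1), 4.5)
  expect_equal(policy_loss(1, 2, 0.2), -2)
  expect_equal(policy_loss(2, 1, 0.2), -1.2)
  expect_equal(policy_loss(0.5, -1, 0.2), 0.8)
  expect_error(policy_loss(-0.5, 1, 0.2), "positive")
  expect_equal(entropy_term(rep(0.25, 4)), -log(4), tolerance = 1e-12)
  expect_identical(entropy_term(c(1, 0, 0)), 0)
  expect_equal(entropy_term(c(0.5, 0.5)), -log(2), tolerance = 1e-12)
  expect_error(entropy_term(c(0.7, 0.7)), "probability")
})

test_that("the clip dead zones flatten the surrogate's slope", {
  num_d <- function(r, k, s, h = 1e-6)
    (policy_loss(r + h, k, s) - policy_loss(r - h, k, s)) / (2 * h)
  expect_equal(num_d(1.5, 2, 0.2), 0, tolerance = 1e-6)    # r > 1+s, k > 0
  expect_equal(num_d(0.5, -2, 0.2), 0, tolerance = 1e-6)   # r < 1-s, k < 0
  expect_equal(num_d(1.0, 2, 0.2), -2, tolerance = 1e-4)   # interior slope -k
  expect_equal(num_d(0.5, 2, 0.2), -2, tolerance = 1e-4)   # pessimistic side live
})

test_that("advantage estimation matches a discounted double-loop oracle", {
  one <- list(rewards = 1, values = 0)
  expect_identical(compute_advantages(one, 0.5, 0.9),
                   list(advantages = 1, returns = 1))
  zero <- list(rewards = rep(0, 4), values = rep(0, 4))
  expect_identical(compute_advantages(zero, 0.9, 0.95)$advantages, rep(0, 4))
  set.seed(59)
  r <- rnorm(5); v <- rnorm(5)
  got <- compute_advantages(list(rewards = r, values = v), 0.9, 0.95)
  delta <- r + 0.9 * c(v[-1], 0) - v
  adv <- sapply(1:5, function(t)
    sum((0.9 * 0.95)^(0:(5 - t)) * delta[t:5]))
  expect_equal(got$advantages, adv, tolerance = 1e-12)
  expect_equal(got$returns, adv + v, tolerance = 1e-12)
})

test_that("action probabilities form a distribution and params flatten", {
  p <- init_refine_params(7, 5, hidden = 6, seed = 2)
  obs <- matrix(rnorm(21), 3, 7)
  P <- policy_probs(p, obs)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
  expect_true(all(P > 0))
  expect_length(state_value(p, obs), 3)
  expect_true(is.numeric(as.numeric(p)) && length(as.numeric(p)) > 50)
  # reproducible initialization
  expect_identical(as.numeric(init_refine_params(7, 5, 6, 2)), as.numeric(p))
})

test_that("the analytic PPO gradient matches finite differences", {
  set.seed(61)
  params <- init_refine_params(3, 3, hidden = 4, seed = 11)
  cfg <- ppo_config(clip = 0.2, value_coef = 0.5, entropy_coef = 0.02,
                    seed = 1)
  m <- 6
  X <- matrix(rnorm(m * 3), m, 3)
  a <- sample.int(3, m, replace = TRUE)
  old_logp <- log(pmax(policy_probs(params, X)[cbind(1:m, a)] *
                         exp(rnorm(m, sd = 0.1)), 1e-6))
  A <- rnorm(m); R <- rnorm(m)
  loss_fn <- function(p) {
    P <- policy_probs(p, X)
    logp <- log(P[cbind(1:m, a)])
    ratio <- exp(logp - old_logp)
    lp <- mean(policy_loss(ratio, A, cfg$clip))
    lv <- mean(value_loss(state_value(p, X), R))
    le <- mean(apply(P, 1, entropy_term))
    lp + cfg$value_coef * lv + cfg$entropy_coef * le
  }
  g <- dtcwtseg:::.ppo_grad(params, X, a, old_logp, A, R, cfg)
  for (nm in c("W1", "b2", "v2", "c2", "W2", "c1")) {
    th <- params$theta[[nm]]
    for (ii in seq_len(min(length(th), 4))) {
      pp <- params; pp$theta[[nm]][ii] <- pp$theta[[nm]][ii] + 1e-6
      pm <- params; pm$theta[[nm]][ii] <- pm$theta[[nm]][ii] - 1e-6
      fd <- (loss_fn(pp) - loss_fn(pm)) / 2e-6
      expect_equal(as.vector(g[[nm]])[ii], fd, tolerance = 1e-4)
    }
  }
})

test_that("ppo_update is deterministic and decomposes by loss term", {
  set.seed(67)
  params <- init_refine_params(2, 3, hidden = 4, seed = 5)
  obs <- matrix(rnorm(8), 4, 2)
  acts <- c(1L, 2L, 3L, 1L)
  v <- as.vector(state_value(params, obs))
  # rewards chosen so every temporal difference is zero: advantages
  # vanish and the returns equal the current value predictions
  gamma <- 0.99
  rew <- v - gamma * c(v[-1], 0)
  traj <- list(observations = obs, actions = acts, rewards = rew,
               values = v,
               probs = policy_probs(params, obs)[cbind(1:4, acts)],
               terminal = TRUE)
  cfg <- ppo_config(minibatch = 4, epochs_per_update = 2, seed = 3)
  u1 <- ppo_update(list(traj), params, cfg)
  u2 <- ppo_update(list(traj), params, cfg)
  expect_identical(as.numeric(u1), as.numeric(u2))
  expect_error(ppo_update(list(), params, cfg), "empty")
  # zero advantages + value targets met: only the entropy term moves params
  cfg0 <- ppo_config(minibatch = 4, epochs_per_update = 1,
                     entropy_coef = 0, seed = 3)
  u0 <- ppo_update(list(traj), params, cfg0)
  expect_equal(as.numeric(u0), as.numeric(params), tolerance = 1e-12)
  cfg1 <- ppo_config(minibatch = 4, epochs_per_update = 1,
                     entropy_coef = 0.05, seed = 3)
  ue <- ppo_update(list(traj), params, cfg1)
  expect_gt(max(abs(as.numeric(ue) - as.numeric(params))), 1e-6)
})

test_that("PPO solves a two-armed bandit", {
  cfg <- ppo_config(clip = 0.2, gamma = 0.99, gae_lambda = 0.95,
                    lr = 0.01, minibatch = 16, epochs_per_update = 4,
                    entropy_coef = 0.01, seed = 7)
  params <- init_refine_params(1, 2, hidden = 8, seed = 7)
  obs <- matrix(1, 16, 1)
  for (u in 1:200) {
    probs <- policy_probs(params, obs)[1, ]
    set.seed(1000 + u)
    acts <- sample.int(2, 16, replace = TRUE, prob = probs)
    v <- state_value(params, c(1))
    trajs <- lapply(seq_len(16), function(i)
      list(observations = matrix(1, 1, 1), actions = acts[i],
           rewards = as.numeric(acts[i] == 1L), values = v,
           probs = probs[acts[i]], terminal = TRUE))
    params <- ppo_update(trajs, params, cfg)
    if (policy_probs(params, c(1))[1] > 0.97) break
  }
  expect_gt(policy_probs(params, c(1))[1], 0.95)
})

test_that("the environment transitions are deterministic and auditable", {
  s <- easy_sample(71, size = 64)
  regions <- matrix(rep(0:15, each = 256), 64, 64)   # 16 truth-free blocks
  init <- s$truth
  # a policy forced to STOP leaves the mask untouched
  params <- init_refine_params(dtcwtseg:::.obs_dim(9L, 4L), 13L, 8L, seed = 1)
  params$theta$W2[] <- 0; params$theta$b2[] <- 0
  params$theta$b2[13] <- 10                      # STOP is the last action
  cfg <- ppo_config(patch = 9, n_superpixels = 16, hidden = 8)
  out <- run_episode(s, init, params, cfg, train_mode = FALSE,
                     regions = regions, n_classes = 4)
  expect_identical(out$labels, init)
  expect_lte(length(out$trajectory$actions), 16)
  expect_true(out$trajectory$terminal)
  # identical inputs give identical episodes (pure transition function)
  out2 <- run_episode(s, init, params, cfg, train_mode = FALSE,
                      regions = regions, n_classes = 4)
  expect_identical(out2$labels, out$labels)
})

test_that("a scripted oracle policy repairs every mislabelled superpixel", {
  sp <- phantom_spec(64, 64, 4, c(1, 1), class_texture_sd = 0, seed = 13)
  ph <- generate_phantom(sp)
  regions <- slic_superpixels(ph$image, 48)
  # corrupt: relabel two regions wholesale
  bad <- ph$truth
  bad[regions == 3] <- 0L
  bad[regions == 20] <- 2L
  # truth-aligned regions: refine regions by truth class so each focus
  # region is label-pure
  pure <- regions * 4L + ph$truth
  ids <- sort(unique(as.vector(pure)))
  pure <- matrix(match(pure, ids) - 1L, 64, 64)
  lab <- bad
  for (rid in sort(unique(as.vector(pure)))) {
    maj <- as.integer(names(which.max(table(ph$truth[pure == rid]))))
    lab <- dtcwtseg:::.apply_action(lab, pure, rid, "relabel", maj, 4L)
  }
  expect_identical(lab, ph$truth)
  expect_identical(f_measure_macro(ph$truth, lab), 1)
  # dilate/erode act only inside the focus region and are inverses on a
  # straight boundary interior
  lab2 <- dtcwtseg:::.apply_action(ph$truth, regions, 5, "dilate", 1L, 4L)
  expect_true(all((lab2 != ph$truth) <= (regions == 5)))
})

test_that("training runs, is reproducible, and refinement never explodes", {
  ds <- lapply(c(81, 82, 83, 84), easy_sample, size = 64)
  seg_fn <- function(s) {
    fit <- fit_on_truth(s$noisy, s$truth, levels = 2, beta = 2)
    segment_icm(fit$features, fit$model, 6)
  }
  cfg <- ppo_config(updates = 2, episodes_per_update = 2, n_superpixels = 16,
                    patch = 7, hidden = 16, minibatch = 32, seed = 11)
  p0 <- train_refiner(ds, seg_fn, ppo_config(updates = 0, patch = 7,
                                             hidden = 16, seed = 11),
                      n_classes = 4)
  expect_identical(p0$update_count, 0L)
  p1 <- train_refiner(ds, seg_fn, cfg, n_classes = 4)
  p2 <- train_refiner(ds, seg_fn, cfg, n_classes = 4)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_length(attr(p1, "training_curve"), 2)
  # refinement with the (barely trained) policy never severely degrades
  s <- ds[[1]]
  init <- seg_fn(s)
  ref <- refine(s$noisy, init, p1, cfg, n_classes = 4)
  expect_true(all(unique(as.vector(ref)) %in% 0:3))
  f0 <- f_measure_macro(s$truth, init)
  f1 <- f_measure_macro(s$truth, ref)
  expect_gte(f1, 0.95 * f0)
  # inference is deterministic
  expect_identical(refine(s$noisy, init, p1, cfg, n_classes = 4), ref)
})
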