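# Refinement of an initial segmentation by a small agent trained with
# clipped-surrogate policy optimization (PPO).
#
# The environment walks over superpixel focus regions of the image in a
# deterministic scan order. At each focus region the agent picks one
# discrete action: dilate class k by one pixel inside the region, erode
# class k by one pixel inside the region, relabel the whole region to
# class k, or STOP (ends the episode). During training the per-step
# reward is the change in macro-averaged F-measure of the evolving mask
# against the ground truth. The agent is a pair of small fully-connected
# networks on a flattened local observation: an action scorer whose
# softmax gives the action probabilities, and a state-value head. Both
# are updated by minimizing
#   L = policy clip loss + value_coef * value loss + entropy_coef * (neg-entropy)
# with a standard adaptive first-order optimizer (Adam).

#' PPO configuration
#'
#' @param clip clipping half-width sigma of the probability ratio,
#'   in (0, 1); default 0.2.
#' @param gamma discount factor in (0, 1], default 0.99.
#' @param gae_lambda generalized-advantage-estimation decay in `[0, 1]`,
#'   default 0.95.
#' @param value_coef weight of the value loss, default 0.5.
#' @param entropy_coef weight of the negative-entropy regularizer,
#'   default 0.01.
#' @param epochs_per_update optimization passes over each batch, default 4.
#' @param minibatch minibatch size, default 64.
#' @param lr Adam learning rate, default 3e-3.
#' @param episode_cap maximum steps per episode; `NULL` means one pass
#'   over the focus regions.
#' @param hidden hidden-layer width of both networks, default 64.
#' @param n_superpixels focus-region count, default 64.
#' @param patch observation window side (odd), default 9.
#' @param updates number of PPO updates performed by [train_refiner()],
#'   default 20.
#' @param episodes_per_update episodes collected per update, default 4.
#' @param seed master seed for initialization, action sampling and
#'   minibatch shuffling.
#' @return object of class `ppo_config`.
#' @export
ppo_config <- function(clip = 0.2, gamma = 0.99, gae_lambda = 0.95,
                       value_coef = 0.5, entropy_coef = 0.01,
                       epochs_per_update = 4L, minibatch = 64L,
                       lr = 3e-3, episode_cap = NULL, hidden = 64L,
                       n_superpixels = 64L, patch = 9L, updates = 20L,
                       episodes_per_update = 4L, seed = 1L) {
  if (clip <= 0 || clip >= 1) .fail("clip must be in (0, 1)")
  if (gamma <= 0 || gamma > 1) .fail("gamma must be in (0, 1]")
  if (gae_lambda < 0 || gae_lambda > 1) .fail("gae_lambda must be in [0, 1]")
  if (patch %% 2 != 1) .fail("patch must be odd")
  structure(list(clip = clip, gamma = gamma, gae_lambda = gae_lambda,
                 value_coef = value_coef, entropy_coef = entropy_coef,
                 epochs_per_update = as.integer(epochs_per_update),
                 minibatch = as.integer(minibatch), lr = lr,
                 episode_cap = episode_cap, hidden = as.integer(hidden),
                 n_superpixels = as.integer(n_superpixels),
                 patch = as.integer(patch), updates = as.integer(updates),
                 episodes_per_update = as.integer(episodes_per_update),
                 seed = as.integer(seed)),
            class = "ppo_config")
}

# ---- elementary loss terms --------------------------------------------

#' Value loss
#'
#' Squared error between the value prediction and the empirical return,
#' halved: `0.5 * (value - ret)^2`.
#'
#' @param value predicted state value.
#' @param ret empirical (discounted) return.
#' @return non-negative loss.
#' @export
value_loss <- function(value, ret) {
  if (!all(is.finite(value), is.finite(ret))) .fail("non-finite inputs")
  0.5 * (value - ret)^2
}

#' Clipped-surrogate policy loss
#'
#' The negative of `min(ratio * advantage, clip(ratio, 1-clip, 1+clip) *
#' advantage)` (minimization convention). The clipping removes the
#' incentive to move the action probability ratio outside
#' `[1-clip, 1+clip]`.
#'
#' @param ratio new/old action probability ratio, > 0.
#' @param advantage advantage estimate.
#' @param clip clipping half-width in (0, 1).
#' @return scalar loss.
#' @export
policy_loss <- function(ratio, advantage, clip = 0.2) {
  if (any(ratio <= 0)) .fail("probability ratio must be positive")
  -pmin(ratio * advantage,
        pmin(pmax(ratio, 1 - clip), 1 + clip) * advantage)
}

#' Negative entropy of an action distribution
#'
#' `sum(p * log p)` with `0 * log 0 := 0`. The PPO objective adds
#' `entropy_coef` times this term, i.e. subtracts the entropy, to keep
#' the policy exploratory.
#'
#' @param probs probability vector (sums to 1, entries >= 0).
#' @return scalar in `[-log(length(probs)), 0]`.
#' @export
entropy_term <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6)
    .fail("probs must be a probability vector")
  p <- probs[probs > 0]
  sum(p * log(p))
}

#' Generalized advantage estimation
#'
#' Standard GAE recursion over one trajectory: with temporal differences
#' `delta_t = r_t + gamma * V_{t+1} - V_t` (zero bootstrap after the last
#' step), `adv_t = delta_t + gamma * lambda * adv_{t+1}`; returns are
#' `adv + V`.
#'
#' @param traj a trajectory as produced by [run_episode()]: a list with
#'   numeric `rewards` and `values` of equal length.
#' @param gamma discount factor.
#' @param gae_lambda GAE decay.
#' @return list with `advantages` and `returns`.
#' @export
compute_advantages <- function(traj, gamma = 0.99, gae_lambda = 0.95) {
  r <- traj$rewards; v <- traj$values
  n <- length(r)
  if (n < 1L) .fail("empty trajectory")
  adv <- numeric(n)
  nxt <- 0; nxt_v <- 0
  for (t in n:1) {
    delta <- r[t] + gamma * nxt_v - v[t]
    adv[t] <- delta + gamma * gae_lambda * nxt
    nxt <- adv[t]; nxt_v <- v[t]
  }
  list(advantages = adv, returns = adv + v)
}

# ---- parameter container and network evaluation ------------------------

#' Initialize policy/value parameters
#'
#' Two single-hidden-layer tanh networks (action scorer and state value)
#' with small random weights; reproducible for a fixed seed.
#'
#' @param obs_dim observation dimensionality.
#' @param n_actions number of discrete actions.
#' @param hidden hidden width.
#' @param seed RNG seed.
#' @param stop_bias initial logit bias on the final action. The refiner's
#'   final action is STOP, so a positive bias makes the untrained agent
#'   conservative (approximately the identity on the mask).
#' @return object of class `refine_params`; `as.numeric()` flattens it to
#'   the parameter vector lambda.
#' @export
init_refine_params <- function(obs_dim, n_actions, hidden = 64L, seed = 1L,
                               stop_bias = 0) {
  sc <- function(n, m) matrix(rnorm(n * m, sd = 1 / sqrt(m)), n, m)
  b2 <- numeric(n_actions)
  b2[n_actions] <- stop_bias
  with_seed(seed, {
    theta <- list(
      W1 = sc(hidden, obs_dim), b1 = numeric(hidden),
      W2 = sc(n_actions, hidden) * 0.01, b2 = b2,
      V1 = sc(hidden, obs_dim), c1 = numeric(hidden),
      v2 = matrix(rnorm(hidden, sd = 0.01), 1, hidden), c2 = 0)
    structure(list(theta = theta, obs_dim = as.integer(obs_dim),
                   n_actions = as.integer(n_actions),
                   hidden = as.integer(hidden),
                   opt = NULL, update_count = 0L),
              class = "refine_params")
  })
}

#' @export
print.refine_params <- function(x, ...) {
  cat("refine_params: obs_dim=", x$obs_dim, " actions=", x$n_actions,
      " hidden=", x$hidden, " (", length(as.numeric(x)),
      " parameters, ", x$update_count, " updates)\n", sep = "")
  invisible(x)
}

#' @export
as.double.refine_params <- function(x, ...) unlist(x$theta, use.names = FALSE)

# forward passes; obs may be a vector or an n x obs_dim matrix
.policy_forward <- function(params, X) {
  th <- params$theta
  if (is.null(dim(X))) X <- matrix(X, 1)
  H <- tanh(X %*% t(th$W1) + matrix(th$b1, nrow(X), params$hidden, byrow = TRUE))
  Z <- H %*% t(th$W2) + matrix(th$b2, nrow(X), params$n_actions, byrow = TRUE)
  Zm <- Z - apply(Z, 1, max)
  P <- exp(Zm) / rowSums(exp(Zm))
  list(H = H, Z = Z, P = P)
}
.value_forward <- function(params, X) {
  th <- params$theta
  if (is.null(dim(X))) X <- matrix(X, 1)
  G <- tanh(X %*% t(th$V1) + matrix(th$c1, nrow(X), params$hidden, byrow = TRUE))
  V <- as.vector(G %*% t(th$v2) + th$c2)
  list(G = G, V = V)
}

#' Action probabilities of the policy
#'
#' @param params a `refine_params` object.
#' @param obs observation vector (or matrix of row observations).
#' @return probability vector (or matrix of rows summing to 1).
#' @export
policy_probs <- function(params, obs) {
  P <- .policy_forward(params, obs)$P
  if (nrow(P) == 1L) as.vector(P) else P
}

#' State-value prediction
#'
#' @param params a `refine_params` object.
#' @param obs observation vector (or matrix of row observations).
#' @return scalar value (or vector).
#' @export
state_value <- function(params, obs) .value_forward(params, obs)$V

# ---- PPO update --------------------------------------------------------

#' One PPO update from a batch of trajectories
#'
#' Computes GAE advantages per trajectory, standardizes them across the
#' batch, and performs `epochs_per_update` Adam passes over shuffled
#' minibatches of the combined loss (clipped policy surrogate +
#' `value_coef` * value loss + `entropy_coef` * negative entropy).
#' Deterministic for a fixed config seed and update count.
#'
#' @param trajectories non-empty list of trajectories from [run_episode()].
#' @param params a `refine_params` object.
#' @param config a [ppo_config()].
#' @return updated `refine_params` (with Adam state and update counter).
#' @export
ppo_update <- function(trajectories, params, config) {
  if (length(trajectories) == 0L) .fail("empty trajectory batch")
  adv <- list(); ret <- list()
  for (i in seq_along(trajectories)) {
    ga <- compute_advantages(trajectories[[i]], config$gamma, config$gae_lambda)
    adv[[i]] <- ga$advantages; ret[[i]] <- ga$returns
  }
  X <- do.call(rbind, lapply(trajectories, `[[`, "observations"))
  a <- unlist(lapply(trajectories, `[[`, "actions"))
  old_logp <- log(unlist(lapply(trajectories, `[[`, "probs")))
  A <- unlist(adv); R <- unlist(ret)
  if (sd(A) > 1e-12) A <- (A - mean(A)) / sd(A) else A <- A - mean(A)
  n <- length(a)

  shuffle_seed <- derive_seed(config$seed, paste0("update", params$update_count))
  for (ep in seq_len(config$epochs_per_update)) {
    ord <- with_seed(derive_seed(shuffle_seed, ep), sample.int(n))
    for (s in seq(1, n, by = config$minibatch)) {
      idx <- ord[s:min(s + config$minibatch - 1L, n)]
      g <- .ppo_grad(params, X[idx, , drop = FALSE], a[idx],
                     old_logp[idx], A[idx], R[idx], config)
      params <- .adam_step(params, g, config$lr)
    }
  }
  params$update_count <- params$update_count + 1L
  params
}

# gradient of the mean combined loss over a minibatch
.ppo_grad <- function(params, X, a, old_logp, A, R, config) {
  th <- params$theta
  m <- nrow(X)
  pf <- .policy_forward(params, X)
  vf <- .value_forward(params, X)
  ai <- cbind(seq_len(m), a)
  logp <- log(pmax(pf$P[ai], 1e-12))
  ratio <- exp(logp - old_logp)
  clipped <- pmin(pmax(ratio, 1 - config$clip), 1 + config$clip)
  use_unclipped <- (ratio * A) <= (clipped * A)
  g_logp <- ifelse(use_unclipped, -A * ratio, 0) / m
  # d(neg-entropy)/dz
  logP <- log(pmax(pf$P, 1e-12))
  negent_rowgrad <- pf$P * (logP - rowSums(pf$P * logP))
  dZ <- matrix(0, m, params$n_actions)
  dZ[ai] <- g_logp
  dZ <- dZ - pf$P * g_logp          # through softmax: (e_a - p) * g
  dZ <- dZ + (config$entropy_coef / m) * negent_rowgrad
  dW2 <- t(dZ) %*% pf$H; db2 <- colSums(dZ)
  dH <- dZ %*% th$W2
  dU <- dH * (1 - pf$H^2)
  dW1 <- t(dU) %*% X; db1 <- colSums(dU)
  # value head
  dV <- config$value_coef * (vf$V - R) / m
  dv2 <- matrix(colSums(dV * vf$G), 1); dc2 <- sum(dV)
  dG <- outer(dV, as.vector(th$v2))
  dGu <- dG * (1 - vf$G^2)
  dV1 <- t(dGu) %*% X; dc1 <- colSums(dGu)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       V1 = dV1, c1 = dc1, v2 = dv2, c2 = dc2)
}

.adam_step <- function(params, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(params$opt))
    params$opt <- list(m = lapply(params$theta, function(x) x * 0),
                       v = lapply(params$theta, function(x) x * 0), t = 0L)
  o <- params$opt
  o$t <- o$t + 1L
  for (nm in names(params$theta)) {
    o$m[[nm]] <- beta1 * o$m[[nm]] + (1 - beta1) * g[[nm]]
    o$v[[nm]] <- beta2 * o$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- o$m[[nm]] / (1 - beta1^o$t)
    vhat <- o$v[[nm]] / (1 - beta2^o$t)
    params$theta[[nm]] <- params$theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$opt <- o
  params
}

# ---- environment -------------------------------------------------------

# action table: for each class k in action_classes: dilate k, erode k,
# relabel k; then STOP as the final action id
.action_table <- function(action_classes) {
  acts <- do.call(rbind, lapply(action_classes, function(k)
    data.frame(op = c("dilate", "erode", "relabel"), class = k)))
  rbind(acts, data.frame(op = "stop", class = NA_integer_))
}

.region_order <- function(regions) {
  ids <- sort(unique(as.vector(regions)))
  h <- nrow(regions)
  cent <- t(vapply(ids, function(id) {
    px <- which(regions == id)
    c(mean(((px - 1L) %% h) + 1L), mean(((px - 1L) %/% h) + 1L))
  }, numeric(2)))
  ids[order(cent[, 1], cent[, 2])]
}

# deterministic mask transition; returns the new label matrix
.apply_action <- function(labels, regions, region_id, op, class_k, n_classes) {
  if (op == "stop") return(labels)
  sel <- regions == region_id
  if (op == "relabel") {
    labels[sel] <- class_k
    return(labels)
  }
  h <- nrow(labels); w <- ncol(labels)
  up <- rbind(labels[1, , drop = FALSE], labels[-h, , drop = FALSE])
  dn <- rbind(labels[-1, , drop = FALSE], labels[h, , drop = FALSE])
  lf <- cbind(labels[, 1, drop = FALSE], labels[, -w, drop = FALSE])
  rt <- cbind(labels[, -1, drop = FALSE], labels[, w, drop = FALSE])
  if (op == "dilate") {
    grow <- sel & labels != class_k &
      (up == class_k | dn == class_k | lf == class_k | rt == class_k)
    labels[grow] <- class_k
  } else {  # erode: boundary pixels of class k take the dominant
            # non-k neighbour label (ties to the lowest id)
    shrink <- sel & labels == class_k &
      (up != class_k | dn != class_k | lf != class_k | rt != class_k)
    if (any(shrink)) {
      idx <- which(shrink)
      nb <- cbind(up[idx], dn[idx], lf[idx], rt[idx])
      repl <- apply(nb, 1, function(v) {
        v <- v[v != class_k]
        if (length(v) == 0) return(class_k)
        tt <- tabulate(v + 1L)
        which.max(tt) - 1L    # ties: lowest id wins
      })
      labels[idx] <- repl
    }
  }
  labels
}

# observation for focus region `rid` at step t
.observe <- function(image, labels, regions, rid, t, cap, patch, n_classes) {
  h <- nrow(image); w <- ncol(image)
  px <- which(regions == rid)
  cr <- round(mean(((px - 1L) %% h) + 1L))
  cc <- round(mean(((px - 1L) %/% h) + 1L))
  half <- (patch - 1L) %/% 2L
  r0 <- min(max(cr - half, 1L), h - patch + 1L)
  c0 <- min(max(cc - half, 1L), w - patch + 1L)
  imp <- image[r0:(r0 + patch - 1L), c0:(c0 + patch - 1L)]
  lap <- labels[r0:(r0 + patch - 1L), c0:(c0 + patch - 1L)]
  onehot <- vapply(0:(n_classes - 1L), function(k) as.numeric(lap == k),
                   numeric(patch * patch))
  c(as.vector(imp), as.vector(onehot), t / cap)
}

.obs_dim <- function(patch, n_classes) patch * patch * (1L + n_classes) + 1L

#' Run one refinement episode
#'
#' Walks the focus regions in scan order; at each step the policy picks an
#' action (sampled under `train_mode`, greedy with lowest-id tie-break
#' otherwise), the mask transitions deterministically, and — in training
#' mode — the reward is the change of macro-F against the ground truth.
#' The episode ends at STOP, after the episode cap, or when the regions
#' are exhausted.
#'
#' @param sample list with at least the image used for focus regions
#'   (`denoised` preferred, else `clean`, else `noisy`) and, for
#'   `train_mode`, a `truth` label matrix.
#' @param init_labels initial label matrix.
#' @param params a `refine_params`.
#' @param config a [ppo_config()].
#' @param train_mode logical; sample actions and record rewards.
#' @param regions optional precomputed focus-region matrix (ids 0-based);
#'   computed by [slic_superpixels()] when missing.
#' @param n_classes number of classes; default inferred from `params`.
#' @param seed RNG seed for action sampling in training mode.
#' @return list with `trajectory` (observations, actions, rewards, probs,
#'   values, terminal) and `labels` (the refined mask).
#' @export
run_episode <- function(sample, init_labels, params, config,
                        train_mode = FALSE, regions = NULL,
                        n_classes = NULL, seed = 1L) {
  img <- sample$denoised
  if (is.null(img)) img <- sample$clean
  if (is.null(img)) img <- sample$noisy
  if (is.null(img)) .fail("sample carries no image")
  if (train_mode && is.null(sample$truth))
    .fail("train_mode requires ground truth in the sample")
  if (is.null(regions))
    regions <- slic_superpixels(img, config$n_superpixels)
  if (is.null(n_classes))
    n_classes <- (params$n_actions - 1L) %/% 3L
  acts <- .action_table(0:(n_classes - 1L))
  stopifnot(nrow(acts) == params$n_actions)
  order_ids <- .region_order(regions)
  cap <- if (is.null(config$episode_cap)) length(order_ids)
         else min(config$episode_cap, length(order_ids))
  labels <- init_labels
  obs_l <- list(); act_v <- integer(0); rew_v <- numeric(0)
  prob_v <- numeric(0); val_v <- numeric(0)
  f_prev <- if (train_mode) f_measure_macro(sample$truth, labels) else NA
  rng <- derive_seed(seed, "episode")
  terminal <- FALSE
  t <- 0L
  while (t < cap) {
    t <- t + 1L
    rid <- order_ids[t]
    obs <- .observe(img, labels, regions, rid, t, cap, config$patch, n_classes)
    p <- policy_probs(params, obs)
    a <- if (train_mode)
      with_seed(derive_seed(rng, t), sample.int(length(p), 1L, prob = p))
    else which.max(p)   # ties: lowest action id
    labels <- .apply_action(labels, regions, rid, acts$op[a], acts$class[a],
                            n_classes)
    reward <- 0
    if (train_mode) {
      f_new <- f_measure_macro(sample$truth, labels)
      reward <- f_new - f_prev
      f_prev <- f_new
    }
    obs_l[[t]] <- obs
    act_v[t] <- a; rew_v[t] <- reward
    prob_v[t] <- p[a]; val_v[t] <- state_value(params, obs)
    if (acts$op[a] == "stop") { terminal <- TRUE; break }
  }
  traj <- list(observations = do.call(rbind, obs_l), actions = act_v,
               rewards = rew_v, probs = prob_v, values = val_v,
               terminal = terminal || t >= cap)
  list(trajectory = traj, labels = labels)
}

#' Train the refinement agent
#'
#' Splits the dataset into training samples and a held-out monitor set,
#' precomputes each sample's initial segmentation with `segment_fn`, and
#' alternates episode collection with PPO updates. The mean collected
#' reward per update is attached as attribute `"training_curve"`.
#'
#' @param dataset list of >= 2 samples (see [make_dataset()]).
#' @param segment_fn function(sample) -> initial label matrix.
#' @param config a [ppo_config()]; `updates = 0` returns the freshly
#'   initialized parameters.
#' @param n_classes label-class count of the segmentation task.
#' @param monitor_frac fraction of samples held out (>= 1 sample).
#' @return trained `refine_params` with attributes `training_curve` and
#'   `monitor_idx`.
#' @export
train_refiner <- function(dataset, segment_fn, config, n_classes,
                          monitor_frac = 0.25) {
  if (length(dataset) < 2L) .fail("dataset must hold at least 2 samples")
  n_mon <- max(1L, floor(length(dataset) * monitor_frac))
  mon_idx <- seq_len(n_mon)              # deterministic split
  train_idx <- setdiff(seq_along(dataset), mon_idx)
  inits <- lapply(dataset, segment_fn)
  obs_dim <- .obs_dim(config$patch, n_classes)
  params <- init_refine_params(obs_dim, 3L * n_classes + 1L,
                               config$hidden, config$seed, stop_bias = 1.5)
  curve <- numeric(0)
  if (config$updates >= 1L) for (u in seq_len(config$updates)) {
    trajs <- list()
    for (e in seq_len(config$episodes_per_update)) {
      i <- train_idx[((u - 1L) * config$episodes_per_update + e - 1L) %%
                       length(train_idx) + 1L]
      ep <- run_episode(dataset[[i]], inits[[i]], params, config,
                        train_mode = TRUE, n_classes = n_classes,
                        seed = derive_seed(config$seed, paste0("ep", u, "_", e)))
      trajs[[e]] <- ep$trajectory
    }
    curve[u] <- mean(unlist(lapply(trajs, `[[`, "rewards")))
    params <- ppo_update(trajs, params, config)
  }
  attr(params, "training_curve") <- curve
  attr(params, "monitor_idx") <- mon_idx
  params
}

#' Apply the trained refiner to a segmentation
#'
#' Runs one inference episode (greedy action selection, no rewards) and
#' returns the refined label map. Deterministic.
#'
#' @param image the image the initial segmentation came from (used for
#'   the focus regions and observations).
#' @param init_labels initial label matrix.
#' @param params trained `refine_params`.
#' @param config the [ppo_config()] used at training time.
#' @param n_classes class count; inferred from `params` when missing.
#' @return refined integer label matrix.
#' @export
refine <- function(image, init_labels, params, config, n_classes = NULL) {
  out <- run_episode(list(denoised = image), init_labels, params, config,
                     train_mode = FALSE, n_classes = n_classes)
  out$labels
}
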