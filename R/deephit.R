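# Discrete-time competing-risk neural hazard model: a fully connected
# shared trunk feeding two cause-specific subnetworks whose outputs are
# joined by a single softmax over the K x T event-by-month grid, so each
# patient's prediction is a joint probability mass r(k, t | x) with
# sum_{k,t} r = 1. Trained by minimizing
#   L = L_NLL + alpha_rank * L_rank
# with analytically derived gradients (no autodiff): the two loss terms
# are differentiated with respect to the mass, mapped through the softmax
# Jacobian, and backpropagated through the linear/ReLU stack; optimization
# is mini-batch Adam with early stopping on a stratified validation split.
#
# Likelihood convention: a patient with event k in bin l contributes
# -log r(k, l); a patient censored in bin c contributes -log(1 - F(c-1)),
# where F is the all-cause cumulative mass — the event is constrained to
# bins tau >= c. This boundary convention keeps the likelihood proper for
# patients administratively censored in the final bin (the last bin
# absorbs residual survivor mass) while preserving the exact K x T
# normalization.

#' Hyperparameters for the competing-risk network
#'
#' @param shared_layers integer widths of the shared trunk.
#' @param cause_layers integer widths of each cause-specific subnetwork.
#' @param activation `"relu"` or `"tanh"`.
#' @param dropout dropout rate on hidden activations, in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (best-epoch weights are restored).
#' @param alpha_rank weight of the ranking loss (`0` disables it).
#' @param sigma_rank ranking kernel scale (> 0).
#' @param seed integer; same seed, same fitted parameters.
#' @return object of class `wl_hyperparams`.
#' @export
hyperparams <- function(shared_layers = c(64L, 64L), cause_layers = 32L,
                        activation = c("tanh", "relu"), dropout = 0.1,
                        learning_rate = 1e-3, batch_size = 256L,
                        max_epochs = 300L, early_stop_patience = 20L,
                        alpha_rank = 0.02, sigma_rank = 0.1, seed = 1L) {
  activation <- match.arg(activation)
  hp <- structure(
    list(shared_layers = as.integer(shared_layers),
         cause_layers = as.integer(cause_layers),
         activation = activation, dropout = dropout,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         alpha_rank = alpha_rank, sigma_rank = sigma_rank,
         seed = as.integer(seed)),
    class = "wl_hyperparams"
  )
  stopifnot(all(hp$shared_layers >= 1), all(hp$cause_layers >= 1),
            hp$dropout >= 0, hp$dropout < 1, hp$learning_rate > 0,
            hp$batch_size >= 1, hp$max_epochs >= 1, hp$alpha_rank >= 0,
            hp$sigma_rank > 0)
  hp
}

act_fun <- function(name) {
  if (name == "relu") list(f = function(z) pmax(z, 0),
                           df = function(z) (z > 0) * 1)
  else list(f = tanh, df = function(z) 1 - tanh(z)^2)
}

# He-style initialization; all matrices drawn from the seeded RNG stream.
init_params <- function(p, n_bins, hp) {
  mk <- function(nin, nout) {
    list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
         b = rep(0, nout))
  }
  shared <- list()
  nin <- p
  for (w in hp$shared_layers) {
    shared[[length(shared) + 1]] <- mk(nin, w)
    nin <- w
  }
  branch <- function() {
    layers <- list()
    m <- nin
    for (w in hp$cause_layers) {
      layers[[length(layers) + 1]] <- mk(m, w)
      m <- w
    }
    layers[[length(layers) + 1]] <- mk(m, n_bins)  # linear output
    layers
  }
  list(shared = shared, death = branch(), transplant = branch())
}

# Forward pass. Returns the softmax mass (n x 2T) and, when cache = TRUE,
# every pre-activation/activation needed for the backward pass.
net_forward <- function(params, X, hp, dropout_masks = NULL, cache = FALSE) {
  act <- act_fun(hp$activation)
  mi <- 0
  run_stack <- function(H, layers, n_hidden) {
    pre <- list(); post <- list()
    for (li in seq_along(layers)) {
      Z <- sweep(H %*% layers[[li]]$W, 2, layers[[li]]$b, "+")
      if (li <= n_hidden) {
        A <- act$f(Z)
        if (!is.null(dropout_masks)) {
          mi <<- mi + 1
          A <- A * dropout_masks[[mi]]
        }
      } else A <- Z
      pre[[li]] <- Z; post[[li]] <- A
      H <- A
    }
    list(pre = pre, post = post, out = H)
  }
  sh <- run_stack(X, params$shared, length(params$shared))
  d <- run_stack(sh$out, params$death, length(hp$cause_layers))
  tr <- run_stack(sh$out, params$transplant, length(hp$cause_layers))
  z <- cbind(d$out, tr$out)
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  mass <- ez / rowSums(ez)
  if (!cache) return(mass)
  list(mass = mass, shared = sh, death = d, transplant = tr, X = X)
}

# Loss value and gradient with respect to the mass matrix (n x 2T).
# Returns list(loss_nll, loss_rank, n_pairs, g) with g already scaled by
# batch-mean / pair-mean normalization.
mass_loss_grad <- function(mass, event_type, event_month, n_bins, hp,
                           want_grad = TRUE) {
  eps <- 1e-12
  n <- nrow(mass)
  g <- if (want_grad) matrix(0, n, 2 * n_bins) else NULL
  col_of <- function(k, l) (k - 1L) * n_bins + l + 1L
  loss_nll <- 0
  # uncensored: -log r(k, l)
  unc <- which(event_type != EVENT_CENSORED)
  if (length(unc) > 0) {
    cols <- col_of(event_type[unc], event_month[unc])
    r <- pmax(mass[cbind(unc, cols)], eps)
    loss_nll <- loss_nll + sum(-log(r))
    if (want_grad) g[cbind(unc, cols)] <- g[cbind(unc, cols)] - 1 / r / n
  }
  # censored in bin c: -log(1 - F(c-1)); c = 0 contributes nothing
  cen <- which(event_type == EVENT_CENSORED & event_month > 0)
  if (length(cen) > 0) {
    Fall <- t(apply(mass[cen, seq_len(n_bins), drop = FALSE] +
                      mass[cen, n_bins + seq_len(n_bins), drop = FALSE],
                    1, cumsum))
    if (length(cen) == 1) Fall <- matrix(Fall, 1)
    S <- pmax(1 - Fall[cbind(seq_along(cen), event_month[cen])], eps)
    loss_nll <- loss_nll + sum(-log(S))
    if (want_grad) {
      for (ii in seq_along(cen)) {
        cc <- event_month[cen[ii]]
        tau <- seq_len(cc)  # bins 0..c-1
        g[cen[ii], tau] <- g[cen[ii], tau] + 1 / S[ii] / n
        g[cen[ii], n_bins + tau] <- g[cen[ii], n_bins + tau] + 1 / S[ii] / n
      }
    }
  }
  loss_nll <- loss_nll / n
  # ranking loss over comparable pairs, per event
  loss_rank <- 0
  n_pairs <- 0L
  gF <- NULL
  if (hp$alpha_rank > 0) {
    gF <- list(matrix(0, n, n_bins), matrix(0, n, n_bins))
    pair_terms <- vector("list", 2)
    for (k in 1:2) {
      cases <- which(event_type == k)
      if (length(cases) == 0) next
      Fk <- t(apply(mass[, (k - 1L) * n_bins + seq_len(n_bins),
                         drop = FALSE], 1, cumsum))
      if (n == 1) Fk <- matrix(Fk, 1)
      l <- event_month[cases]
      A <- Fk[, l + 1L, drop = FALSE]               # n x |cases|: F_j(k, l_i)
      fi <- Fk[cbind(cases, l + 1L)]
      valid <- outer(event_month, l, ">")           # j at risk past l_i
      val <- exp(-(matrix(fi, n, length(cases), byrow = TRUE) - A) /
                   hp$sigma_rank) * valid
      pair_terms[[k]] <- list(cases = cases, l = l, val = val)
      n_pairs <- n_pairs + sum(valid)
    }
    if (n_pairs > 0) {
      for (k in 1:2) {
        pt <- pair_terms[[k]]
        if (is.null(pt)) next
        loss_rank <- loss_rank + sum(pt$val)
        if (want_grad) {
          scale <- 1 / (hp$sigma_rank * n_pairs)
          # d/dF_i at (i, l_i): -scale * sum_j val
          gF[[k]][cbind(pt$cases, pt$l + 1L)] <-
            gF[[k]][cbind(pt$cases, pt$l + 1L)] - colSums(pt$val) * scale
          # d/dF_j at (j, l_i): +scale * val
          agg <- rowsum(t(pt$val), group = pt$l)     # unique l x n
          lu <- as.integer(rownames(agg))
          gF[[k]][, lu + 1L] <- gF[[k]][, lu + 1L] + t(agg) * scale
        }
      }
      loss_rank <- loss_rank / n_pairs
      if (want_grad) {
        # F(k, t) = sum_{tau <= t} mass -> d/dmass[tau] = sum_{t >= tau} gF[t]
        for (k in 1:2) {
          rc <- t(apply(gF[[k]][, n_bins:1, drop = FALSE], 1, cumsum))
          if (n == 1) rc <- matrix(rc, 1)
          g[, (k - 1L) * n_bins + seq_len(n_bins)] <-
            g[, (k - 1L) * n_bins + seq_len(n_bins)] +
            hp$alpha_rank * rc[, n_bins:1, drop = FALSE]
        }
      }
    }
  }
  list(loss = loss_nll + hp$alpha_rank * loss_rank, loss_nll = loss_nll,
       loss_rank = loss_rank, n_pairs = n_pairs, g = g)
}

# Full backward pass: gradient of the scalar loss with respect to every
# parameter, given the forward cache and dL/dmass.
net_backward <- function(params, fw, g_mass, hp, dropout_masks = NULL) {
  act <- act_fun(hp$activation)
  mass <- fw$mass
  # softmax Jacobian: dL/dz = m * (g - sum(g * m))
  dz <- mass * (g_mass - rowSums(g_mass * mass))
  n_bins <- ncol(mass) / 2
  mi_total <- length(params$shared) + 2 * length(hp$cause_layers)
  mi <- mi_total
  back_stack <- function(layers, cache, dOut, input, n_hidden) {
    grads <- vector("list", length(layers))
    d <- dOut
    for (li in rev(seq_along(layers))) {
      A_in <- if (li == 1) input else cache$post[[li - 1]]
      if (li <= n_hidden) {
        if (!is.null(dropout_masks)) {
          d <- d * dropout_masks[[mi]]
        }
        mi <<- mi - 1
        d <- d * act$df(cache$pre[[li]])
      }
      grads[[li]] <- list(W = crossprod(A_in, d), b = colSums(d))
      d <- d %*% t(layers[[li]]$W)
    }
    list(grads = grads, d_input = d)
  }
  # branch order must mirror forward mask consumption: shared, death, transplant
  nh <- length(hp$cause_layers)
  # transplant branch (masks consumed last in forward)
  bt <- back_stack(params$transplant, fw$transplant,
                   dz[, n_bins + seq_len(n_bins), drop = FALSE],
                   fw$shared$out, nh)
  bd <- back_stack(params$death, fw$death,
                   dz[, seq_len(n_bins), drop = FALSE],
                   fw$shared$out, nh)
  d_shared_out <- bd$d_input + bt$d_input
  mi <- length(params$shared)
  bs <- back_stack(params$shared, fw$shared, d_shared_out, fw$X,
                   length(params$shared))
  list(shared = bs$grads, death = bd$grads, transplant = bt$grads)
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (blk in names(params)) {
    for (li in seq_along(params[[blk]])) {
      for (w in c("W", "b")) {
        gmat <- grads[[blk]][[li]][[w]]
        state$m[[blk]][[li]][[w]] <- beta1 * state$m[[blk]][[li]][[w]] +
          (1 - beta1) * gmat
        state$v[[blk]][[li]][[w]] <- beta2 * state$v[[blk]][[li]][[w]] +
          (1 - beta2) * gmat^2
        mhat <- state$m[[blk]][[li]][[w]] / (1 - beta1^step)
        vhat <- state$v[[blk]][[li]][[w]] / (1 - beta2^step)
        params[[blk]][[li]][[w]] <- params[[blk]][[li]][[w]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = params, state = state)
}

stratified_indices <- function(event_type, fraction, min_per_class = 1L) {
  held <- integer(0)
  for (k in unique(event_type)) {
    members <- which(event_type == k)
    n_take <- max(min_per_class, round(length(members) * fraction))
    n_take <- min(n_take, length(members))
    held <- c(held, sample(members, n_take))
  }
  sort(held)
}

#' Fit the competing-risk neural model
#'
#' @param train a `wl_cohort` used for training; must contain at least one
#'   death and one transplant.
#' @param hp a [hyperparams()] object.
#' @param val_fraction fraction of `train` carved out (stratified by event
#'   class) as the early-stopping validation split.
#' @param verbose print per-epoch losses.
#' @return object of class `wl_deephit`: network parameters, the frozen
#'   training-data encoder, training history, and the hyperparameters.
#' @export
fit_deephit <- function(train, hp = hyperparams(), val_fraction = 0.1,
                        verbose = FALSE) {
  stopifnot(inherits(train, "wl_cohort"))
  n <- nrow(train$covariates)
  if (n == 0) stopf("training cohort is empty")
  types <- train$outcomes$event_type
  if (!any(types == EVENT_DEATH) || !any(types == EVENT_TRANSPLANT)) {
    stopf("cannot fit: training cohort lacks an event type (all-censored or single-event)")
  }
  encoder <- make_encoder(train$covariates)
  X_all <- encode_covariates(encoder, train$covariates)
  n_bins <- train$horizon
  with_seed(hp$seed, {
    params <- init_params(ncol(X_all), n_bins, hp)
    use_val <- val_fraction > 0 && n >= 30
    if (use_val) {
      val_idx <- stratified_indices(types, val_fraction)
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      val_idx <- integer(0)
      tr_idx <- seq_len(n)
    }
    Xtr <- X_all[tr_idx, , drop = FALSE]
    et_tr <- types[tr_idx]
    em_tr <- train$outcomes$event_month[tr_idx]
    Xva <- X_all[val_idx, , drop = FALSE]
    et_va <- types[val_idx]
    em_va <- train$outcomes$event_month[val_idx]
    ntr <- length(tr_idx)
    state <- list(m = adam_init(params), v = adam_init(params))
    step <- 0L
    best <- list(loss = Inf, params = params, epoch = 0L)
    patience_left <- hp$early_stop_patience
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    n_hidden_masks <- length(hp$shared_layers) + 2 * length(hp$cause_layers)
    widths <- c(hp$shared_layers, hp$cause_layers, hp$cause_layers)
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample.int(ntr)
      batch_starts <- seq(1, ntr, by = hp$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + hp$batch_size - 1L, ntr)]
        Xb <- Xtr[idx, , drop = FALSE]
        masks <- NULL
        if (hp$dropout > 0) {
          masks <- lapply(widths, function(w) {
            matrix((stats::runif(length(idx) * w) > hp$dropout) /
                     (1 - hp$dropout), length(idx), w)
          })
        }
        fw <- net_forward(params, Xb, hp, dropout_masks = masks, cache = TRUE)
        lg <- mass_loss_grad(fw$mass, et_tr[idx], em_tr[idx], n_bins, hp)
        if (!is.finite(lg$loss)) {
          stopf("training diverged (non-finite loss at epoch %d); lower the learning rate", epoch)
        }
        grads <- net_backward(params, fw, lg$g, hp, dropout_masks = masks)
        step <- step + 1L
        upd <- adam_step(params, grads, state, hp$learning_rate, step)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      ep_loss <- ep_loss / ntr
      val_loss <- NA_real_
      if (use_val) {
        mv <- net_forward(params, Xva, hp)
        val_loss <- mass_loss_grad(mv, et_va, em_va, n_bins, hp,
                                   want_grad = FALSE)$loss
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, params = params, epoch = epoch)
          patience_left <- hp$early_stop_patience
        } else {
          patience_left <- patience_left - 1L
        }
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, ep_loss,
                        val_loss))
      }
      if (use_val && patience_left <= 0) break
    }
    if (use_val && is.finite(best$loss)) params <- best$params
    structure(
      list(params = params, encoder = encoder, hp = hp, history = hist,
           horizon = n_bins, n_features = ncol(X_all),
           schema = encoder$schema),
      class = "wl_deephit"
    )
  })
}

#' @export
print.wl_deephit <- function(x, ...) {
  cat(sprintf(
    "<wl_deephit> %d features -> shared [%s] -> 2 x cause [%s] -> softmax 2x%d\n  trained %d epochs (final train loss %.4f)\n",
    x$n_features, paste(x$hp$shared_layers, collapse = ","),
    paste(x$hp$cause_layers, collapse = ","), x$horizon,
    nrow(x$history), utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' Predict the joint event-month risk mass
#'
#' Deterministic forward pass (dropout off). The returned array satisfies
#' the mass invariants: non-negative entries summing to 1 per patient, and
#' nondecreasing cumulative incidence for both events.
#'
#' @param model a fitted `wl_deephit`.
#' @param newdata covariate data.frame (one or more patients).
#' @return n x 2 x T array of probabilities; event dimension named
#'   `death`, `transplant`.
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "wl_deephit"))
  X <- encode_covariates(model$encoder, newdata)
  predict_risk_encoded(model, X)
}

predict_risk_encoded <- function(model, X) {
  mass <- net_forward(model$params, X, model$hp)
  n_bins <- model$horizon
  out <- array(0, dim = c(nrow(X), 2, n_bins),
               dimnames = list(NULL, EVENT_NAMES, NULL))
  out[, 1, ] <- mass[, seq_len(n_bins)]
  out[, 2, ] <- mass[, n_bins + seq_len(n_bins)]
  out
}

#' Cumulative incidence curves from a mass array
#'
#' @param mass n x K x T mass array (from [predict_risk()]).
#' @return n x K x T array of CIF values (cumulative sums over months).
#' @export
risk_cif <- function(mass) {
  out <- mass
  for (k in seq_len(dim(mass)[2])) {
    m <- mass[, k, , drop = FALSE]
    dim(m) <- dim(mass)[c(1, 3)]
    cs <- t(apply(m, 1, cumsum))
    if (dim(mass)[1] == 1) cs <- matrix(cs, 1)
    out[, k, ] <- cs
  }
  out
}

#' Save a fitted competing-risk model
#'
#' Writes a single archive holding the network parameters, the frozen
#' standardization statistics, hyperparameters, training history and the
#' feature-schema hash.
#'
#' @param model a `wl_deephit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_deephit <- function(model, path) {
  stopifnot(inherits(model, "wl_deephit"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a fitted competing-risk model
#'
#' Fails loudly when the archive's feature schema does not match the
#' package's covariate layout.
#'
#' @param path file path written by [save_deephit()].
#' @return a `wl_deephit`.
#' @export
load_deephit <- function(path) {
  obj <- readRDS(path)
  expected <- schema_hash(covariate_names())
  if (!identical(obj$schema, expected)) {
    stopf("model archive schema %s does not match this package's covariate schema %s",
          obj$schema, expected)
  }
  structure(obj, class = "wl_deephit")
}
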