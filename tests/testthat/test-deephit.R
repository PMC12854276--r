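test_that("analytic gradients match finite differences", {
  withr::local_seed(42)
  p <- 5; n_bins <- 6; n <- 9
  hp <- hyperparams(shared_layers = c(7, 6), cause_layers = 5,
                    activation = "tanh", dropout = 0, alpha_rank = 0.5,
                    sigma_rank = 0.2, seed = 3)
  X <- matrix(rnorm(n * p), n, p)
  et <- c(1L, 2L, 0L, 1L, 0L, 2L, 1L, 0L, 2L)
  em <- c(2L, 4L, 5L, 0L, 3L, 1L, 5L, 0L, 2L)
  params <- waitlistcr:::with_seed(3, waitlistcr:::init_params(p, n_bins, hp))
  loss_at <- function(pp) {
    m <- waitlistcr:::net_forward(pp, X, hp)
    waitlistcr:::mass_loss_grad(m, et, em, n_bins, hp, want_grad = FALSE)$loss
  }
  fw <- waitlistcr:::net_forward(params, X, hp, cache = TRUE)
  lg <- waitlistcr:::mass_loss_grad(fw$mass, et, em, n_bins, hp)
  gr <- waitlistcr:::net_backward(params, fw, lg$g, hp)
  eps <- 1e-6
  worst <- 0
  for (blk in names(params)) for (li in seq_along(params[[blk]])) {
    for (w in c("W", "b")) {
      th <- params[[blk]][[li]][[w]]
      for (ii in seq_len(min(length(th), 6))) {
        pp <- params; pp[[blk]][[li]][[w]][ii] <- th[ii] + eps
        pm <- params; pm[[blk]][[li]][[w]][ii] <- th[ii] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        ana <- gr[[blk]][[li]][[w]][ii]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("fitted models emit normalized mass with monotone CIFs", {
  fx <- shared_fit()
  mass <- predict_risk(fx$fit, fx$cohort$covariates[1:50, ])
  sums <- apply(mass, 1, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(mass >= 0))
  cif <- risk_cif(mass)
  for (k in 1:2) {
    expect_true(all(cif[, k, -1] - cif[, k, -dim(cif)[3]] >= -1e-12))
  }
  expect_true(all(cif[, 1, ] + cif[, 2, ] <= 1 + 1e-5))
})

test_that("training is seed-deterministic end to end", {
  cfg <- default_cohort_config(n_patients = 300, horizon = 8, seed = 17)
  cohort <- generate_cohort(cfg)
  hp <- hyperparams(shared_layers = 16, cause_layers = 8, max_epochs = 10,
                    seed = 99)
  f1 <- fit_deephit(cohort, hp)
  f2 <- fit_deephit(cohort, hp)
  x <- cohort$covariates[1:5, ]
  expect_identical(predict_risk(f1, x), predict_risk(f2, x))
  expect_identical(f1$history, f2$history)
  # prediction itself is deterministic
  expect_identical(predict_risk(f1, x), predict_risk(f1, x))
})

test_that("training reduces the loss on a non-degenerate cohort", {
  fx <- shared_fit()
  h <- fx$fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("degenerate cohorts are rejected before training", {
  cohort <- generate_cohort(default_cohort_config(80, 6, seed = 2))
  allcens <- cohort
  allcens$outcomes$event_type[] <- 0L
  expect_error(fit_deephit(allcens, hyperparams(max_epochs = 1)),
               "all-censored|lacks an event")
  onetype <- cohort
  onetype$outcomes$event_type[onetype$outcomes$event_type == 2L] <- 0L
  expect_error(fit_deephit(onetype, hyperparams(max_epochs = 1)),
               "lacks an event")
})

test_that("death-loaded covariates rank above the cohort median death risk", {
  fx <- shared_fit()
  cohort <- fx$cohort
  cif_all <- risk_cif(predict_risk(fx$fit, cohort$covariates))
  median_death <- stats::median(cif_all[, 1, 12])
  # 100 draws from the top death-risk decile of the generator's own law
  draws <- waitlistcr:::with_seed(
    7, waitlistcr:::sample_covariates(fx$cfg, 1000))
  oracle <- true_cif(fx$cfg, draws, "death", 11)
  top <- draws[order(-oracle)[1:100], ]
  cif_hi <- risk_cif(predict_risk(fx$fit, top))
  expect_gte(mean(cif_hi[, 1, 12] > median_death), 0.95)
})

test_that("unknown categories are rejected at prediction time", {
  fx <- shared_fit()
  x <- fx$cohort$covariates[1, , drop = FALSE]
  x$blood_type <- "Q"
  expect_error(predict_risk(fx$fit, x), "blood_type")
})

test_that("model archives round-trip and reject a foreign schema", {
  fx <- shared_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_deephit(fx$fit, path)
  back <- load_deephit(path)
  x <- fx$cohort$covariates[1:4, ]
  expect_identical(predict_risk(back, x), predict_risk(fx$fit, x))
  tampered <- unclass(fx$fit)
  tampered$schema <- "deadbeef"
  saveRDS(tampered, path)
  expect_error(load_deephit(path), "schema")
})
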