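# latent R2, standardization, trait-only and lagged models

fake_fit <- function(eta_fix, u_hat, subj) {
  structure(list(eta_fix = eta_fix, u_hat = u_hat, obs_subject = subj,
                 coef = c(alpha = 0.5), mode = "penalized", lag = FALSE),
            class = "store_fit")
}

test_that("latent R2 follows its variance-ratio definition", {
  subj <- rep(c("a", "b"), each = 4)
  # constant fixed part, no random effects: R2 = 0
  r0 <- latent_r2(fake_fit(rep(1.3, 8), c(a = 0, b = 0), subj))
  expect_equal(r0$r2, 0)
  # Var(fhat) = 1 and u = 0: R2 = 1/2 with unit error variance
  eta <- scale(rnorm(8))[, 1] # exact unit sample variance
  r1 <- latent_r2(fake_fit(eta, c(a = 0, b = 0), subj))
  expect_equal(r1$r2, 0.5, tolerance = 1e-12)
  expect_equal(r1$latent_sd, sqrt(2), tolerance = 1e-12)
  # logistic option uses pi^2/3 as the error variance
  r2 <- latent_r2(fake_fit(eta, c(a = 0, b = 0), subj), error_var = "logistic")
  expect_equal(r2$r2, 1 / (1 + pi^2 / 3), tolerance = 1e-12)
  # invariant to adding a constant to the fitted surface
  r3 <- latent_r2(fake_fit(eta + 7, c(a = 0, b = 0), subj))
  expect_equal(r3$r2, r1$r2, tolerance = 1e-12)
})

test_that("R2 on simulated data tracks the generating surface", {
  cfg <- small_config(p = 1)
  panel <- simulate_panel(cfg, seed = 404)
  fit <- fit_store(panel, "penalized", lambda = 1e4)
  r <- latent_r2(fit)
  # plug-in oracle from the generating f and the true random intercepts
  tr <- person_medians(panel)
  dat <- dplyr::left_join(panel, tr, by = "subject")
  f_true <- true_f(cfg, dat$x_med, dat$x)
  u_true <- attr(panel, "u_true")[as.character(dat$subject)]
  r_true <- var(f_true) / (var(f_true + u_true) + 1)
  expect_equal(r$r2, r_true, tolerance = 0.15)
  expect_gte(r$r2, 0)
  expect_lte(r$r2, 1)
  expect_gte(r$latent_sd, 1)
})

test_that("standardized coefficients preserve sign and scale correctly", {
  panel <- simulate_panel(small_config(p = 1), seed = 405)
  fit <- fit_store(panel, "penalized", lambda = 100)
  sd_l <- latent_r2(fit)$latent_sd
  std <- standardize_coefs(fit)
  expect_equal(std, fit$coef / sd_l)
  expect_true(all(sign(std) == sign(fit$coef) | fit$coef == 0))
  td <- tidy(fit)
  expect_equal(td$standardized_estimate, td$estimate / sd_l)
})

test_that("trait-only model matches the full model when states never deviate", {
  set.seed(11)
  d <- do.call(rbind, lapply(1:10, function(i) {
    r <- sample(2:4, 1)
    data.frame(subject = sprintf("c%d", i), x = rep(r, 6),
               y = sample.int(4, 6, TRUE))
  }))
  panel <- ordinal_panel(d, x_levels = 5, y_levels = 4)
  f_full <- fit_store(panel, "unpenalized")
  f_trait <- fit_trait_only(panel, lambda = 0)
  expect_equal(f_full$loglik, f_trait$loglik, tolerance = 1e-6)
})

test_that("trait-only R2 is near zero when the trait effect is absent", {
  cfg <- small_config(p = 1)
  cfg$coefs[["trait"]] <- 0
  panel <- simulate_panel(cfg, seed = 406)
  ft <- fit_trait_only(panel, lambda = 1e4)
  expect_lt(latent_r2(ft)$r2, 0.05)
})

test_that("lagged models drop the first observation per subject or per day", {
  d <- data.frame(subject = rep(c("a", "b"), each = 3),
                  x = rep(2, 6), y = c(1, 2, 3, 2, 2, 1))
  p <- ordinal_panel(d, x_levels = 3, y_levels = 3)
  mf <- statetrait:::st_model_frame(p, "linear", lag = TRUE)
  expect_equal(length(mf$y), 4) # 2 retained per subject
  d$day <- rep(c(1, 1, 2), 2)
  p2 <- ordinal_panel(d, day = "day", x_levels = 3, y_levels = 3)
  mf2 <- statetrait:::st_model_frame(p2, "linear", lag = TRUE)
  expect_equal(length(mf2$y), 2) # first of each subject-day dropped
  expect_equal(mf2$X[, "beta_lag"], c(1, 2), ignore_attr = TRUE)
})

test_that("lagged coefficient is null when the process has no serial dependence", {
  cfg <- small_config(p = 1)
  est <- vapply(1:6, function(k) {
    panel <- simulate_panel(cfg, seed = 500 + k)
    fit <- fit_lagged(panel, mode = "linear")
    fit$coef[["beta_lag"]]
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
  # scaled AIC comparable with and without the lag term
  panel <- simulate_panel(cfg, seed = 507)
  f0 <- fit_store(panel, "linear")
  f1 <- fit_lagged(panel, mode = "linear")
  expect_lt(abs(f0$scaled_aic - f1$scaled_aic), 0.05)
})
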