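# Fit-level behaviour on scaled-down synthetic panels.

panel_small <- simulate_panel(small_config(p = 1), seed = 202)

test_that("penalized fit at lambda = 0 reproduces the unpenalized fit", {
  fu <- fit_store(panel_small, "unpenalized")
  f0 <- fit_store(panel_small, "penalized", lambda = 0)
  expect_equal(fitted_f(f0)$f, fitted_f(fu)$f, tolerance = 1e-5)
  expect_equal(f0$loglik, fu$loglik, tolerance = 1e-8)
  expect_equal(f0$aic, fu$aic, tolerance = 1e-4)
  # EDF at lambda = 0 equals the number of coefficients exactly
  expect_equal(fu$edf$total, length(fu$coef))
})

test_that("heavily penalized fit collapses onto the linear model", {
  # needs a key set covering the full grid, where the penalty null space is
  # exactly the space of linear surfaces
  panel <- simulate_panel(sim_config(p = 1), seed = 42)
  expect_equal(nrow(key_set(panel)), 49)
  fl <- fit_store(panel, "linear")
  fbig <- fit_store(panel, "penalized", lambda = 1e8)
  f_lin <- fitted_f(fl, cells = fbig$layout$cells)
  expect_lt(max(abs(fitted_f(fbig)$f - f_lin$f)), 1e-3)
  expect_lt(abs(fbig$edf$total - 3), 0.01)
  expect_equal(fbig$sigma_u, fl$sigma_u, tolerance = 1e-3)
})

test_that("EDF decreases monotonically in lambda and partitions by term", {
  edfs <- vapply(c(0.1, 1, 10), function(l) {
    fit_store(panel_small, "penalized", lambda = l)$edf$total
  }, numeric(1))
  expect_true(all(diff(edfs) < 0))
  f1 <- fit_store(panel_small, "penalized", lambda = 1)
  expect_equal(f1$edf$total,
               unname(f1$edf$by_term["alpha"] + f1$edf$by_term["tau"] +
                        f1$edf$by_term["gamma"]),
               tolerance = 1e-10)
  expect_gte(f1$edf$total, 3)
  expect_lte(f1$edf$total, length(f1$coef))
})

test_that("the reported optimum has a small penalized-objective gradient", {
  fp <- fit_store(panel_small, "penalized", lambda = 5)
  expect_true(fp$converged)
  expect_lt(fp$grad_norm, 1e-5)
  expect_equal(fp$theta[1], -1)
  expect_false(is.unsorted(fp$theta, strictly = TRUE))
  expect_gt(fp$sigma_u, 0)
})

test_that("fits fail informatively on empty response categories", {
  d <- as.data.frame(panel_small)
  d$y[d$y == 7] <- 6
  p <- ordinal_panel(d, x_levels = 7, y_levels = 7)
  expect_error(fit_store(p, "linear"), "empty response category: 7")
})

test_that("lambda selection prefers heavy shrinkage for linear truth", {
  fp <- fit_store(panel_small, "penalized")
  expect_gte(fp$lambda, 100)
  expect_lt(fp$edf$total, 6)
  # criterion path was explored over the whole default grid
  expect_equal(nrow(fp$lambda_path), length(statetrait:::default_lambda_grid()))
})

test_that("laplace criterion tracks brute-force integration of the ridge prior", {
  # toy: all subjects share trait 2, states in {1,2,3}; coefficients are
  # (alpha, gamma_2_1, gamma_2_3) and the penalty has rank 1
  set.seed(31)
  d <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(subject = sprintf("t%d", i),
               x = c(2, 2, 2, sample(c(1, 3), 2, TRUE)),
               y = sample.int(3, 5, TRUE))
  }))
  panel <- ordinal_panel(d, x_levels = 3, y_levels = 3)
  mf <- statetrait:::st_model_frame(panel, "penalized")
  expect_equal(nrow(mf$layout$terms), 3)
  sel <- statetrait:::select_lambda(mf, grid = c(0.5, 5, 50))
  # brute-force: integrate exp(l(zeta) - lambda/2 zeta'P zeta) over a grid,
  # holding theta and sigma at the lambda-specific estimates
  brute <- vapply(seq_along(sel$grid), function(k) {
    lam <- sel$grid[k]
    eng <- statetrait:::st_fit_engine(mf, lambda = lam)
    gr <- seq(-2.5, 2.5, length.out = 41)
    zg <- as.matrix(expand.grid(a = gr + eng$zeta[1], g1 = gr + eng$zeta[2],
                                g3 = gr + eng$zeta[3]))
    lp <- apply(zg, 1, function(z) {
      as.numeric(marginal_loglik(mf$y, drop(mf$X %*% z), mf$subject,
                                 eng$theta, eng$sigma_u)) -
        0.5 * lam * drop(crossprod(z, mf$P %*% z))
    })
    m <- max(lp)
    step <- gr[2] - gr[1]
    m + log(sum(exp(lp - m))) + 3 * log(step) + 0.5 * log(lam)
  }, numeric(1))
  # criteria agree up to a lambda-free constant
  diffs <- (sel$criterion - brute)
  expect_lt(max(diffs) - min(diffs), 0.1)
})

test_that("linear-mode estimates agree with an independent ordinal mixed-model engine", {
  panel <- simulate_panel(small_config(p = 1), seed = 202)
  fl <- fit_store(panel, "linear")
  tr <- person_medians(panel)
  dat <- as.data.frame(dplyr::left_join(panel, tr, by = "subject"))
  dat$dev <- dat$x - dat$x_med
  dat$subject <- factor(dat$subject)
  g <- mgcv::gam(y ~ x_med + dev + s(subject, bs = "re"),
                 family = mgcv::ocat(R = 7), data = dat, method = "ML")
  # Laplace (mgcv) vs adaptive quadrature: near, not identical
  expect_equal(unname(fl$coef), unname(coef(g)[1:3]), tolerance = 0.02)
  expect_equal(fl$sigma_u, unname(mgcv::gam.vcomp(g)[1]), tolerance = 0.02)
  expect_equal(fl$theta, as.numeric(g$family$getTheta(TRUE)), tolerance = 0.01)
})
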