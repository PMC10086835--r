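theta6 <- c(-1, 1, 3, 5, 7, 9)

test_that("category log-probabilities follow the logistic latent mechanism", {
  # closed form at eta = 0: P(Y = 1) = F(theta_1) = F(-1)
  expect_equal(category_logprob(0, theta6, 1), log(plogis(-1)),
               tolerance = 1e-12)
  # probabilities over the categories sum to one for any eta
  for (eta in c(-8, -0.3, 0, 2.7, 12)) {
    expect_equal(sum(exp(category_logprob(rep(eta, 7), theta6, 1:7))), 1,
                 tolerance = 1e-12)
  }
  # P(Y <= m) = 1/2 when eta sits on the cutpoint
  for (m in 1:6) {
    expect_equal(sum(exp(category_logprob(rep(theta6[m], m), theta6, 1:m))),
                 0.5, tolerance = 1e-12)
  }
  # stability deep in the tails
  expect_true(all(is.finite(category_logprob(c(-60, 60), theta6, c(4, 4)))))
  expect_error(category_logprob(0, c(1, -1), 1), "increasing")
})

test_that("adaptive quadrature matches dense numeric integration", {
  set.seed(7)
  n <- 12
  subj <- sort(rep(sprintf("s%d", 1:5), length.out = n))
  eta <- rnorm(n)
  y <- pmin(pmax(1L + findInterval(eta + rnorm(n), theta6), 1L), 7L)
  for (sig in c(0.4, 1, 2.5)) {
    ll <- marginal_loglik(y, eta, subj, theta6, sig, nodes = 15)
    oracle <- trapezoid_loglik(y, eta, subj, theta6, sig)
    expect_equal(as.numeric(ll), oracle, tolerance = 1e-6)
  }
  # single-subject case at sigma_u = 1
  ll1 <- marginal_loglik(y[1:2], eta[1:2], c("a", "a"), theta6, 1)
  expect_equal(as.numeric(ll1),
               trapezoid_loglik(y[1:2], eta[1:2], c("a", "a"), theta6, 1),
               tolerance = 1e-8)
  # node-doubling stability
  ll15 <- marginal_loglik(y, eta, subj, theta6, 1, nodes = 15)
  ll31 <- marginal_loglik(y, eta, subj, theta6, 1, nodes = 31)
  expect_lt(abs(as.numeric(ll15) - as.numeric(ll31)), 1e-6)
})

test_that("sigma_u = 0 degenerates to the independent ordinal likelihood", {
  set.seed(1)
  eta <- rnorm(9)
  y <- sample.int(7, 9, replace = TRUE)
  subj <- rep(c("a", "b", "c"), each = 3)
  expect_equal(as.numeric(marginal_loglik(y, eta, subj, theta6, 0)),
               sum(category_logprob(eta, theta6, y)), tolerance = 1e-12)
})

test_that("analytic gradient and Hessian agree with finite differences", {
  set.seed(5)
  panel <- random_panel(n_subj = 8, J = 7, M = 4, My = 4)
  mf <- statetrait:::st_model_frame(panel, "unpenalized")
  gh <- statetrait:::gauss_hermite(15)
  p <- ncol(mf$X)
  theta <- c(-1, 0.5, 2)
  zeta <- rnorm(p, 0, 0.3)
  sigma <- 0.9
  ll_of <- function(par) {
    as.numeric(marginal_loglik(mf$y, drop(mf$X %*% par[1:p]), mf$subject,
                               c(-1, par[p + 1], par[p + 2]),
                               exp(par[p + 3])))
  }
  par0 <- c(zeta, theta[2], theta[3], log(sigma))
  res <- statetrait:::ll_kernel(mf$y, drop(mf$X %*% zeta), mf$blocks, theta,
                                sigma, gh, want_grad = TRUE, want_hess = TRUE,
                                X = mf$X)
  g_analytic <- unname(c(drop(crossprod(mf$X, res$grad_eta)),
                         as.numeric(res$grad_theta)[2:3],
                         as.numeric(res$grad_logsigma)))
  g_fd <- vapply(seq_along(par0), function(j) {
    h <- 1e-6 * (1 + abs(par0[j]))
    pp <- par0; pp[j] <- pp[j] + h
    pm <- par0; pm[j] <- pm[j] - h
    (ll_of(pp) - ll_of(pm)) / (2 * h)
  }, numeric(1))
  expect_equal(g_analytic, g_fd, tolerance = 1e-5)

  # zeta-block Hessian against finite differences of the analytic gradient
  H <- statetrait:::hessian_zeta(mf, list(zeta = zeta, theta = theta,
                                          sigma_u = sigma))
  gz <- function(z) {
    r <- statetrait:::ll_kernel(mf$y, drop(mf$X %*% z), mf$blocks, theta,
                                sigma, gh, want_grad = TRUE)
    -drop(crossprod(mf$X, r$grad_eta))
  }
  Hfd <- statetrait:::fd_jacobian(gz, zeta)
  expect_equal(H, (Hfd + t(Hfd)) / 2, tolerance = 1e-5, ignore_attr = TRUE)
})
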