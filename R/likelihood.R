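#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch computation of the n-point rule for the weight function
#' `exp(-t^2)` (physicists' convention), used by the adaptive quadrature.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights`.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

#' Ordinal category log-probability under the logistic latent mechanism
#'
#' Computes `log P(Y = m)` where `P(Y <= m) = F(theta_m - eta)` with `F` the
#' standard logistic CDF, `theta_0 = -Inf` and `theta_My = +Inf`, in a form
#' stable for large `|eta|` (log-difference of log-CDF values).
#'
#' @param eta Latent linear predictor (vectorized).
#' @param theta Increasing cutpoint vector of length `My - 1`.
#' @param m Response category in `1..My` (vectorized, recycled against `eta`).
#' @return Log-probabilities.
#' @export
category_logprob <- function(eta, theta, m) {
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("cutpoints `theta` must be strictly increasing", call. = FALSE)
  }
  My <- length(theta) + 1L
  stopifnot(all(m >= 1), all(m <= My))
  n <- max(length(eta), length(m))
  eta <- rep_len(eta, n)
  m <- rep_len(m, n)
  out <- numeric(n)
  hi <- m < My
  lo <- m > 1
  lFa <- ifelse(hi, stats::plogis(theta[pmin(m, My - 1)] - eta, log.p = TRUE), 0)
  lFb <- ifelse(lo, stats::plogis(theta[pmax(m - 1, 1)] - eta, log.p = TRUE), -Inf)
  # log(exp(lFa) - exp(lFb)) done on the log scale
  d <- lFb - lFa
  l1m <- ifelse(d > -log(2), log(-expm1(d)), log1p(-exp(d)))
  out <- lFa + l1m
  out[!lo] <- stats::plogis(theta[1] - eta[!lo], log.p = TRUE)
  out[!hi] <- stats::plogis(theta[My - 1] - eta[!hi], lower.tail = FALSE,
                            log.p = TRUE)
  out
}

# subject run-length bookkeeping for the C++ kernel; rows must be grouped by
# subject (we sort once per model frame, not per likelihood call)
subject_blocks <- function(subject) {
  subject <- as.integer(factor(subject, levels = unique(subject)))
  ends <- cumsum(rle(subject)$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  list(start = starts - 1L, end = ends - 1L, n = length(starts))
}

# core call: marginal loglik (and gradient pieces) given per-observation eta
ll_kernel <- function(y, eta, blocks, theta, sigma, gh, u_init = NULL,
                      want_grad = FALSE, want_hess = FALSE, X = NULL) {
  if (is.null(u_init)) u_init <- numeric(blocks$n)
  agq_core(as.integer(y), as.numeric(eta), blocks$start, blocks$end,
           length(theta) + 1L, as.numeric(theta), sigma,
           gh$nodes, gh$weights, u_init, want_grad, want_hess, X)
}

#' Marginal log-likelihood of the cumulative logistic mixed model
#'
#' Integrates the random intercept out of the conditional ordinal likelihood
#' by adaptive Gauss-Hermite quadrature centred at each subject's posterior
#' mode (with the curvature there setting the scale). At `sigma_u = 0` the
#' integral degenerates and the independent ordinal log-likelihood is
#' returned.
#'
#' @param y Integer responses in `1..(length(theta)+1)`.
#' @param eta Fixed-effect part of the latent predictor, one value per row.
#' @param subject Subject identifier, one per row (rows grouped by subject).
#' @param theta Increasing cutpoints.
#' @param sigma_u Random-intercept standard deviation (>= 0).
#' @param nodes Number of quadrature nodes (default 15).
#' @return The marginal log-likelihood, with per-subject contributions in
#'   attribute `by_subject` and posterior modes in attribute `u_hat`.
#' @export
marginal_loglik <- function(y, eta, subject, theta, sigma_u, nodes = 15) {
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("cutpoints `theta` must be strictly increasing", call. = FALSE)
  }
  stopifnot(sigma_u >= 0, length(y) == length(eta),
            length(y) == length(subject))
  if (sigma_u == 0) {
    lp <- category_logprob(eta, theta, y)
    ll <- sum(lp)
    sub <- factor(subject, levels = unique(subject))
    return(structure(ll,
                     by_subject = as.numeric(tapply(lp, sub, sum)),
                     u_hat = numeric(nlevels(sub))))
  }
  blocks <- subject_blocks(subject)
  res <- ll_kernel(y, eta, blocks, theta, sigma_u, gauss_hermite(nodes))
  if (!is.finite(res$loglik)) {
    bad <- which(!is.finite(res$loglik_i))
    stop("non-finite marginal likelihood for subject block(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(res$loglik, by_subject = as.numeric(res$loglik_i),
            u_hat = as.numeric(res$u_hat))
}
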