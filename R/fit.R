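#' Optimizer settings for state-trait fits
#'
#' @param rel_tol Relative objective-change tolerance of the outer
#'   quasi-Newton optimization.
#' @param grad_tol Max-norm gradient tolerance declaring convergence; fits
#'   whose gradient exceeds this after polishing are flagged, not rejected.
#' @param iter_max Maximum outer iterations.
#' @param polish_max Maximum Newton polishing steps (finite-difference
#'   Hessian) applied when the quasi-Newton stage leaves a large gradient.
#' @return A list of control values.
#' @export
st_control <- function(rel_tol = 1e-8, grad_tol = 1e-5, iter_max = 500,
                       polish_max = 12) {
  list(rel_tol = rel_tol, grad_tol = grad_tol, iter_max = iter_max,
       polish_max = polish_max)
}

default_lambda_grid <- function() 10^seq(-2, 6, length.out = 17)

theta_from_delta <- function(delta) {
  c(-1, -1 + cumsum(exp(delta)))
}

theta_init <- function(y, My) {
  miss <- setdiff(seq_len(My), unique(y))
  if (length(miss)) {
    stop("empty response categor", if (length(miss) > 1) "ies: " else "y: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- cumsum(tabulate(y, My))[seq_len(My - 1)] / length(y)
  th <- stats::qlogis(p)
  th <- th - th[1] - 1
  log(diff(th))
}

# ---- model frame -----------------------------------------------------------

# Assembles the response, design matrix, penalty and bookkeeping for one of
# the four model modes. Rows are ordered by subject (and day/obs for lagged
# models); `row_order` maps back to the panel's row order.
st_model_frame <- function(panel, mode, lag = FALSE, min_count = 0L) {
  traits <- person_medians(panel)
  keys <- key_set(panel, traits, min_count = min_count)
  gm <- attr(traits, "global_median")
  My <- attr(panel, "M_y")

  dat <- dplyr::left_join(panel, traits, by = "subject")
  dat$.row <- seq_len(nrow(dat))
  has_day <- "day" %in% names(dat)
  if (has_day) {
    dat <- dplyr::arrange(dat, .data$subject, .data$day, .data$obs)
  } else {
    dat <- dplyr::arrange(dat, .data$subject, .data$obs)
  }

  if (lag) {
    grp <- if (has_day) list(dat$subject, dat$day) else list(dat$subject)
    gid <- do.call(paste, grp)
    first <- !duplicated(gid)
    ylag <- c(NA_integer_, dat$y[-nrow(dat)])
    ylag[first] <- NA_integer_
    keep <- !is.na(ylag)
    lost <- setdiff(unique(dat$subject), unique(dat$subject[keep]))
    if (length(lost)) {
      warning("subject(s) with no retained rows after lagging dropped: ",
              paste(lost, collapse = ", "), call. = FALSE)
    }
    dat <- dat[keep, , drop = FALSE]
    dat$y_lag <- as.numeric(ylag[keep])
  }

  layout <- NULL
  P <- NULL
  cellidx <- NULL
  if (mode %in% c("penalized", "unpenalized")) {
    layout <- coef_layout(keys, gm)
    pen <- penalty_matrix(keys, layout)
    P <- pen$P
    cells <- layout$cells
    raw <- match(paste(dat$x_med, dat$x), paste(keys$r, keys$s))
    cellidx <- match(paste(keys$rep_r[raw], keys$rep_s[raw]),
                     paste(cells$r, cells$s))
    X <- layout$A[cellidx, , drop = FALSE]
    types <- layout$terms$type
    cnames <- layout$terms$term
  } else if (mode == "linear") {
    X <- cbind(beta0 = 1, beta1 = dat$x_med, beta2 = dat$x - dat$x_med)
    types <- c("beta0", "beta1", "beta2")
    cnames <- colnames(X)
  } else if (mode == "trait_only") {
    tr <- sort(unique(dat$x_med))
    ref <- tr[order(abs(tr - gm), tr)][1]
    tau_r <- setdiff(tr, ref)
    A <- cbind(alpha = 1,
               matrix(0, length(tr), length(tau_r),
                      dimnames = list(NULL, paste0("tau_", tau_r))))
    for (k in seq_along(tau_r)) A[tr == tau_r[k], k + 1] <- 1
    # second differences of the diagonal profile f(r) = alpha + tau_r over
    # consecutive attained trait triples: shrinks tau towards linearity in r
    rows <- list()
    for (r in tr) {
      if (all(c(r - 1, r + 1) %in% tr)) {
        v <- numeric(length(tr))
        v[match(c(r - 1, r, r + 1), tr)] <- c(1, -2, 1)
        rows[[length(rows) + 1L]] <- v
      }
    }
    Dt <- if (length(rows)) do.call(rbind, rows) else
      matrix(0, 0, length(tr))
    P <- crossprod(Dt %*% A)
    P <- (P + t(P)) / 2
    tidx <- match(dat$x_med, tr)
    X <- A[tidx, , drop = FALSE]
    types <- c("alpha", rep("tau", length(tau_r)))
    cnames <- colnames(A)
    layout <- list(trait_levels = tr, A = A,
                   terms = tibble::tibble(term = cnames, type = types,
                                          r = c(NA_integer_, tau_r),
                                          s = c(NA_integer_, tau_r)),
                   global_median = gm)
  } else {
    stop("unknown mode '", mode, "'", call. = FALSE)
  }
  if (lag) {
    X <- cbind(X, beta_lag = dat$y_lag)
    types <- c(types, "lag")
    cnames <- c(cnames, "beta_lag")
    if (!is.null(P)) {
      P <- rbind(cbind(P, 0), 0)
      dimnames(P) <- list(cnames, cnames)
    }
  }
  colnames(X) <- cnames
  list(y = as.integer(dat$y), X = X, P = P, types = types,
       subject = dat$subject, blocks = subject_blocks(dat$subject),
       row_order = dat$.row, cellidx = cellidx, layout = layout,
       keys = keys, traits = traits, global_median = gm, My = My,
       mode = mode, lag = lag,
       x_med = dat$x_med, x = dat$x)
}

# ---- penalized maximum likelihood ------------------------------------------

# Maximizes l(zeta, theta, sigma_u) - (lambda/2) zeta' P zeta over the fixed
# effects, the free cutpoints theta_2..theta_{My-1} (positive-increment
# parametrization from theta_1 = -1) and log sigma_u, by PORT quasi-Newton
# with analytic gradients, then Newton-polishes if the gradient is not small.
st_fit_engine <- function(mf, lambda = 0, nodes = 15, start = NULL,
                          control = st_control()) {
  y <- mf$y
  X <- mf$X
  p <- ncol(X)
  My <- mf$My
  nd <- My - 2L
  P <- mf$P
  gh <- gauss_hermite(nodes)
  zi <- seq_len(p)
  di <- p + seq_len(nd)
  si <- p + nd + 1L
  npar <- p + nd + 1L
  use_pen <- lambda > 0 && !is.null(P)

  env <- new.env(parent = emptyenv())
  env$u <- numeric(mf$blocks$n)

  eval_fit <- function(par, want_grad) {
    zeta <- par[zi]
    theta <- theta_from_delta(par[di])
    sigma <- exp(par[si])
    eta <- drop(X %*% zeta)
    res <- ll_kernel(y, eta, mf$blocks, theta, sigma, gh, env$u, want_grad)
    env$u <- res$u_hat
    res$zeta <- zeta
    res$theta <- theta
    res$sigma <- sigma
    res
  }
  objective <- function(par) {
    res <- eval_fit(par, FALSE)
    v <- -res$loglik
    if (use_pen) v <- v + 0.5 * lambda * drop(crossprod(res$zeta, P %*% res$zeta))
    if (!is.finite(v)) v <- 1e12
    v
  }
  gradient <- function(par) {
    res <- eval_fit(par, TRUE)
    gz <- -drop(crossprod(X, res$grad_eta))
    if (use_pen) gz <- gz + lambda * drop(P %*% res$zeta)
    gth <- res$grad_theta # d loglik / d theta_m, m = 1..My-1
    gd <- if (nd > 0) {
      -exp(par[di]) * rev(cumsum(rev(gth[-1])))
    } else numeric(0)
    c(gz, gd, -res$grad_logsigma)
  }

  # Hessian of the penalized objective at `par`, from the kernel's analytic
  # second derivatives over (zeta, theta, log sigma), chained through the
  # cutpoint-increment parametrization; also returns the objective gradient.
  hess_obj <- function(par) {
    zeta <- par[zi]
    delta <- par[di]
    theta <- theta_from_delta(delta)
    sigma <- exp(par[si])
    res <- ll_kernel(y, drop(X %*% zeta), mf$blocks, theta, sigma, gh, env$u,
                     want_grad = TRUE, want_hess = TRUE, X = X)
    env$u <- res$u_hat
    nth <- My - 1L
    a <- as.numeric(res$hess_a)
    chi <- as.numeric(res$c_hi)
    clo <- as.numeric(res$c_lo)
    taa <- as.numeric(res$t_aa)
    tbb <- as.numeric(res$t_bb)
    tab <- as.numeric(res$t_ab)
    Hzz <- crossprod(X, X * a)
    Hzt <- matrix(0, p, nth)
    for (m in seq_len(nth)) {
      w <- chi * (y == m) + clo * (y == m + 1)
      Hzt[, m] <- crossprod(X, w)
    }
    Htt <- matrix(0, nth, nth)
    for (m in seq_len(nth)) {
      Htt[m, m] <- sum(taa[y == m]) + sum(tbb[y == m + 1])
    }
    for (m in 2:nth) {
      off <- sum(tab[y == m])
      Htt[m, m - 1] <- Htt[m, m - 1] + off
      Htt[m - 1, m] <- Htt[m - 1, m] + off
    }
    Hll <- matrix(0, p + nth + 1, p + nth + 1)
    Hll[zi, zi] <- Hzz
    Hll[zi, p + seq_len(nth)] <- Hzt
    Hll[p + seq_len(nth), zi] <- t(Hzt)
    Hll[p + seq_len(nth), p + seq_len(nth)] <- Htt
    Hll[p + nth + 1, p + nth + 1] <- res$sig2nd
    Hll <- Hll + res$hess_cov
    # chain theta -> delta: theta_l = -1 + sum_{m<=l} e^{delta_m} (l >= 2)
    gth <- as.numeric(res$grad_theta)
    J <- matrix(0, nth, nd)
    for (m in seq_len(nd)) J[(m + 1):nth, m] <- exp(par[di][m])
    Hp <- matrix(0, npar, npar)
    Hp[zi, zi] <- Hll[zi, zi]
    Hp[zi, di] <- Hll[zi, p + seq_len(nth)] %*% J
    Hp[di, zi] <- t(Hp[zi, di])
    Hp[di, di] <- t(J) %*% Hll[p + seq_len(nth), p + seq_len(nth)] %*% J +
      diag(exp(par[di]) * rev(cumsum(rev(gth[-1]))), nd)
    Hp[zi, si] <- Hll[zi, p + nth + 1]
    Hp[si, zi] <- Hp[zi, si]
    Hp[di, si] <- t(J) %*% Hll[p + seq_len(nth), p + nth + 1]
    Hp[si, di] <- Hp[di, si]
    Hp[si, si] <- Hll[p + nth + 1, p + nth + 1]
    Hobj <- -Hp
    if (use_pen) Hobj[zi, zi] <- Hobj[zi, zi] + lambda * P
    gz <- -drop(crossprod(X, res$grad_eta))
    if (use_pen) gz <- gz + lambda * drop(P %*% zeta)
    gobj <- c(gz, -exp(par[di]) * rev(cumsum(rev(gth[-1]))),
              -res$grad_logsigma)
    list(H = (Hobj + t(Hobj)) / 2, g = gobj, loglik = res$loglik,
         Hzeta_ll = Hll[zi, zi], u_hat = as.numeric(res$u_hat))
  }

  if (is.null(start)) {
    start <- c(rep(0, p), theta_init(y, My), 0)
  }
  lower <- c(rep(-30, p), rep(-20, nd), -8)
  upper <- c(rep(30, p), rep(20, nd), 8)
  gnorm_of <- function(par, g) {
    free <- (par > lower + 1e-9 & par < upper - 1e-9) |
      (g < 0 & par < upper - 1e-9) | (g > 0 & par > lower + 1e-9)
    max(abs(g[free]))
  }
  # safeguarded Newton: Levenberg ridge escalation + backtracking line search
  newton <- function(par, max_iter) {
    last <- NULL
    for (it in seq_len(max_iter)) {
      hg <- hess_obj(par)
      last <- hg
      if (gnorm_of(par, hg$g) < control$grad_tol) {
        return(list(par = par, ok = TRUE, hg = hg))
      }
      H <- hg$H
      ridge <- 0
      base <- max(abs(diag(H)), 1)
      repeat {
        ch <- tryCatch(chol(H + diag(ridge, npar)), error = function(e) NULL)
        if (!is.null(ch)) break
        ridge <- if (ridge == 0) 1e-6 * base else ridge * 10
        if (ridge > 1e8 * base) return(list(par = par, ok = FALSE, hg = hg))
      }
      step <- -backsolve(ch, forwardsolve(t(ch), hg$g))
      f0 <- objective(par)
      sc <- 1
      repeat {
        cand <- pmin(pmax(par + sc * step, lower), upper)
        if (objective(cand) <= f0 + 1e-12 * abs(f0)) break
        sc <- sc / 2
        if (sc < 1e-10) return(list(par = par, ok = FALSE, hg = hg))
      }
      par <- pmin(pmax(par + sc * step, lower), upper)
    }
    hg <- hess_obj(par)
    list(par = par, ok = gnorm_of(par, hg$g) < control$grad_tol, hg = hg)
  }

  nr <- NULL
  if (!is.null(start)) {
    nr <- newton(start, 40)
  }
  if (is.null(nr) || !nr$ok) {
    from <- if (is.null(nr)) start else nr$par
    opt <- stats::nlminb(from, objective, gradient,
                         lower = lower, upper = upper,
                         control = list(iter.max = control$iter_max,
                                        eval.max = 4 * control$iter_max,
                                        rel.tol = control$rel_tol))
    nr <- newton(opt$par, control$polish_max)
  }
  par <- nr$par
  gnorm <- gnorm_of(par, nr$hg$g)
  final <- eval_fit(par, FALSE)
  pen_q <- if (!is.null(P)) {
    drop(crossprod(final$zeta, P %*% final$zeta))
  } else 0
  list(par = par, zeta = stats::setNames(final$zeta, colnames(X)),
       theta = final$theta, sigma_u = final$sigma,
       loglik = final$loglik, u_hat = as.numeric(final$u_hat),
       penalty_quadform = pen_q,
       objective = -final$loglik + 0.5 * lambda * pen_q,
       grad_norm = gnorm,
       converged = gnorm < control$grad_tol,
       H_zeta = -nr$hg$Hzeta_ll,
       gradient_fn = gradient, zi = zi)
}

# central finite-difference Jacobian of a gradient function
fd_jacobian <- function(gr, par, h = 1e-5) {
  n <- length(par)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * (1 + abs(par[j]))
    pp <- par; pp[j] <- pp[j] + hj
    pm <- par; pm[j] <- pm[j] - hj
    J[, j] <- (gr(pp) - gr(pm)) / (2 * hj)
  }
  J
}

# negative Hessian of the *unpenalized* marginal log-likelihood with respect
# to the fixed effects, at the fitted parameters (analytic, via the
# posterior-moment identities of the quadrature kernel)
hessian_zeta <- function(mf, eng, nodes = 15) {
  X <- mf$X
  p <- ncol(X)
  res <- ll_kernel(mf$y, drop(X %*% as.numeric(eng$zeta)), mf$blocks,
                   eng$theta, eng$sigma_u, gauss_hermite(nodes),
                   want_grad = FALSE, want_hess = TRUE, X = X)
  H <- -(crossprod(X, X * as.numeric(res$hess_a)) +
           res$hess_cov[seq_len(p), seq_len(p)])
  (H + t(H)) / 2
}

# ---- effective degrees of freedom and AIC ----------------------------------

# EDF = trace[(H + lambda P)^{-1} H], partitioned across terms by the
# corresponding diagonal entries; exactly dim(zeta) at lambda = 0
edf_calc <- function(H, P, lambda, types) {
  p <- length(types)
  if (lambda == 0 || is.null(P)) {
    d <- rep(1, p)
    aic_df <- p
  } else {
    M <- tryCatch(solve(H + lambda * P, H), error = function(e) {
      stop("singular (H + lambda P); increase lambda or merge rare cells",
           call. = FALSE)
    })
    d <- diag(M)
    # degrees of freedom used in AIC: trace(2F - F^2), the bias-corrected
    # count for penalized fits (the convention of likelihood-based smoothing
    # engines); coincides with trace(F) at the lambda limits
    aic_df <- sum(2 * d - rowSums(M * t(M)))
  }
  by_term <- vapply(split(d, types), sum, numeric(1))
  list(total = sum(d), by_term = by_term[unique(types)], by_coef = d,
       aic_df = aic_df)
}

aic_calc <- function(loglik, edf_total, My) {
  -2 * loglik + 2 * (edf_total + (My - 2) + 1)
}

# ---- lambda selection ------------------------------------------------------

# Laplace-approximate marginal criterion: the penalized coefficients are
# viewed as random effects with precision lambda P; integrating them out gives
#   l_pen(zeta_hat) + (rank(P)/2) log lambda - (1/2) log det(H + lambda P)
# up to constants, maximized over a log-spaced grid with warm starts.
select_lambda <- function(mf, grid = default_lambda_grid(), nodes = 15,
                          control = st_control()) {
  stopifnot(length(grid) > 0, all(grid > 0))
  grid <- sort(grid)
  P <- mf$P
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  rankP <- sum(ev > max(ev) * 1e-10)
  crit <- rep(-Inf, length(grid))
  fits <- vector("list", length(grid))
  Hs <- vector("list", length(grid))
  start <- NULL
  for (k in seq_along(grid)) {
    eng <- st_fit_engine(mf, lambda = grid[k], nodes = nodes,
                         start = start, control = control)
    start <- eng$par
    fits[[k]] <- eng
    if (!eng$converged) next
    H <- eng$H_zeta
    Hs[[k]] <- H
    ld <- determinant(H + grid[k] * P, logarithm = TRUE)
    if (ld$sign <= 0) next
    crit[k] <- (eng$loglik - 0.5 * grid[k] * eng$penalty_quadform) -
      0.5 * as.numeric(ld$modulus) + 0.5 * rankP * log(grid[k])
  }
  if (all(!is.finite(crit))) {
    stop("no lambda in the grid produced a converged fit", call. = FALSE)
  }
  best <- max(which(crit == max(crit, na.rm = TRUE))) # ties -> more shrinkage
  list(lambda = grid[best], engine = fits[[best]], H = Hs[[best]],
       grid = grid, criterion = crit)
}

# ---- user-facing fit -------------------------------------------------------

#' Fit an ordinal state-trait regression
#'
#' Maximum (penalized) marginal likelihood estimation of the cumulative
#' logistic random-intercept model in which the latent response mean is a
#' surface `f(trait, state)` over the person-median / current-level cells of
#' an ordinal predictor. Four modes are available:
#'
#' * `"penalized"` (default): all cell effects, shrunk towards a linear
#'   surface by the second-difference penalty, with `lambda` selected by a
#'   Laplace-approximate marginal criterion unless given;
#' * `"unpenalized"`: all cell effects, `lambda = 0`;
#' * `"linear"`: the classical 3-coefficient between/within disaggregation
#'   model `beta0 + beta1 * median + beta2 * (current - median)`;
#' * `"trait_only"`: the state term deleted, only `alpha + tau_r` (penalized
#'   towards a linear trait profile).
#'
#' @param panel An [ordinal_panel()].
#' @param mode Model mode, see above.
#' @param lambda `"auto"` (grid selection; forced to 0 for `"unpenalized"`
#'   and ignored for `"linear"`) or a fixed value `>= 0`.
#' @param lag Add the previous response `y_{i,j-1}` as a numeric predictor;
#'   the first observation of each subject (or subject-day when a `day` column
#'   is present) is dropped.
#' @param min_count Merge trait-state cells rarer than this (see [key_set()]).
#' @param nodes Adaptive Gauss-Hermite nodes (default 15).
#' @param lambda_grid Grid searched when `lambda = "auto"`.
#' @param control See [st_control()].
#' @return An object of class `store_fit`; see [tidy.store_fit()],
#'   [glance.store_fit()], [latent_r2()], [fitted_f()].
#' @export
fit_store <- function(panel,
                      mode = c("penalized", "unpenalized", "linear", "trait_only"),
                      lambda = "auto", lag = FALSE, min_count = 0L,
                      nodes = 15, lambda_grid = default_lambda_grid(),
                      control = st_control()) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ordinal_panel"))
  mf <- st_model_frame(panel, mode, lag = lag, min_count = min_count)
  H <- NULL
  sel <- NULL
  if (mode == "unpenalized" || mode == "linear") lambda <- 0
  if (identical(lambda, "auto")) {
    sel <- select_lambda(mf, grid = lambda_grid, nodes = nodes,
                         control = control)
    lambda <- sel$lambda
    eng <- sel$engine
    H <- sel$H
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    eng <- st_fit_engine(mf, lambda = lambda, nodes = nodes, control = control)
  }
  p <- ncol(mf$X)
  if (mode == "linear" || lambda == 0) {
    edf <- edf_calc(NULL, NULL, 0, mf$types)
  } else {
    if (is.null(H)) H <- eng$H_zeta
    edf <- edf_calc(H, mf$P, lambda, mf$types)
  }
  aic <- aic_calc(eng$loglik, edf$aic_df, mf$My)
  eta_fix <- drop(mf$X %*% eng$zeta)
  fit <- structure(list(
    mode = mode, lag = mf$lag, coef = eng$zeta, theta = eng$theta,
    sigma_u = eng$sigma_u, lambda = lambda, loglik = eng$loglik,
    edf = edf, aic = aic, scaled_aic = aic / length(mf$y),
    converged = eng$converged, grad_norm = eng$grad_norm,
    n_obs = length(mf$y), n_subjects = mf$blocks$n,
    u_hat = stats::setNames(eng$u_hat, unique(as.character(mf$subject))),
    layout = mf$layout, keys = mf$keys, traits = mf$traits,
    global_median = mf$global_median, My = mf$My, nodes = nodes,
    types = mf$types, eta_fix = eta_fix,
    obs_subject = as.character(mf$subject), cellidx = mf$cellidx,
    x_med = mf$x_med, x = mf$x, H = H, P = mf$P,
    lambda_path = if (!is.null(sel)) {
      tibble::tibble(lambda = sel$grid, criterion = sel$criterion)
    } else NULL
  ), class = "store_fit")
  fit
}

#' Fixed-effect effective degrees of freedom of a fit
#' @param fit A `store_fit`.
#' @return List with `total`, `by_term` and `by_coef` components.
#' @export
edf_fixed <- function(fit) {
  stopifnot(inherits(fit, "store_fit"))
  fit$edf
}

#' Latent surface implied by a fit
#'
#' Evaluates the fitted `f(r, s)` on the model's cells: the cell effects for
#' state-trait modes, `beta0 + beta1 r + beta2 (s - r)` for the linear mode,
#' and the diagonal trait profile for trait-only fits.
#'
#' @param fit A `store_fit`.
#' @param cells Optional tibble of `(r, s)` cells to evaluate a linear-mode
#'   fit on (defaults to the fit's key-set cells).
#' @return Tibble with columns `r`, `s`, `f`.
#' @export
fitted_f <- function(fit, cells = NULL) {
  stopifnot(inherits(fit, "store_fit"))
  cf <- fit$coef
  if (fit$mode == "linear") {
    if (is.null(cells)) cells <- merged_cells(fit$keys)
    return(tibble::tibble(r = cells$r, s = cells$s,
                          f = cf[["beta0"]] + cf[["beta1"]] * cells$r +
                            cf[["beta2"]] * (cells$s - cells$r)))
  }
  k <- length(fit$layout$terms$term)
  f <- drop(fit$layout$A %*% cf[seq_len(k)])
  if (fit$mode == "trait_only") {
    tr <- fit$layout$trait_levels
    tibble::tibble(r = tr, s = tr, f = f)
  } else {
    tibble::tibble(r = fit$layout$cells$r, s = fit$layout$cells$s, f = f)
  }
}
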