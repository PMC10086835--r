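#' Configuration of the synthetic experience-sampling generator
#'
#' Describes the generating process of the method-comparison study: the
#' latent response of observation `j` on subject `i` is
#' `g(r_i, x_ij) + u_i + e_ij`, with
#' `g(r, s) = alpha + b_trait * sgn(r - gm) |r - gm|^p + b_state * sgn(s - r) |s - r|^p`,
#' `u_i ~ N(0, sigma_u^2)`, standard logistic `e_ij`, and the ordinal
#' response cut at `theta`. `p = 1` makes the surface linear (the classical
#' disaggregation model holds); `p = 1/3` makes it nonlinear. Subject median
#' levels are assigned with fixed frequencies; their pooled median `gm` is
#' the global median of the design.
#'
#' @param p Exponent of the signed-power transform (1 or 1/3 in the study).
#' @param coefs Named vector `(alpha, trait, state)`.
#' @param median_freqs Subjects per median level `1..M_x`.
#' @param J Observations per subject.
#' @param theta Latent cutpoints (first element -1).
#' @param sigma_u Random-intercept SD.
#' @param M_y Response levels.
#' @param mix_unif Probability mass of the uniform component of the state
#'   sampler (keeps all trait-state cells reachable).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(p = 1,
                       coefs = c(alpha = 0.17, trait = -0.15, state = -0.72),
                       median_freqs = c(16, 46, 85, 106, 85, 46, 16),
                       J = 15, theta = c(-1, 1, 3, 5, 7, 9), sigma_u = 1,
                       M_y = 7, mix_unif = 0.1) {
  stopifnot(p > 0, length(coefs) == 3, all(median_freqs >= 0),
            J >= 1, !is.unsorted(theta, strictly = TRUE),
            length(theta) == M_y - 1, sigma_u >= 0,
            mix_unif >= 0, mix_unif < 1)
  names(coefs) <- c("alpha", "trait", "state")
  structure(list(p = p, coefs = coefs, median_freqs = median_freqs,
                 M_x = length(median_freqs), J = J, theta = theta,
                 sigma_u = sigma_u, M_y = M_y, mix_unif = mix_unif,
                 global_median = lower_median(rep(seq_along(median_freqs),
                                                  median_freqs))),
            class = "sim_config")
}

signed_power <- function(d, p) sign(d) * abs(d)^p

#' True latent surface of a generator configuration
#' @param config A [sim_config()].
#' @param r,s Trait and state levels (vectorized).
#' @return `g(r, s)` as defined in [sim_config()].
#' @export
true_f <- function(config, r, s) {
  gm <- config$global_median
  config$coefs[["alpha"]] +
    config$coefs[["trait"]] * signed_power(r - gm, config$p) +
    config$coefs[["state"]] * signed_power(s - r, config$p)
}

# true coefficients in the (alpha, tau, gamma) parametrization:
# tau_r = g(r,r) - g(gm,gm), gamma_{r,s} = g(r,s) - g(r,r)
true_zeta_table <- function(config) {
  M <- config$M_x
  gm <- config$global_median
  grid <- expand.grid(r = seq_len(M), s = seq_len(M))
  tau <- true_f(config, seq_len(M), seq_len(M)) - true_f(config, gm, gm)
  gam <- true_f(config, grid$r, grid$s) - true_f(config, grid$r, grid$r)
  out <- tibble::tibble(
    term = c("alpha", paste0("tau_", setdiff(seq_len(M), gm)),
             paste0("gamma_", grid$r, "_", grid$s)[grid$r != grid$s]),
    true = c(true_f(config, gm, gm), tau[setdiff(seq_len(M), gm)],
             gam[grid$r != grid$s]))
  out
}

#' Assign subject median levels
#'
#' Deterministic composition with the configured frequencies, in an order
#' shuffled by the current RNG state.
#'
#' @param config A [sim_config()].
#' @return Integer vector of median levels, one per subject.
#' @export
gen_medians <- function(config) {
  m <- rep(seq_len(config$M_x), config$median_freqs)
  sample(m)
}

#' Draw one subject's predictor series with an exact target median
#'
#' Proposal: a shifted binomial centred near the target level, mixed with a
#' small uniform component so every level remains reachable; the batch is
#' redrawn (up to 200 times) until its lower median equals the target, with a
#' deterministic repair (replacing middle order statistics by the target) as
#' a guaranteed fallback.
#'
#' @param median Target median level.
#' @param J Series length.
#' @param config A [sim_config()].
#' @return Integer vector of length `J` whose lower median equals `median`.
#' @export
gen_states <- function(median, J, config) {
  M <- config$M_x
  q <- min(max((median - 1) / (M - 1), 0.08), 0.92)
  draw <- function() {
    x <- 1L + stats::rbinom(J, M - 1L, q)
    unif <- stats::runif(J) < config$mix_unif
    x[unif] <- sample.int(M, sum(unif), replace = TRUE)
    x
  }
  for (i in seq_len(200)) {
    x <- draw()
    if (lower_median(x) == median) {
      attr(x, "attempts") <- i
      return(x)
    }
  }
  # deterministic repair: force middle order statistics to the target
  o <- order(x)
  mid <- floor((J + 1) / 2)
  k <- 0
  while (lower_median(x) != median && k < J) {
    x[o[mid + ifelse(k %% 2 == 0, k %/% 2, -(k %/% 2 + 1))]] <- median
    k <- k + 1
  }
  attr(x, "attempts") <- 200L
  x
}

#' Draw ordinal responses from the latent model
#'
#' Given one subject's predictor series and median level, draws the latent
#' response `g(median, x) + u + e` with standard logistic errors `e` and
#' thresholds it at the configured cutpoints.
#'
#' @param x Predictor series.
#' @param median The subject's median level.
#' @param config A [sim_config()].
#' @param u Subject random intercept (drawn from `N(0, sigma_u^2)` when
#'   omitted).
#' @return Integer responses in `1..M_y`.
#' @export
gen_response <- function(x, median, config,
                         u = stats::rnorm(1, 0, config$sigma_u)) {
  eta <- true_f(config, median, x)
  ell <- eta + u + stats::rlogis(length(x))
  1L + findInterval(ell, config$theta)
}

#' Simulate an ordinal state-trait panel
#'
#' Generates a full panel under the configured latent model: median
#' assignment, state series with exact medians, normal random intercepts,
#' logistic latent errors, and cutpoint thresholding of the latent response.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (set locally).
#' @return An [ordinal_panel()] with the true random intercepts in attribute
#'   `u_true` and the configuration in attribute `config`.
#' @export
simulate_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  med <- gen_medians(config)
  I <- length(med)
  u <- stats::rnorm(I, 0, config$sigma_u)
  rows <- vector("list", I)
  for (i in seq_len(I)) {
    x <- as.integer(gen_states(med[i], config$J, config))
    y <- gen_response(x, med[i], config, u = u[i])
    rows[[i]] <- tibble::tibble(subject = sprintf("S%03d", i),
                                obs = seq_len(config$J), x = x, y = y)
  }
  dat <- dplyr::bind_rows(rows)
  panel <- ordinal_panel(dat, x_levels = config$M_x, y_levels = config$M_y)
  attr(panel, "u_true") <- stats::setNames(u, sprintf("S%03d", seq_len(I)))
  attr(panel, "config") <- config
  panel
}

# seed for replicate k derived from a master seed (kept below 2^31)
replicate_seed <- function(seed, k) {
  (as.numeric(seed) + 9973 * as.numeric(k)) %% 2147483647
}

#' Run the three-method comparison study
#'
#' For each replicate, simulates a panel from `config` and fits the linear,
#' unpenalized and penalized models to the same data, collecting AIC, EDF and
#' coefficient estimates against the generating truth. Fully reproducible
#' from `seed`.
#'
#' @param config A [sim_config()].
#' @param reps Number of replicates.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param methods Subset of `c("linear", "unpenalized", "penalized")`.
#' @param nodes,lambda_grid,control Passed to [fit_store()].
#' @return An object of class `store_study`: list with `fits` (tibble: one
#'   row per replicate x method with loglik, edf, aic, lambda, converged) and
#'   `params` (tibble: one row per replicate x method x coefficient with
#'   estimate and truth). See [study_wins()] and [study_mse()].
#' @export
run_study <- function(config, reps = 100, seed = 1,
                      methods = c("linear", "unpenalized", "penalized"),
                      nodes = 15, lambda_grid = default_lambda_grid(),
                      control = st_control()) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- true_zeta_table(config)
  fit_rows <- list()
  par_rows <- list()
  n_failed <- 0L
  for (k in seq_len(reps)) {
    panel <- simulate_panel(config, seed = replicate_seed(seed, k))
    for (m in methods) {
      fit <- tryCatch(
        fit_store(panel, mode = m, nodes = nodes,
                  lambda_grid = lambda_grid, control = control),
        error = function(e) NULL)
      ok <- !is.null(fit) && fit$converged
      if (!ok) n_failed <- n_failed + 1L
      fit_rows[[length(fit_rows) + 1L]] <- tibble::tibble(
        rep = k, method = m,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        edf = if (is.null(fit)) NA_real_ else fit$edf$total,
        aic = if (is.null(fit)) NA_real_ else fit$aic,
        lambda = if (is.null(fit)) NA_real_ else fit$lambda,
        converged = ok)
      if (ok && m %in% c("unpenalized", "penalized")) {
        par_rows[[length(par_rows) + 1L]] <- tibble::tibble(
          rep = k, method = m, term = names(fit$coef),
          estimate = as.numeric(fit$coef))
      }
    }
  }
  params <- if (length(par_rows)) {
    dplyr::inner_join(dplyr::bind_rows(par_rows), truth, by = "term")
  } else tibble::tibble()
  structure(list(fits = dplyr::bind_rows(fit_rows), params = params,
                 truth = truth, config = config, reps = reps, seed = seed,
                 n_failed = n_failed),
            class = "store_study")
}

#' Pairwise AIC comparisons across replicates
#'
#' @param study A [run_study()] result.
#' @return Tibble with, per replicate (only replicates where all fits
#'   converged), the AIC-best and AIC-worst method, plus attribute `pairs`
#'   giving the count of replicates where each method's AIC beats each
#'   other's.
#' @export
study_wins <- function(study) {
  stopifnot(inherits(study, "store_study"))
  fits <- dplyr::filter(study$fits, .data$converged)
  wide <- tidyr::pivot_wider(fits[, c("rep", "method", "aic")],
                             names_from = "method", values_from = "aic")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  meth <- setdiff(names(wide), "rep")
  aic <- as.matrix(wide[, meth])
  out <- tibble::tibble(rep = wide$rep,
                        best = meth[apply(aic, 1, which.min)],
                        worst = meth[apply(aic, 1, which.max)])
  pairs <- list()
  for (a in meth) for (b in setdiff(meth, a)) {
    pairs[[paste(a, "<", b)]] <- sum(aic[, a] < aic[, b])
  }
  attr(out, "pairs") <- unlist(pairs)
  attr(out, "n") <- nrow(wide)
  out
}

#' Per-coefficient bias and MSE of the penalized and unpenalized estimates
#'
#' @param study A [run_study()] result.
#' @return Tibble with one row per coefficient and method: `n` (replicates in
#'   which the coefficient was estimated), `bias`, `mse`, and (wide across
#'   methods) the percentage MSE difference of the penalized relative to the
#'   unpenalized estimates, `pct_mse_diff = 100 (mse_pen - mse_unpen) /
#'   mse_unpen`.
#' @export
study_mse <- function(study) {
  stopifnot(inherits(study, "store_study"))
  per <- dplyr::summarise(
    dplyr::group_by(study$params, .data$term, .data$method),
    n = dplyr::n(),
    bias = mean(.data$estimate - .data$true),
    mse = mean((.data$estimate - .data$true)^2), .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = "method",
                             values_from = c("n", "bias", "mse"))
  if (all(c("mse_penalized", "mse_unpenalized") %in% names(wide))) {
    wide$pct_mse_diff <- 100 * (wide$mse_penalized - wide$mse_unpenalized) /
      wide$mse_unpenalized
  }
  wide
}
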