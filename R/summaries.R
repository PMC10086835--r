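#' Latent-scale R-squared of a fit
#'
#' The ratio of the sample variance of the fitted fixed-effects part
#' `f_hat(trait, state)` to the estimated variance of the latent response,
#' `Var(f_hat + u_hat) + c`, with the predicted random intercepts repeated
#' within subject. By default the latent error variance constant `c` is 1;
#' `error_var = "logistic"` uses `pi^2 / 3`, the variance of the standard
#' logistic latent error.
#'
#' @param fit A `store_fit`.
#' @param error_var `"one"` (default) or `"logistic"`.
#' @return A tibble with columns `r2`, `latent_sd`, `var_fixed`, `var_total`.
#' @export
latent_r2 <- function(fit, error_var = c("one", "logistic")) {
  stopifnot(inherits(fit, "store_fit"))
  cval <- switch(match.arg(error_var), one = 1, logistic = pi^2 / 3)
  u_obs <- fit$u_hat[fit$obs_subject]
  vf <- stats::var(fit$eta_fix)
  vt <- stats::var(fit$eta_fix + u_obs) + cval
  tibble::tibble(r2 = vf / vt, latent_sd = sqrt(vt),
                 var_fixed = vf, var_total = vt)
}

#' Standardized coefficients
#'
#' Divides the latent-scale coefficients by the estimated latent response
#' standard deviation (the square root of `Var(f_hat + u_hat) + c`), making
#' effects comparable across models whose cutpoints differ.
#'
#' @inheritParams latent_r2
#' @return Named numeric vector of standardized coefficients.
#' @export
standardize_coefs <- function(fit, error_var = c("one", "logistic")) {
  sd_l <- latent_r2(fit, error_var)$latent_sd
  fit$coef / sd_l
}

#' Trait-only model
#'
#' Fits the model with the state term deleted: the latent mean is
#' `alpha + tau_{median}` only. The penalty (used when `lambda` is `"auto"`
#' or positive) is the second difference of the trait profile, shrinking
#' `tau_r` towards linearity in `r`.
#'
#' @inheritParams fit_store
#' @return A `store_fit`.
#' @export
fit_trait_only <- function(panel, lambda = "auto", nodes = 15,
                           lambda_grid = default_lambda_grid(),
                           control = st_control()) {
  fit_store(panel, mode = "trait_only", lambda = lambda, nodes = nodes,
            lambda_grid = lambda_grid, control = control)
}

#' Lagged-response model
#'
#' Augments the state-trait model with the previous response `y_{i,j-1}`
#' (entered as a numeric predictor, unpenalized). The first observation of
#' each subject, or of each subject-day when a `day` column is present, is
#' dropped. Because the retained sample differs from the unlagged model's,
#' cross-model comparison should use the scaled AIC (`AIC / n`), stored in
#' the fit as `scaled_aic`.
#'
#' @inheritParams fit_store
#' @return A `store_fit` with a `beta_lag` coefficient.
#' @export
fit_lagged <- function(panel,
                       mode = c("penalized", "unpenalized", "linear"),
                       lambda = "auto", min_count = 0L, nodes = 15,
                       lambda_grid = default_lambda_grid(),
                       control = st_control()) {
  fit_store(panel, mode = match.arg(mode), lambda = lambda, lag = TRUE,
            min_count = min_count, nodes = nodes, lambda_grid = lambda_grid,
            control = control)
}

#' Trait-only versus state-trait R-squared report
#'
#' Fits the full state-trait model and the trait-only model on the same panel
#' and reports the two latent R-squared values and their ratio, an informal
#' index of how trait-driven the association is (near 1: trait-driven; low:
#' state-driven).
#'
#' @inheritParams fit_store
#' @param error_var See [latent_r2()].
#' @return A tibble with columns `RTS2`, `RT2`, `ratio`, `latent_sd`, plus
#'   the two fits in attributes `fit_state_trait`, `fit_trait_only`.
#' @export
r2_report <- function(panel, lambda = "auto", min_count = 0L, nodes = 15,
                      lambda_grid = default_lambda_grid(),
                      control = st_control(),
                      error_var = c("one", "logistic")) {
  error_var <- match.arg(error_var)
  fts <- fit_store(panel, "penalized", lambda = lambda, min_count = min_count,
                   nodes = nodes, lambda_grid = lambda_grid, control = control)
  ft <- fit_trait_only(panel, lambda = lambda, nodes = nodes,
                       lambda_grid = lambda_grid, control = control)
  r2s <- latent_r2(fts, error_var)
  r2t <- latent_r2(ft, error_var)
  out <- tibble::tibble(RTS2 = r2s$r2, RT2 = r2t$r2, ratio = r2t$r2 / r2s$r2,
                        latent_sd = r2s$latent_sd)
  attr(out, "fit_state_trait") <- fts
  attr(out, "fit_trait_only") <- ft
  out
}

#' Fit every ordered response-predictor pair among several ordinal variables
#'
#' Runs the penalized state-trait model for each ordered pair of the declared
#' variables (each variable as response against each other as predictor) and
#' collects standardized coefficients and the trait-only/state-trait
#' R-squared ratio.
#'
#' @param data Long-format data frame with a subject column and the ordinal
#'   variable columns.
#' @param vars Character vector (length >= 2) of ordinal variable columns.
#' @param subject Subject column name.
#' @param levels Number of ordinal levels, or a list of external-label
#'   vectors named by variable.
#' @param day Optional day column name.
#' @param ... Passed to [fit_store()] / [fit_trait_only()].
#' @return A tibble with one row per fitted pair: `response`, `predictor`,
#'   `RTS2`, `RT2`, `ratio`; standardized coefficient tables are in the
#'   attribute `coefs` (list of tibbles) and the fits in attribute `fits`.
#'   Pairs with degenerate variation are skipped with a warning.
#' @export
fit_grid <- function(data, vars, subject = "subject", levels = 7,
                     day = NULL, ...) {
  stopifnot(length(vars) >= 2)
  lev_of <- function(v) if (is.list(levels)) levels[[v]] else levels
  rows <- list()
  coefs <- list()
  fits <- list()
  for (resp in vars) {
    for (pred in setdiff(vars, resp)) {
      key <- paste(resp, pred, sep = "~")
      panel <- try(ordinal_panel(data, subject = subject, x = pred, y = resp,
                                 day = day, x_levels = lev_of(pred),
                                 y_levels = lev_of(resp)), silent = TRUE)
      if (inherits(panel, "try-error") ||
          length(unique(panel$x)) < 2 || length(unique(panel$y)) < 2) {
        warning("pair ", key, " skipped: degenerate variation", call. = FALSE)
        next
      }
      rep2 <- try(r2_report(panel, ...), silent = TRUE)
      if (inherits(rep2, "try-error")) {
        warning("pair ", key, " skipped: ", attr(rep2, "condition")$message,
                call. = FALSE)
        next
      }
      fts <- attr(rep2, "fit_state_trait")
      rows[[key]] <- tibble::tibble(response = resp, predictor = pred,
                                    RTS2 = rep2$RTS2, RT2 = rep2$RT2,
                                    ratio = rep2$ratio)
      coefs[[key]] <- tidy(fts)
      fits[[key]] <- fts
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "coefs") <- coefs
  attr(out, "fits") <- fits
  out
}
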