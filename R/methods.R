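#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient table of a state-trait fit
#'
#' One row per fixed-effect coefficient, with its trait/state indices (where
#' applicable) and the estimate standardized by the latent response SD.
#'
#' @param x A `store_fit`.
#' @param error_var Constant used in the latent SD, see [latent_r2()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `type`, `r`, `s`, `estimate`,
#'   `standardized_estimate`.
#' @export
tidy.store_fit <- function(x, error_var = c("one", "logistic"), ...) {
  sd_l <- latent_r2(x, error_var)$latent_sd
  if (x$mode == "linear") {
    terms <- tibble::tibble(term = names(x$coef),
                            type = x$types,
                            r = NA_integer_, s = NA_integer_)
  } else {
    terms <- x$layout$terms[, c("term", "type", "r", "s")]
    if (x$lag) {
      terms <- dplyr::bind_rows(terms,
                                tibble::tibble(term = "beta_lag", type = "lag",
                                               r = NA_integer_, s = NA_integer_))
    }
  }
  terms$estimate <- as.numeric(x$coef)
  terms$standardized_estimate <- terms$estimate / sd_l
  terms
}

#' One-row summary of a state-trait fit
#'
#' @param x A `store_fit`.
#' @param ... Unused.
#' @return Tibble with log-likelihood, EDF, AIC, scaled AIC, lambda, the
#'   random-intercept SD, sample sizes and convergence information.
#' @export
glance.store_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, edf_fixed = x$edf$total, AIC = x$aic,
                 scaled_AIC = x$scaled_aic, lambda = x$lambda,
                 sigma_u = x$sigma_u, nobs = x$n_obs,
                 n_subjects = x$n_subjects, converged = x$converged)
}

#' @export
print.store_fit <- function(x, ...) {
  cat("Ordinal state-trait regression (", x$mode,
      if (x$lag) ", lagged response" else "", ")\n", sep = "")
  cat(sprintf("  %d observations, %d subjects, %d response levels\n",
              x$n_obs, x$n_subjects, x$My))
  if (x$mode %in% c("penalized", "trait_only")) {
    cat(sprintf("  lambda = %.4g, fixed-effect EDF = %.2f\n",
                x$lambda, x$edf$total))
  }
  cat(sprintf("  logLik = %.2f, AIC = %.2f, sigma_u = %.3f\n",
              x$loglik, x$aic, x$sigma_u))
  cat("  cutpoints:", paste(sprintf("%.3f", x$theta), collapse = " "), "\n")
  if (!x$converged) cat("  WARNING: fit flagged as not converged (grad ",
                        format(x$grad_norm), ")\n", sep = "")
  invisible(x)
}

#' @export
print.store_study <- function(x, ...) {
  cat("State-trait simulation study:", x$reps, "replicates, p =",
      x$config$p, "\n")
  w <- study_wins(x)
  tab <- table(factor(w$best, levels = unique(x$fits$method)))
  cat("  lowest-AIC counts (", attr(w, "n"), " complete replicates):\n",
      sep = "")
  for (m in names(tab)) cat(sprintf("    %-12s %d\n", m, tab[[m]]))
  if (x$n_failed > 0) cat("  ", x$n_failed, " fit(s) failed/not converged\n")
  invisible(x)
}

#' Coefficient-surface plot of a state-trait fit
#'
#' The numeric content of the trait-state coefficient display: the fitted
#' latent surface `f(r, s)` (equivalently `tau_r` on the diagonal and
#' `gamma_{r,s}` off it) as a tile grid, optionally with point size showing
#' the number of observations per cell.
#'
#' @param object A `store_fit`.
#' @param what `"coef"` plots `tau`/`gamma` values (diagonal/off-diagonal),
#'   `"f"` the full surface.
#' @param bubble Overlay cell counts as point size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.store_fit <- function(object, what = c("coef", "f"), bubble = FALSE,
                               ...) {
  what <- match.arg(what)
  f <- fitted_f(object)
  if (what == "coef" && object$mode != "linear" && object$mode != "trait_only") {
    td <- tidy(object)
    td <- td[td$type %in% c("tau", "gamma"), , drop = FALSE]
    gm <- object$global_median
    dat <- dplyr::bind_rows(
      tibble::tibble(r = gm, s = gm, value = 0),
      tibble::tibble(r = td$r, s = td$s,
                     value = ifelse(td$type == "tau", td$estimate, td$estimate))
    )
    lab <- "tau (diag) / gamma (off-diag)"
  } else {
    dat <- tibble::tibble(r = f$r, s = f$s, value = f$f)
    lab <- "f(r, s)"
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$s, y = .data$r,
                                         fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = lab) +
    ggplot2::labs(x = "state level s", y = "trait level r (person median)") +
    ggplot2::theme_minimal()
  if (bubble) {
    cnt <- object$keys
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(r = cnt$r, s = cnt$s, n = cnt$n),
      ggplot2::aes(x = .data$s, y = .data$r, size = .data$n),
      inherit.aes = FALSE, alpha = 0.4)
  }
  p
}

#' AIC comparison plot for a simulation study
#'
#' @param object A `store_study`.
#' @param ... Unused.
#' @return A ggplot object: AIC box plots per fitting method.
#' @export
autoplot.store_study <- function(object, ...) {
  fits <- dplyr::filter(object$fits, .data$converged)
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$method, y = .data$aic)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "AIC") +
    ggplot2::theme_minimal()
}

#' @export
logLik.store_fit <- function(object, ...) {
  structure(object$loglik,
            df = object$edf$total + (object$My - 2) + 1,
            nobs = object$n_obs, class = "logLik")
}

#' @export
AIC.store_fit <- function(object, ..., k = 2) {
  object$aic
}
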