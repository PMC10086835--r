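# Fixture builders and independent oracles shared across the suite.

# Panel whose key set is the full M x M grid: one subject per trait level,
# with enough copies of the median to pin it and one visit to every state.
full_grid_panel <- function(M = 7, My = 7, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(M), function(r) {
    x <- c(rep(r, M + 1), seq_len(M))
    data.frame(subject = sprintf("P%d", r), x = x,
               y = sample(rep(seq_len(My), length.out = length(x))))
  })
  ordinal_panel(do.call(rbind, rows), x_levels = M, y_levels = My)
}

# Small random panel for property tests (keys are whatever turns up).
random_panel <- function(n_subj = 12, J = 9, M = 5, My = 4) {
  rows <- lapply(seq_len(n_subj), function(i) {
    data.frame(subject = sprintf("r%02d", i),
               x = sample.int(M, J, replace = TRUE,
                              prob = stats::dbinom(0:(M - 1), M - 1,
                                                   stats::runif(1, .2, .8))),
               y = sample.int(My, J, replace = TRUE))
  })
  ordinal_panel(do.call(rbind, rows), x_levels = M, y_levels = My)
}

# Direct summation of the penalty functional: squared second differences in
# the trait and state directions plus twice the squared mixed differences,
# over every window whose cells all occur in the key set, with f values read
# through the merge map. Independent of the D-matrix construction.
jstar_oracle <- function(keys, f) {
  M <- attr(keys, "M_x")
  key_id <- paste(keys$r, keys$s)
  fv <- function(r, s) {
    i <- match(paste(r, s), key_id)
    f$f[match(paste(keys$rep_r[i], keys$rep_s[i]), paste(f$r, f$s))]
  }
  in_k <- function(r, s) paste(r, s) %in% key_id
  total <- 0
  for (r in seq_len(M)) {
    for (s in seq_len(M)) {
      if (r >= 2 && r <= M - 1 && in_k(r - 1, s) && in_k(r, s) && in_k(r + 1, s)) {
        total <- total + (fv(r + 1, s) - 2 * fv(r, s) + fv(r - 1, s))^2
      }
      if (s >= 2 && s <= M - 1 && in_k(r, s - 1) && in_k(r, s) && in_k(r, s + 1)) {
        total <- total + (fv(r, s + 1) - 2 * fv(r, s) + fv(r, s - 1))^2
      }
      if (r < M && s < M && in_k(r, s) && in_k(r + 1, s) &&
          in_k(r, s + 1) && in_k(r + 1, s + 1)) {
        total <- total + 2 * (fv(r + 1, s + 1) - fv(r + 1, s) -
                                fv(r, s + 1) + fv(r, s))^2
      }
    }
  }
  total
}

# Dense-trapezoid marginal log-likelihood (the integration oracle).
trapezoid_loglik <- function(y, eta, subject, theta, sigma_u,
                             lim = 8, npts = 1e5) {
  total <- 0
  for (s in unique(subject)) {
    i <- subject == s
    u <- seq(-lim * max(sigma_u, 1), lim * max(sigma_u, 1), length.out = npts)
    lg <- vapply(u, function(uu) {
      sum(category_logprob(eta[i] + uu, theta, y[i]))
    }, numeric(1))
    g <- exp(lg) * stats::dnorm(u, 0, sigma_u)
    total <- total + log(sum((g[-1] + g[-length(g)]) / 2) * (u[2] - u[1]))
  }
  total
}

# Scaled-down generator for fit-level unit tests (not the study conditions);
# tighter cutpoints keep all response categories populated at this size.
small_config <- function(p = 1) {
  sim_config(p = p, median_freqs = c(2, 5, 9, 11, 9, 5, 2), J = 15,
             theta = c(-1, 0, 1, 2, 3, 4))
}
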