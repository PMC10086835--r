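test_that("coefficient layout applies the identifiability constraints", {
  p <- full_grid_panel(7)
  k <- key_set(p)
  lay <- coef_layout(k)
  # full 7x7 grid: alpha + 6 tau + 42 gamma = 49 = |K|
  expect_equal(nrow(lay$terms), 49)
  expect_equal(sum(lay$terms$type == "tau"), 6)
  expect_equal(sum(lay$terms$type == "gamma"), 42)
  gm <- attr(k, "global_median")
  expect_false(paste0("tau_", gm) %in% lay$terms$term)
  expect_false(any(lay$terms$type == "gamma" & lay$terms$r == lay$terms$s))

  # two-cell key set with global median 2: only alpha and gamma_2_3 remain
  d <- data.frame(subject = rep(c("a", "b"), each = 3),
                  x = c(2, 2, 3, 2, 2, 2), y = rep(1:3, 2))
  k2 <- key_set(ordinal_panel(d, x_levels = 3, y_levels = 3))
  lay2 <- coef_layout(k2)
  expect_setequal(lay2$terms$term, c("alpha", "gamma_2_3"))
})

test_that("zeta_to_f and f_to_zeta are exact inverses", {
  p <- full_grid_panel(5, My = 4)
  lay <- coef_layout(key_set(p))
  set.seed(3)
  for (i in 1:10) {
    z <- rnorm(nrow(lay$terms))
    f <- zeta_to_f(z, lay)
    expect_equal(unname(f_to_zeta(f, lay)), z, tolerance = 1e-12)
  }
  # linear surface decomposes as tau_r = 0.2 (r - gm), gamma = -0.3 (s - r)
  gm <- lay$global_median
  f_lin <- tibble::tibble(r = lay$cells$r, s = lay$cells$s,
                          f = 2 + 0.5 * lay$cells$r - 0.3 * lay$cells$s)
  z <- f_to_zeta(f_lin, lay)
  expect_equal(unname(z["alpha"]), 2 + 0.2 * gm, tolerance = 1e-12)
  for (r in setdiff(1:5, gm)) {
    expect_equal(unname(z[paste0("tau_", r)]), 0.2 * (r - gm),
                 tolerance = 1e-12)
  }
  expect_equal(unname(z["gamma_2_4"]), -0.3 * 2, tolerance = 1e-12)
  # constant surface: alpha carries it all
  zc <- f_to_zeta(tibble::tibble(r = lay$cells$r, s = lay$cells$s, f = 0.17),
                  lay)
  expect_equal(unname(zc["alpha"]), 0.17)
  expect_true(all(abs(zc[-1]) < 1e-12))
  # missing diagonal cell is reported by name
  expect_error(f_to_zeta(f_lin[-which(f_lin$r == 3 & f_lin$s == 3), ], lay),
               "\\(3,3\\)")
})

test_that("difference rows enumerate admissible windows only", {
  p3 <- full_grid_panel(3, My = 3)
  D <- difference_rows(key_set(p3))
  w <- attr(D, "windows")
  expect_equal(unname(table(w$op)[c("rr", "rs", "ss")]), c(3L, 4L, 3L),
               ignore_attr = TRUE)
  # cells (2,1) and (2,3) absent: every window referencing them must go
  d <- rbind(
    data.frame(subject = "P1", x = c(rep(1, 5), 2, 3), y = 1),
    data.frame(subject = "P2", x = rep(2, 5), y = 1),
    data.frame(subject = "P3", x = c(rep(3, 5), 1, 2), y = 1)
  )
  d$y <- rep_len(1:3, nrow(d))
  panel <- ordinal_panel(d, x_levels = 3, y_levels = 3)
  keys <- key_set(panel)
  expect_false(any(keys$r == 2 & keys$s != 2))
  D2 <- difference_rows(keys)
  w2 <- attr(D2, "windows")
  # brute-force admissibility over all window positions
  in_k <- function(r, s) any(keys$r == r & keys$s == s)
  expected <- 0
  for (r in 1:3) for (s in 1:3) {
    if (r == 2 && in_k(r - 1, s) && in_k(r, s) && in_k(r + 1, s))
      expected <- expected + 1
    if (s == 2 && in_k(r, s - 1) && in_k(r, s) && in_k(r, s + 1))
      expected <- expected + 1
    if (r < 3 && s < 3 && in_k(r, s) && in_k(r + 1, s) && in_k(r, s + 1) &&
        in_k(r + 1, s + 1))
      expected <- expected + 1
  }
  expect_equal(nrow(w2), expected)

  # single-cell key set: no admissible window, penalty identically zero
  d1 <- data.frame(subject = c("a", "a", "b", "b"), x = 2, y = c(1, 2, 1, 2))
  k1 <- key_set(ordinal_panel(d1, x_levels = 3, y_levels = 2))
  expect_equal(nrow(difference_rows(k1)), 0)
})

test_that("penalty quadratic form equals the direct-summation oracle", {
  set.seed(42)
  for (i in 1:20) {
    panel <- random_panel(M = sample(4:6, 1))
    keys <- key_set(panel)
    lay <- coef_layout(keys)
    pen <- penalty_matrix(keys, lay)
    z <- rnorm(nrow(lay$terms))
    f <- zeta_to_f(z, lay)
    qf <- drop(crossprod(z, pen$P %*% z))
    expect_gte(qf, -1e-12)
    expect_equal(qf, jstar_oracle(keys, f), tolerance = 1e-10)
  }
})

test_that("penalty vanishes exactly on linear surfaces; full-grid null space is 3", {
  panel <- full_grid_panel(7)
  keys <- key_set(panel)
  lay <- coef_layout(keys)
  pen <- penalty_matrix(keys, lay)
  for (b in list(c(0, 1, 0), c(1, -2, 3), c(-0.4, 0.25, 0.8))) {
    f <- tibble::tibble(r = lay$cells$r, s = lay$cells$s,
                        f = b[1] + b[2] * lay$cells$r + b[3] * lay$cells$s)
    z <- f_to_zeta(f, lay)
    expect_lt(abs(drop(crossprod(z, pen$P %*% z))), 1e-10 * max(1, sum(z^2)))
  }
  ev <- eigen(pen$P, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-9 * max(ev)), 3)
  expect_true(all(ev > -1e-9 * max(ev))) # positive semidefinite
})

test_that("penalty value is invariant to the ordering of the key rows", {
  set.seed(9)
  panel <- random_panel(M = 5)
  keys <- key_set(panel)
  lay <- coef_layout(keys)
  pen <- penalty_matrix(keys, lay)
  shuf <- keys[sample(nrow(keys)), ]
  attributes(shuf)[c("global_median", "M_x", "class")] <-
    attributes(keys)[c("global_median", "M_x", "class")]
  lay2 <- coef_layout(shuf)
  pen2 <- penalty_matrix(shuf, lay2)
  z <- rnorm(nrow(lay$terms))
  f <- zeta_to_f(z, lay)
  z2 <- f_to_zeta(f, lay2)
  expect_equal(drop(crossprod(z, pen$P %*% z)),
               drop(crossprod(z2, pen2$P %*% z2)), tolerance = 1e-10)
})
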