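#' Coefficient layout for the state-trait surface
#'
#' Orders the fixed-effect parameters of the latent model
#' `f(r, s) = alpha + tau_r + gamma_{r,s}`: the intercept `alpha` first, then
#' the trait effects `tau_r` (one per level attained as a person median,
#' excluding the reference trait: the global median, or the nearest attained
#' trait level if no subject's median equals it), then the state effects
#' `gamma_{r,s}` for off-diagonal cells, lexicographically. The identifiability
#' constraints `tau_{global median} = 0` and `gamma_{r,r} = 0` are structural:
#' those parameters simply do not exist. The layout also carries the linear
#' map `A` from the coefficient vector to the vector of `f` values on the
#' (merged) cell set, which is square and invertible, so there is exactly one
#' parameter per cell.
#'
#' If merging removed the diagonal cell of some trait level that still has
#' off-diagonal cells, the corresponding `tau_r` is structurally zero as well
#' (its role is absorbed by the `gamma`s), keeping the map invertible.
#'
#' @param keys A [key_set()].
#' @param global_median The pooled median level (defaults to the value stored
#'   in `keys`).
#' @return An object of class `st_layout`: a list with `terms` (tibble:
#'   `term`, `type`, `r`, `s`), `cells` (tibble of merged cells), the matrix
#'   `A`, and `global_median`.
#' @export
coef_layout <- function(keys, global_median = attr(keys, "global_median")) {
  stopifnot(inherits(keys, "st_keys"), nrow(keys) > 0)
  gm <- as.integer(global_median)
  cells <- merged_cells(keys)
  diag_r <- sort(cells$r[cells$r == cells$s])
  if (length(diag_r) == 0) {
    stop("no diagonal (r,r) cell in the (merged) key set; the intercept is ",
         "not identifiable", call. = FALSE)
  }
  # reference trait whose tau is fixed to zero: the global median when some
  # subject attains it as a personal median, else the nearest attained trait
  ref <- diag_r[order(abs(diag_r - gm), diag_r)][1]
  tau_r <- setdiff(diag_r, ref)
  off <- cells[cells$r != cells$s, , drop = FALSE]
  terms <- dplyr::bind_rows(
    tibble::tibble(term = "alpha", type = "alpha", r = NA_integer_, s = NA_integer_),
    tibble::tibble(term = paste0("tau_", tau_r), type = "tau",
                   r = as.integer(tau_r), s = as.integer(tau_r)),
    tibble::tibble(term = paste0("gamma_", off$r, "_", off$s), type = "gamma",
                   r = as.integer(off$r), s = as.integer(off$s))
  )
  A <- matrix(0, nrow(cells), nrow(terms),
              dimnames = list(paste0(cells$r, ",", cells$s), terms$term))
  A[, 1] <- 1
  for (k in seq_len(nrow(terms))[-1]) {
    tt <- terms$type[k]
    if (tt == "tau") {
      A[cells$r == terms$r[k], k] <- 1
    } else {
      A[cells$r == terms$r[k] & cells$s == terms$s[k], k] <- 1
    }
  }
  structure(list(terms = terms, cells = cells, A = A, global_median = gm),
            class = "st_layout")
}

#' Evaluate the latent surface from a coefficient vector
#'
#' Applies `f(r, s) = alpha + tau_r + gamma_{r,s}` (with the structural zeros
#' of the identifiability constraints) on every cell of the layout.
#'
#' @param zeta Numeric coefficient vector matching `layout$terms`.
#' @param layout An [coef_layout()] object.
#' @return A tibble with columns `r`, `s`, `f`.
#' @export
zeta_to_f <- function(zeta, layout) {
  stopifnot(inherits(layout, "st_layout"),
            length(zeta) == nrow(layout$terms))
  tibble::tibble(r = layout$cells$r, s = layout$cells$s,
                 f = as.numeric(layout$A %*% zeta))
}

#' Recover coefficients from a latent surface
#'
#' Exact inverse of [zeta_to_f()]: `alpha = f(gm, gm)`,
#' `tau_r = f(r, r) - f(gm, gm)`, `gamma_{r,s} = f(r, s) - f(r, r)` with `gm`
#' the global median, realized by solving the (square, invertible) layout map.
#'
#' @param f A data frame with columns `r`, `s`, `f` covering every cell of the
#'   layout.
#' @param layout An [coef_layout()] object.
#' @return Named numeric vector of coefficients in layout order.
#' @export
f_to_zeta <- function(f, layout) {
  stopifnot(inherits(layout, "st_layout"), is.data.frame(f))
  idx <- match(paste(layout$cells$r, layout$cells$s), paste(f$r, f$s))
  if (anyNA(idx)) {
    miss <- layout$cells[is.na(idx), , drop = FALSE]
    stop("f is missing required cell(s): ",
         paste0("(", miss$r, ",", miss$s, ")", collapse = " "), call. = FALSE)
  }
  zeta <- solve(layout$A, f$f[idx])
  stats::setNames(as.numeric(zeta), layout$terms$term)
}

#' Second-difference rows of the linearity penalty
#'
#' Builds one row per admissible window of the three discrete second-order
#' difference operators on the trait-state grid: the pure differences in the
#' trait direction (`f(r+1,s) - 2 f(r,s) + f(r-1,s)`) and state direction, and
#' the mixed difference (`f(r+1,s+1) - f(r+1,s) - f(r,s+1) + f(r,s)`), the
#' latter scaled by `sqrt(2)` so that the sum of squared rows carries the
#' weight 2 of the mixed term. A window is admissible when every cell it
#' references occurs in the data; with merging, values are read through the
#' merge map, so coefficients of cells sharing a representative accumulate.
#'
#' @param keys A [key_set()].
#' @return A matrix `D` with one column per merged cell (in `merged_cells()`
#'   order) and attribute `windows` (tibble describing each row).
#' @export
difference_rows <- function(keys) {
  stopifnot(inherits(keys, "st_keys"))
  M <- attr(keys, "M_x")
  cells <- merged_cells(keys)
  in_k <- function(r, s) paste(r, s) %in% paste(keys$r, keys$s)
  rep_idx <- function(r, s) {
    raw <- match(paste(r, s), paste(keys$r, keys$s))
    match(paste(keys$rep_r[raw], keys$rep_s[raw]), paste(cells$r, cells$s))
  }
  rows <- list()
  info <- list()
  add_row <- function(rr, ss, coefs, op) {
    v <- numeric(nrow(cells))
    for (k in seq_along(coefs)) {
      i <- rep_idx(rr[k], ss[k])
      v[i] <- v[i] + coefs[k]
    }
    rows[[length(rows) + 1L]] <<- v
    info[[length(info) + 1L]] <<- tibble::tibble(op = op, r = rr[1], s = ss[1])
  }
  for (r in seq_len(M)) {
    for (s in seq_len(M)) {
      if (r >= 2 && r <= M - 1 &&
          in_k(r - 1, s) && in_k(r, s) && in_k(r + 1, s)) {
        add_row(c(r + 1, r, r - 1), c(s, s, s), c(1, -2, 1), "rr")
      }
      if (s >= 2 && s <= M - 1 &&
          in_k(r, s - 1) && in_k(r, s) && in_k(r, s + 1)) {
        add_row(c(r, r, r), c(s + 1, s, s - 1), c(1, -2, 1), "ss")
      }
      if (r <= M - 1 && s <= M - 1 &&
          in_k(r, s) && in_k(r + 1, s) && in_k(r, s + 1) && in_k(r + 1, s + 1)) {
        add_row(c(r + 1, r + 1, r, r), c(s + 1, s, s + 1, s),
                sqrt(2) * c(1, -1, -1, 1), "rs")
      }
    }
  }
  D <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, nrow(cells))
  colnames(D) <- paste0(cells$r, ",", cells$s)
  attr(D, "windows") <- if (length(info)) dplyr::bind_rows(info) else
    tibble::tibble(op = character(), r = integer(), s = integer())
  D
}

#' Penalty matrix shrinking towards a linear latent surface
#'
#' Assembles `P = A' D' D A` on coefficient space, so that the quadratic form
#' `zeta' P zeta` equals the discrete thin-plate-style penalty functional: the
#' sum of squared second differences of `f` in the trait and state directions
#' plus twice the squared mixed differences, over all admissible windows. The
#' quadratic form vanishes exactly when `f` is linear in `(r, s)`; on a full
#' grid its null space is exactly the 3-dimensional space of linear surfaces.
#'
#' @param keys A [key_set()].
#' @param layout Optional [coef_layout()]; computed from `keys` if omitted.
#' @return An object of class `st_penalty`: list with `P`, `D`, `A`, `layout`.
#' @export
penalty_matrix <- function(keys, layout = coef_layout(keys)) {
  D <- difference_rows(keys)
  A <- layout$A
  P <- crossprod(D %*% A)
  P <- (P + t(P)) / 2
  dimnames(P) <- list(layout$terms$term, layout$terms$term)
  structure(list(P = P, D = D, A = A, layout = layout), class = "st_penalty")
}
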