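#' Construct a validated ordinal panel
#'
#' Builds the long-format data structure used throughout the package: one row
#' per momentary observation, with a subject identifier, an ordinal predictor
#' `x` and an ordinal response `y`, both recoded internally to consecutive
#' integers `1..M`. External labels (e.g. a -3..+3 pleasantness scale or a
#' 0..6 stress scale) are declared through `x_levels` / `y_levels` and mapped
#' to the internal coding; the original labels are kept as attributes.
#'
#' Rows with a missing predictor or response are dropped (the count is
#' recorded in the `n_dropped` attribute and reported via a message); subjects
#' left with no retained rows are dropped with a warning.
#'
#' @param data A data frame in long format.
#' @param subject,x,y,obs,day Column names (strings). `obs` is an
#'   within-subject observation index (created in observed order when absent);
#'   `day` is an optional day index used by lagged-response models.
#' @param x_levels,y_levels Either a single integer `M` (levels are `1..M`) or
#'   a vector of the external labels in increasing order, which are mapped to
#'   `1..M`.
#' @return A tibble of class `ordinal_panel` with columns `subject` (factor),
#'   `obs`, `x`, `y` and optionally `day`, plus attributes `M_x`, `M_y`,
#'   `x_labels`, `y_labels`, `n_dropped`.
#' @examples
#' d <- data.frame(subject = rep(1:2, each = 3), x = c(1, 2, 2, 3, 3, 3),
#'                 y = c(2, 1, 3, 3, 2, 3))
#' ordinal_panel(d, x_levels = 3, y_levels = 3)
#' @export
ordinal_panel <- function(data, subject = "subject", x = "x", y = "y",
                          obs = NULL, day = NULL,
                          x_levels = 7, y_levels = 7) {
  stopifnot(is.data.frame(data))
  for (col in c(subject, x, y, obs, day)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in `data`", call. = FALSE)
    }
  }
  x_labels <- if (length(x_levels) == 1L) seq_len(x_levels) else x_levels
  y_labels <- if (length(y_levels) == 1L) seq_len(y_levels) else y_levels

  recode_levels <- function(v, labels, what) {
    idx <- match(v, labels)
    bad <- which(!is.na(v) & is.na(idx))
    if (length(bad)) {
      stop("unknown ", what, " level '", v[bad[1]], "' at row ", bad[1],
           " (declared levels: ", paste(labels, collapse = ", "), ")",
           call. = FALSE)
    }
    idx
  }

  out <- tibble::tibble(
    subject = as.character(data[[subject]]),
    x = recode_levels(data[[x]], x_labels, "predictor"),
    y = recode_levels(data[[y]], y_labels, "response")
  )
  if (!is.null(day)) out$day <- as.integer(data[[day]])
  keep <- !is.na(out$x) & !is.na(out$y) & !is.na(out$subject)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing subject/x/y dropped")
  }
  all_subj <- unique(out$subject)
  out <- out[keep, , drop = FALSE]
  lost <- setdiff(all_subj, unique(out$subject))
  if (length(lost)) {
    warning("subject(s) with no retained observations dropped: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  if (length(unique(out$subject)) < 2L) {
    stop("an ordinal panel needs at least 2 subjects with retained rows",
         call. = FALSE)
  }
  out$subject <- factor(out$subject, levels = unique(out$subject))
  if (is.null(obs)) {
    out <- dplyr::mutate(dplyr::group_by(out, .data$subject),
                         obs = dplyr::row_number())
    out <- dplyr::ungroup(out)
  } else {
    out$obs <- as.integer(data[[obs]][keep])
  }
  out <- dplyr::relocate(out, "subject", "obs", "x", "y")
  structure(out,
            M_x = length(x_labels), M_y = length(y_labels),
            x_labels = x_labels, y_labels = y_labels,
            n_dropped = n_dropped,
            class = c("ordinal_panel", class(tibble::tibble())))
}

# lower median: for even counts with a half-integer midpoint, take the lower
# of the two middle order statistics so the result is an attained ordinal level
lower_median <- function(v) {
  v <- sort(v)
  v[floor((length(v) + 1) / 2)]
}

#' Person-specific and global median predictor levels
#'
#' The trait construct: each person's median level of the ordinal predictor,
#' and the pooled (global) median. Medians of an even number of values use the
#' lower of the two middle order statistics, so that the result is always an
#' attained ordinal level.
#'
#' @param panel An [ordinal_panel()].
#' @return A tibble with columns `subject` and `x_med`, carrying the pooled
#'   median in attribute `global_median`.
#' @export
person_medians <- function(panel) {
  stopifnot(inherits(panel, "ordinal_panel"))
  out <- dplyr::summarise(dplyr::group_by(panel, .data$subject),
                          x_med = lower_median(.data$x), .groups = "drop")
  attr(out, "global_median") <- lower_median(panel$x)
  out
}

#' Global median of the ordinal predictor
#' @param panel An [ordinal_panel()].
#' @return Integer scalar, the pooled lower median of `x`.
#' @export
global_median <- function(panel) {
  lower_median(panel$x)
}

#' Trait-state key set
#'
#' Enumerates the set K of trait-state pairs (r, s) = (person median, current
#' level) occurring in the data, with observation counts. With `min_count > 0`,
#' rare cells are merged into the nearest sufficiently-frequent cell
#' (Chebyshev distance), preferring a cell on the same off-diagonal band
#' `s - r` (where a linear latent surface is constant), then cells closer to
#' the main diagonal; remaining ties go to smaller `r`, then smaller `s`.
#'
#' @param panel An [ordinal_panel()].
#' @param traits Optional precomputed [person_medians()] result.
#' @param min_count Cells with fewer observations are merged (default 0: no
#'   merging).
#' @return A tibble of class `st_keys` with columns `r`, `s`, `n`, `rep_r`,
#'   `rep_s` (the representative cell after merging), and attributes
#'   `global_median` and `M_x`.
#' @export
key_set <- function(panel, traits = person_medians(panel), min_count = 0L) {
  stopifnot(inherits(panel, "ordinal_panel"), min_count >= 0)
  dat <- dplyr::left_join(panel, traits, by = "subject")
  keys <- dplyr::count(dat, r = .data$x_med, s = .data$x, name = "n")
  keys <- dplyr::arrange(keys, .data$r, .data$s)
  keys$rep_r <- keys$r
  keys$rep_s <- keys$s
  if (min_count > 0) {
    rare <- which(keys$n < min_count)
    donors <- which(keys$n >= min_count)
    if (length(donors) == 0L) {
      stop("no cell reaches min_count = ", min_count, "; cannot merge",
           call. = FALSE)
    }
    for (i in rare) {
      j <- merge_target(keys$r[i], keys$s[i],
                        keys$r[donors], keys$s[donors])
      keys$rep_r[i] <- keys$r[donors[j]]
      keys$rep_s[i] <- keys$s[donors[j]]
    }
  }
  structure(keys,
            global_median = attr(traits, "global_median"),
            M_x = attr(panel, "M_x"),
            class = c("st_keys", class(keys)))
}

# deterministic choice of the donor cell a rare cell is merged into:
# ordered by Chebyshev distance, then same-band preference, then distance of
# the donor's band from the main diagonal, then smaller r, then smaller s
merge_target <- function(r, s, cand_r, cand_s) {
  d <- pmax(abs(cand_r - r), abs(cand_s - s))
  band_mismatch <- as.integer((cand_s - cand_r) != (s - r))
  band_depth <- abs(cand_s - cand_r)
  order(d, band_mismatch, band_depth, cand_r, cand_s)[1]
}

# per-observation index into the merged cell table of a key set
obs_cell_index <- function(panel, traits, keys) {
  dat <- dplyr::left_join(panel, traits, by = "subject")
  cells <- merged_cells(keys)
  raw <- match(paste(dat$x_med, dat$x), paste(keys$r, keys$s))
  match(paste(keys$rep_r[raw], keys$rep_s[raw]), paste(cells$r, cells$s))
}

# unique representative cells, ordered by r then s
merged_cells <- function(keys) {
  cells <- dplyr::distinct(tibble::tibble(r = keys$rep_r, s = keys$rep_s))
  dplyr::arrange(cells, .data$r, .data$s)
}
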