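#' Tumor volume from caliper measurements
#'
#' \eqn{V = (3.14 / 6) (L W)^{3/2}} with length and width in mm. The
#' constant 3.14 (rather than `pi`) matches the formula as used in the
#' animal protocol. The formula is symmetric in L and W.
#'
#' @param L tumor length, mm (> 0)
#' @param W tumor width, mm (> 0)
#' @return volume, mm^3
#' @export
tumor_volume <- function(L, W) {
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L <= 0) || any(W <= 0)) {
    stop("caliper dimensions must be positive")
  }
  (3.14 / 6) * (L * W)^(3 / 2)
}

#' ROI mean of biomarker maps with artifact filtering
#'
#' Means of each biomarker over the pixels that are simultaneously inside
#' the ROI, valid after inversion/masking, and not flagged as
#' low-absorption artifacts (pixels whose mua at the artifact-filter
#' wavelength falls below a physiological floor are non-physiological and
#' excluded).
#'
#' @param bm an `sfdi_biomarkers`
#' @param roi_mask logical matrix (nonempty)
#' @param mua_filter_map optional matrix of mua values (mm^-1) at the
#'   filter wavelength (typically 659 nm)
#' @param mua_floor artifact floor, mm^-1 (default 0.002)
#' @return named list of biomarker means plus `n_valid_pixels`; all-NA with
#'   a warning when no pixel survives filtering
#' @export
roi_mean <- function(bm, roi_mask, mua_filter_map = NULL, mua_floor = 0.002) {
  stopifnot(inherits(bm, "sfdi_biomarkers"))
  if (!any(roi_mask)) stop("ROI mask is empty")
  keep <- roi_mask & bm$valid
  if (!is.null(mua_filter_map)) keep <- keep & mua_filter_map >= mua_floor
  vars <- c("a", "b", "ctHbO2", "ctHHb", "ctTHb", "StO2")
  if (!any(keep)) {
    warning("no valid ROI pixels after artifact filtering")
    out <- stats::setNames(as.list(rep(NA_real_, length(vars))), vars)
    out$n_valid_pixels <- 0L
    return(out)
  }
  out <- lapply(stats::setNames(vars, vars), function(v) mean(bm[[v]][keep]))
  out$n_valid_pixels <- sum(keep)
  out
}

#' Percent change from the day-0 baseline
#'
#' \eqn{100 (x_d - x_0) / x_0} for each day of a per-subject series. The
#' day-0 value must be present, finite and nonzero; otherwise the series
#' cannot be normalized and `NULL` is returned with a message so the
#' caller can exclude the subject.
#'
#' @param values biomarker values by day
#' @param days measurement days (must contain 0)
#' @return vector of percent changes (0 at day 0), or `NULL` when the
#'   baseline is unusable
#' @export
percent_change <- function(values, days) {
  if (length(values) != length(days)) stop("length mismatch")
  i0 <- which(days == 0)
  if (length(i0) != 1 || !is.finite(values[i0]) || values[i0] == 0) {
    message("missing or zero day-0 baseline: subject excluded from normalization")
    return(NULL)
  }
  100 * (values - values[i0]) / values[i0]
}

#' Morphological erosion of a logical mask (4-neighborhood, 1 pixel)
#'
#' Used to shrink the ground-truth tumor footprint into a conservative ROI
#' that avoids the rim, standing in for manual ROI selection.
#'
#' @param mask logical matrix
#' @return eroded logical matrix
#' @export
erode_mask <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  ctr <- pad[2:(n + 1), 2:(m + 1)]
  ctr & pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
    pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
}

#' Assemble and validate the long-format cohort table
#'
#' Stacks per-subject-day rows into the long-format table consumed by the
#' longitudinal models and classifiers, enforcing its invariants: one row
#' per (subject, day), percent changes exactly zero at day 0, and
#' deterministic (subject, day) row order.
#'
#' @param rows data.frame with at least `subject`, `group`, `day` and the
#'   `pct_change_*` columns
#' @return validated, ordered data.frame of class `cohort_table`
#' @export
assemble_cohort_table <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) {
    out <- data.frame(subject = character(), group = character(),
                      day = numeric())
    class(out) <- c("cohort_table", "data.frame")
    return(out)
  }
  key <- paste(rows$subject, rows$day)
  if (anyDuplicated(key)) stop("duplicate subject-day rows")
  pct_cols <- grep("^pct_change_", names(rows), value = TRUE)
  d0 <- rows$day == 0
  for (cc in pct_cols) {
    bad <- d0 & !is.na(rows[[cc]]) & abs(rows[[cc]]) > 1e-9
    if (any(bad)) stop("nonzero percent change at day 0 in ", cc)
  }
  out <- rows[order(rows$subject, rows$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
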