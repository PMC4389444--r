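#' Area-overlay confusion of detected versus true risk areas
#'
#' Cross-tabulates the significant-region mask against the true risk mask on
#' the shared analysis grid, cell by cell (cell-centre rule), and converts
#' counts to areas: TP = significant and risk, FP = significant and non-risk,
#' FN = non-significant risk, TN = the rest. Sensitivity `Se = TP/(TP + FN)`,
#' specificity `Sp = TN/(FP + TN)` and the positive likelihood ratio
#' `LR+ = Se/(1 - Sp)` follow.
#'
#' @param significant An `rr_contours`, `rr_risk_surface` or 0/1 [rr_raster].
#' @param risk_mask An `rr_risk_mask` or 0/1 [rr_raster] on the same grid.
#' @param estimator,scenario Labels copied into the output row.
#' @return One-row tibble of class `rr_confusion` with columns `estimator`,
#'   `scenario`, `tp`, `fp`, `fn`, `tn` (m2), `se`, `sp`, `lr_plus`.
#' @export
overlay_confusion <- function(significant, risk_mask,
                              estimator = NA_character_, scenario = NA_character_) {
  sig_r <- extract_mask(significant)
  truth_r <- extract_mask(risk_mask)
  stopifnot_same_grid(sig_r, truth_r)
  a <- raster_cell_area(sig_r)
  s <- sig_r$values > 0
  t <- truth_r$values > 0
  tp <- sum(s & t) * a
  fp <- sum(s & !t) * a
  fn <- sum(!s & t) * a
  tn <- sum(!s & !t) * a
  # undefined (0/0) rates are NA: a window without true risk areas carries no
  # sensitivity information
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  out <- tibble::tibble(
    estimator = estimator, scenario = scenario,
    tp = tp, fp = fp, fn = fn, tn = tn,
    se = se, sp = sp,
    lr_plus = if (is.na(se) || is.na(sp)) NA_real_
              else positive_likelihood_ratio(se, sp)
  )
  class(out) <- c("rr_confusion", class(out))
  out
}

extract_mask <- function(x) {
  if (inherits(x, "rr_risk_surface")) return(x$contours$mask)
  if (inherits(x, "rr_contours")) return(x$mask)
  if (inherits(x, "rr_risk_mask")) return(x$mask)
  if (inherits(x, "rr_raster")) return(x)
  stop("cannot interpret object as a mask raster", call. = FALSE)
}

#' Positive likelihood ratio
#'
#' `LR+ = Se / (1 - Sp)`: how many times more likely a significant contour is
#' inside a true risk area than outside. With perfect specificity the ratio is
#' reported as `Inf`.
#'
#' @param se,sp Sensitivity and specificity in `[0, 1]` (vectorised).
#' @return Numeric vector of likelihood ratios.
#' @export
positive_likelihood_ratio <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  ifelse(sp < 1, se / (1 - sp), Inf)
}

#' Nearest-neighbour ratio against complete spatial randomness
#'
#' Clark-Evans style diagnostic: the mean distance of each point to its
#' nearest neighbour, divided by the expectation `1/(2 sqrt(lambda))` under
#' complete spatial randomness at intensity `lambda = n / area`. Values < 1
#' indicate clustering, values > 1 dispersion. No edge correction is applied
#' (the plain CSR expectation).
#'
#' @param pattern Point pattern (data frame with `x`, `y`), n >= 2.
#' @param window Window (defaults to the pattern's attribute).
#' @return One-row tibble: `n`, `mean_nn_distance`, `expected_csr_distance`,
#'   `nn_ratio`.
#' @export
nn_ratio <- function(pattern, window = NULL) {
  window <- pattern_window(pattern, window)
  x <- pattern$x; y <- pattern$y
  n <- length(x)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  chunk <- 512L
  nnd <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    nnd[idx] <- sqrt(apply(d2, 1, min))
  }
  lambda <- n / window_area(window)
  expected <- 1 / (2 * sqrt(lambda))
  tibble::tibble(
    n = n, mean_nn_distance = mean(nnd),
    expected_csr_distance = expected,
    nn_ratio = mean(nnd) / expected
  )
}
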