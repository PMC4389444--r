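#' Effective sample size for pooled-bandwidth selection
#'
#' The fixed risk estimator takes the overall sample size `n_f + n_g` of the
#' pooled case/control data; the adaptive estimator uses the geometric mean
#' `sqrt(n_f * n_g)` as its effective sample size. With equal samples the two
#' conventions differ by a factor 2, so the two oversmoothing bandwidths
#' differ by exactly `2^(1/6)`.
#'
#' @param n_f,n_g Case and control sample sizes (>= 1).
#' @param estimator `"fixed"` or `"adaptive"`.
#' @return The effective sample size (numeric scalar).
#' @export
effective_sample_size <- function(n_f, n_g, estimator = c("fixed", "adaptive")) {
  estimator <- match.arg(estimator)
  if (any(c(n_f, n_g) < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  if (estimator == "fixed") n_f + n_g else sqrt(n_f * n_g)
}

# Terrell maximal-smoothing constant, bivariate Gaussian kernel:
# h = (2500 / (3072 n))^(1/6) * sigma
OS_CONST_2D <- (2500 / 3072)^(1 / 6)

#' Oversmoothing (maximal smoothing) bandwidth
#'
#' Terrell's oversmoothing principle gives the largest bandwidth consistent
#' with the scale of the data — a conservative upper bound that suppresses
#' spurious modes. For bivariate data with a Gaussian kernel,
#' `h = (2500/(3072 n))^(1/6) * sigma`, where `sigma` is the square root of
#' the mean of the two marginal sample variances and `n` the (effective)
#' sample size, so the bandwidth narrows as `n^(-1/6)`.
#'
#' @param pattern Point pattern (data frame with `x`, `y`), typically the
#'   pooled cases + controls.
#' @param n_eff Effective sample size; defaults to `nrow(pattern)`. Use
#'   [effective_sample_size()] for the fixed/adaptive conventions.
#' @return Bandwidth in metres.
#' @export
os_bandwidth <- function(pattern, n_eff = NULL) {
  x <- pattern$x; y <- pattern$y
  if (length(x) < 2 || nrow(unique(cbind(x, y))) < 2) {
    stop("need at least 2 distinct points", call. = FALSE)
  }
  n_eff <- n_eff %||% length(x)
  stopifnot(n_eff > 0)
  sigma <- sqrt(mean(c(stats::var(x), stats::var(y))))
  if (sigma <= 0) stop("zero scale: all points identical", call. = FALSE)
  OS_CONST_2D * sigma * n_eff^(-1 / 6)
}

# LSCV criterion for the bivariate Gaussian kernel, closed form over pairwise
# squared distances d2 (unique pairs, length n(n-1)/2):
#   LSCV(h) = int fhat^2 - (2/n) sum_i fhat_{-i}(X_i)
#           = [n/(4 pi h^2) + 2 sum_p exp(-d2/(4h^2))/(4 pi h^2)] / n^2
#             - 4 sum_p exp(-d2/(2h^2)) / (2 pi h^2 n (n-1))
lscv_score <- function(h, d2, n) {
  vapply(h, function(hh) {
    t1 <- (n / (4 * pi * hh^2) +
             sum(exp(-d2 / (4 * hh^2))) / (2 * pi * hh^2)) / n^2
    t2 <- 2 * sum(exp(-d2 / (2 * hh^2))) / (pi * hh^2 * n * (n - 1))
    t1 - t2
  }, numeric(1))
}

#' Least-squares cross-validation bandwidth
#'
#' Minimises the LSCV estimate of the integrated squared error,
#' `LSCV(h) = int fhat_h^2 - (2/n) sum_i fhat_{h,-i}(X_i)`, evaluated in
#' closed form for the bivariate Gaussian kernel. The criterion is scanned on
#' a log-spaced grid over the search interval and the global minimum is
#' refined by golden-section search; all grid-local minima are reported. LSCV
#' is known to develop multiple minima and a degenerate `h -> 0` solution when
#' points are duplicated or near-duplicated; a minimum on the lower interval
#' boundary is therefore returned with a `degenerate` flag, and tied global
#' minima are broken towards the largest bandwidth.
#'
#' @param pattern Point pattern (data frame with `x`, `y`), n >= 10.
#' @param interval Search interval `c(lower, upper)` in metres; default
#'   `[sigma * n^(-1/2), 3 * h_OS]`.
#' @param ngrid Number of coarse grid points (default 61).
#' @return Bandwidth in metres, with attributes `minima` (tibble of grid-local
#'   minima: `h`, `score`), `degenerate` (TRUE if the optimum sits on the
#'   lower boundary) and `interval`.
#' @export
lscv_bandwidth <- function(pattern, interval = NULL, ngrid = 61) {
  x <- pattern$x; y <- pattern$y
  n <- length(x)
  if (n < 10) stop("LSCV needs at least 10 points", call. = FALSE)
  if (anyDuplicated(cbind(x, y)) > 0) {
    warning("duplicated points detected: LSCV is prone to a degenerate h -> 0 minimum",
            call. = FALSE)
  }
  if (is.null(interval)) {
    sigma <- sqrt(mean(c(stats::var(x), stats::var(y))))
    interval <- c(sigma * n^(-1 / 2), 3 * os_bandwidth(pattern))
  }
  stopifnot(length(interval) == 2, all(is.finite(interval)),
            interval[1] > 0, interval[2] > interval[1])
  d2 <- stats::dist(cbind(x, y))^2
  hs <- exp(seq(log(interval[1]), log(interval[2]), length.out = ngrid))
  sc <- lscv_score(hs, d2, n)

  is_min <- vapply(seq_along(hs), function(i) {
    left <- if (i == 1) Inf else sc[i - 1]
    right <- if (i == length(hs)) Inf else sc[i + 1]
    sc[i] <= left && sc[i] <= right
  }, logical(1))
  minima <- tibble::tibble(h = hs[is_min], score = sc[is_min])

  # refine each grid-local minimum within its bracketing grid cells
  refined <- purrr::map(which(is_min), function(i) {
    lo <- hs[max(i - 1, 1)]; up <- hs[min(i + 1, length(hs))]
    if (up <= lo) return(list(minimum = hs[i], objective = sc[i]))
    stats::optimise(lscv_score, c(lo, up), d2 = d2, n = n, tol = 1e-3 * lo)
  })
  minima$h <- vapply(refined, `[[`, numeric(1), "minimum")
  minima$score <- vapply(refined, `[[`, numeric(1), "objective")

  best <- min(minima$score)
  tol <- 1e-9 * max(abs(best), 1e-300)
  h <- max(minima$h[minima$score <= best + tol]) # tie-break: most smoothing
  degenerate <- h <= interval[1] * (hs[2] / hs[1]) # within one log-grid step

  if (degenerate) {
    warning("LSCV minimum on the lower search boundary: degenerate (h -> 0) solution",
            call. = FALSE)
  }
  structure(h, minima = minima[order(minima$h), ],
            degenerate = degenerate, interval = interval)
}

#' Bandwidth specification for one estimator run
#'
#' Collects all smoothing parameters: the fixed bandwidth (oversmoothing on
#' the pooled data with `n_f + n_g`), the adaptive global bandwidth
#' (oversmoothing with effective size `sqrt(n_f n_g)`), and the per-pattern
#' LSCV pilot bandwidths.
#'
#' @param h_fixed Fixed-estimator bandwidth (metres).
#' @param h0_global Adaptive global bandwidth (metres).
#' @param h_pilot_f,h_pilot_g Pilot bandwidths for cases / controls (metres).
#' @param scenario Scenario label (`"none"`, `"S1"`–`"S4"`).
#' @param method_tags Character vector of provenance strings.
#' @return A list of class `bandwidth_spec`.
#' @export
bandwidth_spec <- function(h_fixed, h0_global = h_fixed * 2^(1 / 6),
                           h_pilot_f = NULL, h_pilot_g = NULL,
                           scenario = "none", method_tags = character()) {
  bw <- c(h_fixed, h0_global, h_pilot_f, h_pilot_g)
  if (any(bw <= 0)) stop("all bandwidths must be > 0", call. = FALSE)
  structure(
    list(h_fixed = h_fixed, h0_global = h0_global,
         h_pilot_f = h_pilot_f, h_pilot_g = h_pilot_g,
         scenario = scenario, method_tags = method_tags),
    class = "bandwidth_spec"
  )
}

#' @export
print.bandwidth_spec <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else sprintf("%.2f m", v)
  cat(sprintf(
    "<bandwidth_spec> fixed h = %s | global h0 = %s | pilots f = %s, g = %s | scenario %s\n",
    fmt(x$h_fixed), fmt(x$h0_global), fmt(x$h_pilot_f), fmt(x$h_pilot_g), x$scenario
  ))
  invisible(x)
}

#' Scenario scalings of a bandwidth specification
#'
#' Sensitivity-analysis scalings: S1 halves pilot and global bandwidths (and
#' the fixed bandwidth); S4 doubles all of them; S2 halves the pilots while
#' doubling the global bandwidth; S3 does the reverse. `"none"` is the
#' identity. S2/S3 concern only the adaptive estimator and leave the fixed
#' bandwidth unchanged.
#'
#' @param spec A [bandwidth_spec()].
#' @param scenario One of `"none"`, `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return The scaled [bandwidth_spec()].
#' @export
scale_bandwidths <- function(spec, scenario = c("none", "S1", "S2", "S3", "S4")) {
  scenario <- match.arg(scenario)
  fac <- switch(scenario,
    none = c(pilot = 1, global = 1, fixed = 1),
    S1 = c(pilot = 0.5, global = 0.5, fixed = 0.5),
    S2 = c(pilot = 0.5, global = 2, fixed = 1),
    S3 = c(pilot = 2, global = 0.5, fixed = 1),
    S4 = c(pilot = 2, global = 2, fixed = 2)
  )
  out <- spec
  out$h_fixed <- spec$h_fixed * fac[["fixed"]]
  out$h0_global <- spec$h0_global * fac[["global"]]
  if (!is.null(spec$h_pilot_f)) out$h_pilot_f <- spec$h_pilot_f * fac[["pilot"]]
  if (!is.null(spec$h_pilot_g)) out$h_pilot_g <- spec$h_pilot_g * fac[["pilot"]]
  out$scenario <- scenario
  out
}

#' Data-driven bandwidth selection for a case/control pair
#'
#' Computes the full specification used by the two risk estimators: the fixed
#' oversmoothing bandwidth on the pooled pattern with `n_eff = n_f + n_g`, the
#' adaptive global bandwidth with `n_eff = sqrt(n_f n_g)`, and LSCV pilot
#' bandwidths selected separately for cases and controls (separate pilots
#' preserve the spatial heterogeneity of each pattern).
#'
#' @param cases,controls Point patterns (tibbles with `x`, `y`).
#' @return A [bandwidth_spec()] with attribute `report`: a one-row tibble
#'   `n_f, n_g, os_h_pooled, lscv_h_f, lscv_h_g, os_prime_h_pooled`.
#' @export
select_bandwidths <- function(cases, controls) {
  pooled <- tibble::tibble(x = c(cases$x, controls$x), y = c(cases$y, controls$y))
  n_f <- nrow(cases); n_g <- nrow(controls)
  h_fix <- os_bandwidth(pooled, effective_sample_size(n_f, n_g, "fixed"))
  h0 <- os_bandwidth(pooled, effective_sample_size(n_f, n_g, "adaptive"))
  hp_f <- as.numeric(lscv_bandwidth(cases))
  hp_g <- as.numeric(lscv_bandwidth(controls))
  spec <- bandwidth_spec(h_fix, h0, hp_f, hp_g,
                         method_tags = c("os_pooled", "os_prime_pooled",
                                         "lscv_cases", "lscv_controls",
                                         "sigma=rms_of_marginal_sd"))
  attr(spec, "report") <- tibble::tibble(
    n_f = n_f, n_g = n_g,
    os_h_pooled = h_fix, lscv_h_f = hp_f, lscv_h_g = hp_g,
    os_prime_h_pooled = h0
  )
  spec
}

#' @export
tidy.bandwidth_spec <- function(x, ...) {
  tibble::tibble(
    parameter = c("h_fixed", "h0_global", "h_pilot_f", "h_pilot_g"),
    metres = c(x$h_fixed, x$h0_global,
               x$h_pilot_f %||% NA_real_, x$h_pilot_g %||% NA_real_),
    scenario = x$scenario
  )
}
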