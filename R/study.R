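#' Configuration of a full synthetic detection study
#'
#' Bundles the region generator settings with sampling, bandwidth, testing and
#' scenario choices. Defaults mirror the reference design: 1:1 case/control
#' sampling, a -50 percent relative-error cutoff buffered by 500 m for the
#' true risk areas, a 20 m population grid, and pointwise one-sided tolerance
#' contours at alpha = 0.05 on a 200 m analysis grid.
#'
#' @param region A [region_config()].
#' @param n_cases Number of cases sampled from the true population surface.
#' @param control_ratio Controls per case (1 = the 1:1 design).
#' @param threshold,threshold_mode,buffer_m Risk-area derivation, see
#'   [derive_risk_areas()].
#' @param alpha Significance level of the tolerance contours.
#' @param scenarios Character vector of bandwidth scenarios to run
#'   (subset of `"none"`, `"S1"`–`"S4"`).
#' @param estimators Estimators to run (`"fixed"`, `"adaptive"`).
#' @param edge_correction `"diggle"` or `"none"`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(region = region_config(),
                         n_cases = 1000,
                         control_ratio = 1,
                         threshold = -50,
                         threshold_mode = "percent",
                         buffer_m = 500,
                         alpha = 0.05,
                         scenarios = "none",
                         estimators = c("fixed", "adaptive"),
                         edge_correction = "diggle") {
  stopifnot(alpha > 0, alpha < 1, control_ratio > 0, n_cases >= 1)
  stopifnot(all(scenarios %in% c("none", "S1", "S2", "S3", "S4")))
  structure(as.list(environment()), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognised sections: `region` (fields of [region_config()]), `bias`
#' (`height_max`), `risk_areas` (`threshold`, `mode`, `buffer_m`), `sampling`
#' (`n`, `ratio`, `seed`) and `test` (`alpha`); missing fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A list with `config` (a [study_config()]) and `seed`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  rc <- do.call(region_config, c(y$region, y$bias) %||% list())
  # YAML 1.1 reads a bare `n` key as boolean FALSE; accept n_cases/n/FALSE
  n_sample <- y$sampling$n_cases %||% y$sampling[["n"]] %||%
    y$sampling[["FALSE"]] %||% 1000
  cfg <- study_config(
    region = rc,
    n_cases = n_sample,
    control_ratio = y$sampling$ratio %||% 1,
    threshold = y$risk_areas$threshold %||% -50,
    threshold_mode = y$risk_areas$mode %||% "percent",
    buffer_m = y$risk_areas$buffer_m %||% 500,
    alpha = y$test$alpha %||% 0.05
  )
  list(config = cfg, seed = y$sampling$seed %||% NULL)
}

#' Run one end-to-end synthetic detection study
#'
#' Generates the synthetic region, derives the true risk areas, samples cases
#' (from the true population) and controls (from the biased estimate), selects
#' bandwidths (oversmoothing fixed/global, LSCV pilots), fits the requested
#' estimators under each scenario, and scores every fit against the truth by
#' area overlay. Deterministic given `seed`.
#'
#' @param config A [study_config()].
#' @param seed Integer seed for the whole run.
#' @param keep_surfaces Keep the full risk-surface objects (memory-heavy) in
#'   the result; default `TRUE`.
#' @return An object of class `rr_study`: list with `results` (tibble of
#'   confusion rows), `bandwidths` (Table-style report tibble), `nn`
#'   (diagnostics tibble), `region`, `risk_mask`, `cases`, `controls`,
#'   `surfaces` (named list), `config`, `seed`.
#' @export
run_study <- function(config = study_config(), seed = 1, keep_surfaces = TRUE) {
  set.seed(seed)
  region <- simulate_region(config$region)
  grid <- raster_template(region$window, config$region$analysis_cellsize)
  risk <- derive_risk_areas(region$tracts, grid,
                            threshold = config$threshold,
                            mode = config$threshold_mode,
                            buffer_m = config$buffer_m)
  n_f <- config$n_cases
  n_g <- max(1L, round(config$n_cases * config$control_ratio))
  cases <- sample_point_pattern(region$true_population, n_f, label = "case")
  controls <- sample_point_pattern(region$biased_estimate, n_g, label = "control")

  spec <- select_bandwidths(cases, controls)
  report <- attr(spec, "report")

  surfaces <- list()
  results <- purrr::map_dfr(config$scenarios, function(sc) {
    sspec <- scale_bandwidths(spec, sc)
    purrr::map_dfr(config$estimators, function(est) {
      surf <- risk_surface(cases, controls, sspec, grid, estimator = est,
                           alpha = config$alpha,
                           edge_correction = config$edge_correction)
      if (keep_surfaces) surfaces[[paste(est, sc, sep = "_")]] <<- surf
      overlay_confusion(surf, risk, estimator = est, scenario = sc)
    })
  })
  results$seed <- seed

  nn <- dplyr::bind_rows(
    dplyr::mutate(nn_ratio(cases), pattern = "cases"),
    dplyr::mutate(nn_ratio(controls), pattern = "controls")
  )

  structure(
    list(results = results, bandwidths = report, nn = nn,
         region = region, risk_mask = risk, cases = cases, controls = controls,
         surfaces = surfaces, config = config, seed = seed),
    class = "rr_study"
  )
}

#' @export
print.rr_study <- function(x, ...) {
  cat(sprintf("<rr_study> seed %d; %d estimator x scenario runs\n",
              x$seed, nrow(x$results)))
  print(tibble::as_tibble(x$results[, c("estimator", "scenario", "se", "sp", "lr_plus")]))
  invisible(x)
}

#' @export
tidy.rr_study <- function(x, ...) tibble::as_tibble(x$results)

#' @export
glance.rr_study <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(seed = x$seed,
                   risk_area_m2 = sum(x$risk_mask$mask$values) *
                     raster_cell_area(x$risk_mask$mask)),
    x$bandwidths
  )
}

#' @export
autoplot.rr_study <- function(object, ...) {
  df <- tidyr::pivot_longer(object$results, c("se", "sp"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$value,
                                   fill = .data$estimator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(y = NULL, title = "Overlay sensitivity / specificity")
}

#' Summarise replicated studies
#'
#' Aggregates the confusion rows of several seeded replicates: mean and spread
#' of Se/Sp/LR+ per estimator and scenario, plus the fraction of replicates in
#' which the adaptive estimator's sensitivity is at least the fixed
#' estimator's (computed per scenario when both estimators are present).
#'
#' @param results Either a list of `rr_study` objects or a tibble of their
#'   combined `results` rows (must contain a `seed` column).
#' @return A list with `summary` (tibble per estimator x scenario) and
#'   `adaptive_vs_fixed` (tibble per scenario with
#'   `frac_adaptive_se_ge_fixed`).
#' @export
replicate_summary <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    cfgs <- unique(vapply(results, function(s) {
      paste(deparse(s$config[c("n_cases", "alpha", "threshold")]), collapse = "")
    }, character(1)))
    if (length(cfgs) > 1) stop("replicates have heterogeneous configs", call. = FALSE)
    results <- purrr::map_dfr(results, tidy.rr_study)
  }
  if (!"seed" %in% names(results)) stop("results need a `seed` column", call. = FALSE)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$estimator, .data$scenario),
    n_replicates = dplyr::n(),
    mean_se = mean(.data$se, na.rm = TRUE), sd_se = stats::sd(.data$se, na.rm = TRUE),
    mean_sp = mean(.data$sp, na.rm = TRUE), sd_sp = stats::sd(.data$sp, na.rm = TRUE),
    mean_lr_plus = mean(.data$lr_plus[is.finite(.data$lr_plus)]),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    results[, c("seed", "estimator", "scenario", "se")],
    names_from = "estimator", values_from = "se"
  )
  avf <- if (all(c("adaptive", "fixed") %in% names(wide))) {
    dplyr::summarise(
      dplyr::group_by(wide, .data$scenario),
      n_replicates = dplyr::n(),
      frac_adaptive_se_ge_fixed = mean(.data$adaptive >= .data$fixed, na.rm = TRUE),
      .groups = "drop"
    )
  } else {
    tibble::tibble(scenario = character(), n_replicates = integer(),
                   frac_adaptive_se_ge_fixed = numeric())
  }
  list(summary = summary, adaptive_vs_fixed = avf)
}
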