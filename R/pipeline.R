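cohort_columns <- c("unit_id", "x", "y", "age", "sex", "hypertension",
                    "residency", "accessibility_rate", "delay_time",
                    "response_time", "transport_time", "revealed_access",
                    "screening_time", "distance_to_hospital", "los",
                    "triage", "final_dx", "death")

cohort_factor_levels <- list(
  sex = c("female", "male"),
  hypertension = c("no", "yes"),
  residency = c("suburban", "urban"),
  triage = c("levels12", "levels34"),
  final_dx = c("no", "yes")
)

# covariates screened by default, in reporting order
default_candidates <- function() {
  c("sex", "age", "hypertension", "residency", "accessibility_rate",
    "delay_time", "response_time", "transport_time", "revealed_access",
    "screening_time", "distance_to_hospital", "los", "triage", "final_dx")
}

#' Write a cohort CSV with the fixed header
#'
#' @param cohort a cohort data.frame with the standard columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop_validation("cohort is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(cohort)[, cohort_columns]
  for (col in names(cohort_factor_levels)) out[[col]] <- as.character(out[[col]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a geocoded cohort CSV
#'
#' Reads a patient-level cohort with the fixed header written by
#' [write_cohort()] / [generate_dataset()], validates types and the 0/1
#' outcome, converts categorical columns to factors with the standard
#' reference levels (female, no hypertension, suburban, triage levels 1-2,
#' no confirmed stroke), and — for geographic input — projects
#' longitude/latitude to local planar meters via [project_lonlat()]. Rows
#' with missing values in modelled fields are excluded (complete-case) with
#' the count reported.
#'
#' @param path CSV path.
#' @param coords `"projected"` (x/y already in meters, default) or
#'   `"lonlat"` (x = longitude, y = latitude, to be projected).
#' @return a `geo_cohort` data.frame.
#' @export
load_cohort <- function(path, coords = c("projected", "lonlat")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop_validation("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols)) {
    stop_validation("cohort file is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(raw), cohort_columns)
  if (length(unknown)) {
    stop_validation("unknown column(s) in cohort file: ",
                    paste(unknown, collapse = ", "))
  }
  numeric_cols <- setdiff(cohort_columns,
                          c("unit_id", names(cohort_factor_levels)))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      stop_validation("unparseable numeric values in `", col, "` at row(s) ",
                      paste(utils::head(bad, 5), collapse = ", "))
    }
    raw[[col]] <- v
  }
  for (col in names(cohort_factor_levels)) {
    levs <- cohort_factor_levels[[col]]
    bad <- which(!is.na(raw[[col]]) & !raw[[col]] %in% levs)
    if (length(bad)) {
      stop_validation("invalid level(s) in `", col, "` at row(s) ",
                      paste(utils::head(bad, 5), collapse = ", "),
                      "; expected ", paste(levs, collapse = "/"))
    }
    raw[[col]] <- factor(raw[[col]], levels = levs)
  }
  bad_death <- which(!is.na(raw$death) & !raw$death %in% c(0, 1))
  if (length(bad_death)) {
    stop_validation("non-binary death value at row(s) ",
                    paste(utils::head(bad_death, 5), collapse = ", "))
  }
  raw$death <- as.integer(raw$death)
  if (coords == "lonlat") {
    xy <- project_lonlat(raw$x, raw$y)
    raw$x <- xy$x
    raw$y <- xy$y
  }
  complete <- stats::complete.cases(raw[, cohort_columns])
  if (any(!complete)) {
    message("excluded ", sum(!complete),
            " row(s) with missing modelled fields (complete-case analysis)")
    raw <- raw[complete, , drop = FALSE]
    rownames(raw) <- NULL
  }
  if (anyDuplicated(raw$unit_id)) stop_validation("duplicate unit_id values")
  class(raw) <- c("geo_cohort", "data.frame")
  raw
}

#' Run the full spatial mortality analysis pipeline
#'
#' Executes, in order: descriptive summary; univariate screening at
#' `threshold`; multiple logistic regression on the screened covariates;
#' auto-logistic regression (autocovariate from the observed outcome over
#' the distance band); AIC/AUC model comparison; residual Moran diagnostics
#' for both models; and, when `out_dir` is given, CSV/JSON/GeoJSON exports
#' including the per-patient autocovariate map layer. All stochastic steps
#' (permutation tests) run under `seed`, so a given (cohort, configuration,
#' seed) triple yields an identical report.
#'
#' @param cohort a `geo_cohort` (from [load_cohort()] or
#'   [generate_dataset()]) with complete modelled columns.
#' @param radius distance-band radius in meters; default
#'   [default_band_radius()] of the cohort locations.
#' @param candidates covariates entering the univariate screen.
#' @param threshold screening retention threshold (default 0.25).
#' @param n_permutations permutations for the residual Moran tests.
#' @param seed integer seed for all stochastic steps.
#' @param out_dir optional run directory for exports.
#' @return An object of class `analysis_report`: list with `descriptive`,
#'   `screen`, `fit_logistic`, `fit_autologistic`, `comparison`,
#'   `moran_logistic`, `moran_autologistic`, `autocovariate`, `weights`,
#'   `radius`, `seed` and (if written) `paths`.
#' @export
run_pipeline <- function(cohort, radius = NULL,
                         candidates = default_candidates(),
                         threshold = 0.25, n_permutations = 999,
                         seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  desc <- stage("descriptive", descriptive_table(cohort))
  message("descriptive: n = ", nrow(cohort), ", mortality ",
          attr(desc, "outcome_prevalence_pct"), "%")
  radius <- radius %||% default_band_radius(cohort)
  weights <- stage("weights", build_weights(cohort, radius = radius))
  message(sprintf("weights: radius %.1f m, %d isolated unit(s)", radius,
                  sum(weights$isolated)))
  screen <- stage("screen",
                  univariate_screen(candidates, cohort, threshold = threshold))
  sel <- selected(screen)
  message("screen: retained ", length(sel), " of ", length(candidates),
          " candidates (p < ", threshold, ")")
  if (length(sel) == 0L) {
    warning("no covariate passed the screen; fitting intercept-only models",
            call. = FALSE)
    sel <- "1"
  }
  f <- reformulate(sel, response = "death")
  fit_log <- stage("logistic", fit_logistic(f, cohort))
  fit_auto <- stage("autologistic",
                    suppressWarnings(fit_autologistic(f, cohort, weights)))
  comparison <- stage("comparison", compare_models(fit_log, fit_auto))
  moran_log <- stage("residual moran (logistic)",
                     residual_moran_check(fit_log, weights,
                                          n_permutations = n_permutations,
                                          seed = seed))
  moran_auto <- stage("residual moran (autologistic)",
                      residual_moran_check(fit_auto, weights,
                                           n_permutations = n_permutations,
                                           seed = seed + 1L))
  ac <- fit_auto$autocov
  report <- list(
    descriptive = desc, screen = screen,
    fit_logistic = fit_log, fit_autologistic = fit_auto,
    comparison = comparison,
    moran_logistic = moran_log, moran_autologistic = moran_auto,
    autocovariate = ac, weights = weights, radius = radius, seed = seed
  )
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(
      write_fit(fit_log, file.path(out_dir, "fit_logistic"),
                auc = comparison$auc_a,
                residual_moran_p = moran_log$p_value),
      write_fit(fit_auto, file.path(out_dir, "fit_autologistic"),
                auc = comparison$auc_b,
                residual_moran_p = moran_auto$p_value)
    )
    write.csv(as.data.frame(desc), file.path(out_dir, "descriptive.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(screen), file.path(out_dir, "screen.csv"),
              row.names = FALSE)
    geo <- file.path(out_dir, "autocovariate.geojson")
    export_autocovariate_map(cohort, weights, cohort$death, geo)
    report$paths <- c(paths,
                      descriptive = file.path(out_dir, "descriptive.csv"),
                      screen = file.path(out_dir, "screen.csv"),
                      autocovariate_map = geo)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Spatial mortality analysis report\n")
  cat(sprintf("  n = %d, mortality %.1f%%\n", x$fit_logistic$n,
              100 * mean(x$fit_logistic$outcome)))
  cat("  screened covariates:",
      paste(selected(x$screen), collapse = ", "), "\n")
  cat(sprintf("  logistic:      AIC %.1f  AUC %.3f  residual Moran p %.4g\n",
              x$comparison$aic_a, x$comparison$auc_a,
              x$moran_logistic$p_value))
  cat(sprintf("  auto-logistic: AIC %.1f  AUC %.3f  residual Moran p %.4g\n",
              x$comparison$aic_b, x$comparison$auc_b,
              x$moran_autologistic$p_value))
  gamma_row <- x$fit_autologistic$terms[
    x$fit_autologistic$terms$term == "autocovariate", ]
  cat(sprintf("  gamma (autocovariate): %.2f  OR %.2f (%.2f-%.2f)\n",
              gamma_row$estimate, gamma_row$or, gamma_row$ci_low,
              gamma_row$ci_high))
  cat("  preferred model:",
      c(a = "logistic", b = "auto-logistic",
        neither = "neither")[x$comparison$preferred], "\n")
  invisible(x)
}

#' Export the autocovariate as a GeoJSON point layer
#'
#' Writes an RFC 7946 FeatureCollection of Point features, one per patient,
#' with the autocovariate (and optionally local Moran statistics) as
#' properties — the machine-readable layer behind an autocovariate
#' choropleth. Coordinates are emitted as stored (the package works in
#' local projected meters; reproject before display on a geographic map).
#' Optionally aggregates the autocovariate to user-supplied zone polygons
#' by the mean over the points falling inside each zone.
#'
#' @param cohort cohort data.frame with `x`, `y` (and `unit_id`).
#' @param weights a [build_weights()] object on the cohort.
#' @param outcome 0/1 outcome vector used to compute the autocovariate.
#' @param path output `.geojson` path.
#' @param zones optional named list of polygons, each a matrix/data.frame
#'   with columns x, y (closed or open ring); requires the mgcv package for
#'   the point-in-polygon test.
#' @param lisa optional [local_morans_i()] table to attach per point.
#' @return invisibly, a list with `path` and (when `zones` given)
#'   `zone_means`, a data.frame of per-zone mean autocovariate.
#' @export
export_autocovariate_map <- function(cohort, weights, outcome, path,
                                     zones = NULL, lisa = NULL) {
  ac <- suppressWarnings(autocovariate(weights, outcome))
  ids <- cohort$unit_id %||% seq_len(nrow(cohort))
  features <- lapply(seq_along(ac), function(i) {
    props <- list(unit_id = ids[i], autocovariate = ac[i],
                  isolated = weights$isolated[i])
    if (!is.null(lisa)) {
      props$local_i <- lisa$local_i[i]
      props$p_value <- lisa$p_value[i]
      props$cluster_class <- as.character(lisa$cluster[i])
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(cohort$x[i], cohort$y[i])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  out <- list(path = path)
  if (!is.null(zones)) {
    if (!requireNamespace("mgcv", quietly = TRUE)) {
      stop_validation("zone aggregation requires the mgcv package")
    }
    if (is.null(names(zones)) || any(names(zones) == "")) {
      stop_validation("`zones` must be a *named* list of polygons")
    }
    pts <- cbind(cohort$x, cohort$y)
    means <- vapply(zones, function(poly) {
      poly <- as.matrix(as.data.frame(poly))
      if (ncol(poly) != 2 || nrow(poly) < 3 || anyNA(poly)) {
        stop_validation("each zone polygon needs >= 3 finite x/y vertices")
      }
      inside <- mgcv::in.out(poly, pts)
      if (!any(inside)) return(NA_real_)
      mean(ac[inside])
    }, numeric(1))
    out$zone_means <- data.frame(zone = names(zones),
                                 mean_autocovariate = unname(means),
                                 stringsAsFactors = FALSE)
  }
  invisible(out)
}
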