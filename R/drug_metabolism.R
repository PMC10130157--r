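#' Fit a linear LC-MS calibration curve
#'
#' Ordinary least squares of peak-area ratio (analyte / internal standard)
#' on concentration: \eqn{y = a x + b}. The fit quality is reported as
#' r-squared; curves below the conventional acceptance threshold 0.99
#' trigger a warning.
#'
#' @param conc_uM concentrations of the calibration points (µM); at least 3
#'   points with at least 2 distinct concentrations.
#' @param area_ratio matching peak-area ratios.
#' @param analyte analyte name carried as metadata.
#' @param r2_warn warn when r² falls below this (default 0.99).
#' @return object of class `"calibration_curve"`: list with `analyte`,
#'   `slope`, `intercept`, `r_squared`, `range` (µM), `n`.
#' @export
fit_calibration <- function(conc_uM, area_ratio, analyte = "analyte",
                            r2_warn = 0.99) {
  if (length(conc_uM) != length(area_ratio)) stop("length mismatch")
  if (length(conc_uM) < 3L) stop("need at least 3 calibration points")
  if (length(unique(conc_uM)) < 2L)
    stop("all calibration concentrations are equal; slope is undefined")
  fit <- stats::lm(area_ratio ~ conc_uM)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  sst <- sum((area_ratio - mean(area_ratio))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  if (r2 < r2_warn)
    warning(sprintf("calibration r-squared %.4f below %.2f for %s",
                    r2, r2_warn, analyte))
  structure(list(analyte = analyte, slope = a, intercept = b,
                 r_squared = r2, range = range(conc_uM), n = length(conc_uM)),
            class = "calibration_curve")
}

#' Calibration curve from a printed equation
#'
#' Builds a `"calibration_curve"` directly from known slope and intercept
#' (e.g. an equation printed in a report), for inverse prediction without
#' refitting.
#'
#' @param slope,intercept coefficients of y = slope * x + intercept.
#' @param analyte analyte name.
#' @param range calibration range in µM (optional).
#' @return a `"calibration_curve"`.
#' @export
calibration_curve <- function(slope, intercept, analyte = "analyte",
                              range = c(0, Inf)) {
  if (slope == 0) stop("calibration slope must be nonzero")
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = NA_real_, range = range, n = NA_integer_),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration: %s  y = %gx %s %g", x$analyte, x$slope,
              if (x$intercept < 0) "-" else "+", abs(x$intercept)))
  if (!is.na(x$r_squared)) cat(sprintf("  (r2 = %.4f, n = %d)", x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict peak-area ratio from concentration
#'
#' @param object a `"calibration_curve"`.
#' @param newdata concentrations (µM).
#' @param ... ignored.
#' @return predicted area ratios.
#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' Inverse prediction: concentration from a peak-area ratio
#'
#' \eqn{x = (y - b) / a}. Negative results are clipped to 0 with a warning
#' (signal below the calibration intercept, i.e. nondetectable); values
#' outside the calibration range are flagged by the `"extrapolated"`
#' attribute.
#'
#' @param area_ratio measured peak-area ratio(s).
#' @param curve a `"calibration_curve"` for the same analyte.
#' @param analyte optional analyte name; must match the curve when given.
#' @return concentration(s) in µM.
#' @export
quantify <- function(area_ratio, curve, analyte = NULL) {
  if (!inherits(curve, "calibration_curve")) stop("need a calibration_curve")
  if (!is.null(analyte) && !identical(analyte, curve$analyte))
    stop("analyte '", analyte, "' does not match curve for '", curve$analyte, "'")
  x <- (area_ratio - curve$intercept) / curve$slope
  neg <- x < 0
  if (any(neg)) {
    warning(sum(neg), " concentration(s) below zero clipped to 0 (",
            curve$analyte, " nondetectable)")
    x[neg] <- 0
  }
  out_of_range <- x < curve$range[1L] | x > curve$range[2L]
  attr(x, "extrapolated") <- out_of_range
  x
}

#' Fraction of drug remaining
#'
#' Measured concentration divided by the reference: either the nominal dose
#' (500 µM in the standard assay) or the time-matched no-microbiome control
#' concentration, which isolates microbial metabolism from passive
#' degradation.
#'
#' @param conc_t measured concentration(s), µM.
#' @param reference reference concentration (> 0), recycled.
#' @return fraction(s) remaining (>= 0; can exceed 1 under noise).
#' @export
remaining_fraction <- function(conc_t, reference) {
  if (any(reference <= 0)) stop("reference concentration must be positive")
  conc_t / reference
}

#' Inter-donor variation of a metabolism readout
#'
#' Mean, sample SD (n-1 denominator) and coefficient of variation of one
#' value per donor (e.g. the fraction of levodopa remaining at 24 h).
#'
#' @param values numeric vector, one per donor (>= 2 donors).
#' @return list with `mean`, `sd`, `cv`, `n`.
#' @export
interdonor_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need values from at least 2 donors")
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0) stop("mean is zero; CV undefined")
  list(mean = m, sd = s, cv = s / m, n = length(values))
}

#' Microbiome-attributable drug loss
#'
#' Difference between the time-matched no-microbiome control concentration
#' and the culture concentration, floored at 0: the part of the parent-drug
#' disappearance that passive (abiotic) degradation cannot explain.
#'
#' @param culture_conc,control_conc time-matched concentration series (µM).
#' @return attributable loss per time point (µM, >= 0).
#' @export
control_correct <- function(culture_conc, control_conc) {
  if (length(culture_conc) != length(control_conc))
    stop("culture and control series must be time-matched (equal length)")
  pmax(control_conc - culture_conc, 0)
}

#' Read an LC-MS calibration table
#'
#' @param path TSV with columns analyte, conc_uM, area_ratio.
#' @return named list of `"calibration_curve"` objects, one per analyte.
#' @export
read_calibration <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("analyte", "conc_uM", "area_ratio")
  if (!all(need %in% names(df)))
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  sp <- split(df, df$analyte)
  lapply(sp, function(x) fit_calibration(x$conc_uM, x$area_ratio,
                                         analyte = x$analyte[1L]))
}

#' Read an LC-MS measurement table
#'
#' @param path TSV with columns donor, drug, analyte, time_h, condition,
#'   area_ratio (condition one of culture/control).
#' @return validated data.frame.
#' @export
read_measurements <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("donor", "drug", "analyte", "time_h", "condition", "area_ratio")
  if (!all(need %in% names(df)))
    stop("measurement table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$condition), c("culture", "control"))
  if (length(bad) > 0L)
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(df$area_ratio < 0)) stop("negative peak-area ratio")
  df
}

#' Quantify a drug-metabolism assay
#'
#' Converts every peak-area ratio to a concentration through its analyte's
#' calibration curve, computes per-donor remaining fractions of the parent
#' drug (against the time-matched control by default, or the nominal dose),
#' and summarises inter-donor variation per drug at the final time point.
#'
#' @param measurements data.frame as from [read_measurements()].
#' @param curves named list of `"calibration_curve"` objects covering every
#'   analyte in `measurements`.
#' @param reference `"control"` (time-matched no-microbiome control) or
#'   `"nominal"`.
#' @param nominal_uM nominal dose used when `reference = "nominal"`.
#' @return list with `concentrations` (the measurement table plus a `conc_uM`
#'   column), `remaining` (donor x drug x time remaining fractions of the
#'   parent, long format), `interdonor` (per drug: mean/sd/cv of the
#'   final-time remaining fraction).
#' @export
quantify_assay <- function(measurements, curves,
                           reference = c("control", "nominal"),
                           nominal_uM = 500) {
  reference <- match.arg(reference)
  missing_a <- setdiff(unique(measurements$analyte), names(curves))
  if (length(missing_a) > 0L)
    stop("no calibration curve for analyte(s): ",
         paste(missing_a, collapse = ", "))
  conc <- suppressWarnings(vapply(seq_len(nrow(measurements)), function(i)
    as.numeric(quantify(measurements$area_ratio[i],
                        curves[[measurements$analyte[i]]])), numeric(1L)))
  measurements$conc_uM <- conc

  parent <- measurements[measurements$analyte == measurements$drug |
                           grepl("parent", measurements$analyte), , drop = FALSE]
  if (nrow(parent) == 0L) {
    # convention: the parent analyte carries the drug's own name; fall back
    # to the first analyte per drug
    first <- tapply(measurements$analyte, measurements$drug, function(a) a[1L])
    parent <- measurements[measurements$analyte ==
                             first[measurements$drug], , drop = FALSE]
  }
  cult <- parent[parent$condition == "culture", , drop = FALSE]
  ctrl <- parent[parent$condition == "control", , drop = FALSE]
  if (reference == "control") {
    key <- function(x) paste(x$drug, x$time_h)
    ctrl_mean <- tapply(ctrl$conc_uM, key(ctrl), mean)
    ref <- ctrl_mean[key(cult)]
    if (anyNA(ref)) {
      miss <- unique(key(cult)[is.na(ref)])
      stop("no time-matched control for: ", paste(miss, collapse = "; "))
    }
  } else {
    ref <- rep(nominal_uM, nrow(cult))
  }
  remaining <- data.frame(donor = cult$donor, drug = cult$drug,
                          time_h = cult$time_h,
                          remaining = remaining_fraction(cult$conc_uM, as.numeric(ref)),
                          stringsAsFactors = FALSE)
  t_final <- max(remaining$time_h)
  fin <- remaining[remaining$time_h == t_final, , drop = FALSE]
  inter <- lapply(split(fin$remaining, fin$drug), function(v)
    if (length(v) >= 2L && mean(v) != 0) interdonor_variation(v)
    else list(mean = mean(v), sd = NA_real_, cv = NA_real_, n = length(v)))
  list(concentrations = measurements, remaining = remaining,
       interdonor = inter, t_final = t_final)
}
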