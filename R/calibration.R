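# Gamma-radiation standard curve: converts percent tail DNA differences to
# absolute SSB-per-cell estimates via a dose series of known SSB yield.

#' Convert gamma dose to induced SSBs
#'
#' @param dose_gy Gamma dose in Gy (vectorised, non-negative).
#' @return Induced SSBs per cell (1000 per Gy).
#' @export
#' @examples
#' dose_to_ssb(c(0, 0.9, 9))
dose_to_ssb <- function(dose_gy) {
  if (!is.numeric(dose_gy) || any(is.na(dose_gy)) || any(dose_gy < 0)) {
    abort_validation("`dose_gy` must be non-negative and non-missing.")
  }
  SSB_PER_GY * dose_gy
}

#' Fit a gamma standard curve
#'
#' Fits the linear map between induced SSBs and the rise in percent tail DNA
#' above the unirradiated baseline. Points within `saturation_margin` of the
#' assay ceiling are excluded (the tail response flattens there and would
#' bias the slope). The fit is forced through the origin by default: zero
#' induced breaks must give zero rise.
#'
#' @param data Tibble with columns `dose_gy` and `percent_tail` (one row per
#'   measured condition; replicate rows per dose are allowed). Must include
#'   the zero dose, which defines the baseline.
#' @param cell_model Cell model the curve applies to (recorded and checked on
#'   use).
#' @param force_origin Fit without intercept (default) or with one.
#' @param t_max,saturation_margin Assay ceiling and the margin below it at
#'   which points are flagged `saturated` and excluded.
#' @return A `comet_standard_curve`: `slope_ssb_per_pct` (SSBs per percent
#'   tail DNA), its standard error, `baseline_pct`, the annotated input
#'   `data` (with `used` and `saturated` flags), `r_squared`, `cell_model`.
#' @export
fit_standard_curve <- function(data, cell_model = "fibroblast",
                               force_origin = TRUE, t_max = T_MAX,
                               saturation_margin = 2) {
  if (!all(c("dose_gy", "percent_tail") %in% names(data))) {
    abort_validation("`data` needs columns `dose_gy` and `percent_tail`.")
  }
  if (!any(data$dose_gy == 0)) {
    abort_validation("The dose series must include the 0 Gy baseline.")
  }
  get_cell_model(cell_model)
  baseline <- mean(data$percent_tail[data$dose_gy == 0])
  d <- as_tibble(data) %>%
    mutate(ssb_induced = dose_to_ssb(.data$dose_gy),
           delta_pct = .data$percent_tail - baseline,
           saturated = .data$percent_tail > t_max - saturation_margin,
           used = .data$dose_gy > 0 & !.data$saturated)
  if (length(unique(d$dose_gy[d$used])) < 3) {
    rlang::abort(
      "Fewer than 3 usable non-zero doses below saturation.",
      class = "cometscreen_insufficient_doses_error")
  }
  fitdat <- d %>% filter(.data$used)
  # regress SSBs on the tail rise: the slope is directly SSBs per percent
  fit <- if (force_origin) {
    lm(ssb_induced ~ 0 + delta_pct, data = fitdat)
  } else {
    lm(ssb_induced ~ delta_pct, data = fitdat)
  }
  sl <- coef(fit)[["delta_pct"]]
  if (!is.finite(sl) || sl <= 0) {
    rlang::abort(
      "Standard curve slope is not positive; the dose series shows no dose response.",
      class = "cometscreen_degenerate_curve_error")
  }
  sm <- summary(fit)
  structure(
    list(slope_ssb_per_pct = sl,
         slope_se = sm$coefficients["delta_pct", "Std. Error"],
         intercept = if (force_origin) 0 else coef(fit)[["(Intercept)"]],
         force_origin = force_origin,
         baseline_pct = baseline,
         r_squared = sm$r.squared,
         data = d, fit = fit, cell_model = cell_model,
         t_max = t_max, saturation_margin = saturation_margin),
    class = "comet_standard_curve"
  )
}

#' @export
print.comet_standard_curve <- function(x, ...) {
  cat("<comet_standard_curve> ", round(x$slope_ssb_per_pct, 2),
      " SSB per %T (se ", signif(x$slope_se, 3), "), baseline ",
      round(x$baseline_pct, 2), " %T, cell model ", x$cell_model,
      ", R2 ", round(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_standard_curve
#' @param x A `comet_standard_curve`.
#' @param ... Unused.
#' @export
tidy.comet_standard_curve <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"], statistic = sm[, "t value"],
         p.value = sm[, "Pr(>|t|)"])
}

#' @rdname fit_standard_curve
#' @export
glance.comet_standard_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared,
         slope_ssb_per_pct = x$slope_ssb_per_pct,
         baseline_pct = x$baseline_pct,
         n_used = sum(x$data$used),
         n_saturated = sum(x$data$saturated))
}

#' Estimate absolute SSB burdens from percent tail DNA
#'
#' Converts measured percent tail DNA to induced SSBs per cell through a
#' fitted standard curve. Conditions at or below the curve's baseline get an
#' induced estimate of 0 and a `no_change` flag rather than a negative break
#' count.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param percent_tail Numeric vector of measured percent tail DNA.
#' @param cell_model If supplied, must match the curve's cell model; the SSB
#'   to percent-tail map differs between cell lines, so applying a curve
#'   across lines is refused.
#' @return Tibble: `percent_tail`, `delta_pct`, `ssb_induced`, `no_change`.
#' @export
estimate_ssb <- function(curve, percent_tail, cell_model = NULL) {
  stopifnot(inherits(curve, "comet_standard_curve"))
  if (!is.null(cell_model) && !identical(cell_model, curve$cell_model)) {
    abort_validation(paste0(
      "Standard curve was fitted on '", curve$cell_model,
      "' but `cell_model` is '", cell_model,
      "'; refusing to convert across cell models."))
  }
  if (!is.numeric(percent_tail) || any(is.na(percent_tail))) {
    abort_validation("`percent_tail` must be numeric and non-missing.")
  }
  delta <- percent_tail - curve$baseline_pct
  raw <- curve$intercept + curve$slope_ssb_per_pct * delta
  tibble(percent_tail = percent_tail, delta_pct = delta,
         ssb_induced = pmax(raw, 0),
         no_change = raw <= 0)
}
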