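# Statistics on well-level summaries: the biological replicate is the
# microwell (one macrowell of the array), so comet-level records are first
# collapsed to well medians and all inference runs on those.

#' Collapse comet records to well medians
#'
#' @param records Comet-record tibble with `condition`, `well` and the value
#'   column.
#' @param value Name of the value column (default `"percent_tail"`).
#' @return Tibble: `condition`, `well`, `n_comets`, `value` (the median).
#' @export
well_medians <- function(records, value = "percent_tail") {
  if (!all(c("condition", "well", value) %in% names(records))) {
    abort_validation("`records` needs `condition`, `well` and the value column.")
  }
  records %>%
    group_by(.data$condition, .data$well) %>%
    summarise(n_comets = dplyr::n(),
              value = stats::median(.data[[value]], na.rm = TRUE),
              .groups = "drop")
}

#' Summarise conditions from comet records
#'
#' Mean and standard error across well medians, the proper replicate unit.
#'
#' @inheritParams well_medians
#' @return Tibble: `condition`, `n_wells`, `n_comets`, `mean_pct`, `sem`.
#' @export
summarize_conditions <- function(records, value = "percent_tail") {
  well_medians(records, value) %>%
    group_by(.data$condition) %>%
    summarise(n_wells = dplyr::n(), n_comets = sum(.data$n_comets),
              mean_pct = mean(.data$value),
              sem = sd(.data$value) / sqrt(dplyr::n()),
              .groups = "drop")
}

# Dunnett many-to-one adjusted p-values for t statistics with the classical
# correlation structure; shared by the data path and the null simulation so
# both exercise the same code.
dunnett_adjust_p <- function(tstat, n_trt, n_ctl, df,
                             alternative = c("two.sided", "greater")) {
  alternative <- arg_match(alternative)
  k <- length(tstat)
  lam <- sqrt(n_trt / (n_trt + n_ctl))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  # 2.5e-4 absolute error is an order of magnitude below any decision
  # tolerance used on these p-values; tightening further only costs time
  alg <- mvtnorm::GenzBretz(abseps = 2.5e-4, maxpts = 25000)
  p <- purrr::map_dbl(tstat, function(t0) {
    if (!is.finite(t0)) return(NA_real_)
    if (alternative == "two.sided") {
      1 - mvtnorm::pmvt(lower = rep(-abs(t0), k), upper = rep(abs(t0), k),
                        df = df, corr = corr, algorithm = alg)[1]
    } else {
      1 - mvtnorm::pmvt(lower = rep(-Inf, k), upper = rep(t0, k),
                        df = df, corr = corr, algorithm = alg)[1]
    }
  })
  pmin(pmax(p, 0), 1)
}

#' Dunnett many-to-one comparisons against a control
#'
#' Compares every treated condition to the shared control with familywise
#' error control over the whole family, on well-level values. The parametric
#' method evaluates the exact equicorrelated multivariate-t tail
#' (`mvtnorm::pmvt`); the permutation method uses a seeded max-|t| label
#' permutation and needs no normality assumption.
#'
#' @param wells Tibble of well-level values: `condition`, `well`, `value`
#'   (as from [well_medians()]).
#' @param control Name of the control condition.
#' @param method `"parametric"` (default) or `"permutation"`.
#' @param alternative `"two.sided"` (default) or `"greater"` (treated above
#'   control).
#' @param n_perm Number of permutations for the permutation method.
#' @param seed Seed for the permutation method (required there, ignored
#'   otherwise).
#' @return Tibble with one row per treated condition: `condition`,
#'   `estimate` (mean difference from control), `statistic`, `df`,
#'   `p_adjusted`. Attributes: `omnibus_p` (one-way ANOVA F-test across all
#'   conditions), `control`, `method`.
#' @export
dunnett_vs_control <- function(wells, control,
                               method = c("parametric", "permutation"),
                               alternative = c("two.sided", "greater"),
                               n_perm = 2000, seed = NULL) {
  method <- arg_match(method)
  alternative <- arg_match(alternative)
  if (!all(c("condition", "value") %in% names(wells))) {
    abort_validation("`wells` needs `condition` and `value` columns.")
  }
  if (!control %in% wells$condition) {
    abort_validation(paste0("Control condition '", control,
                            "' not present in `wells`."))
  }
  conds <- unique(wells$condition)
  trt <- setdiff(conds, control)
  if (length(trt) == 0) {
    abort_validation("No treated conditions to compare against the control.")
  }
  g <- length(conds)
  ns <- purrr::map_dbl(conds, ~ sum(wells$condition == .x))
  if (any(ns < 2)) {
    abort_validation("Every condition needs at least 2 wells.")
  }
  means <- purrr::map_dbl(conds, ~ mean(wells$value[wells$condition == .x]))
  names(means) <- names(ns) <- conds
  df <- nrow(wells) - g
  mse <- sum(purrr::map_dbl(conds, function(cd) {
    v <- wells$value[wells$condition == cd]
    sum((v - mean(v))^2)
  })) / df
  est <- means[trt] - means[control]
  se <- sqrt(mse * (1 / ns[trt] + 1 / ns[control]))
  tstat <- est / se

  omnibus_p <- {
    fit <- aov(value ~ factor(condition), data = wells)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }

  if (method == "parametric") {
    p_adj <- dunnett_adjust_p(tstat, ns[trt], ns[control], df, alternative)
  } else {
    if (is.null(seed)) {
      abort_validation("The permutation method requires a `seed`.")
    }
    keep_stat <- function(v) {
      m <- purrr::map_dbl(conds, ~ mean(v[wells$condition == .x]))
      names(m) <- conds
      ms <- sum(purrr::map_dbl(conds, function(cd) {
        x <- v[wells$condition == cd]
        sum((x - mean(x))^2)
      })) / df
      (m[trt] - m[control]) / sqrt(ms * (1 / ns[trt] + 1 / ns[control]))
    }
    obs <- if (alternative == "two.sided") abs(tstat) else tstat
    maxes <- withr_seed(seed, {
      purrr::map_dbl(seq_len(n_perm), function(b) {
        tb <- keep_stat(sample(wells$value))
        if (alternative == "two.sided") max(abs(tb)) else max(tb)
      })
    })
    p_adj <- purrr::map_dbl(obs, ~ (1 + sum(maxes >= .x)) / (n_perm + 1))
  }

  out <- tibble(condition = trt, estimate = unname(est),
                statistic = unname(tstat), df = df,
                p_adjusted = unname(p_adj))
  attr(out, "omnibus_p") <- omnibus_p
  attr(out, "control") <- control
  attr(out, "method") <- method
  out
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate the familywise error rate of the Dunnett procedure
#'
#' Draws null datasets (all groups sharing one normal distribution), runs
#' [dunnett_vs_control()] on each, and reports the fraction of families with
#' any adjusted p-value below `alpha` -- the realised familywise error rate,
#' which should not exceed `alpha`.
#'
#' @param n_treated Number of treated groups.
#' @param n_wells Wells per group.
#' @param n_sims Number of simulated families (at least 2000 recommended).
#' @param alpha Nominal level.
#' @param seed RNG seed.
#' @param alternative Passed to [dunnett_vs_control()].
#' @return List: `fwer`, `n_sims`, `alpha`, `n_rejections`.
#' @export
dunnett_fwer_sim <- function(n_treated = 4, n_wells = 3, n_sims = 2000,
                             alpha = 0.05, seed = 1,
                             alternative = "two.sided") {
  conds <- c("control", paste0("trt", seq_len(n_treated)))
  design <- tidyr::expand_grid(condition = conds, well = seq_len(n_wells))
  hits <- withr_seed(seed, {
    purrr::map_lgl(seq_len(n_sims), function(i) {
      wells <- design %>% mutate(value = rnorm(dplyr::n()))
      res <- dunnett_vs_control(wells, "control",
                                alternative = alternative)
      any(res$p_adjusted < alpha)
    })
  })
  list(fwer = mean(hits), n_sims = n_sims, alpha = alpha,
       n_rejections = sum(hits))
}

#' Two-way ANOVA with Bonferroni-corrected cell contrasts
#'
#' Fits `value ~ a * b` on well-level data and tests the difference between
#' the two levels of `a` within every level of `b`, multiplying each p-value
#' by the total number of contrasts (Bonferroni over the whole family).
#'
#' @param wells Tibble with `value` and the two factor columns.
#' @param a Name of the two-level factor of interest (e.g. inhibitor arm).
#' @param b Name of the stratifying factor (e.g. time point or dose).
#' @return Tibble: `level_b`, `estimate`, `se`, `df`, `p_raw`, `p_adjusted`
#'   (capped at 1). Attribute `anova` holds the two-way ANOVA table.
#' @export
twoway_bonferroni <- function(wells, a, b) {
  if (!all(c(a, b, "value") %in% names(wells))) {
    abort_validation("`wells` needs `value` and both factor columns.")
  }
  d <- wells %>%
    mutate(.a = factor(.data[[a]]), .b = factor(.data[[b]]))
  if (nlevels(d$.a) != 2) {
    abort_validation("`a` must have exactly two levels.")
  }
  fit <- aov(value ~ .a * .b, data = d)
  emm <- emmeans::emmeans(fit, ~ .a | .b)
  ctr <- summary(emmeans::contrast(emm, method = "revpairwise"),
                 adjust = "none")
  m <- nrow(ctr)
  out <- tibble(level_b = as.character(ctr$.b),
                estimate = ctr$estimate, se = ctr$SE, df = ctr$df,
                p_raw = ctr$p.value,
                p_adjusted = pmin(ctr$p.value * m, 1))
  attr(out, "anova") <- summary(fit)
  out
}

#' Paired t-test across matched wells
#'
#' Paired comparison of two conditions measured on the same wells, with the
#' degenerate edge cases handled explicitly: identical values in every well
#' give p = 1 (no evidence of a difference), and a constant non-zero
#' difference gives p = 0 with a warning (the t statistic is undefined but
#' the direction is unambiguous).
#'
#' @param wells Tibble with `condition`, `well`, `value`; exactly two
#'   conditions sharing the same wells.
#' @param cond1,cond2 The two condition names; the difference is
#'   `cond2 - cond1`.
#' @return Tibble: `estimate`, `statistic`, `df`, `p_value`, `n_pairs`.
#' @export
paired_t_wells <- function(wells, cond1, cond2) {
  w <- wells %>% filter(.data$condition %in% c(cond1, cond2))
  wide <- w %>%
    select("condition", "well", "value") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (!all(c(cond1, cond2) %in% names(wide)) ||
      any(is.na(wide[[cond1]])) || any(is.na(wide[[cond2]]))) {
    abort_validation("Both conditions must be measured on the same wells.")
  }
  diffs <- wide[[cond2]] - wide[[cond1]]
  n <- length(diffs)
  if (n < 2) abort_validation("Need at least 2 paired wells.")
  if (sd(diffs) == 0) {
    if (all(diffs == 0)) {
      return(tibble(estimate = 0, statistic = 0, df = n - 1,
                    p_value = 1, n_pairs = n))
    }
    warn("Constant non-zero paired difference: t statistic undefined, reporting p = 0.")
    return(tibble(estimate = mean(diffs), statistic = Inf * sign(mean(diffs)),
                  df = n - 1, p_value = 0, n_pairs = n))
  }
  tt <- t.test(diffs)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, n_pairs = n)
}

#' Call genotoxicity for one chemical
#'
#' Decision rule for a dose series against its vehicle control: the family
#' must pass the omnibus ANOVA gate, and a chemical is positive when any
#' scored dose shows a significant *increase* over the control after Dunnett
#' adjustment. There is no formal viability threshold in standard comet
#' scoring, so none is applied by default; setting `min_viability` (e.g. to
#' 0.5) excludes doses below it, since heavy cytotoxicity can fragment DNA
#' and overstate genotoxicity. The returned row counts how many doses fall
#' below 50 % viability either way.
#'
#' @param dunnett Result of [dunnett_vs_control()] on the dose series (rows
#'   are dose conditions).
#' @param viability Named numeric vector of viability fractions, names
#'   matching the `condition` column.
#' @param alpha Significance level.
#' @param min_viability Minimum viability for a dose to be scored; the
#'   default 0 scores every dose.
#' @return Tibble (one row): `call` (`"positive"`/`"negative"`),
#'   `lowest_effect_condition` (lowest-dose significant condition by row
#'   order, `NA` if negative), `n_doses_scored`, `n_doses_excluded`,
#'   `n_below_half_viability`, `omnibus_p`.
#' @export
call_genotoxicity <- function(dunnett, viability, alpha = 0.05,
                              min_viability = 0) {
  if (is.null(names(viability)) ||
      !all(dunnett$condition %in% names(viability))) {
    abort_validation("`viability` must be named by every dose condition.")
  }
  viab <- viability[dunnett$condition]
  scored <- dunnett %>%
    mutate(viability = unname(viab)) %>%
    filter(.data$viability >= min_viability)
  omnibus_p <- attr(dunnett, "omnibus_p") %||% 0
  sig <- scored %>%
    filter(.data$p_adjusted < alpha, .data$estimate > 0)
  positive <- nrow(sig) > 0 && omnibus_p < alpha
  tibble(
    call = if (positive) "positive" else "negative",
    lowest_effect_condition = if (positive) sig$condition[1] else NA_character_,
    n_doses_scored = nrow(scored),
    n_doses_excluded = nrow(dunnett) - nrow(scored),
    n_below_half_viability = sum(viab < 0.5),
    omnibus_p = omnibus_p
  )
}
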