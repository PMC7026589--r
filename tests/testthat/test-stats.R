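test_that("well medians and condition summaries are computed correctly", {
  recs <- tibble::tibble(
    condition = rep(c("a", "b"), each = 6),
    well = rep(rep(1:2, each = 3), 2),
    percent_tail = c(1, 2, 9, 4, 5, 6, 10, 20, 30, 40, 50, 60))
  wm <- well_medians(recs)
  expect_equal(wm$value[wm$condition == "a" & wm$well == 1], 2)
  expect_equal(wm$value[wm$condition == "b" & wm$well == 2], 50)
  sm <- summarize_conditions(recs)
  expect_equal(sm$mean_pct[sm$condition == "a"], mean(c(2, 5)))
  expect_equal(sm$sem[sm$condition == "a"], sd(c(2, 5)) / sqrt(2))
  expect_equal(sm$n_wells, c(2L, 2L))
  expect_error(well_medians(recs %>% dplyr::select(-well)),
               class = "cometscreen_validation_error")
})

test_that("parametric Dunnett matches the multcomp oracle", {
  wells <- null_wells(n_groups = 5, n_wells = 4, seed = 7,
                      shift = c(trt2 = 1.5))
  own <- dunnett_vs_control(wells, "control")
  fit <- stats::aov(value ~ condition,
                    data = wells %>%
                      dplyr::mutate(condition = factor(condition)))
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(
    condition = "Dunnett"))
  oracle <- summary(glht, test = multcomp::adjusted("single-step"))
  est_o <- as.vector(oracle$test$coefficients)
  p_o <- as.vector(oracle$test$pvalues)
  expect_equal(own$estimate, est_o, tolerance = 1e-9)
  expect_equal(own$p_adjusted, p_o, tolerance = 0.005)
  expect_lt(attr(own, "omnibus_p"), 0.05)
})

test_that("Dunnett input validation and structure", {
  wells <- null_wells()
  expect_error(dunnett_vs_control(wells, "nope"),
               class = "cometscreen_validation_error")
  single <- wells %>% dplyr::filter(well == 1)
  expect_error(dunnett_vs_control(single, "control"),
               class = "cometscreen_validation_error")
  res <- dunnett_vs_control(wells, "control")
  expect_setequal(res$condition, paste0("trt", 1:4))
  expect_true(all(res$p_adjusted >= 0 & res$p_adjusted <= 1))
  expect_identical(attr(res, "control"), "control")
})

test_that("permutation Dunnett is seeded and tracks the parametric one", {
  wells <- null_wells(n_groups = 4, n_wells = 5, seed = 11,
                      shift = c(trt1 = 2))
  p1 <- dunnett_vs_control(wells, "control", method = "permutation",
                           n_perm = 999, seed = 5)
  p2 <- dunnett_vs_control(wells, "control", method = "permutation",
                           n_perm = 999, seed = 5)
  expect_identical(p1$p_adjusted, p2$p_adjusted)
  expect_error(dunnett_vs_control(wells, "control", method = "permutation"),
               class = "cometscreen_validation_error")  # seed required
  pp <- dunnett_vs_control(wells, "control")
  # the strongly shifted group is significant under both routes
  expect_lt(p1$p_adjusted[p1$condition == "trt1"], 0.05)
  expect_lt(pp$p_adjusted[pp$condition == "trt1"], 0.05)
  # null groups agree loosely between routes
  expect_equal(p1$p_adjusted[p1$condition != "trt1"],
               pp$p_adjusted[pp$condition != "trt1"], tolerance = 0.2)
})

test_that("a quick null simulation keeps the familywise rate near level", {
  sim <- dunnett_fwer_sim(n_treated = 4, n_wells = 3, n_sims = 300,
                          seed = 21)
  # loose bound for the short run; the full >= 2000-replicate check is an
  # acceptance criterion
  expect_lte(sim$fwer, 0.05 + 0.035)
  expect_identical(sim$n_sims, 300)
})

test_that("two-way Bonferroni contrasts control the whole family", {
  set.seed(33)
  d <- tidyr::expand_grid(arm = c("ctl", "trt"), time = c(1, 4, 24),
                          well = 1:4) %>%
    dplyr::mutate(value = rnorm(dplyr::n(), sd = 0.5) +
                    ifelse(arm == "trt" & time == 24, 5, 0))
  res <- twoway_bonferroni(d, "arm", "time")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, pmin(res$p_raw * 3, 1))
  expect_lt(res$p_adjusted[res$level_b == "24"], 0.05)
  expect_gt(min(res$p_adjusted[res$level_b != "24"]), 0.05)
  expect_error(twoway_bonferroni(d %>% dplyr::mutate(arm = "one"),
                                 "arm", "time"),
               class = "cometscreen_validation_error")
})

test_that("paired t-test handles regular and degenerate cases", {
  base <- tibble::tibble(condition = "a", well = 1:6,
                         value = c(10, 11, 12, 13, 14, 15))
  # regular case agrees with stats::t.test
  d2 <- dplyr::bind_rows(base, tibble::tibble(
    condition = "b", well = 1:6, value = c(12, 12, 15, 13, 17, 16)))
  res <- paired_t_wells(d2, "a", "b")
  ref <- t.test(d2$value[d2$condition == "b"],
                d2$value[d2$condition == "a"], paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$estimate, unname(ref$estimate))
  # identical values: p = 1
  same <- dplyr::bind_rows(base, base %>% dplyr::mutate(condition = "b"))
  expect_equal(paired_t_wells(same, "a", "b")$p_value, 1)
  # constant non-zero difference: p = 0 with a warning
  const <- dplyr::bind_rows(base, base %>%
                              dplyr::mutate(condition = "b",
                                            value = value + 2))
  expect_warning(res0 <- paired_t_wells(const, "a", "b"), "Constant")
  expect_equal(res0$p_value, 0)
  expect_equal(res0$estimate, 2)
})

test_that("genotoxicity calls gate on omnibus, direction and viability", {
  mk <- function(p, est, omnibus = 1e-4) {
    d <- tibble::tibble(condition = paste0("d", seq_along(p)),
                        estimate = est, statistic = est, df = 10,
                        p_adjusted = p)
    attr(d, "omnibus_p") <- omnibus
    d
  }
  viab <- c(d1 = 1, d2 = 0.9, d3 = 0.3)
  # significant increase: positive, lowest effective dose reported
  pos <- call_genotoxicity(mk(c(0.2, 0.01, 0.001), c(1, 5, 9)), viab)
  expect_identical(pos$call, "positive")
  expect_identical(pos$lowest_effect_condition, "d2")
  expect_identical(pos$n_below_half_viability, 1L)
  # same but only the low-viability dose is significant and a 50% gate is on
  gated <- call_genotoxicity(mk(c(0.2, 0.2, 0.001), c(1, 1, 9)), viab,
                             min_viability = 0.5)
  expect_identical(gated$call, "negative")
  expect_identical(gated$n_doses_excluded, 1L)
  # significant *decrease* is not a positive
  dec <- call_genotoxicity(mk(c(0.001, 0.5, 0.5), c(-5, 0, 0)), viab)
  expect_identical(dec$call, "negative")
  # failing the omnibus gate blocks the call
  omn <- call_genotoxicity(mk(c(0.01, 0.5, 0.5), c(5, 0, 0), omnibus = 0.4),
                           viab)
  expect_identical(omn$call, "negative")
  expect_error(call_genotoxicity(mk(0.5, 1), c(1)),
               class = "cometscreen_validation_error")
})
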