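test_that("damage_scenario validates its inputs with classed errors", {
  expect_error(damage_scenario("uvc", dose = -1),
               class = "cometscreen_validation_error")
  expect_error(damage_scenario("uvc", dose = 5, time_h = -1),
               class = "cometscreen_validation_error")
  expect_error(damage_scenario("uvc", dose = 5, vehicle = TRUE),
               class = "cometscreen_validation_error")
  expect_error(damage_scenario("not_an_agent", 1) %>% lesions_from_dose(),
               class = "cometscreen_config_error")
  expect_error(damage_scenario("uvc", 1, cell_model = "hela"),
               class = "cometscreen_config_error")
  expect_error(damage_scenario("uvc", 1, cyp_scalars = c(CYP3A4 = -1)),
               class = "cometscreen_validation_error")
  expect_s3_class(damage_scenario("uvc", 5), "comet_scenario")
})

test_that("gamma lesion yield is exactly 1000 SSBs per Gy", {
  for (gy in c(0.9, 1.8, 3.6, 9)) {
    sc <- damage_scenario("gamma", gy, time_h = 0)
    expect_identical(lesions_from_dose(sc)$ssb, 1000 * gy)
  }
})

test_that("inert agents induce no lesions at any dose", {
  for (agent in c("vehicle", "pca")) {
    les <- lesions_from_dose(
      damage_scenario(agent, 0, time_h = 24, cell_model = "heparg",
                      vehicle = TRUE))
    expect_identical(les$bulky + les$ber + les$ssb + les$crosslinks, 0)
  }
  les <- lesions_from_dose(
    damage_scenario("pca", 5, time_h = 24, cell_model = "heparg"))
  expect_identical(les$bulky + les$ber + les$ssb + les$crosslinks, 0)
})

test_that("metabolic activation follows the cell model's CYP scalars", {
  bap_in <- function(cm, ...) {
    lesions_from_dose(damage_scenario("bap", 10, time_h = 24,
                                      cell_model = cm, ...))$bulky
  }
  expect_gt(bap_in("heparg"), 0)
  expect_identical(bap_in("tk6"), 0)        # no CYP1A2 in TK6
  expect_equal(bap_in("hepg2") / bap_in("heparg"), 0.1)  # 10x lower CYP1A2
  expect_identical(bap_in("heparg", anf = TRUE), 0)      # ANF zeroes CYP1A2

  afb1_in <- function(cm, ...) {
    lesions_from_dose(damage_scenario("afb1", 3, time_h = 24,
                                      cell_model = cm, ...))$bulky
  }
  expect_equal(afb1_in("hepg2") / afb1_in("heparg"), 0.01)  # 100x lower 3A4
  expect_equal(afb1_in("heparg", ket = TRUE) / afb1_in("heparg"), 0.01)
})

test_that("pulse kinetics respect mass balance and limits", {
  n <- 1000
  # never more intermediates than lesions
  for (t in c(0.1, 0.5, 1, 5, 24)) {
    expect_lte(pulse_intermediates(n, 0.5, 60, t), n)
    expect_gte(pulse_intermediates(n, 0.5, 60, t), 0)
  }
  # blocked resolution: intermediates approach the full lesion count
  expect_equal(pulse_intermediates(n, 0.5, 0, 1e3), n, tolerance = 1e-9)
  # k_res ~ k_inc limit is continuous
  expect_equal(pulse_intermediates(n, 0.5, 0.5 + 1e-10, 2),
               pulse_intermediates(n, 0.5, 0.5 - 1e-10, 2),
               tolerance = 1e-5)
  # fast resolution clears everything eventually
  expect_lt(pulse_intermediates(n, 0.5, 60, 100), 1e-6)
})

test_that("steady-state trapping scales inversely with the resolution rate", {
  expect_equal(flux_intermediates(600, 60, 24), 10)
  expect_equal(flux_intermediates(600, 60 * 0.03, 24), 10 / 0.03)
  expect_equal(flux_intermediates(600, 0, 2), 1200)  # linear when blocked
})

test_that("tail transform hits the background and saturation landmarks", {
  expect_equal(tail_percent_from_ssb(BASELINE_SSB), 10)
  expect_equal(tail_percent_from_ssb(1e9), 75)
  # monotone in ssb: strictly increasing below saturation, never decreasing
  s <- seq(2000, 8000, length.out = 50)
  expect_true(all(diff(tail_percent_from_ssb(s)) > 0))
  s_hi <- seq(2000, 50000, length.out = 50)
  expect_true(all(diff(tail_percent_from_ssb(s_hi)) >= 0))
  # crosslinks suppress the induced component only
  expect_lt(tail_percent_from_ssb(20000, crosslinks = 5000),
            tail_percent_from_ssb(20000))
  expect_equal(tail_percent_from_ssb(BASELINE_SSB, crosslinks = 1e6), 10)
  expect_error(tail_percent_from_ssb(-5))
})

test_that("NER genotypes behave as designed", {
  uv <- function(genotype, hu = FALSE) {
    model_tail_percent(damage_scenario("uvc", 5, time_h = 1,
                                       genotype = genotype, hu_arac = hu))
  }
  # incision-null: no intermediates, with or without trapping
  expect_equal(uv("XPG_null"), 10)
  expect_equal(uv("XPG_null", hu = TRUE), 10)
  expect_equal(uv("XPA_null"), 10)
  # ligation-blocked catalytic mutant: trapped even without inhibitors
  expect_gt(uv("XPG_E791A"), 70)
  # wild type needs the inhibitors to show the bulky damage
  expect_lt(uv("WT"), 25)
  expect_gt(uv("WT", hu = TRUE), 70)
})

test_that("HU/AraC trapping amplifies a continuous exposure by 1/f_inhib", {
  base <- damage_scenario("cp", 10, time_h = 24, cell_model = "heparg")
  trap <- damage_scenario("cp", 10, time_h = 24, cell_model = "heparg",
                          hu_arac = TRUE)
  les <- lesions_from_dose(base)
  induced0 <- ssb_at_time(les, base) - BASELINE_SSB
  induced1 <- ssb_at_time(lesions_from_dose(trap), trap) - BASELINE_SSB
  expect_equal(induced1 / induced0, 1 / 0.03, tolerance = 1e-9)
})

test_that("viability is monotone decreasing and includes the HU/AraC cost", {
  d <- c(0.5, 1, 2, 4, 8)
  v <- purrr::map_dbl(d, function(x) {
    scenario_viability(damage_scenario("cam", x, time_h = 24,
                                       cell_model = "heparg"))
  })
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0 & v <= 1))
  veh <- damage_scenario("vehicle", 0)
  expect_equal(scenario_viability(veh), 1)
  veh_hu <- damage_scenario("vehicle", 0, hu_arac = TRUE)
  expect_equal(scenario_viability(veh_hu), 0.85)
  # ~50% death at 5 mM PCA
  expect_equal(scenario_viability(
    damage_scenario("pca", 5, time_h = 24, cell_model = "heparg")), 0.5)
})

test_that("scenario preset and YAML config round trip", {
  sc <- scenario_preset("uv_1h_huarac")
  expect_s3_class(sc, "comet_scenario")
  expect_error(scenario_preset("nope"), class = "cometscreen_config_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenarios(list(a = sc, b = scenario_preset("vehicle_wt")), path)
  back <- read_scenarios(path)
  expect_named(back, c("a", "b"))
  expect_equal(model_tail_percent(back$a), model_tail_percent(sc))
  expect_true(back$a$inhibitors$hu_arac)
})
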