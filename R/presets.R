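# Shipped scenario presets: the benchmark conditions the package is
# calibrated against, plus the nine-chemical screen design.

.scenario_presets <- function() {
  list(
    vehicle_wt = damage_scenario("vehicle", 0, time_h = 1,
                                 label = "vehicle_wt"),
    huarac_default = damage_scenario("vehicle", 0, time_h = 1,
                                     hu_arac = TRUE,
                                     label = "huarac_default"),
    uv_1h = damage_scenario("uvc", 5, time_h = 1, label = "uv_1h"),
    uv_1h_huarac = damage_scenario("uvc", 5, time_h = 1, hu_arac = TRUE,
                                   label = "uv_1h_huarac"),
    uv_1h_xpg_null = damage_scenario("uvc", 5, time_h = 1,
                                     genotype = "XPG_null",
                                     label = "uv_1h_xpg_null"),
    uv_1h_xpg_null_huarac = damage_scenario("uvc", 5, time_h = 1,
                                            genotype = "XPG_null",
                                            hu_arac = TRUE,
                                            label = "uv_1h_xpg_null_huarac"),
    uv_1h_e791a = damage_scenario("uvc", 5, time_h = 1,
                                  genotype = "XPG_E791A",
                                  label = "uv_1h_e791a"),
    afb1_heparg_huarac = damage_scenario("afb1", 3, time_h = 24,
                                         cell_model = "heparg",
                                         hu_arac = TRUE,
                                         label = "afb1_heparg_huarac"),
    afb1_heparg_ket = damage_scenario("afb1", 3, time_h = 24,
                                      cell_model = "heparg", hu_arac = TRUE,
                                      ket = TRUE,
                                      label = "afb1_heparg_ket"),
    afb1_tk6_huarac = damage_scenario("afb1", 3, time_h = 24,
                                      cell_model = "tk6", hu_arac = TRUE,
                                      label = "afb1_tk6_huarac")
  )
}

#' Named scenario presets
#'
#' The calibration landmarks of the model: untreated wild type (~10 %T),
#' 5 J/m2 UV-C at 1 h (~20 %T), the same pulse with HU/AraC trapping
#' (73-78 %T plateau), the NER-null and ligation-blocked genotypes, and the
#' aflatoxin B1 scenarios across cell models.
#'
#' @param name Preset name; omit to list all presets.
#' @return A [damage_scenario()] (or a named list of them).
#' @export
#' @examples
#' model_tail_percent(scenario_preset("uv_1h_huarac"))
scenario_preset <- function(name = NULL) {
  presets <- .scenario_presets()
  if (is.null(name)) return(presets)
  p <- presets[[name]]
  if (is.null(p)) {
    abort_config(paste0("Unknown scenario preset '", name, "'."))
  }
  p
}

#' Nine-chemical screen design
#'
#' Dose series for the genotoxicity screen of nine in-vivo genotoxins on the
#' metabolically competent hepatic cell model, incubated 24 h, run with and
#' without HU/AraC trapping.
#'
#' @return A tibble with one row per chemical: `chemical`, `doses` (list
#'   column), `dose_unit`, `cell_model`, `time_h`.
#' @export
screen_presets <- function() {
  tibble::tribble(
    ~chemical,    ~doses,                              ~dose_unit,
    "etoposide",  c(1.25, 2.5, 5, 10),                 "uM",
    "dat24",      c(1.25, 2.5, 5, 10),                 "mM",
    "cp",         c(1.25, 2.5, 5, 10),                 "mM",
    "pca",        c(0.625, 1.25, 2.5, 5),              "mM",
    "ndma",       c(2.5, 5, 10, 20),                   "mM",
    "hq",         c(0.33 / 8, 0.33 / 4, 0.33 / 2, 0.33), "mM",
    "bap",        c(1.25, 2.5, 5, 10),                 "uM",
    "cam",        c(3.1 / 8, 3.1 / 4, 3.1 / 2, 3.1),   "mM",
    "cisplatin",  c(2.5, 5, 10, 20),                   "uM"
  ) %>%
    mutate(cell_model = "heparg", time_h = 24)
}

# ---- scenario configuration files ------------------------------------------

#' Read scenarios from a YAML configuration file
#'
#' The file holds one block per scenario under a top-level `scenarios:` key;
#' each block accepts the arguments of [damage_scenario()] (`agent`, `dose`,
#' `time_h`, `genotype`, `cell_model`, `hu_arac`, `ket`, `anf`, `label`).
#' See `system.file("extdata", "example_screen.yaml",
#' package = "cometscreen")`.
#'
#' @param path Path to a YAML file.
#' @return Named list of [damage_scenario()] objects.
#' @export
read_scenarios <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) {
    abort_config("Configuration file has no `scenarios:` block.")
  }
  out <- purrr::imap(cfg$scenarios, function(block, nm) {
    args <- block
    args$label <- args$label %||% nm
    do.call(damage_scenario, args)
  })
  out
}

#' Write scenarios to a YAML configuration file
#'
#' @param scenarios Named list of [damage_scenario()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  blocks <- purrr::map(scenarios, function(s) {
    list(agent = s$agent, dose = s$dose, time_h = s$time_h,
         genotype = s$genotype, cell_model = s$cell_model,
         hu_arac = s$inhibitors$hu_arac, ket = s$inhibitors$ket,
         anf = s$inhibitors$anf, label = s$label)
  })
  yaml::write_yaml(list(scenarios = blocks), path)
  invisible(path)
}
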