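# End-to-end screening: simulate comet-level data for dose series (with or
# without full image rendering), summarise, test against vehicle, and call
# genotoxicity per chemical and inhibitor arm.

#' Draw comet-level percent tail values for one condition
#'
#' The sampling model shared by the statistical ("model") path and the image
#' renderer: each well's mean percent tail is the condition's true value plus
#' a normal well effect, and individual comets scatter around the well mean
#' with a Beta distribution of fixed dispersion. Uses the current RNG stream.
#'
#' @param true_pct True mean percent tail DNA of the condition.
#' @param n_wells Number of replicate wells.
#' @param comets_per_well Comets scored per well.
#' @param sd_well Between-well standard deviation, percent tail DNA.
#' @param dispersion Beta dispersion of comet-to-comet scatter.
#' @return Tibble: `well`, `comet`, `percent_tail`.
#' @export
simulate_condition_percents <- function(true_pct, n_wells = 3,
                                        comets_per_well = 150,
                                        sd_well = 2.5, dispersion = 0.04) {
  stopifnot(true_pct >= 0, true_pct <= 100, n_wells >= 1,
            comets_per_well >= 1)
  purrr::map(seq_len(n_wells), function(w) {
    mu <- (true_pct + rnorm(1, 0, sd_well)) / 100
    mu <- min(max(mu, 0.005), 0.995)
    kap <- beta_kappa(mu, dispersion)
    tibble(well = w, comet = seq_len(comets_per_well),
           percent_tail = 100 * rbeta(comets_per_well,
                                      mu * kap, (1 - mu) * kap))
  }) %>% purrr::list_rbind()
}

screen_condition_label <- function(dose, unit) {
  if (dose == 0) "vehicle" else paste0(format(dose, trim = TRUE), "_", unit)
}

#' Run the simulated nine-chemical genotoxicity screen
#'
#' For every chemical in the design and both inhibitor arms (with and
#' without HU/AraC repair trapping), simulates the dose series alongside a
#' vehicle control, collapses to well medians, runs Dunnett many-to-one
#' tests against the vehicle, and calls each chemical/arm combination with
#' the viability-gated decision rule of [call_genotoxicity()].
#'
#' @param seed RNG seed for the whole screen (one stream).
#' @param design Screen design tibble (default [screen_presets()]).
#' @param n_wells,comets_per_well,sd_well,dispersion Sampling-model
#'   parameters (see [simulate_condition_percents()]).
#' @param alpha Significance level for calls.
#' @param min_viability Viability threshold below which doses are excluded
#'   from scoring; 0 (default) scores all doses, mirroring standard comet
#'   scoring which has no formal viability cut-off.
#' @return A `comet_screen` list: `calls` (chemical x arm decisions),
#'   `conditions` (per-condition summaries, truth, viability and adjusted
#'   p-values), `wells` (well medians), plus the seed and parameters.
#' @export
simulate_screen <- function(seed, design = screen_presets(), n_wells = 3,
                            comets_per_well = 150, sd_well = 2.5,
                            dispersion = 0.04, alpha = 0.05,
                            min_viability = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  runs <- tidyr::expand_grid(i = seq_len(nrow(design)),
                             hu_arac = c(FALSE, TRUE))
  out <- withr_seed(seed, {
    purrr::map(seq_len(nrow(runs)), function(r) {
      row <- design[runs$i[r], ]
      arm <- runs$hu_arac[r]
      doses <- c(0, row$doses[[1]])
      conds <- purrr::map(doses, function(d) {
        sc <- damage_scenario(row$chemical, d, time_h = row$time_h,
                              cell_model = row$cell_model, hu_arac = arm,
                              vehicle = d == 0,
                              label = screen_condition_label(d, row$dose_unit))
        list(scenario = sc, dose = d,
             true_pct = model_tail_percent(sc),
             viability = scenario_viability(sc))
      })
      records <- purrr::map(conds, function(cd) {
        simulate_condition_percents(cd$true_pct, n_wells, comets_per_well,
                                    sd_well, dispersion) %>%
          mutate(condition = cd$scenario$label, flags = "")
      }) %>% purrr::list_rbind()
      qc <- qc_filter(records)
      wells <- well_medians(qc$records)
      dn <- dunnett_vs_control(wells, "vehicle")
      viab <- setNames(purrr::map_dbl(conds, "viability"),
                       purrr::map_chr(conds, ~ .x$scenario$label))
      call <- call_genotoxicity(dn, viab[dn$condition], alpha = alpha,
                                min_viability = min_viability)
      cond_tbl <- tibble(
        chemical = row$chemical, hu_arac = arm,
        condition = purrr::map_chr(conds, ~ .x$scenario$label),
        dose = doses, dose_unit = row$dose_unit,
        true_pct = purrr::map_dbl(conds, "true_pct"),
        viability = unname(viab)
      ) %>%
        left_join(summarize_conditions(qc$records), by = "condition") %>%
        left_join(dn %>% select("condition", "estimate", "p_adjusted"),
                  by = "condition")
      list(
        conditions = cond_tbl,
        wells = wells %>% mutate(chemical = row$chemical, hu_arac = arm),
        call = call %>% mutate(chemical = row$chemical, hu_arac = arm,
                               .before = 1)
      )
    })
  })
  structure(
    list(calls = purrr::map(out, "call") %>% purrr::list_rbind(),
         conditions = purrr::map(out, "conditions") %>% purrr::list_rbind(),
         wells = purrr::map(out, "wells") %>% purrr::list_rbind(),
         seed = seed, alpha = alpha, min_viability = min_viability,
         params = list(n_wells = n_wells,
                       comets_per_well = comets_per_well,
                       sd_well = sd_well, dispersion = dispersion)),
    class = "comet_screen"
  )
}

#' @export
print.comet_screen <- function(x, ...) {
  cat("<comet_screen> seed ", x$seed, ", ",
      length(unique(x$calls$chemical)), " chemicals x 2 arms\n", sep = "")
  print(x$calls %>%
          select("chemical", "hu_arac", "call", "lowest_effect_condition"),
        n = Inf)
  invisible(x)
}

# ---- config-driven experiment runner ----------------------------------------

#' Run a configured experiment
#'
#' Drives a full run from a configuration (YAML path or equivalent list):
#' simulate scenarios statistically (`mode: simulate`), render and quantify
#' synthetic image fields (`mode: full`), or quantify existing TIFF fields
#' (`mode: quantify_only`). Writes `records.csv`, `wells.csv`, `summary.csv`,
#' optionally `stats.csv` (when a `control` condition is named), and
#' `run_info.yaml` (seed, mode, configuration hash) into `out_dir`.
#'
#' Configuration keys: `mode`, `seed`, `out_dir`, `scenarios` (as in
#' [read_scenarios()]; not needed for `quantify_only`), `images` (named list
#' of TIFF paths per condition, `quantify_only` mode only), `control`
#' (optional condition label for Dunnett tests), optional sampling
#' parameters `n_wells`, `comets_per_well`, `sd_well`, `dispersion`, and
#' `min_comets` (QC gate, default 100 clean comets per condition).
#'
#' @param config Path to a YAML file or a list with the keys above.
#' @param out_dir Output directory; overrides the configuration's `out_dir`.
#' @return Invisibly, a list with `records`, `wells`, `summary`, `stats`
#'   (`NULL` without a control), and `out_dir`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    cfg <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    cfg <- config
  } else {
    abort_config("`config` must be a YAML path or a list.")
  }
  mode <- cfg$mode %||% "simulate"
  if (!mode %in% c("simulate", "full", "quantify_only")) {
    abort_config("`mode` must be simulate, full or quantify_only.")
  }
  out_dir <- out_dir %||% cfg$out_dir %||%
    abort_config("No `out_dir` given.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  n_wells <- cfg$n_wells %||% 3L
  comets <- cfg$comets_per_well %||% 150L
  sd_well <- cfg$sd_well %||% 2.5
  dispersion <- cfg$dispersion %||% 0.04

  records <- if (mode == "quantify_only") {
    if (is.null(cfg$images)) {
      abort_config("quantify_only mode needs an `images` map.")
    }
    purrr::imap(cfg$images, function(paths, cond) {
      purrr::imap(as.list(paths), function(p, k) {
        fld <- read_field_tiff(p)
        quantify_field(fld, field_id = as.integer(k)) %>%
          mutate(condition = cond, well = as.integer(k))
      }) %>% purrr::list_rbind()
    }) %>% purrr::list_rbind()
  } else {
    scenarios <- if (is.character(cfg$scenarios)) {
      read_scenarios(cfg$scenarios)
    } else {
      purrr::imap(cfg$scenarios, function(block, nm) {
        block$label <- block$label %||% nm
        do.call(damage_scenario, block)
      })
    }
    if (mode == "simulate") {
      withr_seed(seed, {
        purrr::map(scenarios, function(sc) {
          simulate_condition_percents(model_tail_percent(sc), n_wells,
                                      comets, sd_well, dispersion) %>%
            mutate(condition = sc$label, flags = "")
        }) %>% purrr::list_rbind()
      })
    } else {
      purrr::imap(scenarios, function(sc, nm) {
        fields <- simulate_condition_fields(
          sc, n_wells = n_wells, comets_per_well = comets,
          dispersion = dispersion, sd_well = sd_well,
          seed = seed + match(nm, names(scenarios)))
        purrr::imap(fields, function(fld, w) {
          # the rendering geometry is known exactly here; registering from
          # fluorescence alone is ill-posed for near-saturated conditions
          # whose heads are fainter than their tail ridge
          quantify_field(fld, grid = grid_from_geometry(fld$geometry),
                         field_id = w) %>%
            mutate(condition = sc$label, well = w)
        }) %>% purrr::list_rbind()
      }) %>% purrr::list_rbind()
    }
  }

  qc <- qc_filter(records, min_comets = cfg$min_comets %||% 100)
  wells <- well_medians(qc$records)
  summary_tbl <- summarize_conditions(qc$records)
  stats_tbl <- NULL
  if (!is.null(cfg$control) && cfg$control %in% wells$condition &&
      dplyr::n_distinct(wells$condition) >= 2) {
    stats_tbl <- dunnett_vs_control(wells, cfg$control)
    stats_tbl <- stats_tbl %>%
      mutate(omnibus_p = attr(stats_tbl, "omnibus_p"))
  }

  readr::write_csv(records, file.path(out_dir, "records.csv"))
  readr::write_csv(wells, file.path(out_dir, "wells.csv"))
  readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"))
  if (!is.null(stats_tbl)) {
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
  }
  yaml::write_yaml(
    list(mode = mode, seed = seed, config_hash = rlang::hash(cfg),
         n_conditions = dplyr::n_distinct(records$condition),
         qc = purrr::transpose(qc$conditions)),
    file.path(out_dir, "run_info.yaml"))
  invisible(list(records = records, wells = wells, summary = summary_tbl,
                 stats = stats_tbl, out_dir = out_dir))
}
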