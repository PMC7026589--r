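# Synthetic fluorescence fields: comets arrayed on a microwell lattice with
# per-comet ground truth, emulating single-focal-plane array imaging.

#' Array geometry
#'
#' Physical and raster geometry of a microwell comet array: 240 um
#' centre-to-centre pitch, ~45 um well diameter, and a pixel scale standing
#' in for low-magnification imaging where one field captures the order of
#' 60-100 comets.
#'
#' @param pitch_um Centre-to-centre microwell spacing (um).
#' @param well_diameter_um Microwell diameter (um); the rendered head
#'   Gaussian has sigma = `well_diameter_um / 4`.
#' @param um_per_px Physical pixel size (um/px).
#' @param n_rows,n_cols Lattice dimensions of one field.
#' @param rotation_deg Small in-plane grid rotation (|rotation| <= 5 deg).
#' @param bit_depth Raster bit depth (intensities clipped to
#'   `2^bit_depth - 1`).
#' @return An `array_geometry` list, including the derived pixel-space pitch,
#'   head sigma, raster size (`field_px`, rows x cols) and the unrotated
#'   lattice margins. Columns are the electrophoresis/tail axis (+x).
#' @export
array_geometry <- function(pitch_um = 240, well_diameter_um = 45,
                           um_per_px = 1.6, n_rows = 8, n_cols = 8,
                           rotation_deg = 0, bit_depth = 16) {
  stopifnot(pitch_um > well_diameter_um, well_diameter_um > 0,
            um_per_px > 0, n_rows >= 1, n_cols >= 1)
  if (abs(rotation_deg) > 5) {
    abort_validation("`rotation_deg` must be within +-5 degrees.")
  }
  pitch_px <- pitch_um / um_per_px
  sigma_px <- well_diameter_um / 4 / um_per_px
  margin_x <- pitch_px          # room for a leading half-window + tail
  margin_y <- 0.75 * pitch_px
  field_px <- c(
    rows = ceiling((n_rows - 1) * pitch_px + 2 * margin_y),
    cols = ceiling((n_cols - 1) * pitch_px + 2 * margin_x)
  )
  structure(
    list(pitch_um = pitch_um, well_diameter_um = well_diameter_um,
         um_per_px = um_per_px, n_rows = n_rows, n_cols = n_cols,
         rotation_deg = rotation_deg, bit_depth = bit_depth,
         pitch_px = pitch_px, sigma_px = sigma_px,
         margin_x = margin_x, margin_y = margin_y, field_px = field_px),
    class = "array_geometry"
  )
}

#' Lattice node positions of an array geometry
#'
#' Pixel coordinates (1-based pixel centres) of every microwell site, after
#' applying the geometry's in-plane rotation about the raster centre.
#'
#' @param geometry An [array_geometry()].
#' @return Tibble: `row`, `col`, `x`, `y`.
#' @export
lattice_nodes <- function(geometry) {
  g <- geometry
  x0 <- g$margin_x + (seq_len(g$n_cols) - 1) * g$pitch_px
  y0 <- g$margin_y + (seq_len(g$n_rows) - 1) * g$pitch_px
  grid <- tidyr::expand_grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  cx <- x0[grid$col]
  cy <- y0[grid$row]
  th <- g$rotation_deg * pi / 180
  ctr <- (g$field_px[c("cols", "rows")] + 1) / 2
  xr <- ctr[1] + cos(th) * (cx - ctr[1]) - sin(th) * (cy - ctr[2])
  yr <- ctr[2] + sin(th) * (cx - ctr[1]) + cos(th) * (cy - ctr[2])
  tibble(row = grid$row, col = grid$col, x = xr, y = yr)
}

#' Noise parameters for rendering
#'
#' @param background Constant background offset (counts/pixel).
#' @param poisson Apply per-pixel counting (Poisson) noise?
#' @return A list of noise parameters.
#' @export
noise_params <- function(background = 100, poisson = TRUE) {
  stopifnot(background >= 0)
  list(background = background, poisson = poisson)
}

# Tail length scale (px) as a function of true tail fraction; linear growth,
# kept short enough that the tail of a fully occupied lattice stays within
# its own measurement window.
tail_length_px <- function(tail_frac, pitch_px) {
  pitch_px * (0.08 + 0.45 * tail_frac)
}
TAIL_OFFSET_SIGMA <- 2  # tail emission starts 2 head-sigmas behind the peak

# Add one comet to `img` in place-ish (returns modified matrix). Continuous
# pixel integrals via normal CDF differences, so the pre-noise integral
# equals the photon budget up to patch truncation (< 0.5%).
render_comet <- function(img, cx, cy, budget, tail_frac, geometry) {
  g <- geometry
  s <- g$sigma_px
  st <- 0.8 * s
  L <- tail_length_px(tail_frac, g$pitch_px)
  x0 <- cx + TAIL_OFFSET_SIGMA * s

  xs <- max(1L, floor(cx - 5 * s)):min(ncol(img), ceiling(x0 + 4 * L))
  ys <- max(1L, floor(cy - 6 * s)):min(nrow(img), ceiling(cy + 6 * s))

  head_x <- stats::pnorm(xs + 0.5, cx, s) - stats::pnorm(xs - 0.5, cx, s)
  head_y <- stats::pnorm(ys + 0.5, cy, s) - stats::pnorm(ys - 0.5, cy, s)
  lo <- pmax(xs - 0.5, x0)
  hi <- pmax(xs + 0.5, x0)
  tail_x <- 2 * (stats::pnorm(hi, x0, L) - stats::pnorm(lo, x0, L))
  tail_y <- stats::pnorm(ys + 0.5, cy, st) - stats::pnorm(ys - 0.5, cy, st)

  patch <- budget * ((1 - tail_frac) * outer(head_y, head_x) +
                       tail_frac * outer(tail_y, tail_x))
  img[ys, xs] <- img[ys, xs] + patch
  img
}

#' Render a synthetic comet field
#'
#' Renders each comet as an isotropic Gaussian head (sigma tied to the well
#' diameter) plus a half-Gaussian tail decaying along the electrophoresis
#' axis, with extent growing with the true tail fraction; adds a constant
#' background offset and per-pixel Poisson counting noise. The pre-noise
#' integrated intensity of each comet equals its photon budget.
#'
#' @param truth A tibble with one row per comet: columns `x`, `y` (pixel
#'   centre coordinates), `budget` (total photons) and `tail_frac` in
#'   `[0, 1]`; optional `row`/`col` grid indices and `occupied` flag
#'   (unoccupied rows are kept in the manifest but not rendered).
#' @param geometry An [array_geometry()].
#' @param noise [noise_params()].
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   raster. `NULL` continues the current RNG stream.
#' @return A `comet_field`: list with the intensity `matrix`, `geometry`,
#'   ground-truth `manifest`, `background` and `seed`.
#' @export
render_field <- function(truth, geometry = array_geometry(),
                         noise = noise_params(), seed = NULL) {
  g <- geometry
  if (!is.null(seed)) set.seed(seed)
  truth <- as_tibble(truth)
  if (nrow(truth) > 0) {
    stopifnot(all(c("x", "y", "budget", "tail_frac") %in% names(truth)))
    if (any(truth$budget < 0)) {
      abort_validation("Photon budgets must be non-negative.")
    }
    if (any(truth$tail_frac < 0 | truth$tail_frac > 1)) {
      abort_validation("`tail_frac` must lie in [0, 1].")
    }
    inside <- truth$x >= 1 & truth$x <= g$field_px["cols"] &
      truth$y >= 1 & truth$y <= g$field_px["rows"]
    if (!all(inside)) {
      abort_validation("All comet centres must lie inside the raster.")
    }
  }
  if (!"occupied" %in% names(truth)) truth$occupied <- rep(TRUE, nrow(truth))

  img <- matrix(0, nrow = g$field_px["rows"], ncol = g$field_px["cols"])
  occ <- truth[truth$occupied, , drop = FALSE]
  if (nrow(occ) > 0) {
    for (i in seq_len(nrow(occ))) {
      img <- render_comet(img, occ$x[i], occ$y[i], occ$budget[i],
                          occ$tail_frac[i], g)
    }
  }
  img <- img + noise$background
  if (isTRUE(noise$poisson)) {
    img <- matrix(stats::rpois(length(img), img), nrow = nrow(img))
  }
  img <- pmin(round(img), 2^g$bit_depth - 1)

  structure(
    list(intensity = img, geometry = g, manifest = truth,
         background = noise$background, noise = noise, seed = seed),
    class = "comet_field"
  )
}

#' @export
print.comet_field <- function(x, ...) {
  cat("<comet_field> ", nrow(x$intensity), " x ", ncol(x$intensity),
      " px, ", sum(x$manifest$occupied), " comets\n", sep = "")
  invisible(x)
}

# Beta concentration for a given mean and comet-level dispersion (sd of the
# tail fraction); floor keeps the distribution unimodal-ish near the edges.
beta_kappa <- function(mu, dispersion) {
  max(mu * (1 - mu) / dispersion^2 - 1, 2)
}

#' Simulate replicate-well fields for a scenario
#'
#' Draws per-comet true tail fractions from a Beta distribution centred on
#' the damage model's true percent tail DNA -- with a between-well shift
#' (`sd_well`) emulating replicate gel variability and a comet-level
#' `dispersion` -- applies random well occupancy, and renders one field per
#' replicate well.
#'
#' @param scenario A [damage_scenario()].
#' @param n_wells Number of replicate wells (fields).
#' @param comets_per_well Target lattice sites per well; the geometry's
#'   lattice is reshaped to a near-square grid of at least this many sites.
#' @param dispersion Comet-level SD of the true tail fraction (0 collapses
#'   every comet onto the well mean).
#' @param sd_well Between-well SD of the mean, in percent-tail points.
#' @param occupancy Probability a lattice site holds a comet.
#' @param geometry,noise See [render_field()].
#' @param budget_mean,budget_cv Mean and CV of the per-comet photon budget
#'   (log-normal).
#' @param seed Integer seed (one stream drives all wells).
#' @return List of `comet_field`s, one per well, each carrying `condition`
#'   and `well` fields and the scenario's true mean percent tail.
#' @export
simulate_condition_fields <- function(scenario, n_wells = 3,
                                      comets_per_well = NULL,
                                      dispersion = 0.04, sd_well = 2.5,
                                      occupancy = 0.95,
                                      geometry = array_geometry(),
                                      noise = noise_params(),
                                      budget_mean = 2e5, budget_cv = 0.1,
                                      seed = NULL) {
  stopifnot(n_wells >= 1)
  if (!is.null(comets_per_well)) {
    stopifnot(comets_per_well >= 1)
    ncol_g <- ceiling(sqrt(comets_per_well))
    nrow_g <- ceiling(comets_per_well / ncol_g)
    geometry <- array_geometry(
      pitch_um = geometry$pitch_um,
      well_diameter_um = geometry$well_diameter_um,
      um_per_px = geometry$um_per_px, n_rows = nrow_g, n_cols = ncol_g,
      rotation_deg = geometry$rotation_deg, bit_depth = geometry$bit_depth
    )
  }
  if (!is.null(seed)) set.seed(seed)
  true_pct <- model_tail_percent(scenario)

  nodes <- lattice_nodes(geometry)
  purrr::map(seq_len(n_wells), function(w) {
    mu <- min(max((true_pct + stats::rnorm(1, 0, sd_well)) / 100,
                  0.005), 0.995)
    occ <- stats::runif(nrow(nodes)) < occupancy
    f <- if (dispersion <= 0) {
      rep(mu, nrow(nodes))
    } else {
      k <- beta_kappa(mu, dispersion)
      stats::rbeta(nrow(nodes), mu * k, (1 - mu) * k)
    }
    budget <- budget_mean * exp(stats::rnorm(nrow(nodes), 0, budget_cv) -
                                  budget_cv^2 / 2)
    truth <- nodes %>%
      mutate(budget = budget, tail_frac = f, occupied = occ)
    fld <- render_field(truth, geometry, noise, seed = NULL)
    fld$condition <- scenario$label
    fld$well <- w
    fld$true_tail_pct <- true_pct
    fld
  })
}

# ---- TIFF and manifest I/O -------------------------------------------------

#' Write / read a comet field as 16-bit grayscale TIFF
#'
#' The manifest (if any) is written alongside as `<path>_manifest.csv` and
#' the geometry, seed and background into a `<path>.yaml` sidecar.
#'
#' @param field A `comet_field`.
#' @param path TIFF path.
#' @return `path` (write) or a `comet_field` (read).
#' @export
write_field_tiff <- function(field, path) {
  g <- field$geometry
  tiff::writeTIFF(field$intensity / (2^g$bit_depth - 1), path,
                  bits.per.sample = 16L, compression = "none")
  if (!is.null(field$manifest) && nrow(field$manifest) > 0) {
    readr::write_csv(field$manifest, paste0(path, "_manifest.csv"))
  }
  side <- list(
    pitch_um = g$pitch_um, well_diameter_um = g$well_diameter_um,
    um_per_px = g$um_per_px, n_rows = g$n_rows, n_cols = g$n_cols,
    rotation_deg = g$rotation_deg, bit_depth = g$bit_depth,
    background = field$background, seed = field$seed
  )
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_field_tiff
#' @param geometry Geometry to attach when no sidecar file is present.
#' @export
read_field_tiff <- function(path, geometry = NULL) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  side_path <- paste0(path, ".yaml")
  background <- 0
  seed <- NULL
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    geometry <- array_geometry(
      pitch_um = side$pitch_um, well_diameter_um = side$well_diameter_um,
      um_per_px = side$um_per_px, n_rows = side$n_rows,
      n_cols = side$n_cols, rotation_deg = side$rotation_deg,
      bit_depth = side$bit_depth
    )
    background <- side$background %||% 0
    seed <- side$seed
  } else if (is.null(geometry)) {
    geometry <- array_geometry()
  }
  img <- round(m * (2^geometry$bit_depth - 1))
  manifest_path <- paste0(path, "_manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    readr::read_csv(manifest_path, show_col_types = FALSE)
  } else {
    tibble(x = numeric(), y = numeric(), budget = numeric(),
           tail_frac = numeric(), occupied = logical())
  }
  structure(
    list(intensity = img, geometry = geometry, manifest = manifest,
         background = background, noise = NULL, seed = seed),
    class = "comet_field"
  )
}
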