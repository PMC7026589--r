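# Shared test fixtures: small geometries and quick renders.

small_geometry <- function(rotation_deg = 0) {
  array_geometry(n_rows = 4, n_cols = 4, rotation_deg = rotation_deg)
}

single_geometry <- function() {
  array_geometry(n_rows = 1, n_cols = 1)
}

# One noiseless single-comet field at a given tail fraction.
render_single_comet <- function(tail_frac, budget = 2e5,
                                geometry = single_geometry(),
                                poisson = FALSE, seed = NULL) {
  truth <- lattice_nodes(geometry) %>%
    dplyr::mutate(tail_frac = tail_frac, budget = budget)
  render_field(truth, geometry, noise_params(poisson = poisson), seed = seed)
}

# Well-level null data for statistics tests.
null_wells <- function(n_groups = 5, n_wells = 4, seed = 99, shift = NULL) {
  set.seed(seed)
  conds <- c("control", paste0("trt", seq_len(n_groups - 1)))
  d <- tidyr::expand_grid(condition = conds, well = seq_len(n_wells)) %>%
    dplyr::mutate(value = rnorm(dplyr::n()))
  if (!is.null(shift)) {
    d <- d %>%
      dplyr::mutate(value = value +
                      ifelse(condition %in% names(shift),
                             unname(shift[condition]), 0))
  }
  d
}
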