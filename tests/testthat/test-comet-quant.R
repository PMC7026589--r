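test_that("the reflection rule reproduces the worked profile exactly", {
  s <- segment_profile(c(0, 10, 20, 10, 5, 3, 2))
  expect_identical(s$peak, 3L)
  expect_equal(s$head, 40)
  expect_equal(s$tail, 10)
  expect_equal(s$total, 50)
  expect_equal(s$percent_tail, 20)
})

test_that("segment_profile handles degenerate profiles", {
  # pure symmetric head: zero tail
  prof <- c(1, 5, 10, 5, 1)
  expect_equal(segment_profile(prof)$percent_tail, 0)
  # ties resolve to the smallest (most anti-tail) index
  expect_identical(segment_profile(c(0, 7, 7, 0))$peak, 2L)
  # all-zero profile
  s0 <- segment_profile(rep(0, 10))
  expect_equal(s0$percent_tail, 0)
  expect_equal(s0$total, 0)
})

test_that("head + tail equals total for every record", {
  g <- small_geometry()
  truth <- lattice_nodes(g) %>%
    dplyr::mutate(tail_frac = seq(0.05, 0.8, length.out = dplyr::n()),
                  budget = 2e5)
  fld <- render_field(truth, g, noise_params(), seed = 21)
  rec <- quantify_field(fld, grid = grid_from_geometry(g))
  ok <- !is.na(rec$percent_tail)
  expect_true(any(ok))
  expect_equal(rec$head[ok] + rec$tail[ok], rec$total[ok])
})

test_that("registration recovers pitch and rotation on a rotated field", {
  g <- small_geometry(rotation_deg = -2)
  truth <- lattice_nodes(g) %>%
    dplyr::mutate(tail_frac = 0.3, budget = 2e5)
  fld <- render_field(truth, g, noise_params(), seed = 13)
  gr <- register_grid(fld)
  expect_equal(gr$pitch_um, 240, tolerance = 0.02)
  expect_equal(gr$rotation_deg, -2, tolerance = 0.1)
  expect_gte(gr$score, 0.9)
  expect_equal(nrow(gr$nodes), 16)
})

test_that("registration raises a classed error on a blank field", {
  g <- small_geometry()
  blank <- lattice_nodes(g)[0, ] %>%
    dplyr::mutate(tail_frac = numeric(0), budget = numeric(0))
  fld <- render_field(blank, g, noise_params(), seed = 9)
  expect_error(register_grid(fld), class = "cometscreen_no_grid_error")
})

test_that("registered and ground-truth grids give matching quantification", {
  g <- small_geometry()
  set.seed(31)
  truth <- lattice_nodes(g) %>%
    dplyr::mutate(tail_frac = runif(dplyr::n(), 0.1, 0.7), budget = 2e5)
  fld <- render_field(truth, g, noise_params(), seed = 32)
  r1 <- quantify_field(fld, grid = register_grid(fld))
  r2 <- quantify_field(fld, grid = grid_from_geometry(g))
  m <- dplyr::inner_join(r1, r2, by = c("row", "col"),
                         suffix = c("_reg", "_geo"))
  expect_equal(m$percent_tail_reg, m$percent_tail_geo, tolerance = 0.05)
})

test_that("quantification matches generator truth within tolerance", {
  g <- small_geometry()
  set.seed(17)
  truth <- lattice_nodes(g) %>%
    dplyr::mutate(tail_frac = runif(dplyr::n(), 0.05, 0.85), budget = 2e5)
  fld <- render_field(truth, g, noise_params(), seed = 18)
  rec <- quantify_field(fld)
  m <- dplyr::inner_join(
    rec, truth %>% dplyr::mutate(true_pct = 100 * tail_frac),
    by = c("row", "col"))
  err <- abs(m$percent_tail - m$true_pct)
  # in a fully occupied lattice the measurement windows tile the pitch, so
  # tails longer than one pitch (tail fractions above ~0.8) are truncated
  # and biased low by a few points; the +/-5 oracle applies below that
  expect_true(all(err[m$true_pct <= 75] < 5))
  expect_true(all(err < 10))
})

test_that("window extraction stays inside the raster and flags edges", {
  g <- small_geometry()
  truth <- lattice_nodes(g) %>%
    dplyr::mutate(tail_frac = 0.4, budget = 2e5)
  fld <- render_field(truth, g, noise_params(), seed = 3)
  gr <- grid_from_geometry(g)
  w <- extract_windows(fld, gr)
  expect_true(all(w$xs_start >= 1 & w$xs_end <= ncol(fld$intensity)))
  expect_true(all(w$ys_start >= 1 & w$ys_end <= nrow(fld$intensity)))
  expect_true(all(w$xs_start < w$xs_end))
  # rightmost column has no downstream neighbour: window extends further
  right <- w$col == max(w$col)
  expect_true(all((w$xs_end - round(w$x))[right] >
                    (w$xs_end - round(w$x))[!right][1]))
})

test_that("empty wells are flagged and excluded from metrics", {
  g <- small_geometry()
  truth <- lattice_nodes(g) %>%
    dplyr::mutate(tail_frac = 0.3, budget = 2e5,
                  occupied = dplyr::row_number() != 6)
  fld <- render_field(truth, g, noise_params(), seed = 8)
  rec <- quantify_field(fld, grid = grid_from_geometry(g))
  hole <- rec[rec$row == truth$row[6] & rec$col == truth$col[6], ]
  expect_match(hole$flags, "empty_well")
  expect_true(is.na(hole$percent_tail))
  expect_equal(sum(grepl("empty_well", rec$flags)), 1)
})

test_that("the QC gate excludes conditions below the clean-comet minimum", {
  recs <- dplyr::bind_rows(
    tibble::tibble(condition = "pass", well = rep(1:3, length.out = 120),
                   percent_tail = 20, flags = ""),
    tibble::tibble(condition = "fail", well = rep(1:3, length.out = 99),
                   percent_tail = 20, flags = ""),
    tibble::tibble(condition = "flagged", well = rep(1:3, length.out = 150),
                   percent_tail = 20, flags = "edge")
  )
  qc <- qc_filter(recs, min_comets = 100)
  expect_setequal(unique(qc$records$condition), "pass")
  got <- qc$conditions
  expect_true(got$qc_pass[got$condition == "pass"])
  expect_false(got$qc_pass[got$condition == "fail"])   # 99 < 100, exact
  expect_false(got$qc_pass[got$condition == "flagged"])
  expect_equal(got$n_clean[got$condition == "flagged"], 0L)
  # boundary: exactly 100 clean comets passes
  qc2 <- qc_filter(tibble::tibble(condition = "edge100", well = 1,
                                  percent_tail = 10,
                                  flags = rep("", 100))[1:100, ],
                   min_comets = 100)
  expect_true(qc2$conditions$qc_pass)
})
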