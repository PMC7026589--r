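# Grid-registered comet quantification: lattice registration from the
# periodic intensity structure, per-node window extraction, and head/tail
# segmentation by the reflection rule on the collapsed intensity profile.

odd_width <- function(w) {
  w <- max(1L, as.integer(round(w)))
  if (w %% 2L == 0L) w + 1L else w
}

# Separable box smoothing; edge bins fall back to the raw values.
box_smooth_vec <- function(x, w) {
  w <- odd_width(w)
  if (w <= 1L) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

box_smooth_mat <- function(m, w) {
  w <- odd_width(w)
  if (w <= 1L) return(m)
  sm <- stats::filter(m, rep(1 / w, w), sides = 2)          # columns
  sm <- t(stats::filter(t(sm), rep(1 / w, w), sides = 2))   # rows
  sm[is.na(sm)] <- 0
  matrix(sm, nrow = nrow(m))
}

# Local maxima of `m` over a (2r+1)^2 neighbourhood.
local_maxima <- function(m, r = 2L) {
  mx <- m
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0 && dx == 0) next
      sh <- matrix(-Inf, nrow(m), ncol(m))
      ys <- seq_len(nrow(m)) + dy
      xs <- seq_len(ncol(m)) + dx
      ok_y <- ys >= 1 & ys <= nrow(m)
      ok_x <- xs >= 1 & xs <= ncol(m)
      sh[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
      mx <- pmax(mx, sh)
    }
  }
  m >= mx
}

# Detect comet head peaks: blurred local maxima above an adaptive threshold,
# greedily de-duplicated at half the expected pitch, refined to sub-pixel
# intensity-weighted centroids. Heads (not whole-comet centroids) are used so
# tail migration does not shift the lattice estimate.
detect_heads <- function(field) {
  g <- field$geometry
  img <- field$intensity
  sm <- box_smooth_mat(img, odd_width(g$sigma_px))
  bg <- stats::median(sm)
  peak_amp <- max(sm) - bg
  noise_sd <- stats::mad(sm)
  thr <- bg + max(0.25 * peak_amp, 8 * noise_sd)
  cand <- which(local_maxima(sm, 2L) & sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(tibble(x = numeric(), y = numeric()))
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  min_d2 <- (0.5 * g$pitch_px)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
    keep[i] <- all(d2 > min_d2)
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-pixel refinement: weighted centroid of the background-subtracted
  # raw image within one head sigma
  r <- ceiling(g$sigma_px)
  bg_raw <- stats::median(img)
  ref <- purrr::map(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    ys <- max(1, cy - r):min(nrow(img), cy + r)
    xs <- max(1, cx - r):min(ncol(img), cx + r)
    w <- pmax(img[ys, xs, drop = FALSE] - bg_raw, 0)
    tw <- sum(w)
    if (tw <= 0) return(c(x = as.numeric(cx), y = as.numeric(cy)))
    c(x = sum(t(t(w) * xs)) / tw, y = sum(w * ys) / tw)
  })
  tibble(x = purrr::map_dbl(ref, "x"), y = purrr::map_dbl(ref, "y"))
}

#' Register the microwell lattice of a comet field
#'
#' Estimates the lattice pitch, in-plane rotation and phase offset from the
#' detected head peaks (nearest-neighbour displacement statistics, folded
#' modulo the 90-degree lattice symmetry), and returns node coordinates for
#' every lattice site covered by the field.
#'
#' @param field A `comet_field`.
#' @return A `comet_grid_fit`: `pitch_px`, `pitch_um`, `rotation_deg`,
#'   `offset` (px), `nodes` tibble (`row`, `col`, `x`, `y`), `score`
#'   (fraction of detected peaks within pitch/4 of a node), `peaks`.
#' @export
register_grid <- function(field) {
  stopifnot(inherits(field, "comet_field"))
  g <- field$geometry
  pts <- detect_heads(field)
  if (nrow(pts) < 4) {
    rlang::abort("No lattice found: fewer than 4 comet peaks detected.",
                 class = "cometscreen_no_grid_error")
  }
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  pitch0 <- stats::median(nn)
  # axis-neighbour displacement vectors (unordered pairs at ~one pitch)
  pair_idx <- which(d > 0.7 * pitch0 & d < 1.3 * pitch0, arr.ind = TRUE)
  pair_idx <- pair_idx[pair_idx[, 1] < pair_idx[, 2], , drop = FALSE]
  dx <- pts$x[pair_idx[, 2]] - pts$x[pair_idx[, 1]]
  dy <- pts$y[pair_idx[, 2]] - pts$y[pair_idx[, 1]]
  ang <- atan2(dy, dx) * 180 / pi
  fold <- ((ang %% 90) + 90) %% 90
  fold[fold > 45] <- fold[fold > 45] - 90
  rotation <- stats::median(fold)
  pitch <- stats::median(sqrt(dx^2 + dy^2))

  th <- rotation * pi / 180
  ctr <- c((ncol(field$intensity) + 1) / 2, (nrow(field$intensity) + 1) / 2)
  xr <- ctr[1] + cos(th) * (pts$x - ctr[1]) + sin(th) * (pts$y - ctr[2])
  yr <- ctr[2] - sin(th) * (pts$x - ctr[1]) + cos(th) * (pts$y - ctr[2])
  phase <- function(v) {
    a <- atan2(mean(sin(2 * pi * v / pitch)), mean(cos(2 * pi * v / pitch)))
    (a / (2 * pi) * pitch) %% pitch
  }
  off_x <- phase(xr)
  off_y <- phase(yr)
  ks <- function(v, off) {
    k <- round((v - off) / pitch)
    seq(min(k), max(k))
  }
  kx <- ks(xr, off_x)
  ky <- ks(yr, off_y)
  nodes0 <- tidyr::expand_grid(row = seq_along(ky), col = seq_along(kx)) %>%
    mutate(xu = off_x + kx[.data$col] * pitch,
           yu = off_y + ky[.data$row] * pitch)
  nodes <- nodes0 %>%
    mutate(x = ctr[1] + cos(th) * (.data$xu - ctr[1]) -
             sin(th) * (.data$yu - ctr[2]),
           y = ctr[2] + sin(th) * (.data$xu - ctr[1]) +
             cos(th) * (.data$yu - ctr[2])) %>%
    select("row", "col", "x", "y")
  # goodness: fraction of detections within a quarter pitch of their node
  nd <- purrr::map_dbl(seq_len(nrow(pts)), function(i) {
    min(sqrt((nodes$x - pts$x[i])^2 + (nodes$y - pts$y[i])^2))
  })
  structure(
    list(pitch_px = pitch, pitch_um = pitch * g$um_per_px,
         rotation_deg = rotation, offset = c(x = off_x, y = off_y),
         nodes = nodes, score = mean(nd < 0.25 * pitch), peaks = pts),
    class = "comet_grid_fit"
  )
}

#' Grid fit from a known geometry
#'
#' Builds a `comet_grid_fit` directly from an [array_geometry()] instead of
#' registering it from the image -- for synthetic fields whose layout is
#' known exactly, and as the oracle against which [register_grid()] is
#' checked.
#'
#' @param geometry An [array_geometry()].
#' @return A `comet_grid_fit` with perfect pitch, rotation and nodes.
#' @export
grid_from_geometry <- function(geometry) {
  nodes <- lattice_nodes(geometry)
  structure(
    list(pitch_px = geometry$pitch_px,
         pitch_um = geometry$pitch_um,
         rotation_deg = geometry$rotation_deg,
         offset = c(x = NA_real_, y = NA_real_),
         nodes = nodes, score = 1,
         peaks = nodes %>% select("x", "y")),
    class = "comet_grid_fit"
  )
}

#' @export
print.comet_grid_fit <- function(x, ...) {
  cat("<comet_grid_fit> pitch ", round(x$pitch_um, 1), " um (",
      round(x$pitch_px, 2), " px), rotation ",
      round(x$rotation_deg, 3), " deg, ", nrow(x$nodes),
      " nodes, score ", round(x$score, 3), "\n", sep = "")
  invisible(x)
}

#' Extract one measurement window per lattice node
#'
#' Each window spans one pitch across the transverse axis and, along the
#' electrophoresis axis, from just before the head to either just before the
#' next occupied node (so neighbouring tails tile the lattice without double
#' counting) or up to 1.5 pitches when the downstream site is empty or
#' absent. Windows truncated by the raster border are flagged `edge`.
#'
#' @param field A `comet_field`.
#' @param grid A `comet_grid_fit` from [register_grid()].
#' @return Tibble of window definitions (pixel index ranges, node position,
#'   `edge` flag).
#' @export
extract_windows <- function(field, grid) {
  stopifnot(inherits(grid, "comet_grid_fit"))
  g <- field$geometry
  img <- field$intensity
  p <- grid$pitch_px
  lead <- ceiling(3.25 * g$sigma_px)
  half_t <- floor(p / 2)

  # occupancy from the blurred intensity at the node itself: peak detection
  # can miss the faint head of a high-tail comet, and extending a window
  # over an occupied neighbour silently absorbs that comet
  sm <- box_smooth_mat(img, odd_width(g$sigma_px))
  bg <- stats::median(sm)
  nsd <- stats::mad(sm)
  occupied_near <- function(x, y) {
    xi <- min(max(round(x), 1L), ncol(img))
    yi <- min(max(round(y), 1L), nrow(img))
    sm[yi, xi] > bg + 6 * nsd
  }
  nodes <- grid$nodes
  purrr::map(seq_len(nrow(nodes)), function(i) {
    nx <- nodes$x[i]; ny <- nodes$y[i]
    nxt <- nodes %>%
      filter(.data$row == nodes$row[i], .data$col == nodes$col[i] + 1L)
    end_want <- if (nrow(nxt) == 1 && occupied_near(nxt$x, nxt$y)) {
      round(nxt$x) - lead - 2L
    } else {
      round(nx + 1.5 * p)
    }
    xs0 <- round(nx) - lead
    ys0 <- round(ny) - half_t
    ys1 <- round(ny) + half_t
    edge <- xs0 < 1 || end_want > ncol(img) || ys0 < 1 || ys1 > nrow(img)
    tibble(row = nodes$row[i], col = nodes$col[i], x = nx, y = ny,
           xs_start = max(1L, xs0), xs_end = min(ncol(img), end_want),
           ys_start = max(1L, ys0), ys_end = min(nrow(img), ys1),
           edge = edge)
  }) %>% purrr::list_rbind()
}

#' Segment a collapsed comet profile by the head-reflection rule
#'
#' The head centre is the peak of the smoothed profile within `peak_region`
#' (ties resolved to the smallest index, i.e. the most anti-tail position).
#' The head intensity is the peak bin plus twice the leading (anti-tail)
#' side -- the leading half reflected about the centre -- and the tail is the
#' remainder of the profile.
#'
#' When `refine_sigma` is given, the head centre is refined to sub-pixel
#' precision by an iterated intensity centroid over a window of that
#' half-width (chosen so the window stays clear of the tail), and the
#' reflected leading mass is computed about the sub-pixel centre with the
#' boundary column split linearly. With the centre exactly on a pixel centre
#' this reduces to the discrete rule, but it removes the rule's ~2x-peak-bin
#' sensitivity to one-pixel localisation errors.
#'
#' @param profile Numeric background-subtracted 1-D intensity profile along
#'   the electrophoresis axis.
#' @param peak_region Indices within which the head peak is searched.
#' @param smooth_px Odd box width used only for peak finding.
#' @param refine_sigma Half-width (px) of the sub-pixel centroid window;
#'   `NULL` (default) keeps the purely discrete rule.
#' @return List: `peak` (index), `centre` (sub-pixel head centre), `head`,
#'   `tail`, `total`, `percent_tail`, `tail_centroid_px`
#'   (intensity-weighted tail distance).
#' @export
#' @examples
#' segment_profile(c(0, 10, 20, 10, 5, 3, 2))$percent_tail  # 20
segment_profile <- function(profile, peak_region = seq_along(profile),
                            smooth_px = 1, refine_sigma = NULL) {
  stopifnot(length(profile) >= 1)
  sm <- box_smooth_vec(profile, smooth_px)
  peak_region <- peak_region[peak_region >= 1 &
                               peak_region <= length(profile)]
  peak <- peak_region[which.max(sm[peak_region])]
  total <- sum(profile)

  centre <- as.numeric(peak)
  if (!is.null(refine_sigma) && refine_sigma > 0) {
    for (it in 1:3) {
      w <- which(abs(seq_along(profile) - centre) <= refine_sigma)
      wt <- pmax(profile[w], 0)
      if (sum(wt) <= 0) break
      centre <- sum(w * wt) / sum(wt)
    }
    centre <- min(max(centre, min(peak_region)), max(peak_region))
  }
  # reflected leading mass about the (possibly sub-pixel) centre: full
  # columns entirely left of the centre plus a linear split of the column
  # containing it (pixel j spans [j - 0.5, j + 0.5])
  jc <- floor(centre + 0.5)
  left <- if (jc > 1) sum(profile[seq_len(jc - 1)]) else 0
  left <- left + profile[jc] * (centre - (jc - 0.5))
  head_int <- 2 * left
  head_int <- min(max(head_int, profile[peak]), max(total, profile[peak]))
  tail_int <- max(total - head_int, 0)
  pct <- if (total > 0) 100 * tail_int / total else 0

  centroid <- 0
  if (peak < length(profile) && tail_int > 0) {
    idx <- (peak + 1L):length(profile)
    mirror_idx <- 2L * peak - idx
    mirror <- ifelse(mirror_idx >= 1, profile[pmax(mirror_idx, 1)], 0)
    tail_prof <- pmax(profile[idx] - mirror, 0)
    if (sum(tail_prof) > 0) {
      centroid <- sum(tail_prof * (idx - peak)) / sum(tail_prof)
    }
  }
  list(peak = peak, centre = centre, head = head_int, tail = tail_int,
       total = total, percent_tail = pct, tail_centroid_px = centroid)
}

#' Quantify every comet in a field
#'
#' Registers the lattice (unless a grid fit is supplied), extracts one
#' window per node, subtracts a local robust background estimated from the
#' transverse margins of each window, collapses to a 1-D profile and applies
#' [segment_profile()] with the head search restricted to a one-sigma band
#' around the registered node. Produces one record per lattice site with
#' percent tail DNA, tail moment and QC flags (`edge`, `empty_well`,
#' `low_signal`, `saturated`, `overlap`).
#'
#' @param field A `comet_field`.
#' @param grid Optional pre-computed [register_grid()] fit.
#' @param smooth_px Box width for peak finding (default one head sigma).
#' @param signal_floor Minimum background-subtracted total intensity for a
#'   scoreable comet.
#' @param field_id Identifier copied into the records.
#' @return A tibble of comet records: `field`, `row`, `col`, `x`, `y`,
#'   `total`, `head`, `tail`, `percent_tail`, `tail_moment_um`, `flags`
#'   (comma-separated; empty string for clean records).
#' @export
quantify_field <- function(field, grid = NULL, smooth_px = NULL,
                           signal_floor = 2.5e4, field_id = 1L) {
  g <- field$geometry
  grid <- grid %||% register_grid(field)
  smooth_px <- odd_width(smooth_px %||% g$sigma_px)
  img <- field$intensity
  windows <- extract_windows(field, grid)
  satmax <- 2^g$bit_depth - 1
  hs_r <- max(2L, round(g$sigma_px))

  recs <- purrr::map(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    win <- img[w$ys_start:w$ys_end, w$xs_start:w$xs_end, drop = FALSE]
    yy <- w$ys_start:w$ys_end
    margin_rows <- abs(yy - w$y) > 3.2 * g$sigma_px
    bg <- if (any(margin_rows)) {
      stats::median(win[margin_rows, ])
    } else {
      stats::median(win)
    }
    prof <- colSums(win) - bg * nrow(win)
    nx <- round(w$x) - w$xs_start + 1L
    region <- max(1L, nx - hs_r):min(length(prof), nx + hs_r)

    flags <- character()
    if (w$edge) flags <- c(flags, "edge")
    if (any(win >= satmax)) flags <- c(flags, "saturated")

    sm <- box_smooth_vec(prof, smooth_px)
    noise_sd <- sqrt(max(bg, 1) * nrow(win) / smooth_px)
    if (max(sm[region]) < 6 * noise_sd) {
      flags <- c(flags, "empty_well")
      return(tibble(field = field_id, row = w$row, col = w$col,
                    x = w$x, y = w$y, total = sum(prof), head = NA_real_,
                    tail = NA_real_, percent_tail = NA_real_,
                    tail_moment_um = NA_real_,
                    flags = paste(flags, collapse = ",")))
    }
    seg <- segment_profile(prof, region, smooth_px,
                           refine_sigma = g$sigma_px)
    if (seg$total < signal_floor) flags <- c(flags, "low_signal")
    # a second strong peak well beyond the node hints at an unregistered
    # neighbour inside an extended window
    far <- which(seq_along(sm) > nx + 0.55 * grid$pitch_px)
    if (length(far) > 0 && max(sm[far]) > 0.8 * sm[seg$peak]) {
      flags <- c(flags, "overlap")
    }
    tibble(field = field_id, row = w$row, col = w$col,
           x = w$xs_start + seg$peak - 1, y = w$y,
           total = seg$total, head = seg$head, tail = seg$tail,
           percent_tail = seg$percent_tail,
           tail_moment_um = seg$percent_tail / 100 *
             seg$tail_centroid_px * g$um_per_px,
           flags = paste(flags, collapse = ","))
  })
  purrr::list_rbind(recs)
}

#' QC-filter comet records
#'
#' Drops flagged records, then marks any condition with fewer clean comets
#' than the minimum as a QC failure and excludes it from downstream
#' statistics.
#'
#' @param records Comet-record tibble with a `condition` column (and the
#'   `flags` column from [quantify_field()]).
#' @param min_comets Minimum clean comets per condition (default 100).
#' @return List with `records` (clean rows of passing conditions) and
#'   `conditions` (tibble: `condition`, `n_clean`, `qc_pass`).
#' @export
qc_filter <- function(records, min_comets = 100) {
  stopifnot("condition" %in% names(records))
  flags <- records$flags %||% ""
  clean <- records[is.na(flags) | flags == "", , drop = FALSE]
  conditions <- clean %>%
    group_by(.data$condition) %>%
    summarise(n_clean = dplyr::n(), .groups = "drop") %>%
    # conditions whose records were all flagged away still appear, with 0
    dplyr::right_join(tibble(condition = unique(records$condition)),
                      by = "condition") %>%
    mutate(n_clean = dplyr::coalesce(.data$n_clean, 0L),
           qc_pass = .data$n_clean >= min_comets)
  passing <- conditions$condition[conditions$qc_pass]
  list(records = clean %>% filter(.data$condition %in% passing),
       conditions = conditions)
}
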