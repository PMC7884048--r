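#' Optical-fractionator counting design
#'
#' Describes the systematic random sampling scheme: every `1/ssf`-th section is
#' taken (random start), counting frames of `frame_x x frame_y` um tile each
#' sampled section at `grid_x x grid_y` um spacing from a uniformly random
#' offset, and within each frame particles are counted in an optical disector
#' of height `h` um inside the mounted section thickness `t` um (guard zones
#' above/below default to `(t - h) / 2`).
#'
#' @param ssf Section sampling fraction in (0, 1]; e.g. 1/8 for every 8th section.
#' @param frame_x,frame_y Counting-frame extent in um.
#' @param grid_x,grid_y Grid spacing in um (>= frame extent).
#' @param thickness_t Mounted section thickness t in um.
#' @param disector_h Disector height h in um, 0 < h <= t.
#' @param guard Guard zone above the disector in um (default `(t - h) / 2`).
#' @return A `counting_design` list; `asf` is `frame area / grid area`.
#' @export
counting_design <- function(ssf, frame_x, frame_y, grid_x, grid_y,
                            thickness_t, disector_h,
                            guard = (thickness_t - disector_h) / 2) {
  if (ssf <= 0 || ssf > 1) abort("`ssf` must be in (0, 1].")
  if (disector_h <= 0 || disector_h > thickness_t) {
    abort("need 0 < disector_h <= thickness_t.")
  }
  if (frame_x > grid_x || frame_y > grid_y) {
    abort("counting frame must not exceed the grid spacing.")
  }
  if (guard < 0 || guard + disector_h > thickness_t) {
    abort("guard zone does not fit in the section thickness.")
  }
  structure(
    list(ssf = ssf, frame_x = frame_x, frame_y = frame_y,
         grid_x = grid_x, grid_y = grid_y, thickness_t = thickness_t,
         disector_h = disector_h, guard = guard,
         asf = (frame_x * frame_y) / (grid_x * grid_y)),
    class = "counting_design"
  )
}

#' Sample counting frames from a tissue volume
#'
#' Applies the unbiased counting rules to the point cloud: a nucleus centroid
#' is counted iff it falls in the frame's inclusion region
#' `x in [x0, x0 + frame_x)` and `y in (y0, y0 + frame_y]` (points on the
#' lower/right exclusion edges are not counted) and its depth lies in the
#' disector `[guard, guard + h)` below the section top (the upper bounding
#' plane is excluded). Sections are taken every `round(1/ssf)`-th with a random
#' start; frames tile the plane from a random (x, y) offset, so every point
#' belongs to exactly one tile.
#'
#' @param volume [simulate_tissue()] result (or a compatible list).
#' @param design [counting_design()]; frame/grid must fit the slab and the
#'   design thickness is taken per cut section.
#' @param seed Seed for the random section start and grid offset.
#' @return Tibble of frames (zero counts included): `section`, `x0`, `y0`,
#'   `q_minus`.
#' @export
sample_frames <- function(volume, design, seed = 1L) {
  stopifnot(inherits(design, "counting_design"))
  pts <- volume$points
  dims <- volume$dims_um
  n_sec <- volume$n_sections
  cut <- volume$cut_thickness_um
  if (design$thickness_t > cut) {
    abort("design thickness exceeds the cut section thickness of the volume.")
  }
  period <- max(1L, as.integer(round(1 / design$ssf)))
  rnd <- with_seed(derive_seed(seed, "frames"), {
    list(start = sample.int(period, 1),
         ox = runif(1, 0, design$grid_x), oy = runif(1, 0, design$grid_y))
  })
  sections <- seq(rnd$start, n_sec, by = period)

  # tile index of each point; inclusion tests per counting rules
  kx <- floor((pts$x - rnd$ox) / design$grid_x)
  ky <- floor((pts$y - rnd$oy) / design$grid_y)
  ux <- pts$x - (rnd$ox + kx * design$grid_x)
  uy <- pts$y - (rnd$oy + ky * design$grid_y)
  sec <- floor(pts$z / cut) + 1
  zloc <- pts$z - (sec - 1) * cut
  counted <- sec %in% sections &
    ux < design$frame_x &
    uy > 0 & uy <= design$frame_y &
    zloc >= design$guard & zloc < design$guard + design$disector_h

  # enumerate all tiles intersecting the slab in the sampled sections
  kx_all <- seq(floor((0 - rnd$ox) / design$grid_x),
                floor((dims[1] - rnd$ox) / design$grid_x))
  ky_all <- seq(floor((0 - rnd$oy) / design$grid_y),
                floor((dims[2] - rnd$oy) / design$grid_y))
  frames <- tidyr::expand_grid(section = sections, kx = kx_all, ky = ky_all)
  counts <- tibble(section = sec[counted], kx = kx[counted], ky = ky[counted]) |>
    dplyr::count(.data$section, .data$kx, .data$ky, name = "q_minus")
  frames |>
    left_join(counts, by = c("section", "kx", "ky")) |>
    mutate(
      q_minus = dplyr::coalesce(.data$q_minus, 0L),
      x0 = rnd$ox + .data$kx * design$grid_x,
      y0 = rnd$oy + .data$ky * design$grid_y
    ) |>
    select("section", "x0", "y0", "q_minus")
}

#' Optical-fractionator estimate of total particle number
#'
#' `N_hat = sum(Q-) * (t / h) * (1 / asf) * (1 / ssf)`: the raw disector count
#' divided by the fraction of tissue examined (thickness, area and section
#' sampling fractions).
#'
#' @param counts Frame tibble from [sample_frames()] (only `q_minus` is used).
#' @param design [counting_design()] used to take the counts.
#' @return One-row tibble: `n_hat`, `sum_q`, `thickness_fraction` (t/h),
#'   `asf`, `ssf`.
#' @export
fractionator_estimate <- function(counts, design) {
  stopifnot(inherits(design, "counting_design"))
  if (design$asf == 0 || design$ssf == 0 || design$disector_h == 0) {
    abort("asf, ssf and disector height must be non-zero.")
  }
  sum_q <- sum(counts$q_minus)
  tibble(
    n_hat = sum_q * (design$thickness_t / design$disector_h) *
      (1 / design$asf) * (1 / design$ssf),
    sum_q = sum_q,
    thickness_fraction = design$thickness_t / design$disector_h,
    asf = design$asf, ssf = design$ssf
  )
}
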