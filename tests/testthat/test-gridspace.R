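aoi <- aoi_spec()

# one fixation at the centre of every grid cell, row-major order
lattice_fixations <- function(aoi, rows = 10, cols = 10) {
  cw <- (aoi$x_max - aoi$x_min) / cols
  ch <- (aoi$y_max - aoi$y_min) / rows
  g <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))
  tibble::tibble(x_px = aoi$x_min + (g$col + 0.5) * cw,
                 y_px = aoi$y_min + (g$row + 0.5) * ch)
}

test_that("grid assignment uses half-open equal cells over the AOI", {
  corner <- tibble::tibble(x_px = aoi$x_min, y_px = aoi$y_min)
  a <- assign_grid(corner, aoi)
  expect_equal(c(a$row, a$col), c(0L, 0L))

  centre <- tibble::tibble(x_px = (aoi$x_min + aoi$x_max) / 2,
                           y_px = (aoi$y_min + aoi$y_max) / 2)
  a <- assign_grid(centre, aoi)
  expect_equal(c(a$row, a$col), c(5L, 5L))

  a <- assign_grid(lattice_fixations(aoi), aoi)
  expect_equal(a$inside_fixations, 100L)
  expect_equal(sort(unique(a$cell)), 0:99)
  expect_true(all(table(a$cell) == 1L))
})

test_that("grid entropy follows Shannon's formula in the requested base", {
  one_cell <- assign_grid(tibble::tibble(x_px = rep(300, 5), y_px = rep(300, 5)), aoi)
  expect_equal(grid_entropy(one_cell), 0)

  # equal mass in 4 cells -> 2 bits
  cw <- (aoi$x_max - aoi$x_min) / 10
  four <- tibble::tibble(x_px = aoi$x_min + cw * c(0.5, 1.5, 2.5, 3.5),
                         y_px = rep(aoi$y_min + 10, 4))
  expect_equal(grid_entropy(assign_grid(four, aoi)), 2)

  # counts (2,1,1) -> 1.5 bits
  counts211 <- tibble::tibble(
    x_px = aoi$x_min + cw * c(0.5, 0.5, 1.5, 2.5),
    y_px = rep(aoi$y_min + 10, 4))
  expect_equal(grid_entropy(assign_grid(counts211, aoi)), 1.5)

  empty <- assign_grid(tibble::tibble(x_px = numeric(), y_px = numeric()), aoi)
  expect_true(is.na(grid_entropy(empty)))
})

test_that("entropy is maximal only for the uniform lattice", {
  a <- assign_grid(lattice_fixations(aoi), aoi)
  expect_equal(grid_entropy(a), log2(100))
  set.seed(5)
  for (i in 1:20) {
    fx <- tibble::tibble(x_px = stats::runif(80, aoi$x_min, aoi$x_max - 1),
                         y_px = stats::runif(80, aoi$y_min, aoi$y_max - 1))
    h <- grid_entropy(assign_grid(fx, aoi))
    expect_true(h >= 0 && h < log2(100))
  }
})

test_that("spatial dispersion is the mean consecutive distance in cell units", {
  cw <- (aoi$x_max - aoi$x_min) / 10
  ch <- (aoi$y_max - aoi$y_min) / 10
  two <- tibble::tibble(x_px = c(300, 300 + cw), y_px = c(300, 300))
  expect_equal(spatial_dispersion(two, aoi), 1.0)

  # alternation between two points 3 cells apart: every pair contributes 3
  k <- 3
  alt <- tibble::tibble(x_px = rep(c(400, 400 + k * cw), 4), y_px = 400)
  expect_equal(spatial_dispersion(alt, aoi), k)

  # random sequence equals the brute-force consecutive computation
  set.seed(9)
  fx <- tibble::tibble(x_px = stats::runif(30, aoi$x_min, aoi$x_max),
                       y_px = stats::runif(30, aoi$y_min, aoi$y_max))
  manual <- mean(sapply(1:29, function(i) {
    sqrt(((fx$x_px[i + 1] - fx$x_px[i]) / cw)^2 +
           ((fx$y_px[i + 1] - fx$y_px[i]) / ch)^2)
  }))
  expect_equal(spatial_dispersion(fx, aoi), manual, tolerance = 1e-12)

  expect_true(is.na(spatial_dispersion(two[1, ], aoi)))
})

test_that("grid occupancy is the occupied-cell fraction", {
  one <- assign_grid(tibble::tibble(x_px = rep(300, 7), y_px = rep(300, 7)), aoi)
  expect_equal(grid_occupancy(one), 0.01)
  expect_equal(grid_occupancy(assign_grid(lattice_fixations(aoi), aoi)), 1.0)
  # 40 distinct cells of 100
  forty <- lattice_fixations(aoi)[1:40, ]
  expect_equal(grid_occupancy(assign_grid(forty, aoi)), 0.40)
})

test_that("transition density counts unique inter-cell routes", {
  lat <- lattice_fixations(aoi)
  a_cell <- lat[1, ]; b_cell <- lat[2, ]
  abab <- dplyr::bind_rows(a_cell, b_cell, a_cell, b_cell)
  expect_equal(transition_density(assign_grid(abab, aoi)), 2 / 3)

  five <- lat[1:5, ]
  expect_equal(transition_density(assign_grid(five, aoi)), 1.0)

  same <- dplyr::bind_rows(a_cell, a_cell, a_cell)
  expect_true(is.na(transition_density(assign_grid(same, aoi))))

  # transitions never straddle trial boundaries
  two_trials <- dplyr::bind_rows(a_cell, b_cell, a_cell, b_cell)
  td <- transition_density(assign_grid(two_trials, aoi),
                           trial_id = c("t1", "t1", "t2", "t2"))
  expect_equal(td, 1 / 2)  # the same route once per trial
})

test_that("the nearest-neighbor index separates clustering from dispersion", {
  # coincident points -> 0
  co <- tibble::tibble(x_px = rep(400, 5), y_px = rep(400, 5))
  expect_equal(nearest_neighbor_index(co, aoi), 0)

  # 4 corners of a unit square in a unit-area region -> 1 / 0.25 = 4
  unit_geom <- screen_geometry(width_px = 2, height_px = 2)
  unit_aoi <- aoi_spec(0, 0, 1, 1, geometry = unit_geom)
  corners <- tibble::tibble(x_px = c(0, 0, 1, 1), y_px = c(0, 1, 0, 1))
  expect_equal(nearest_neighbor_index(corners, unit_aoi), 4)

  # a perfect lattice is dispersed
  expect_gt(nearest_neighbor_index(lattice_fixations(aoi), aoi), 1)

  expect_true(is.na(nearest_neighbor_index(co[1, ], aoi)))
})

test_that("NNI approaches 1 for uniform random points in the AOI", {
  set.seed(123)
  fx <- tibble::tibble(x_px = stats::runif(10000, aoi$x_min, aoi$x_max),
                       y_px = stats::runif(10000, aoi$y_min, aoi$y_max))
  expect_equal(nearest_neighbor_index(fx, aoi), 1, tolerance = 0.02)
})

test_that("grid summaries distinguish clustered from dispersed pools", {
  cfg <- pipeline_config()
  mk_events <- function(fx, trial) {
    tibble::tibble(trial_id = trial, kind = "fixation",
                   t_start_ms = seq(0, by = 200, length.out = nrow(fx)),
                   t_end_ms = seq(100, by = 200, length.out = nrow(fx)),
                   x_px = fx$x_px, y_px = fx$y_px,
                   x_end_px = NA_real_, y_end_px = NA_real_, inside_aoi = TRUE)
  }
  set.seed(2)
  clustered <- tibble::tibble(
    x_px = stats::rnorm(60, 900, 30), y_px = stats::rnorm(60, 500, 20))
  dispersed <- tibble::tibble(
    x_px = stats::runif(60, aoi$x_min, aoi$x_max - 1),
    y_px = stats::runif(60, aoi$y_min, aoi$y_max - 1))
  events <- dplyr::bind_rows(mk_events(clustered, "t1"), mk_events(dispersed, "t2"))
  trials <- tibble::tibble(trial_id = c("t1", "t2"),
                           participant_id = c("P1", "P2"),
                           group = c("NPH", "HE"),
                           item = "motorcycle", response_correct = 1L,
                           error_type = NA_character_)
  gs <- summarize_grid(events, trials, cfg)
  h_clustered <- gs$grid_entropy[gs$group == "NPH"]
  h_dispersed <- gs$grid_entropy[gs$group == "HE"]
  expect_lt(h_clustered, h_dispersed)
  expect_true(all(gs$grid_occupancy > 0 & gs$grid_occupancy <= 1))
  expect_true(all(gs$transition_density > 0 & gs$transition_density <= 1))

  # a lattice pool: full occupancy, dispersed NNI
  gl <- summarize_grid(mk_events(lattice_fixations(aoi), "t3"),
                       tibble::tibble(trial_id = "t3", participant_id = "P3",
                                      group = "NPH", item = "eggplant",
                                      response_correct = 0L,
                                      error_type = NA_character_), cfg)
  expect_equal(gl$grid_occupancy, 1.0)
  expect_gt(gl$nni, 1)
})
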