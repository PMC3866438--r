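test_that("field_peak finds the maximum with a deterministic tie rule", {
  env <- square_env()
  r <- matrix(0, 20, 20)
  r[5, 12] <- 3
  m <- make_test_map(r, bin_size = 3, x0 = -10, y0 = -10)
  pk <- field_peak(m, env)
  expect_equal(pk$rate, 3)
  expect_equal(pk$position, c((-10 + 5 - 0.5) * 3, (-10 + 12 - 0.5) * 3))
  # two exact ties: lowest flat (column-major) index wins
  r2 <- r; r2[17, 3] <- 3
  pk2 <- field_peak(make_test_map(r2, 3, -10, -10), env)
  expect_equal(pk2$position[2], (-10 + 3 - 0.5) * 3)
  expect_error(field_peak(make_test_map(matrix(0, 4, 4)), env), "peak")
})

test_that("outer_portion uses the inclusive 75% radial rule", {
  env <- circle_env()
  mk <- function(d) structure(list(position = c(d, 0), rate = 1,
                                   dist_centre = d), class = "bvc_fieldpeak")
  expect_true(outer_portion(mk(70.74), env))
  expect_false(outer_portion(mk(0), env))
  expect_true(outer_portion(mk(0.75 * 75), env))
  expect_false(outer_portion(mk(0.75 * 75 - 0.01), env))
  expect_error(outer_portion(mk(10), square_env()), "circular")
})

test_that("predicted_side reflects the baseline peak across the environment", {
  env <- square_env()
  r <- matrix(0, 34, 34)
  r[17, 2] <- 5                     # peak near the south wall
  ps <- predicted_side(make_test_map(r, 3, -17, -17), env)
  expect_equal(ps$phi_pref, -pi / 2)
  expect_equal(ps$label, "north")
  r2 <- matrix(0, 34, 34)
  r2[33, 17] <- 5                   # peak on the east wall
  ps2 <- predicted_side(make_test_map(r2, 3, -17, -17), env)
  expect_equal(ps2$label, "west")
  # circular environment: direction from the peak angle
  rc <- matrix(0, 50, 50)
  rc[25, 3] <- 5                    # south
  psc <- predicted_side(make_test_map(rc, 3, -25, -25), circle_env())
  expect_equal(psc$label, "north")
})

# Build the constructed coverage scene: east-west barrier in the walled
# square, full visitation, a 10 Hz peak elsewhere, and a chosen pattern of
# abutting-row rates.
coverage_scene <- function(abut_rates) {
  env_b <- insert_barrier(square_env(), c(0, 0), 0)
  r <- matrix(1, 34, 34)            # bins span [-51, 51]
  r[17, 3] <- 10                    # locational peak 10 Hz near south wall
  m <- make_test_map(r, 3, -17, -17)
  bins <- bvctools:::abutting_bins(m, env_b, pi / 2)
  stopifnot(length(bins) == length(abut_rates))
  m$rate[bins] <- abut_rates
  list(map = m, env = env_b, bins = bins)
}

test_that("barrier coverage reproduces the worked two-thirds example", {
  sc <- coverage_scene(rep(1, 18))
  expect_length(sc$bins, 18)        # 18 bins tile the 50 cm face at 3 cm
  # exactly two-thirds of the abutting bins at/above 40% of the 10 Hz peak
  cov <- barrier_coverage(sc$map, sc$env, pi / 2)
  expect_equal(cov$threshold, 4)
  sc2 <- coverage_scene(c(rep(5, 12), rep(1, 6)))
  cov2 <- barrier_coverage(sc2$map, sc2$env, pi / 2)
  expect_equal(cov2$coverage, 200 / 3, tolerance = 1e-9)
  expect_equal(round(cov2$coverage), 67)
  expect_true(cov2$is_bvc)
  # all bins firing and none firing
  expect_equal(barrier_coverage(coverage_scene(rep(10, 18))$map, sc$env,
                                pi / 2)$coverage, 100)
  cov0 <- barrier_coverage(sc$map, sc$env, pi / 2)
  expect_equal(cov0$coverage, 0)
  expect_false(cov0$is_bvc)
})

test_that("coverage is monotone when abutting rates are scaled up", {
  base <- c(seq(0.5, 4.5, length.out = 9), rep(2, 9))
  covs <- vapply(c(1, 1.5, 2, 3), function(f) {
    sc <- coverage_scene(pmin(base * f, 9.9))   # peak stays 10 Hz
    barrier_coverage(sc$map, sc$env, pi / 2)$coverage
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("boundary-off coverage flags low-rate zones, not uniform maps", {
  sc <- coverage_scene(rep(0.2, 18))   # abutting rates far below the median
  off <- boundary_off_coverage(NULL, sc$map, sc$env, pi / 2)
  expect_true(off$is_bvc)
  expect_equal(off$coverage, 100)
  sc_u <- coverage_scene(rep(1, 18))   # same as the map's median rate
  off_u <- boundary_off_coverage(NULL, sc_u$map, sc_u$env, pi / 2)
  expect_false(off_u$is_bvc)
})

test_that("a simulated proximal BVC peaks at the perimeter and classifies", {
  s <- bvc_baseline_session()
  pk <- field_peak(s$map, s$env)
  expect_lt(75 - pk$dist_centre, 10)   # within 10 cm of the wall
  expect_true(outer_portion(pk, s$env))
  # the estimated preferred direction points south
  ps <- predicted_side(s$map, s$env)
  expect_lt(abs(wrap_angle(ps$phi_pref - (-pi / 2))), pi / 4)
})

test_that("a centred bump is not eligible for the barrier criterion", {
  r <- matrix(0, 50, 50)
  r[25:26, 25:26] <- 5               # place-like field at the centre
  m <- make_test_map(r, 3, -25, -25)
  cls <- classify_bvc(m, m, circle_env(),
                      insert_barrier(circle_env(), c(0, 0), 0))
  expect_false(cls$eligible)
  expect_false(cls$is_bvc)
  expect_match(cls$reason, "not eligible")
})
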