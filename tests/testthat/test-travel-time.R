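cs20 <- metres_to_degrees(20)

uniform_surface <- function(n, seconds = 14.4) {
  structure(list(grid = geo_grid(matrix(seconds, n, n), 30, 0.5, cs20),
                 water_mode = "blocked", child_factor = 1, water_speed = 1,
                 cell_size_m = 20),
            class = "cost_surface")
}

test_that("single-source times on a uniform 3 x 3 surface match the 9-node oracle", {
  s <- uniform_surface(3)
  src <- tibble::tibble(row = 2L, col = 2L)
  got <- cost_distance(s, src)$values
  want <- oracle_cost_distance(s$grid$values, src)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[2, 2], 0)
  expect_equal(got[2, 1], 14.4)            # orthogonal: mean cost * 1
  expect_equal(got[1, 1], 14.4 * sqrt(2))  # diagonal: mean cost * sqrt(2)
  expect_equal(got[1, 1], 20.3647, tolerance = 1e-4)
})

test_that("every source cell reads zero and a sealed region reads +Inf", {
  s <- uniform_surface(7)
  s$grid$values[3, 3:5] <- NA   # partial wall
  src <- tibble::tibble(row = c(1L, 7L), col = c(1L, 7L))
  d <- cost_distance(s, src)$values
  expect_true(all(d[cbind(src$row, src$col)] == 0))
  expect_true(all(d[!is.na(d)] >= 0))
  # seal a corner region completely
  s$grid$values[1:2, 6] <- NA
  s$grid$values[2, 6:7] <- NA
  d2 <- cost_distance(s, tibble::tibble(row = 7L, col = 1L))$values
  expect_equal(d2[1, 7], Inf)
  expect_error(cost_distance(s, tibble::tibble(row = integer(), col = integer())),
               "source")
  expect_error(cost_distance(s, tibble::tibble(row = 3L, col = 3L)), "impassable")
})

test_that("cost_distance equals the explicit-graph oracle on random NA-patched surfaces", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    s <- random_cost_surface(n, sample(5:25, 1), na_frac = runif(1, 0, 0.35))
    src <- first_passable_cell(s$grid$values)
    got <- cost_distance(s, src)$values
    want <- oracle_cost_distance(s$grid$values, src)
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-9)
  }
})

test_that("adding a source never increases any travel time", {
  set.seed(5)
  s <- random_cost_surface(15, 15, na_frac = 0.2)
  passable <- which(!is.na(s$grid$values), arr.ind = TRUE)
  one <- tibble::tibble(row = passable[1, 1], col = passable[1, 2])
  two <- tibble::tibble(row = passable[c(1, 40), 1], col = passable[c(1, 40), 2])
  d1 <- cost_distance(s, one)$values
  d2 <- cost_distance(s, two)$values
  ok <- !is.na(d1)
  expect_true(all(d2[ok] <= d1[ok] + 1e-12))
})

test_that("travel times satisfy single-step triangle consistency", {
  set.seed(17)
  s <- random_cost_surface(12, 12, na_frac = 0.15)
  src <- first_passable_cell(s$grid$values)
  d <- cost_distance(s, src)$values
  v <- s$grid$values
  n <- nrow(v)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if (is.na(v[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > n || cc < 1 || cc > n || is.na(v[rr, cc])) next
      step <- 0.5 * (v[r, c] + v[rr, cc]) * ifelse(dr != 0 && dc != 0, sqrt(2), 1)
      expect_lte(d[r, c], d[rr, cc] + step + 1e-9)
    }
  }
})

test_that("the two-pass rule opens water only where pass 1 is infinite", {
  scene <- make_island_scene(15)
  s <- build_cost_surfaces(scene$landcover, NULL, NULL, run_config())
  snap <- validate_and_snap(scene$facilities, s$blocked, rng_seed = 1)
  pass1 <- cost_distance(s$blocked, snap$source_cells)$values
  merged <- two_pass_travel_time(s$blocked, s$passable, snap$source_cells)$values

  island <- which(is.finite(pass1) == FALSE & scene$landcover$values == 3)
  expect_gt(length(island), 0)
  expect_true(all(pass1[island] == Inf))           # unreachable dry land, pass 1
  expect_true(all(is.finite(merged[island])))      # reachable over water
  mainland <- which(is.finite(pass1))
  expect_identical(merged[mainland], pass1[mainland])  # untouched by pass 2
  # pass-2 dominance: the blocked surface can only be slower
  pass2 <- cost_distance(s$passable, snap$source_cells)$values
  fin <- is.finite(pass1)
  expect_true(all(pass1[fin] >= pass2[fin] - 1e-9))
})

test_that("a waterless scene is untouched by the second pass", {
  scene <- make_uniform_scene(9)
  s <- build_cost_surfaces(scene$landcover, scene$dem, NULL, run_config())
  snap <- validate_and_snap(scene$facilities, s$blocked, rng_seed = 1)
  pass1 <- cost_distance(s$blocked, snap$source_cells)$values
  merged <- two_pass_travel_time(s$blocked, s$passable, snap$source_cells)$values
  expect_identical(merged, pass1)
})

test_that("an island sealed by impassable terrain in both passes becomes NA", {
  vals <- matrix(20, 9, 9)
  vals[4:6, 4:6] <- NA; vals[5, 5] <- 20   # cell sealed by NA ring in BOTH surfaces
  blocked <- uniform_surface(9); blocked$grid$values <- vals
  passable <- uniform_surface(9); passable$grid$values <- vals
  merged <- two_pass_travel_time(blocked, passable,
                                 tibble::tibble(row = 1L, col = 1L))$values
  expect_true(is.na(merged[5, 5]))
  expect_true(is.na(merged[4, 4]))   # NA surface cells stay NA
  expect_true(is.finite(merged[9, 9]))
})

test_that("seconds convert to minutes with infinity mapped to NA", {
  g <- geo_grid(matrix(c(14.4, 0, 60, 120), 2, 2))
  g$values[2, 2] <- Inf
  class(g) <- "geo_grid"
  m <- to_minutes(g)$values
  expect_equal(m[1, 1], 0.24)
  expect_equal(m[2, 1], 0)
  expect_equal(m[1, 2], 1)
  expect_true(is.na(m[2, 2]))
})

test_that("point extraction returns containing-cell values and warns off-grid", {
  g <- geo_grid(matrix(1:9, 3, 3), 30, 0.5, cs20)
  pts <- tibble::tibble(lon = c(30 + 0.5 * cs20, 30 + 2.5 * cs20, 50),
                        lat = c(0.5 - 0.5 * cs20, 0.5 - 2.5 * cs20, 0))
  expect_warning(v <- extract_at_points(g, pts), "outside")
  expect_equal(v, c(g$values[1, 1], g$values[3, 3], NA))
})

test_that("summary statistics report the six-number summary over non-NA values", {
  s <- summary_stats(c(1, 2, 3, 4, NA))
  expect_equal(s$min, 1); expect_equal(s$mean, 2.5); expect_equal(s$max, 4)
  s1 <- summary_stats(7)
  expect_true(all(unlist(s1) == 7))
  sc <- summary_stats(rep(3.3, 10))
  expect_equal(sc$max - sc$min, 0)
  expect_error(summary_stats(c(NA, NA)), "non-NA")
})

test_that("threshold counts bucket zeros, intervals and overflow", {
  tc <- threshold_counts(c(0, 10, 20, 40), c(15, 30))
  expect_equal(tc$count, c(1L, 1L, 1L, 1L))
  expect_equal(threshold_counts(numeric(), c(15, 30))$count, rep(0L, 4))
  over <- threshold_counts(c(100, 200), c(15, 30))
  expect_equal(over$count[4], 2L)
  expect_error(threshold_counts(1:3, c(30, 15)), "increasing")
})

test_that("rank correlation behaves like Spearman's rho with midrank ties", {
  a <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(rank_correlation(a, 2 * a), 1)
  expect_equal(rank_correlation(a, -a), -1)
  # hand-computable case: d^2 = (1,1,1,1,0), rho = 1 - 6*4/120
  expect_equal(rank_correlation(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(rank_correlation(1:4, 1:5), "length")
  expect_error(rank_correlation(1:2, 1:2), "3 pairs")
  expect_error(rank_correlation(c(1, NA, 3), c(1, 2, 3)), "non-NA")
})

test_that("travel_time_map assembles the result object with audit and tidiers", {
  scene <- make_random_scene(14, seed = 9, relief = 30)
  s <- build_cost_surfaces(scene$landcover, scene$dem, scene$roads, run_config())
  r <- travel_time_map(s$blocked, s$passable, scene$facilities, rng_seed = 4)
  expect_s3_class(r, "travel_time_result")
  v <- r$minutes$values
  srcs <- cbind(r$source_cells$row, r$source_cells$col)
  expect_true(all(v[srcs] == 0))
  expect_true(all(v[!is.na(v)] >= 0))
  expect_equal(sum(v[!is.na(v)] == 0), nrow(r$source_cells))
  td <- tidy(r)
  expect_equal(nrow(td), length(v))
  gl <- glance(r)
  expect_equal(gl$n_cells, length(v))
  expect_equal(gl$n_kept + gl$n_moved + gl$n_removed, nrow(scene$facilities))
})
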