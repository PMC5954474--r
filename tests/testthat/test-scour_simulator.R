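test_that("growth follows the linear recovery ramp exactly", {
  g <- seabed_grid(1, cell_area_km2 = 1, climax = 16, initial = "bare")
  expect_equal(step_growth(g, dt = 5, t_rec = 5)$stock, 16)    # full recovery
  expect_equal(step_growth(g, dt = 2.5, t_rec = 5)$stock, 8)   # half ramp
  expect_equal(step_growth(g, dt = 1, t_rec = 5)$stock, 3.2)
  at_climax <- seabed_grid(1, climax = 16, initial = "climax")
  expect_equal(step_growth(at_climax, dt = 100, t_rec = 5)$stock, 16) # fixed point
  expect_error(step_growth(g, dt = 0, t_rec = 5))
})

test_that("a scour event recycles stock times area and resets the cell", {
  g <- seabed_grid(2, cell_area_km2 = 1, climax = 16, initial = "climax")
  ev <- scour_event(g, 1)
  expect_equal(ev$recycled_t, 16)
  expect_equal(ev$grid$stock[1], 0)
  expect_equal(ev$grid$years_since_scour[1], 0)
  expect_equal(ev$grid$stock[2], 16) # untouched neighbour
  # freshly scoured cell recycles nothing; duplicates don't double-count
  ev2 <- scour_event(ev$grid, c(1, 1))
  expect_equal(ev2$recycled_t, 0)
  # half-recovered cell
  half <- step_growth(ev$grid, dt = 2.5, t_rec = 5)
  expect_equal(scour_event(half, 1)$recycled_t, 8)
})

test_that("grounding placement is depth-weighted and reproducible", {
  g <- seabed_grid(50, depth_m = 100, climax = 16)
  am <- arrival_model()
  expect_length(place_groundings(0, am, g, seed = 1), 0)
  expect_error(place_groundings(1, am, g[0, ], seed = 1), "empty grid")
  expect_identical(place_groundings(20, am, g, seed = 4),
                   place_groundings(20, am, g, seed = 4))

  # equal depths: counts consistent with a uniform multinomial (3 sd band)
  n <- 20000
  hits <- place_groundings(n, am, g, seed = 8)
  counts <- tabulate(hits, nbins = 50)
  expected <- n / 50
  sd3 <- 3 * sqrt(n * (1 / 50) * (49 / 50))
  expect_true(all(abs(counts - expected) <= sd3))

  # two depth strata: selection odds approx exp(300/150) = e^2
  g2 <- seabed_grid(2, depth_m = c(100, 400), climax = 16)
  hits2 <- place_groundings(50000, am, g2, seed = 9)
  odds <- sum(hits2 == 1) / sum(hits2 == 2)
  expect_lt(abs(odds - exp(2)) / exp(2), 0.1)

  # hotspot placement only ever strikes the hotspot subset
  amh <- arrival_model(placement = "hotspot", hotspot_cells = c(3, 7))
  expect_true(all(place_groundings(200, amh, g, seed = 2) %in% c(3, 7)))
  expect_error(arrival_model(placement = "hotspot"), "non-empty")
})

test_that("no arrivals means full recovery and zero recycling", {
  g <- seabed_grid(10, climax = 16, initial = "bare")
  sim <- run_simulation(g, arrival_model(groundings_per_year = 0),
                        years = 10, seed = 1, t_rec = 5)
  expect_equal(sum(sim$annual$recycled_t), 0)
  expect_equal(sim$grid$stock, rep(16, 10))
  expect_true(check_conservation(sim))
})

test_that("an annually re-scoured cell recycles climax/T_rec per event", {
  g <- seabed_grid(1, cell_area_km2 = 1, climax = 16)
  am <- arrival_model(groundings_per_year = 1, cells_per_grounding = 1)
  sim <- run_simulation(g, am, years = 40, seed = 3, t_rec = 5)
  steady <- sim$annual$recycled_t[-1] # first event recycles the climax stock
  expect_equal(steady, rep(16 / 5, 39))
  expect_true(check_conservation(sim))
})

test_that("carbon is conserved exactly under stochastic scour", {
  for (seed in 1:3) {
    g <- seabed_grid(60, cell_area_km2 = 25, depth_m = rep(c(100, 300), 30),
                     climax = 16)
    am <- arrival_model(groundings_per_year = 8, iceberg_area_km2 = 500)
    sim <- run_simulation(g, am, years = 25, seed = seed, t_rec = 5)
    expect_true(check_conservation(sim))
    # ledger totals match the annual series exactly
    expect_equal(sum(sim$events$recycled_t), sum(sim$annual$recycled_t))
  }
})

test_that("first-year recycling is bounded by the static cost formula", {
  # grid at climax: the first year's recycled carbon equals the sum of
  # scoured-cell stocks, bounded by q * scoured area * rho
  g <- seabed_grid(400, cell_area_km2 = 25, climax = 16)
  am <- arrival_model(groundings_per_year = 8, iceberg_area_km2 = 1250)
  sim <- run_simulation(g, am, years = 1, seed = 5, t_rec = 5)
  expect_lte(sim$annual$recycled_t[1], 0.25 * 10000 * 16)
  expect_equal(sim$annual$recycled_t[1], sum(sim$events$recycled_t))
})

test_that("simulation runs are deterministic in their seed", {
  g <- seabed_grid(40, climax = 16)
  am <- arrival_model(groundings_per_year = 4, count_model = "poisson",
                      iceberg_area_km2 = 200)
  s1 <- run_simulation(g, am, years = 15, seed = 21)
  s2 <- run_simulation(g, am, years = 15, seed = 21)
  expect_identical(s1$annual, s2$annual)
  expect_identical(s1$events, s2$events)
})

test_that("fast-ice modulation scales the arrival rate", {
  g <- seabed_grid(50, climax = 16)
  # 0 open-water days -> multiplier 1; many open-water days -> more events
  am_lo <- arrival_model(groundings_per_year = 2, fastice_coef = 0.01,
                         open_water_days = 0, iceberg_area_km2 = 25)
  am_hi <- arrival_model(groundings_per_year = 2, fastice_coef = 0.01,
                         open_water_days = 200, iceberg_area_km2 = 25)
  s_lo <- run_simulation(g, am_lo, years = 10, seed = 2)
  s_hi <- run_simulation(g, am_hi, years = 10, seed = 2)
  expect_equal(sum(s_lo$annual$n_events), 20)  # 2/yr unmodulated
  expect_equal(sum(s_hi$annual$n_events), 60)  # 2 * (1 + 0.01*200) = 6/yr
})
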