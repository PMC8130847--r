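single_element_field <- function(strain) {
  scaffold_field(data.frame(element_id = 1L, volume = 1,
                            max_principal_strain = strain))
}

test_that("a single element dies within dt of its closed-form fracture time", {
  f <- single_element_field(0.3)
  sim <- run_degradation(f, simulation_config(dt = 0.25, horizon = 60))
  expect_equal(nrow(sim$events), 1L)
  expect_lt(abs(sim$events$time_days - fracture_time(0.3)), 0.25 + 1e-9)
  # at death the degree satisfies the death criterion
  expect_gte(sim$events$degree, 1 - 0.3 / 1.22 - 1e-9)
})

test_that("fast and slow elements separate as the fracture curve predicts", {
  f <- scaffold_field(data.frame(element_id = 1:2, volume = 1,
                                 max_principal_strain = c(0.3, 0.02)))
  sim <- run_degradation(f, simulation_config(dt = 0.5, horizon = 180))
  expect_equal(sim$events$element_id, 1L)          # only the strained one
  expect_lt(sim$events$time_days, 30)
  last <- sim$trajectory[nrow(sim$trajectory), ]
  expect_equal(last$n_alive, 1L)                   # 0.02 outlives 180 d
  expect_equal(last$mass_loss_ratio, 0.5)
})

test_that("an unstrained element survives any horizon below its fracture time", {
  f <- single_element_field(0)
  sim <- run_degradation(f, simulation_config(dt = 1, horizon = 360))
  expect_equal(nrow(sim$events), 0L)
  expect_gt(fracture_time(0), 360)
})

test_that("simulated death times track fracture_time across random strains", {
  set.seed(31)
  strain <- runif(200, 0.01, 0.5)
  f <- scaffold_field(data.frame(element_id = seq_along(strain), volume = 1,
                                 max_principal_strain = strain))
  sim <- run_degradation(f, simulation_config(dt = 0.25, horizon = 330),
                         keep_snapshots = FALSE)
  expect_equal(nrow(sim$events), length(strain))   # all die within 330 d
  predicted <- fracture_time(sim$events$strain)
  expect_true(all(abs(sim$events$time_days - predicted) <= 0.25 + 1e-9))
})

test_that("halving dt moves no death time by more than the larger dt", {
  f <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 13))
  coarse <- run_degradation(f, simulation_config(dt = 1, horizon = 120),
                            keep_snapshots = FALSE)
  fine <- run_degradation(f, simulation_config(dt = 0.5, horizon = 120),
                          keep_snapshots = FALSE)
  shared <- intersect(coarse$events$element_id, fine$events$element_id)
  tc <- coarse$events$time_days[match(shared, coarse$events$element_id)]
  tf <- fine$events$time_days[match(shared, fine$events$element_id)]
  expect_true(all(abs(tc - tf) <= 1 + 1e-9))
})

test_that("mass loss is non-decreasing and capacity non-increasing", {
  f <- generate_stent_field(stent_field_spec(seed = 17))
  sim <- run_degradation(f, simulation_config(dt = 0.5, horizon = 180))
  tr <- sim$trajectory
  expect_true(all(diff(tr$mass_loss_ratio) >= -1e-12))
  expect_true(all(diff(tr$capacity) <= 1e-12))
  # mass conservation at every snapshot
  total <- sum(f$elements$volume)
  for (st in sim$snapshots)
    expect_equal(sum(f$elements$volume[st$alive]) + st$dead_mass, total)
})

test_that("capacity surrogate follows its definition", {
  r8 <- ring_field(8)
  expect_identical(capacity_surrogate(scaffold_state(r8), r8), 1)
  expect_identical(capacity_surrogate(kill_elements(r8, 1:8), r8), 0)
  # half the mass dead but the loop intact on a doubled ring:
  # outer cycle of 4 alive, 4 pendant dead elements
  f <- scaffold_field(
    data.frame(element_id = 1:8, volume = 1, max_principal_strain = 0.1),
    edges = rbind(cbind(1:4, c(2:4, 1)), cbind(1:4, 5:8)))
  expect_equal(capacity_surrogate(kill_elements(f, 5:8), f), 0.5)
  # breaking every cycle zeroes the capacity even with mass remaining
  expect_identical(capacity_surrogate(kill_elements(r8, 3), r8), 0)
  # edge-free point clouds carry no topology: plain alive fraction
  pts <- scaffold_field(data.frame(element_id = 1:4, volume = 1,
                                   max_principal_strain = 0.1))
  expect_equal(capacity_surrogate(kill_elements(pts, 1), pts), 0.75)
})

test_that("crowns die first and discontinuity follows the first deaths", {
  f <- generate_stent_field(stent_field_spec(seed = 42))
  sim <- run_degradation(f, simulation_config(dt = 0.5, horizon = 180))
  role <- f$elements$role[match(sim$events$element_id,
                                f$elements$element_id)]
  expect_equal(role[1], "crown")
  # every element that died before the first body death is crown or link
  t_body <- suppressWarnings(min(sim$events$time_days[role == "body"]))
  expect_true(all(role[sim$events$time_days < t_body] != "body"))
  # fragmentation happens only after the first death
  tr <- sim$trajectory
  frag <- tr$time_days[tr$n_components > tr$n_components[1]]
  if (length(frag))
    expect_gte(min(frag), min(sim$events$time_days))
  expect_gt(nrow(sim$events), 0L)
})

test_that("the strain-update hook feeds back into damage accumulation", {
  f <- single_element_field(0.05)
  # externally raise the strain to 0.4 after the first month
  hook <- function(t, strain) if (t >= 30) rep(0.4, length(strain)) else strain
  sim <- run_degradation(f, simulation_config(dt = 0.5, horizon = 120),
                         strain_update = hook)
  base <- run_degradation(f, simulation_config(dt = 0.5, horizon = 120))
  expect_equal(nrow(sim$events), 1L)     # dies under the raised strain
  expect_equal(nrow(base$events), 0L)    # frozen field survives
})

test_that("simulator validates its configuration", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(horizon = 0.1), "horizon")
  expect_error(simulation_config(dt = 0.7, snapshot_interval = 30),
               "multiple")
  expect_error(simulation_config(accumulation = "magic"), "arg")
  f <- single_element_field(0.1)
  expect_error(run_degradation(f, list()), "simulation_config")
})

test_that("trajectory bookkeeping is coherent", {
  f <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 3))
  sim <- run_degradation(f, simulation_config(dt = 1, horizon = 95,
                                              snapshot_interval = 30))
  tr <- sim$trajectory
  expect_equal(tr$time_days, c(0, 30, 60, 90, 95))  # horizon row appended
  expect_equal(tr$n_alive + tr$n_dead, rep(nrow(f$elements), nrow(tr)))
  expect_equal(tr$time_months, tr$time_days / 30)
  expect_equal(sim$fracture_curve$fracture_time_months,
               sim$fracture_curve$fracture_time_days / 30)
  expect_output(print(sim), "fracture events")
})
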