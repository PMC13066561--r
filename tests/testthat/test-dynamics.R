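test_that("simulation parameters carry the integration settings", {
  p <- simulation_params(n_steps = 100, seed = 5)
  expect_equal(p$dt, 0.2)
  expect_equal(p$temperature, 300)
  expect_equal(p$gamma, 0.25)
  expect_equal(p$seed, 5)
})

test_that("trajectories are bit-exact reproducible for equal seeds", {
  topo <- small_duplex()
  p <- simulation_params(n_steps = 400, save_interval = 50, seed = 7,
                         equilibration_steps = 0)
  t1 <- run_langevin(topo, params = p)
  t2 <- run_langevin(topo, params = p)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final_vel, t2$final_vel)
  p2 <- simulation_params(n_steps = 400, save_interval = 50, seed = 8,
                          equilibration_steps = 0)
  t3 <- run_langevin(topo, params = p2)
  expect_gt(max(abs(t3$final_pos - t1$final_pos)), 1e-6)
})

test_that("a restarted run continues the original bit-exactly", {
  topo <- small_duplex()
  p_full <- simulation_params(n_steps = 400, save_interval = 50, seed = 7,
                              equilibration_steps = 0)
  t_full <- run_langevin(topo, params = p_full)
  p_half <- simulation_params(n_steps = 200, save_interval = 50, seed = 7,
                              equilibration_steps = 0)
  ta <- run_langevin(topo, params = p_half)
  tb <- run_langevin(topo, initial_state = ta$final_pos, params = p_half,
                     velocities = ta$final_vel, start_step = ta$final_step)
  expect_identical(tb$final_pos, t_full$final_pos)
  expect_identical(tb$final_vel, t_full$final_vel)
})

test_that("energy is conserved without thermostat (gamma = 0)", {
  topo <- small_duplex()
  p <- simulation_params(dt = 0.1, n_steps = 4000, gamma = 0, seed = 3,
                         save_interval = 10, equilibration_steps = 0)
  tr <- run_langevin(topo, params = p)
  etot <- tr$kinetic[-1] + tr$potential[-1]
  drift <- (max(etot) - min(etot)) / abs(mean(etot))
  expect_lt(drift, 0.01)
})

test_that("trajectory bookkeeping is consistent", {
  topo <- small_duplex()
  p <- simulation_params(n_steps = 300, save_interval = 50, seed = 1,
                         equilibration_steps = 100)
  tr <- run_langevin(topo, params = p)
  expect_equal(n_frames(tr), 7)  # initial frame + 6 saves
  expect_equal(tr$steps, seq(0, 300, by = 50))
  af <- analysis_frames(tr)
  expect_true(all(tr$steps[af] > 100))
  expect_equal(dim(tr$frames), c(nrow(topo$beads), 3, 7))
})

test_that("replica sets use consecutive distinct seeds", {
  topo <- small_duplex()
  p <- simulation_params(n_steps = 100, save_interval = 50, seed = 1,
                         equilibration_steps = 0)
  reps <- run_replicas(topo, p, n_replicas = 3, base_seed = 7)
  expect_s3_class(reps, "cg_replica_set")
  expect_equal(reps$seeds, c(7, 8, 9))
  expect_equal(vapply(reps$trajectories, function(t) t$seed, 1), c(7, 8, 9))
  expect_gt(max(abs(reps$trajectories[[1]]$final_pos -
                      reps$trajectories[[2]]$final_pos)), 1e-6)
  expect_error(run_replicas(topo, p, n_replicas = 0))
})
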