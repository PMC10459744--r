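# Placement, velocity initialisation, and the integrator in its three modes.

test_that("random placement is deterministic, overlap-free, in-box", {
  tpl <- build_template()
  st1 <- place_capsomers(6, 32, tpl, seed = 4)
  st2 <- place_capsomers(6, 32, tpl, seed = 4)
  expect_identical(st1$pos, st2$pos)
  st3 <- place_capsomers(6, 32, tpl, seed = 5)
  expect_false(identical(st1$pos, st3$pos))
  # pairwise bead distances respect contact distances
  for (a in 1:5) for (b in (a + 1):6) {
    pa <- st1$pos[st1$caps == a, ]
    pb <- st1$pos[st1$caps == b, ]
    ra <- st1$radius[st1$caps == a]
    rb <- st1$radius[st1$caps == b]
    dmin <- Inf
    for (i in seq_len(nrow(pa))) {
      dv <- min_image(sweep(pb, 2, pa[i, ]), st1$L)
      dmin <- min(dmin, sqrt(rowSums(dv^2)) - ra[i] - rb)
    }
    expect_gte(dmin, 0)
  }
  expect_error(place_capsomers(60, 18, tpl, seed = 1, max_tries = 20),
               "larger box")
})

test_that("velocities start uniform, mean-free, and optionally rescaled", {
  tpl <- build_template()
  st <- place_capsomers(2, 30, tpl, seed = 1)
  st <- init_velocities(st, seed = 9)
  expect_lt(max(abs(colMeans(st$vel))), 1e-14)
  expect_true(all(abs(st$vel) < 0.5 + 0.05))  # uniform draw plus mean shift
  expect_identical(init_velocities(st, 9)$vel, st$vel)
  stT <- init_velocities(st, 9, temperature = 1)
  ndf <- 3 * nrow(stT$pos) - 3
  expect_equal(sum(stT$mass * rowSums(stT$vel^2)) / ndf, 1,
               tolerance = 1e-12)
})

test_that("force-free beads move in straight lines", {
  st <- make_harmonic_pair(k_s = 100, rest = 1)
  st$vel <- rbind(c(0.1, -0.2, 0.05), c(0.1, -0.2, 0.05))  # no relative motion
  r <- run_md(st, 200, dt = 1e-3, mode = "nve", sample_every = 0,
              save_frames = FALSE)
  expect_equal(r$state$pos, st$pos + 200 * 1e-3 * st$vel, tolerance = 1e-12)
})

test_that("a resting harmonic pair stays static", {
  st <- make_harmonic_pair(k_s = 300, rest = 1, stretch = 0)
  r <- run_md(st, 500, dt = 1e-3, mode = "nve", sample_every = 0,
              save_frames = FALSE)
  expect_equal(r$state$pos, st$pos, tolerance = 1e-12)
})

test_that("harmonic pair oscillates at the closed-form period", {
  ks <- 300
  st <- make_harmonic_pair(k_s = ks, rest = 1, stretch = 0.1)
  r <- run_md(st, 4000, dt = 5e-4, mode = "nve", sample_every = 2,
              save_frames = TRUE)
  ext <- vapply(r$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)) - 1,
                numeric(1))
  t <- r$samples$time
  s <- which(ext[-1] > 0 & ext[-length(ext)] <= 0)
  cross <- t[s] + (t[s + 1] - t[s]) * (-ext[s]) / (ext[s + 1] - ext[s])
  period <- mean(diff(cross))
  expect_equal(period, 2 * pi * sqrt(0.5 / ks), tolerance = 1e-3)
})

test_that("energy exchange conserves the total for the harmonic pair", {
  st <- make_harmonic_pair(k_s = 300, rest = 1, stretch = 0.15)
  r <- run_md(st, 5000, dt = 5e-4, mode = "nve", sample_every = 100,
              save_frames = FALSE)
  s <- r$samples
  expect_gt(max(s$kinetic), 0.5 * max(s$stretching))  # energy does flow
  expect_lt(diff(range(s$conserved)) / mean(s$conserved), 1e-4)
})

test_that("NVE conserves energy and momentum for a thermalised dimer", {
  st <- make_bound_dimer(eps_att = 2, relax = 1500)
  st <- init_velocities(st, 1, temperature = 1)
  st <- run_md(st, 1500, dt = 5e-4, mode = "nvt", sample_every = 0,
               save_frames = FALSE)$state
  r <- run_md(st, 10000, dt = 5e-4, mode = "nve", sample_every = 200,
              save_frames = FALSE)
  E <- r$samples$conserved
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
  p <- colSums(r$state$mass * r$state$vel)
  p0 <- colSums(st$mass * st$vel)
  expect_equal(p, p0, tolerance = 1e-10)
})

test_that("the thermostat's conserved quantity is stable", {
  tpl <- build_template()
  st <- make_system(tpl, list(list(rotation = diag(3),
                                   translation = rep(15, 3))), 30)
  st <- init_velocities(st, 3, temperature = 1)
  r <- run_md(st, 10000, dt = 5e-4, mode = "nvt", sample_every = 500,
              save_frames = FALSE)
  C <- r$samples$conserved
  expect_lt(diff(range(C)) / max(1, abs(mean(C))), 1e-3)
})

test_that("equipartition: single-edge RMS matches sqrt(kBT / k_s)", {
  st <- make_harmonic_pair(k_s = 500, rest = 1.5)
  st <- init_velocities(st, 5)
  r <- run_md(st, 300000, dt = 1e-3, mode = "nvt", tau = 0.05,
              sample_every = 25, save_frames = TRUE)
  ext <- vapply(r$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)) - 1.5,
                numeric(1))
  keep <- seq(floor(length(ext) * 0.25), length(ext))
  expect_equal(sqrt(mean(ext[keep]^2)), sqrt(1 / 500), tolerance = 0.05)
})

test_that("quench mode decreases the potential energy", {
  st <- make_bound_dimer(eps_att = 2, relax = 0, separation = 1.05)
  e0 <- total_energy(st)[["total"]]
  r <- run_md(st, 500, dt = 0.002, mode = "quench", sample_every = 0,
              save_frames = FALSE)
  expect_lt(total_energy(r$state)[["total"]], e0)
})

test_that("runs are deterministic and restartable from checkpoints", {
  st <- make_bound_dimer(eps_att = 2, relax = 500)
  st <- init_velocities(st, 2, temperature = 1)
  full <- run_md(st, 2000, dt = 5e-4, sample_every = 0, save_frames = FALSE)
  half <- run_md(st, 1000, dt = 5e-4, sample_every = 0, save_frames = FALSE)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(half$state, f)
  resumed <- run_md(load_checkpoint(f), 1000, dt = 5e-4, sample_every = 0,
                    save_frames = FALSE)
  expect_identical(resumed$state$pos, full$state$pos)
  expect_identical(resumed$state$vel, full$state$vel)
  unlink(f)
})

test_that("step_nvt advances one step and keeps the state class", {
  st <- make_bound_dimer(eps_att = 2, relax = 200)
  st <- init_velocities(st, 1, temperature = 1)
  st2 <- step_nvt(st)
  expect_s3_class(st2, "capsomer_system")
  expect_equal(st2$step, st$step + 1L)
  expect_false(identical(st2$pos, st$pos))
})

test_that("integration blow-up is reported with the step index", {
  st <- make_harmonic_pair(k_s = 5000, rest = 1, stretch = 2)
  expect_error(run_md(st, 1000, dt = 0.5, mode = "nve", sample_every = 0,
                      save_frames = FALSE), "step")
})

test_that("configuration validation enforces the timestep bounds", {
  expect_error(sim_config(kappa_b = 10, k_s = 300, dt = 0.002), "0.0005")
  expect_equal(sim_config(kappa_b = 5000, k_s = 5000)$dt, 0.002)
  expect_equal(sim_config(kappa_b = 10, k_s = 1000)$dt, 5e-4)
})

test_that("run_simulation writes config echo, metrics, trajectory, checkpoint", {
  out <- file.path(tempdir(), "softcapsid-run")
  cfg <- sim_config(n_capsomers = 2, box_edge = 30, n_steps = 1500,
                    sample_every = 500, seed = 3)
  run <- run_simulation(cfg, output_dir = out)
  expect_s3_class(run, "md_run")
  expect_true(file.exists(file.path(out, "config.json")))
  expect_true(file.exists(file.path(out, "energies.csv")))
  expect_true(file.exists(file.path(out, "trajectory.xyz")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  echoed <- jsonlite::read_json(file.path(out, "config.json"))
  expect_equal(echoed$n_capsomers, 2)
  unlink(out, recursive = TRUE)
})
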