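# System construction and time evolution: random non-overlapping placement,
# velocity initialisation, and velocity Verlet dynamics in the NVT (Nose-
# Hoover chain), NVE, or damped-quench modes.

#' Assemble a capsomer system from template copies
#'
#' Low-level constructor: instantiates `length(placements)` copies of a
#' template at given rigid-body placements and concatenates their bead and
#' edge tables into a single simulation state.
#'
#' @param template A [build_template()] object.
#' @param placements List of placements, each a list with `rotation`
#'   (3x3 matrix) and `translation` (3-vector).
#' @param box_edge Periodic cubic box edge, nm (use 0 for an open box).
#' @param eps_att Steric attraction strength, kBT.
#' @param electro Optional [electro_params()] for charged systems.
#' @param skin Verlet neighbor-list skin, nm.
#' @return A `capsomer_system` object.
#' @export
make_system <- function(template, placements, box_edge, eps_att = 2,
                        electro = NULL, skin = 0.4) {
  n <- length(placements)
  tb <- template$beads
  nb1 <- nrow(tb)
  xyz0 <- as.matrix(tb[, c("x", "y", "z")])
  pos <- matrix(0, n * nb1, 3)
  for (k in seq_len(n)) {
    p <- placements[[k]]
    pos[(k - 1) * nb1 + seq_len(nb1), ] <-
      sweep(xyz0 %*% t(p$rotation), 2, -p$translation)
  }
  role_code <- c(repulsive = 0L, attractive = 1L, interior = 2L)
  off <- rep((seq_len(n) - 1L) * nb1, each = nrow(template$bonds))
  bonds <- template$bonds[rep(seq_len(nrow(template$bonds)), n), 1:2,
                          drop = FALSE] + off
  rest <- rep(template$bonds[, "rest"], n)
  offb <- rep((seq_len(n) - 1L) * nb1, each = nrow(template$bends))
  bends <- template$bends[rep(seq_len(nrow(template$bends)), n), ,
                          drop = FALSE] + offb

  state <- list(
    pos = pos,
    vel = matrix(0, n * nb1, 3),
    L = box_edge,
    caps = rep(seq_len(n), each = nb1),
    role = rep(role_code[tb$role], n),
    radius = rep(tb$radius, n),
    charge = rep(tb$charge, n),
    mass = rep(tb$mass, n),
    bonds = bonds,
    rest = rest,
    bends = bends,
    kappa_b = template$kappa_b,
    k_s = template$k_s,
    eps_att = eps_att,
    electro = electro,
    template = template,
    n_capsomers = n,
    skin = skin,
    step = 0L,
    thermostat = list(xi = numeric(3), vxi = numeric(3))
  )
  class(state) <- "capsomer_system"
  state
}

#' @export
print.capsomer_system <- function(x, ...) {
  cat(sprintf("Capsomer system: %d capsomers, %d beads, box edge %g nm\n",
              x$n_capsomers, nrow(x$pos), x$L))
  cat(sprintf("  kappa_b = %g, k_s = %g, eps_att = %g%s\n", x$kappa_b, x$k_s,
              x$eps_att,
              if (is.null(x$electro)) "" else
                sprintf(", Yukawa lB = %.3g nm, lambda_D = %.3g nm",
                        x$electro$lB, x$electro$lambda_D)))
  if (x$L > 0)
    cat(sprintf("  concentration: %.0f uM\n",
                concentration_from_state(x$n_capsomers, x$L)))
  invisible(x)
}

# uniform random rotation matrix (Shoemake quaternion method, uses R's RNG)
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation by `angle` about unit `axis` (Rodrigues)
.axis_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Randomly place capsomers in a periodic box
#'
#' Places `n` copies of the template at uniform random positions and uniform
#' random orientations, rejecting placements that overlap earlier capsomers
#' (any inter-capsomer bead pair closer than the sum of the bead radii).
#' Deterministic for a given seed.
#'
#' @param n Number of capsomers.
#' @param box_edge Cubic box edge, nm.
#' @param template A [build_template()] object.
#' @param seed Integer RNG seed.
#' @param eps_att,electro,skin Passed to [make_system()].
#' @param max_tries Attempts per capsomer before giving up.
#' @return A `capsomer_system` with zero velocities.
#' @export
place_capsomers <- function(n, box_edge, template, seed, eps_att = 2,
                            electro = NULL, skin = 0.4, max_tries = 2000) {
  stopifnot(n >= 1, box_edge > 0)
  set.seed(seed)
  xyz0 <- as.matrix(template$beads[, c("x", "y", "z")])
  radius <- template$beads$radius
  placements <- vector("list", n)
  placed_pos <- matrix(numeric(0), ncol = 3)
  placed_rad <- numeric(0)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      rot <- .random_rotation()
      trans <- stats::runif(3, 0, box_edge)
      cand <- sweep(xyz0 %*% t(rot), 2, -trans)
      if (nrow(placed_pos) == 0 ||
          !cpp_any_overlap(placed_pos, placed_rad, cand, radius, box_edge)) {
        placements[[k]] <- list(rotation = rot, translation = trans)
        placed_pos <- rbind(placed_pos, cand)
        placed_rad <- c(placed_rad, radius)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not place capsomer %d of %d after %d tries; use a larger box",
        k, n, max_tries))
  }
  state <- make_system(template, placements, box_edge, eps_att = eps_att,
                       electro = electro, skin = skin)
  state$seed <- seed
  state
}

#' Initialise bead velocities
#'
#' Draws every velocity component i.i.d. uniform on [-0.5, 0.5] (reduced
#' units) and then removes the mean so the average bead velocity is exactly
#' the zero vector. The thermostat subsequently relaxes the distribution to
#' Maxwell-Boltzmann. The bare uniform draw corresponds to a kinetic
#' temperature of about 1/12; passing `temperature` rescales the
#' mean-centred draw so the initial kinetic temperature matches the target,
#' which avoids the violent heat-up transient when a run starts from a
#' carefully prepared (e.g. energy-minimised) configuration.
#'
#' @param state A `capsomer_system`.
#' @param seed Integer RNG seed.
#' @param temperature Optional reduced kinetic temperature to scale the
#'   initial velocities to (`NULL` keeps the bare uniform draw).
#' @return The state with velocities set.
#' @export
init_velocities <- function(state, seed, temperature = NULL) {
  set.seed(seed)
  nb <- nrow(state$pos)
  v <- matrix(stats::runif(3 * nb, -0.5, 0.5), nb, 3)
  v <- sweep(v, 2, colMeans(v))
  if (!is.null(temperature)) {
    ndf <- 3 * nb - 3
    ke <- 0.5 * sum(state$mass * rowSums(v^2))
    v <- v * sqrt(temperature * ndf / (2 * ke))
  }
  state$vel <- v
  state
}

#' Propagate the system with velocity Verlet
#'
#' Integrates the equations of motion for `n_steps` steps of size `dt`
#' (reduced time). In `"nvt"` mode each velocity Verlet step is wrapped in
#' half-steps of a Nose-Hoover chain thermostat (chain length 3,
#' Suzuki-Yoshida subcycling) targeting `temperature`; `"nve"` runs plain
#' velocity Verlet; `"quench"` performs damped dynamics towards a local
#' energy minimum (velocities zeroed whenever the power F.v turns negative).
#' The neighbor list is rebuilt automatically whenever any bead has moved
#' more than half the skin. Propagation is deterministic: re-running from a
#' checkpointed state reproduces the uninterrupted trajectory bit for bit.
#'
#' @param state A `capsomer_system`.
#' @param n_steps Number of timesteps.
#' @param dt Timestep, reduced units (0.002 suits the rigid moduli
#'   (5000, 5000); deformable moduli need 0.0005 for energy conservation).
#' @param mode `"nvt"`, `"nve"`, or `"quench"`.
#' @param temperature Target reduced temperature (1 = 298 K).
#' @param tau Thermostat coupling time, reduced units.
#' @param sample_every Sampling cadence in steps (0 disables sampling).
#' @param save_frames Keep sampled bead positions (needed for trajectory
#'   analysis).
#' @return Object of class `md_run`: the updated `state`, a `samples` data
#'   frame (step, time, energy components, temperature, conserved quantity),
#'   and a list of sampled `frames`.
#' @export
run_md <- function(state, n_steps, dt = 5e-4,
                   mode = c("nvt", "nve", "quench"), temperature = 1,
                   tau = 100 * dt, sample_every = 500, save_frames = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_steps >= 1, dt > 0)
  a <- .sys_args(state)
  imode <- match(mode, c("nve", "nvt", "quench")) - 1L
  res <- cpp_run_md(a$pos, state$vel, a$L, a$caps, a$role, a$radius,
                    a$charge, a$mass, a$bonds, a$rest, a$ks, a$bends, a$kb,
                    a$eps_att, a$use_elec, a$lB, a$lamD, a$rc_elec, a$skin,
                    dt, as.integer(n_steps), imode, temperature, tau, 3L,
                    state$thermostat$xi, state$thermostat$vxi,
                    as.integer(sample_every), save_frames)
  state$pos <- res$pos
  state$vel <- res$vel
  state$thermostat <- list(xi = res$xi, vxi = res$vxi)
  state$step <- state$step + as.integer(n_steps)
  out <- list(state = state, samples = res$samples, frames = res$frames,
              dt = dt, mode = mode, sample_every = sample_every)
  class(out) <- "md_run"
  out
}

#' @export
print.md_run <- function(x, ...) {
  s <- x$samples
  cat(sprintf("MD run (%s): %d sampled points, final step %d\n", x$mode,
              nrow(s), x$state$step))
  if (nrow(s) > 0) {
    last <- s[nrow(s), ]
    cat(sprintf("  final T = %.3f, PE = %.2f kBT, KE = %.2f kBT\n",
                last$temperature,
                last$steric_repulsive + last$steric_attractive +
                  last$bending + last$stretching + last$electrostatic,
                last$kinetic))
  }
  invisible(x)
}

#' Single NVT timestep
#'
#' One velocity Verlet step wrapped in Nose-Hoover chain half-steps;
#' a convenience wrapper around [run_md()].
#'
#' @inheritParams run_md
#' @return The updated `capsomer_system`.
#' @export
step_nvt <- function(state, dt = 5e-4, temperature = 1, tau = 100 * dt) {
  run_md(state, 1L, dt, mode = "nvt", temperature = temperature, tau = tau,
         sample_every = 0L, save_frames = FALSE)$state
}

#' Simulation configuration
#'
#' Collects every Hamiltonian and protocol parameter of a run. Defaults
#' follow the standard study conditions: 100 capsomers in a 59 nm box
#' (about 800 uM), 298 K, sampling every 500,000 steps, and a timestep of
#' 0.002 for the rigid moduli (5000, 5000) or 0.0005 otherwise.
#'
#' @param n_capsomers Number of capsomers.
#' @param box_edge Cubic box edge, nm.
#' @param kappa_b,k_s Elastic moduli (kBT, kBT/nm^2).
#' @param eps_att Steric attraction, kBT.
#' @param charged Charged capsomers (adds Yukawa electrostatics).
#' @param salt_M Monovalent salt concentration, mol/L (charged runs).
#' @param dt Timestep (reduced); chosen from the moduli when `NULL`.
#' @param n_steps Total number of steps.
#' @param sample_every Sampling cadence, steps.
#' @param seed Integer RNG seed for placement and velocities.
#' @param temperature Reduced target temperature.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_capsomers = 100, box_edge = 59, kappa_b = 10,
                       k_s = 1000, eps_att = 2, charged = FALSE,
                       salt_M = 0.1, dt = NULL, n_steps = 1e5,
                       sample_every = 5e5, seed = 1, temperature = 1) {
  rigid <- kappa_b >= 5000 && k_s >= 5000
  if (is.null(dt)) dt <- if (rigid) 0.002 else 5e-4
  if (!rigid && dt > 5e-4)
    stop("deformable moduli require dt <= 0.0005 for stable integration")
  if (dt > 0.002) stop("dt must not exceed 0.002")
  cfg <- list(n_capsomers = n_capsomers, box_edge = box_edge,
              kappa_b = kappa_b, k_s = k_s, eps_att = eps_att,
              charged = charged, salt_M = salt_M, dt = dt,
              n_steps = n_steps, sample_every = sample_every, seed = seed,
              temperature = temperature)
  class(cfg) <- "sim_config"
  cfg
}

#' Run a full simulation from a configuration
#'
#' Builds the template and system from a [sim_config()], initialises
#' velocities, propagates in the NVT ensemble, and (optionally) writes the
#' echoed configuration, per-sample energy breakdown CSV, XYZ trajectory and
#' a checkpoint into `output_dir`.
#'
#' @param config A [sim_config()] (or a list of arguments for it).
#' @param output_dir Output directory; `NULL` for no files.
#' @return An `md_run` object.
#' @export
run_simulation <- function(config, output_dir = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  template <- build_template(kappa_b = config$kappa_b, k_s = config$k_s,
                             charged = config$charged)
  electro <- if (config$charged) electro_params(config$salt_M) else NULL
  state <- place_capsomers(config$n_capsomers, config$box_edge, template,
                           seed = config$seed, eps_att = config$eps_att,
                           electro = electro)
  state <- init_velocities(state, seed = config$seed + 1L)
  run <- run_md(state, config$n_steps, config$dt, mode = "nvt",
                temperature = config$temperature,
                sample_every = config$sample_every)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(config),
                         file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(run$samples, file.path(output_dir, "energies.csv"),
                     row.names = FALSE)
    if (length(run$frames) > 0)
      write_xyz(run$frames, state, file.path(output_dir, "trajectory.xyz"))
    save_checkpoint(run$state, file.path(output_dir, "checkpoint.rds"))
  }
  run
}

#' Save / restore a simulation checkpoint
#'
#' The checkpoint holds the complete `capsomer_system` (positions,
#' velocities, thermostat chain state, step counter), so a restored run
#' continues bit-identically.
#'
#' @param state A `capsomer_system`.
#' @param file Path to the checkpoint file (RDS container).
#' @return `load_checkpoint` returns the restored `capsomer_system`.
#' @export
save_checkpoint <- function(state, file) {
  saveRDS(state, file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(file) {
  readRDS(file)
}
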