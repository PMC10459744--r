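# Deterministic small test systems: a bound dimer, planted clusters with
# known sizes, and a single harmonic pair. All are generated from code so
# geometry changes propagate automatically.

#' Bound capsomer dimer
#'
#' Two capsomers with one pair of lateral walls in contact: the second
#' capsomer is the first rotated by 180 degrees about the in-wall slope axis
#' through a point half the contact separation outside the wall, which
#' mirrors the wall onto itself so the attractive sites of the two faces sit
#' directly across from each other near the Lennard-Jones minimum. The
#' contact is then relaxed by short damped dynamics.
#'
#' @param eps_att Steric attraction, kBT.
#' @param kappa_b,k_s Elastic moduli.
#' @param box_edge Box edge, nm.
#' @param separation Initial wall-wall distance, nm.
#' @param relax Number of damped-quench steps (0 to skip).
#' @param charged,electro Optional charged variant.
#' @return A two-capsomer `capsomer_system` (cluster size 2 under
#'   [find_clusters()]).
#' @export
make_bound_dimer <- function(eps_att = 2, kappa_b = 10, k_s = 1000,
                             box_edge = 40, separation = 2^(1 / 6),
                             relax = 3000, charged = FALSE, electro = NULL) {
  template <- build_template(kappa_b = kappa_b, k_s = k_s, charged = charged)
  w <- template$walls[[1]]
  m <- w$normal                      # outward wall normal
  ctr <- w$centre
  # in-wall slope direction (perpendicular to the wall's horizontal edge)
  zax <- c(0, 0, 1)
  ehat <- zax - sum(zax * m) * m     # project z onto the wall plane
  # the edge direction is horizontal; the slope direction is the in-plane
  # component of z
  ehat <- ehat / sqrt(sum(ehat^2))
  # the contact plane sits at the protruding attractive sites, half the
  # target separation outside them
  pivot <- ctr + (template$protrusion + separation / 2) * m
  rot <- .axis_rotation(ehat, pi)
  # placement B: x -> rot (x - pivot) + pivot, recentred into the box
  centre_box <- rep(box_edge / 2, 3)
  pl_a <- list(rotation = diag(3), translation = centre_box)
  pl_b <- list(rotation = rot,
               translation = centre_box + pivot - as.vector(rot %*% pivot))
  state <- make_system(template, list(pl_a, pl_b), box_edge,
                       eps_att = eps_att, electro = electro)
  if (relax > 0)
    state <- run_md(state, relax, dt = 0.002, mode = "quench",
                    sample_every = 0L, save_frames = FALSE)$state
  state
}

#' Planted clusters of known sizes
#'
#' Places groups of capsomers so that within a group consecutive capsomers
#' are closer than the clustering cutoff while distinct groups stay more
#' than twice the cutoff apart, so [find_clusters()] recovers `sizes`
#' exactly by construction.
#'
#' @param sizes Integer vector of intended cluster sizes.
#' @param box_edge Box edge, nm (enlarged automatically if too small).
#' @param template A [build_template()]; a default is built if omitted.
#' @param seed RNG seed (reserved; the layout itself is deterministic).
#' @param dcut Clustering cutoff the construction should respect, nm.
#' @param gap Bead-surface gap within a chain, nm (must be < `dcut`).
#' @return A `capsomer_system`.
#' @export
make_planted_clusters <- function(sizes, box_edge = NULL, template = NULL,
                                  seed = 1, dcut = 1.5, gap = 0.2) {
  stopifnot(all(sizes >= 1), gap + 1 < dcut)
  if (is.null(template)) template <- build_template()
  xyz0 <- as.matrix(template$beads[, c("x", "y", "z")])
  span <- apply(xyz0, 2, function(v) diff(range(v)))
  # nearest bead centres of consecutive chain members sit at 1 + gap < dcut
  pitch_x <- span[1] + 1 + gap
  clear <- max(span) + 2 * max(template$beads$radius) + 2.5 * dcut
  n_groups <- length(sizes)
  # one chain per row: chains run along +x, rows are stacked along y
  need <- max(max(sizes) * pitch_x + clear, n_groups * clear + 2)
  if (is.null(box_edge)) box_edge <- need
  if (box_edge < need)
    stop(sprintf("box edge %.3g too small for the planted layout (need %.3g)",
                 box_edge, need))
  placements <- list()
  for (g in seq_len(n_groups)) {
    gy <- (g - 1) * clear + clear / 2
    for (k in seq_len(sizes[g])) {
      placements[[length(placements) + 1]] <- list(
        rotation = diag(3),
        translation = c(clear / 2 + (k - 1) * pitch_x, gy, box_edge / 2))
    }
  }
  make_system(template, placements, box_edge)
}

#' Single harmonic pair
#'
#' Two beads joined by one harmonic stretch edge, with no steric, bending or
#' electrostatic interactions (both beads belong to the same "capsomer").
#' The NVE trajectory of this system is the closed-form oscillator with
#' period 2 pi sqrt(mu / k_s), mu = m/2.
#'
#' @param k_s Spring constant, kBT/nm^2.
#' @param rest Rest length, nm.
#' @param stretch Initial extension beyond the rest length, nm.
#' @param mass Bead mass (reduced).
#' @return A two-bead `capsomer_system` in an open box.
#' @export
make_harmonic_pair <- function(k_s = 300, rest = 1, stretch = 0, mass = 1) {
  pos <- rbind(c(0, 0, 0), c(rest + stretch, 0, 0))
  state <- list(
    pos = pos,
    vel = matrix(0, 2, 3),
    L = 0,
    caps = c(1L, 1L),
    role = c(2L, 2L),
    radius = c(0.5, 0.5),
    charge = c(0, 0),
    mass = rep(mass, 2),
    bonds = cbind(i = 1L, j = 2L),
    rest = rest,
    bends = matrix(integer(0), 0, 8,
                   dimnames = list(NULL, c("i", "j", "a1", "b1", "c1",
                                           "a2", "b2", "c2"))),
    kappa_b = 0,
    k_s = k_s,
    eps_att = 0,
    electro = NULL,
    template = NULL,
    n_capsomers = 1L,
    skin = 0.4,
    step = 0L,
    thermostat = list(xi = numeric(3), vxi = numeric(3))
  )
  class(state) <- "capsomer_system"
  state
}
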