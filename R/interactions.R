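# Pair potentials, elastic terms, electrostatics, and the system-level
# energy/force evaluators (thin wrappers over the compiled kernels).

#' Interaction table for the steric pair potentials
#'
#' Builds the table of truncated and shifted Lennard-Jones parameters used
#' between beads of different capsomers. Attractive entries apply only to
#' pairs where both beads carry the attractive role: well depth `eps_att`,
#' cutoff 2.5 sigma_ij, and an energy shift making the potential exactly zero
#' at the cutoff. Every other role combination is purely repulsive
#' (Weeks-Chandler-Andersen form): well depth 1 kBT, cutoff 2^(1/6) sigma_ij,
#' shift +1 kBT. The bead size parameter is the contact distance
#' sigma_ij = R_i + R_j.
#'
#' @param eps_att Steric attraction strength in kBT.
#' @param radii Distinct bead radii present in the system (nm).
#' @return Data frame with one row per (role pair, radius pair): columns
#'   `role_i`, `role_j`, `sigma`, `epsilon`, `r_cut`, `shift`, `kind`.
#' @export
interaction_table <- function(eps_att = 2, radii = c(0.5, 1.2, 1.8)) {
  stopifnot(eps_att >= 0, all(radii > 0))
  roles <- c("repulsive", "attractive", "interior")
  rows <- list()
  for (a in seq_along(roles)) for (b in seq(a, length(roles))) {
    att <- roles[a] == "attractive" && roles[b] == "attractive"
    for (ra in seq_along(radii)) for (rb in seq(ra, length(radii))) {
      if (att && (radii[ra] != 0.5 || radii[rb] != 0.5)) next
      sigma <- radii[ra] + radii[rb]
      if (att) {
        eps <- eps_att
        r_cut <- 2.5 * sigma
        shift <- -4 * eps * ((1 / 2.5)^12 - (1 / 2.5)^6)
      } else {
        eps <- 1
        r_cut <- 2^(1 / 6) * sigma
        shift <- eps
      }
      rows[[length(rows) + 1]] <- data.frame(
        role_i = roles[a], role_j = roles[b], sigma = sigma,
        epsilon = eps, r_cut = r_cut, shift = shift,
        kind = if (att) "attractive" else "repulsive",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("interaction_table", class(out))
  out
}

#' Truncated and shifted Lennard-Jones pair energy
#'
#' U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6) + shift for r < r_cut and
#' exactly 0 beyond; the shift makes U continuous (zero) at the cutoff.
#'
#' @param r Distance(s), nm; must be positive.
#' @param entry One row of an [interaction_table()] (or any list with
#'   `sigma`, `epsilon`, `r_cut`, `shift`).
#' @return Energy in kBT (vectorised over `r`).
#' @examples
#' tab <- interaction_table(eps_att = 2)
#' rep_entry <- tab[tab$kind == "repulsive" & tab$sigma == 1, ][1, ]
#' lj_pair_energy(1, rep_entry)         # +1 kBT at contact
#' lj_pair_energy(2^(1/6), rep_entry)   # 0 at the cutoff
#' @export
lj_pair_energy <- function(r, entry) {
  if (any(r <= 0)) stop("distance must be positive")
  sr6 <- (entry$sigma / r)^6
  u <- 4 * entry$epsilon * (sr6^2 - sr6) + entry$shift
  ifelse(r < entry$r_cut, u, 0)
}

#' Truncated and shifted Lennard-Jones pair force
#'
#' Force on bead i at separation vector `r_vec` = x_i - x_j; equals the
#' negative gradient of [lj_pair_energy()] and is exactly zero at and beyond
#' the cutoff.
#'
#' @param r_vec Separation 3-vector (nm).
#' @param entry One row of an [interaction_table()].
#' @return Force 3-vector in kBT/nm.
#' @export
lj_pair_force <- function(r_vec, entry) {
  r2 <- sum(r_vec^2)
  if (r2 == 0) stop("zero separation vector")
  if (r2 >= entry$r_cut^2) return(c(0, 0, 0))
  sr6 <- (entry$sigma^2 / r2)^3
  fr <- 24 * entry$epsilon * (2 * sr6^2 - sr6) / r2
  fr * r_vec
}

#' Dihedral bending energy between two face normals
#'
#' E = (kappa_b / 2) |n1 - n2|^2 = kappa_b (1 - n1 . n2) for unit normals;
#' zero for coplanar faces with consistently oriented normals.
#'
#' @param n1,n2 Face normals (3-vectors). Normalised internally; a deviation
#'   from unit length beyond 1e-8 triggers a warning.
#' @param kappa_b Bending modulus, kBT.
#' @return Energy in kBT.
#' @export
bending_energy <- function(n1, n2, kappa_b) {
  m1 <- sqrt(sum(n1^2)); m2 <- sqrt(sum(n2^2))
  if (m1 == 0 || m2 == 0) stop("zero-length normal")
  if (abs(m1 - 1) > 1e-8 || abs(m2 - 1) > 1e-8)
    warning("non-unit normals; normalising")
  kappa_b * (1 - sum((n1 / m1) * (n2 / m2)))
}

#' Harmonic stretching energy of an edge
#'
#' E = (k_s / 2) (l - a_e)^2 relative to the rest length a_e.
#'
#' @param l Current edge length(s), nm (>= 0).
#' @param rest Rest length a_e, nm (> 0).
#' @param k_s Stretching modulus, kBT/nm^2.
#' @return Energy in kBT (vectorised over `l`).
#' @export
stretching_energy <- function(l, rest, k_s) {
  if (any(l < 0)) stop("edge length must be non-negative")
  if (any(rest <= 0)) stop("rest length must be positive")
  0.5 * k_s * (l - rest)^2
}

#' Bjerrum length
#'
#' l_B = e^2 / (4 pi eps0 eps_d kB T), the distance at which the Coulomb
#' energy of two unit charges equals kBT. For water at 298 K
#' (eps_d = 78.5) this is about 0.71 nm.
#'
#' @param T_K Absolute temperature in kelvin.
#' @param eps_d Relative permittivity of the solvent.
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(298, 78.5)
#' @export
bjerrum_length <- function(T_K = 298, eps_d = 78.5) {
  stopifnot(T_K > 0, eps_d > 0)
  .e_charge^2 / (4 * pi * .eps0 * eps_d * .kB * T_K) * 1e9
}

#' Screened electrostatics parameters
#'
#' Debye screening for an implicit monovalent electrolyte: the inverse
#' screening length is kappa = sqrt(8 pi l_B n) with n the salt number
#' density, and the Yukawa potential is cut off at `cutoff_factor` Debye
#' lengths (12 by default, where the screened interaction is negligible).
#'
#' @param salt_M Monovalent salt concentration in mol/L (> 0 unless
#'   `lambda_D` is supplied).
#' @param lB Bjerrum length in nm.
#' @param cutoff_factor Cutoff in units of the Debye length.
#' @param lambda_D Optional explicit Debye length in nm (overrides `salt_M`;
#'   use `Inf` for unscreened Coulomb).
#' @return Object of class `electro_params`: `lB`, `salt_M`, `lambda_D`,
#'   `cutoff` (nm).
#' @export
electro_params <- function(salt_M = 0.1, lB = bjerrum_length(),
                           cutoff_factor = 12, lambda_D = NULL) {
  if (is.null(lambda_D)) {
    stopifnot(salt_M > 0)
    n_nm3 <- salt_M * .NA * 1e-24          # number density in nm^-3
    lambda_D <- 1 / sqrt(8 * pi * lB * n_nm3)
  }
  out <- list(lB = lB, salt_M = salt_M, lambda_D = lambda_D,
              cutoff = cutoff_factor * lambda_D)
  class(out) <- "electro_params"
  out
}

#' Yukawa (screened Coulomb) pair energy
#'
#' U(r) = l_B q_i q_j exp(-r / lambda_D) / r in kBT for r below the cutoff,
#' 0 beyond.
#'
#' @param r Distance(s) in nm (> 0).
#' @param qi,qj Bead charges in units of e.
#' @param params An [electro_params()] object.
#' @return Energy in kBT (vectorised over `r`).
#' @export
yukawa_pair_energy <- function(r, qi, qj, params) {
  if (any(r <= 0)) stop("distance must be positive")
  u <- params$lB * qi * qj * exp(-r / params$lambda_D) / r
  ifelse(r < params$cutoff, u, 0)
}

# ---------------------------------------------------------------------------
# System-level evaluation

# assemble the argument list shared by the compiled evaluators
.sys_args <- function(state) {
  el <- state$electro
  list(pos = state$pos, L = state$L, caps = state$caps - 1L,
       role = state$role, radius = state$radius, charge = state$charge,
       mass = state$mass, bonds = state$bonds - 1L, rest = state$rest,
       ks = state$k_s, bends = state$bends - 1L, kb = state$kappa_b,
       eps_att = state$eps_att,
       use_elec = !is.null(el) && any(state$charge != 0),
       lB = if (is.null(el)) 0 else el$lB,
       lamD = if (is.null(el)) 1 else el$lambda_D,
       rc_elec = if (is.null(el)) 0 else el$cutoff,
       skin = state$skin)
}

#' Total potential energy by component
#'
#' Evaluates every term of the system Hamiltonian: inter-capsomer steric
#' Lennard-Jones energies (repulsive and attractive contributions reported
#' separately), intra-capsomer bending and stretching energies, and screened
#' electrostatics (both intra- and inter-capsomer) when the system is
#' charged. Steric terms are never evaluated between beads of the same
#' capsomer. All distances use the minimum-image convention.
#'
#' @param state A capsomer system (see [place_capsomers()]).
#' @return Named numeric vector with components `steric_repulsive`,
#'   `steric_attractive`, `bending`, `stretching`, `electrostatic`, `total`
#'   (kBT).
#' @export
total_energy <- function(state) {
  a <- .sys_args(state)
  r <- cpp_evaluate(a$pos, a$L, a$caps, a$role, a$radius, a$charge, a$mass,
                    a$bonds, a$rest, a$ks, a$bends, a$kb, a$eps_att,
                    a$use_elec, a$lB, a$lamD, a$rc_elec, a$skin, FALSE)
  out <- c(steric_repulsive = r$steric_repulsive,
           steric_attractive = r$steric_attractive,
           bending = r$bending, stretching = r$stretching,
           electrostatic = r$electrostatic)
  c(out, total = sum(out))
}

#' Forces on every bead
#'
#' Negative gradient of the system Hamiltonian, including the bending-term
#' gradient through both adjoining face normals. By translation invariance
#' the forces sum to the zero vector.
#'
#' @param state A capsomer system.
#' @return Matrix (beads x 3) of forces in kBT/nm, with the energy
#'   components attached as attribute `energy`.
#' @export
total_forces <- function(state) {
  a <- .sys_args(state)
  r <- cpp_evaluate(a$pos, a$L, a$caps, a$role, a$radius, a$charge, a$mass,
                    a$bonds, a$rest, a$ks, a$bends, a$kb, a$eps_att,
                    a$use_elec, a$lB, a$lamD, a$rc_elec, a$skin, TRUE)
  f <- r$forces
  attr(f, "energy") <- c(steric_repulsive = r$steric_repulsive,
                         steric_attractive = r$steric_attractive,
                         bending = r$bending, stretching = r$stretching,
                         electrostatic = r$electrostatic)
  f
}

#' Capsomer-cell Verlet neighbor list
#'
#' Candidate inter-capsomer bead pairs: a Verlet search over capsomer
#' centroids (each capsomer acts as a mobile cell) followed by a narrower
#' bead-pair search within each candidate capsomer pair, retaining pairs
#' within (interaction cutoff + skin). The list is complete with respect to
#' an all-pairs search and stays valid until a bead moves more than skin/2.
#'
#' @param state A capsomer system.
#' @param skin Verlet skin in nm (> 0); defaults to the state's skin.
#' @return Data frame of candidate bead pairs (`i`, `j`), 1-based.
#' @export
build_neighbor_list <- function(state, skin = state$skin) {
  stopifnot(skin > 0)
  rc_max <- .max_cutoff(state)
  if (state$L > 0 && state$L < 2 * rc_max)
    stop(sprintf(
      "box edge %.3g is smaller than twice the largest cutoff %.3g; ",
      state$L, rc_max), "minimum-image convention violated")
  a <- .sys_args(state)
  p <- cpp_neighbor_pairs(a$pos, a$L, a$caps, a$role, a$radius, a$charge,
                          a$mass, a$bonds, a$rest, a$ks, a$bends, a$kb,
                          a$eps_att, a$use_elec, a$lB, a$lamD, a$rc_elec,
                          skin)
  data.frame(i = p$i, j = p$j)
}

.max_cutoff <- function(state) {
  rmax <- max(state$radius)
  rc <- max(2.5 * 1, 2^(1 / 6) * 2 * rmax)
  if (!is.null(state$electro) && any(state$charge != 0))
    rc <- max(rc, state$electro$cutoff)
  rc
}
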