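# Independent pure-R oracles and small generated systems used across the
# suite. The oracle evaluates every term of the Hamiltonian by an all-pairs
# search, sharing no code with the compiled kernels.

min_image <- function(d, L) if (L > 0) d - L * round(d / L) else d

# all-pairs energy, pure R
oracle_energy <- function(state) {
  pos <- state$pos
  L <- state$L
  nb <- nrow(pos)
  e_rep <- e_att <- e_elec <- 0
  el <- state$electro
  for (i in seq_len(nb - 1)) {
    for (j in seq(i + 1, nb)) {
      dv <- min_image(pos[i, ] - pos[j, ], L)
      r <- sqrt(sum(dv^2))
      if (state$caps[i] != state$caps[j]) {
        sig <- state$radius[i] + state$radius[j]
        att <- state$role[i] == 1L && state$role[j] == 1L
        if (att) {
          eps <- state$eps_att
          rc <- 2.5 * sig
          shift <- -4 * eps * ((1 / 2.5)^12 - (1 / 2.5)^6)
        } else {
          eps <- 1
          rc <- 2^(1 / 6) * sig
          shift <- 1
        }
        if (r < rc) {
          sr6 <- (sig / r)^6
          u <- 4 * eps * (sr6^2 - sr6) + shift
          if (att) e_att <- e_att + u else e_rep <- e_rep + u
        }
      }
      if (!is.null(el) && state$charge[i] * state$charge[j] != 0 &&
          r < el$cutoff) {
        e_elec <- e_elec +
          el$lB * state$charge[i] * state$charge[j] *
            exp(-r / el$lambda_D) / r
      }
    }
  }
  e_stretch <- 0
  if (nrow(state$bonds) > 0) {
    for (e in seq_len(nrow(state$bonds))) {
      dv <- min_image(pos[state$bonds[e, 1], ] - pos[state$bonds[e, 2], ], L)
      e_stretch <- e_stretch +
        0.5 * state$k_s * (sqrt(sum(dv^2)) - state$rest[e])^2
    }
  }
  e_bend <- 0
  if (nrow(state$bends) > 0) {
    tri_n <- function(a, b, c) {
      u <- min_image(pos[b, ] - pos[a, ], L)
      v <- min_image(pos[c, ] - pos[a, ], L)
      n <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      n / sqrt(sum(n^2))
    }
    for (e in seq_len(nrow(state$bends))) {
      r <- state$bends[e, ]
      n1 <- tri_n(r[["a1"]], r[["b1"]], r[["c1"]])
      n2 <- tri_n(r[["a2"]], r[["b2"]], r[["c2"]])
      e_bend <- e_bend + state$kappa_b * (1 - sum(n1 * n2))
    }
  }
  c(steric_repulsive = e_rep, steric_attractive = e_att,
    bending = e_bend, stretching = e_stretch, electrostatic = e_elec)
}

# bead pairs of different capsomers within their interaction cutoff
oracle_pairs_in_range <- function(state) {
  pos <- state$pos
  L <- state$L
  nb <- nrow(pos)
  el <- state$electro
  out <- character(0)
  for (i in seq_len(nb - 1)) {
    for (j in seq(i + 1, nb)) {
      if (state$caps[i] == state$caps[j]) next
      sig <- state$radius[i] + state$radius[j]
      att <- state$role[i] == 1L && state$role[j] == 1L
      rc <- if (att) 2.5 * sig else 2^(1 / 6) * sig
      if (!is.null(el) && state$charge[i] * state$charge[j] != 0)
        rc <- max(rc, el$cutoff)
      dv <- min_image(pos[i, ] - pos[j, ], L)
      if (sum(dv^2) < rc^2) out <- c(out, paste(i, j))
    }
  }
  out
}

# small generic bead system (no elastic network) for fuzz tests
random_bead_system <- function(n_caps, per_caps, L, seed, charged = FALSE,
                               eps_att = 2) {
  set.seed(seed)
  nb <- n_caps * per_caps
  state <- list(
    pos = matrix(stats::runif(3 * nb, 0, L), nb, 3),
    vel = matrix(0, nb, 3),
    L = L,
    caps = rep(seq_len(n_caps), each = per_caps),
    role = sample(0:2, nb, replace = TRUE),
    radius = sample(c(0.5, 0.5, 0.5, 1.2), nb, replace = TRUE),
    charge = if (charged) sample(c(0, 0.5), nb, replace = TRUE) else rep(0, nb),
    mass = rep(1, nb),
    bonds = matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))),
    rest = numeric(0),
    bends = matrix(integer(0), 0, 8,
                   dimnames = list(NULL, c("i", "j", "a1", "b1", "c1",
                                           "a2", "b2", "c2"))),
    kappa_b = 1, k_s = 1, eps_att = eps_att,
    electro = if (charged) electro_params(salt_M = 0.5) else NULL,
    template = NULL, n_capsomers = n_caps, skin = 0.4, step = 0L,
    thermostat = list(xi = numeric(3), vxi = numeric(3))
  )
  class(state) <- "capsomer_system"
  state
}

# cluster sizes by single linkage over an R-computed distance graph (igraph)
oracle_cluster_sizes <- function(pos, caps, L, dcut) {
  ids <- sort(unique(caps))
  nc <- length(ids)
  adj <- matrix(0, nc, nc)
  for (a in seq_len(nc - 1)) {
    for (b in seq(a + 1, nc)) {
      pa <- pos[caps == ids[a], , drop = FALSE]
      pb <- pos[caps == ids[b], , drop = FALSE]
      linked <- FALSE
      for (i in seq_len(nrow(pa))) {
        dv <- sweep(pb, 2, pa[i, ])
        dv <- min_image(dv, L)
        if (any(rowSums(dv^2) < dcut^2)) { linked <- TRUE; break }
      }
      if (linked) adj[a, b] <- adj[b, a] <- 1
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  sort(as.integer(table(igraph::components(g)$membership)),
       decreasing = TRUE)
}

# finite-difference force check on a random subset of coordinates
fd_force_check <- function(state, n_beads = 8, h = 1e-6, seed = 1) {
  F <- total_forces(state)
  set.seed(seed)
  worst <- 0
  for (k in sample(nrow(state$pos), n_beads)) {
    for (d in 1:3) {
      sp <- state; sp$pos[k, d] <- sp$pos[k, d] + h
      sm <- state; sm$pos[k, d] <- sm$pos[k, d] - h
      fd <- -(total_energy(sp)[["total"]] - total_energy(sm)[["total"]]) /
        (2 * h)
      worst <- max(worst, abs(fd - F[k, d]) / max(1, abs(F[k, d])))
    }
  }
  worst
}
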