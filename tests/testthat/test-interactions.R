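# Pair potentials, system energies and forces, neighbor listing.

tab <- interaction_table(eps_att = 2)
rep_entry <- tab[tab$kind == "repulsive" & tab$sigma == 1, ][1, ]
att_entry <- tab[tab$kind == "attractive", ][1, ]

test_that("interaction table encodes the truncated-shifted LJ variants", {
  expect_true(all(tab$epsilon[tab$kind == "repulsive"] == 1))
  expect_equal(tab$r_cut[tab$kind == "repulsive"],
               2^(1 / 6) * tab$sigma[tab$kind == "repulsive"])
  expect_true(all(tab$kind[tab$role_i == "attractive" &
                           tab$role_j == "attractive"] == "attractive"))
  expect_equal(att_entry$r_cut, 2.5)
  expect_equal(att_entry$shift, -4 * 2 * ((1 / 2.5)^12 - (1 / 2.5)^6))
})

test_that("LJ pair energy matches its closed forms and vanishes at cutoff", {
  expect_equal(lj_pair_energy(2^(1 / 6), rep_entry), 0, tolerance = 1e-14)
  expect_equal(lj_pair_energy(1, rep_entry), 1)      # raw LJ 0 + shift 1
  # attractive minimum: -eps_att plus the (positive) cutoff shift
  expect_equal(lj_pair_energy(2^(1 / 6), att_entry), -1.967366,
               tolerance = 1e-6)
  expect_identical(lj_pair_energy(2.5, att_entry), 0)
  expect_identical(lj_pair_energy(10, rep_entry), 0)
  # continuity at the cutoff
  expect_lt(abs(lj_pair_energy(att_entry$r_cut - 1e-9, att_entry)), 1e-7)
  expect_error(lj_pair_energy(0, rep_entry), "positive")
})

test_that("LJ pair force is the negative gradient and zero past cutoff", {
  expect_equal(lj_pair_force(c(2^(1 / 6), 0, 0), rep_entry), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(lj_pair_force(c(0, 2^(1 / 6), 0), att_entry), c(0, 0, 0),
               tolerance = 1e-12)
  expect_identical(lj_pair_force(c(0, 0, 3), att_entry), c(0, 0, 0))
  h <- 1e-7
  for (r in c(0.95, 1.05, 1.3, 2.2)) {
    fd <- -(lj_pair_energy(r + h, att_entry) -
            lj_pair_energy(r - h, att_entry)) / (2 * h)
    f <- lj_pair_force(c(r, 0, 0), att_entry)[1]
    expect_equal(f, fd, tolerance = 1e-6 * max(1, abs(fd)))
  }
  expect_error(lj_pair_force(c(0, 0, 0), rep_entry), "zero")
})

test_that("bending energy follows kappa_b (1 - n1.n2)", {
  expect_equal(bending_energy(c(0, 0, 1), c(0, 0, 1), 10), 0)
  expect_equal(bending_energy(c(1, 0, 0), c(0, 1, 0), 10), 10)
  expect_equal(bending_energy(c(0, 0, 1), c(0, 0, -1), 1), 2)
  expect_warning(bending_energy(c(0, 0, 2), c(0, 0, 2), 1), "normalising")
  expect_equal(suppressWarnings(bending_energy(c(0, 0, 2), c(0, 0, 2), 1)), 0)
})

test_that("stretching energy is harmonic about the rest length", {
  expect_identical(stretching_energy(1.5, 1.5, 300), 0)
  expect_equal(stretching_energy(1.1, 1.0, 300), 1.5)
  expect_identical(stretching_energy(3, 1, 0), 0)
  expect_error(stretching_energy(-1, 1, 300), "non-negative")
})

test_that("Bjerrum length reproduces water and vacuum values", {
  lb <- bjerrum_length(298, 78.5)
  expect_equal(round(lb, 1), 0.7)
  expect_equal(lb, 0.714, tolerance = 1e-3)
  expect_equal(bjerrum_length(298, 1), 56.05, tolerance = 0.01)
  expect_equal(bjerrum_length(298, 2 * 78.5), lb / 2, tolerance = 1e-12)
})

test_that("Debye screening and the Yukawa potential", {
  ep <- electro_params(salt_M = 0.1, lB = 0.7)
  n_nm3 <- 0.1 * 6.02214076e23 * 1e-24
  expect_equal(ep$lambda_D, 1 / sqrt(8 * pi * 0.7 * n_nm3), tolerance = 1e-12)
  expect_equal(ep$cutoff, 12 * ep$lambda_D)
  # unscreened limit: lB q^2 / r at r = lB gives q^2
  inf <- electro_params(lB = 0.7, lambda_D = Inf)
  expect_equal(yukawa_pair_energy(0.7, 0.5, 0.5, inf), 0.25)
  expect_identical(yukawa_pair_energy(1, 0, 0.5, inf), 0)
  expect_identical(yukawa_pair_energy(12 * ep$lambda_D + 1e-6, 0.5, 0.5, ep),
                   0)
  expect_error(yukawa_pair_energy(0, 0.5, 0.5, ep), "positive")
})

test_that("an isolated capsomer has zero energy; distant capsomers no sterics", {
  tpl <- build_template()
  st1 <- make_system(tpl, list(list(rotation = diag(3),
                                    translation = rep(15, 3))), 30)
  expect_equal(unname(total_energy(st1)[["total"]]), 0, tolerance = 1e-9)
  expect_equal(max(abs(total_forces(st1))), 0, tolerance = 1e-9)
  st2 <- make_system(tpl, list(
    list(rotation = diag(3), translation = c(8, 8, 8)),
    list(rotation = diag(3), translation = c(25, 25, 25))), 34)
  e <- total_energy(st2)
  expect_identical(e[["steric_repulsive"]], 0)
  expect_identical(e[["steric_attractive"]], 0)
})

test_that("no steric interaction between beads of the same capsomer", {
  # two heavily overlapping beads in one capsomer: steric energy stays zero
  st <- make_harmonic_pair(k_s = 1, rest = 1)
  st$role <- c(0L, 0L)
  st$pos[2, ] <- st$pos[1, ] + c(0.2, 0, 0)
  e <- total_energy(st)
  expect_identical(e[["steric_repulsive"]], 0)
  expect_identical(e[["steric_attractive"]], 0)
})

test_that("neighbor-listed energies equal the all-pairs oracle", {
  # generic random systems, including charged ones
  for (seed in 1:6) {
    st <- random_bead_system(3, 5, 12, seed, charged = seed %% 2 == 0)
    e <- total_energy(st)
    o <- oracle_energy(st)
    expect_equal(e[names(o)], o, tolerance = 1e-10)
  }
  # and a full bound capsomer dimer
  dim2 <- make_bound_dimer(eps_att = 2, relax = 200)
  e <- total_energy(dim2)
  o <- oracle_energy(dim2)
  expect_equal(e[names(o)], o, tolerance = 1e-10)
})

test_that("forces match finite differences and sum to zero", {
  st <- make_bound_dimer(eps_att = 2, relax = 200)
  set.seed(3)
  st$pos <- st$pos + matrix(stats::rnorm(length(st$pos), 0, 0.01), ncol = 3)
  expect_lt(fd_force_check(st, n_beads = 6), 1e-5)
  F <- total_forces(st)
  expect_lt(max(abs(colSums(F))), 1e-10 * max(1, max(abs(F))))
})

test_that("forces are invariant under uniform translation (PBC)", {
  st <- make_bound_dimer(eps_att = 2, relax = 200)
  F1 <- total_forces(st)
  st2 <- st
  st2$pos <- st$pos + 7.3   # arbitrary shift; wrapping handled internally
  F2 <- total_forces(st2)
  expect_equal(F2, F1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("neighbor list is complete and validates the box size", {
  st <- make_bound_dimer(eps_att = 2, relax = 200)
  nl <- build_neighbor_list(st)
  keys <- paste(pmin(nl$i, nl$j), pmax(nl$i, nl$j))
  expect_true(all(oracle_pairs_in_range(st) %in% keys))
  # distant capsomers: empty list
  tpl <- build_template()
  far <- make_system(tpl, list(
    list(rotation = diag(3), translation = c(8, 8, 8)),
    list(rotation = diag(3), translation = c(25, 25, 25))), 34)
  expect_equal(nrow(build_neighbor_list(far)), 0)
  # box smaller than twice the largest cutoff is refused
  small <- st
  small$L <- 7
  expect_error(build_neighbor_list(small), "minimum-image")
})
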