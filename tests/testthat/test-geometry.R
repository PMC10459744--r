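# Capsomer template: bead census, elastic topology, inclination, symmetry.

tpl <- build_template(kappa_b = 10, k_s = 1000)

test_that("bead census matches the capsomer blueprint", {
  b <- tpl$beads
  expect_equal(nrow(b), 78)
  expect_equal(sum(b$radius == 0.5), 76)
  expect_equal(sum(b$radius == 1.8), 1)
  expect_equal(sum(b$radius == 1.2), 1)
  expect_length(unique(b$mass), 1)
  expect_true(all(b$layer[b$role == "attractive"] %in% c(2L, 3L)))
  expect_equal(sum(b$charge), 0)
})

test_that("charged variant carries 4.5 e on nine top-layer beads", {
  tc <- build_template(charged = TRUE)
  expect_equal(sum(tc$beads$charge), 4.5)
  expect_equal(sum(tc$beads$charge > 0), 9)
  expect_true(all(tc$beads$layer[tc$beads$charge > 0] == 4L))
  expect_true(all(tc$beads$charge[tc$beads$charge > 0] == 0.5))
})

test_that("as-built elastic energy is exactly zero", {
  st <- make_system(tpl, list(list(rotation = diag(3),
                                   translation = rep(15, 3))), 30)
  e <- total_energy(st)
  expect_lt(e[["stretching"]], 1e-18)
  expect_lt(abs(e[["bending"]]), 1e-9)
  expect_identical(e[["steric_repulsive"]], 0)
  expect_identical(e[["steric_attractive"]], 0)
})

test_that("template centre of mass is the origin and rebuilds are identical", {
  pos <- as.matrix(tpl$beads[, c("x", "y", "z")])
  expect_lt(max(abs(colMeans(pos))), 1e-9)
  expect_identical(tpl, build_template(kappa_b = 10, k_s = 1000))
})

test_that("wall inclination hits the target and is rotation invariant", {
  expect_equal(inclination_angle(tpl), 53.9, tolerance = 0.5)
  rot <- softcapsid:::.axis_rotation(c(1, 2, 3), 1.1)
  tpl2 <- tpl
  tpl2$beads[, c("x", "y", "z")] <-
    as.matrix(tpl$beads[, c("x", "y", "z")]) %*% t(rot)
  expect_equal(inclination_angle(tpl2), inclination_angle(tpl),
               tolerance = 1e-6)
})

test_that("plane-line angle convention: vertical prism walls measure zero", {
  # synthetic right-prism wall: a vertical plane; base normal along z
  wall <- cbind(rep(0:3, each = 4), 0, rep(0:3, 4)) + 0.0
  fit <- softcapsid:::.fit_plane(wall)
  expect_equal(softcapsid:::.plane_line_angle(fit$normal, c(0, 0, 1)), 0,
               tolerance = 1e-9)
  # a horizontal plane measures 90 degrees from the normal
  flat <- cbind(rep(0:3, each = 4), rep(0:3, 4), 0) + 0.0
  fit2 <- softcapsid:::.fit_plane(flat)
  expect_equal(softcapsid:::.plane_line_angle(fit2$normal, c(0, 0, 1)), 90,
               tolerance = 1e-9)
  expect_error(softcapsid:::.fit_plane(cbind(0:5, 0, 0) + 0.0), "degenerate")
})

test_that("bending topology respects the wall rules", {
  bd <- tpl$bends
  # the two faces adjoin the edge
  for (e in sample(nrow(bd), 20)) {
    expect_true(all(bd[e, c("i", "j")] %in% bd[e, c("a1", "b1", "c1")]))
    expect_true(all(bd[e, c("i", "j")] %in% bd[e, c("a2", "b2", "c2")]))
  }
  # never through interior beads, never on slant (corner-corner) edges
  expect_false(any(bd[, 1:2] %in% tpl$interior_ids))
  slant <- apply(bd[, 1:2, drop = FALSE], 1,
                 function(pr) all(pr %in% tpl$corners))
  expect_false(any(slant))
  # bending edges live strictly inside the walls: no bottom/top row edges
  lay <- tpl$beads$layer
  same_row14 <- lay[bd[, "i"]] == lay[bd[, "j"]] & lay[bd[, "i"]] %in% c(1, 4)
  expect_false(any(same_row14))
})

test_that("stretch network is connected and rest lengths equal built lengths", {
  pos <- as.matrix(tpl$beads[, c("x", "y", "z")])
  lens <- sqrt(rowSums((pos[tpl$bonds[, "i"], ] - pos[tpl$bonds[, "j"], ])^2))
  expect_equal(lens, unname(tpl$bonds[, "rest"]), tolerance = 1e-14)
  g <- igraph::graph_from_edgelist(unname(tpl$bonds[, 1:2]), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("the three lateral walls are congruent", {
  pos <- as.matrix(tpl$beads[, c("x", "y", "z")])
  dsort <- function(w) sort(as.vector(stats::dist(pos[unlist(w$rows), ])))
  d1 <- dsort(tpl$walls[[1]])
  expect_equal(dsort(tpl$walls[[2]]), d1, tolerance = 1e-10)
  expect_equal(dsort(tpl$walls[[3]]), d1, tolerance = 1e-10)
})

test_that("validate_template passes the built template and flags defects", {
  v <- validate_template(tpl)
  expect_true(attr(v, "ok"))
  # planted defect: a perturbed rest length breaks the zero-energy check
  bad <- tpl
  bad$bonds[5, "rest"] <- bad$bonds[5, "rest"] + 0.1
  vb <- validate_template(bad)
  expect_false(attr(vb, "ok"))
  expect_false(vb$pass[vb$check == "as-built stretching energy is zero"])
  # planted defect: a bend edge whose faces do not share it
  bad2 <- tpl
  bad2$bends[1, "i"] <- setdiff(seq_len(70), bad2$bends[1, 3:8])[1]
  vb2 <- validate_template(bad2)
  expect_false(vb2$pass[vb2$check == "bend faces share their edge"])
})

test_that("moduli must be positive and blue counts restricted", {
  expect_error(build_template(kappa_b = 0), "positive")
  expect_error(build_template(k_s = -5), "positive")
  expect_error(build_template(blue_per_edge = 4), "blue_per_edge")
})

test_that("template JSON round trip preserves geometry and topology", {
  f <- tempfile(fileext = ".json")
  write_template_json(tpl, f)
  tpl2 <- read_template_json(f)
  expect_equal(as.matrix(tpl2$beads[, c("x", "y", "z")]),
               as.matrix(tpl$beads[, c("x", "y", "z")]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(as.matrix(tpl2$bonds)), unname(tpl$bonds),
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(tpl2$bends)), unname(tpl$bends))
  expect_equal(tpl2$kappa_b, tpl$kappa_b)
  unlink(f)
})

test_that("XYZ export writes one tagged record per bead", {
  f <- tempfile(fileext = ".xyz")
  st <- make_system(tpl, list(list(rotation = diag(3),
                                   translation = rep(15, 3))), 30)
  write_xyz(st, file = f)
  lines <- readLines(f)
  expect_equal(as.integer(lines[1]), 78)
  expect_length(lines, 80)
  expect_true(all(grepl("^[CBO] ", lines[-(1:2)])))
  unlink(f)
})
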