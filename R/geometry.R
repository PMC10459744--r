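# Body-frame template of one deformable trapezoidal capsomer.
#
# The capsomer is a hollow truncated triangular prism built from four
# triangular bead layers (8/7/7/5 beads per edge, bottom to top; the third
# layer is compressed so the lateral walls stay planar), two large interior
# filler beads, a small apex plug, and six attractive wall sites.  Beads are
# joined by harmonic stretch edges; dihedral bending edges act on the
# triangulated lateral walls.

.layer_beads <- c(8, 7, 7, 5)
.layer_side <- c(7, 6, 5, 4)  # side lengths in sigma; layer 3 is compressed

#' Build the body-frame template of one capsomer
#'
#' Constructs the 78-bead deformable capsomer: four triangular frame layers
#' with 8/7/7/5 beads per edge (the third layer compressed so all four layer
#' edges of a lateral wall are exactly coplanar), one interior bead of radius
#' 1.8 nm centred in the bottom layer, one of radius 1.2 nm midway between
#' the third and fourth layers, a small apex bead plugging the top opening,
#' and two attractive sites embedded in each lateral wall at second-layer
#' height. Attractive ("blue") beads drive capsomer binding: per wall they
#' are the two embedded sites plus the `blue_per_edge` central beads of the
#' third-layer edge, and they protrude 0.2 nm outward from the wall plane so
#' that bound faces adhere through the attractive patch without pressing the
#' repulsive wall beads of the partner into steric contact. All other beads
#' are sterically repulsive towards other capsomers.
#'
#' Nearest-neighbour beads are connected by harmonic springs whose rest
#' lengths equal the as-built distances (this includes the non-bending
#' tethers between the interior fillers and every frame bead), so the
#' elastic energy of the template is exactly zero. Each lateral wall is
#' triangulated; interior mesh edges carry a bending penalty on the dihedral
#' between their two adjoining faces, except the outermost edges (wall
#' boundary and corner-to-corner slants), edges involving the interior
#' beads, and edges whose faces are not coplanar as built - in particular
#' the third-layer edges at the protruding attractive beads. Planarity is
#' the zero of the bending energy, so every bending edge starts at zero.
#'
#' The template's centre of mass sits at the body-frame origin and its
#' three-fold symmetry axis is the z axis; the bottom (capsid-exterior)
#' layer faces -z.
#'
#' @param kappa_b Bending modulus in kBT (> 0).
#' @param k_s Stretching modulus in kBT/nm^2 (> 0).
#' @param charged If `TRUE`, assign +0.5 e to each of the three central beads
#'   of the three top-layer edges (total +4.5 e).
#' @param inclination Target angle, in degrees, between each lateral wall
#'   plane and the outward normal of the bottom layer (0 would be a right
#'   prism with vertical walls). The default reproduces the model geometry.
#' @param blue_per_edge Number of central third-layer frame beads per edge
#'   given the attractive role (1, 3 or 5). The default, together with the
#'   two embedded wall sites, calibrates the bound-face attractive energy to
#'   about 14 kBT at steric attraction 2.
#' @return An object of class `capsomer_template`: a list with `beads`
#'   (data frame: layer, x, y, z, radius, role, charge, mass), `bonds`
#'   (i, j, rest), `bends` (i, j and the two oriented adjoining faces),
#'   `kappa_b`, `k_s`, `charged`, and `walls` metadata used by the analysis
#'   and fixture helpers.
#' @examples
#' tpl <- build_template(kappa_b = 10, k_s = 1000)
#' nrow(tpl$beads)          # 78
#' inclination_angle(tpl)   # about 53.9 degrees
#' @export
build_template <- function(kappa_b = 10, k_s = 1000, charged = FALSE,
                           inclination = 53.9, blue_per_edge = 3) {
  if (kappa_b <= 0 || k_s <= 0) stop("elastic moduli must be positive")
  if (!blue_per_edge %in% c(1L, 2L, 3L, 5L))
    stop("blue_per_edge must be 1, 2, 3 or 5")

  nlay <- length(.layer_beads)
  inrad <- .layer_side / (2 * sqrt(3))
  circ <- .layer_side / sqrt(3)
  # equal layer gaps chosen so the wall planes meet the bottom normal at the
  # target inclination (the layer inradii decrease by 1/(2 sqrt(3)) per layer)
  gap <- (inrad[1] - inrad[2]) / tan(inclination * pi / 180)
  zlay <- (seq_len(nlay) - 1) * gap

  corner_dir <- rbind(c(cos(pi / 2), sin(pi / 2)),
                      c(cos(pi * 7 / 6), sin(pi * 7 / 6)),
                      c(cos(pi * 11 / 6), sin(pi * 11 / 6)))

  xyz <- matrix(numeric(0), ncol = 3)
  layer <- integer(0)
  # row_ids[[k]][[w]]: beads of layer k along wall w, corner to corner
  row_ids <- rep(list(vector("list", 3)), nlay)
  corner_id <- matrix(NA_integer_, nlay, 3)

  add_bead <- function(p, lay) {
    xyz <<- rbind(xyz, p)
    layer <<- c(layer, lay)
    nrow(xyz)
  }

  for (k in seq_len(nlay)) {
    n <- .layer_beads[k]
    corners <- circ[k] * corner_dir
    for (w in 1:3) corner_id[k, w] <- add_bead(c(corners[w, ], zlay[k]), k)
    for (w in 1:3) {
      w2 <- w %% 3 + 1
      a <- corners[w, ]; b <- corners[w2, ]
      ids <- corner_id[k, w]
      for (t in seq_len(n - 2)) {
        p <- a + (b - a) * t / (n - 1)
        ids <- c(ids, add_bead(c(p, zlay[k]), k))
      }
      row_ids[[k]][[w]] <- c(ids, corner_id[k, w2])
    }
  }
  n_frame <- nrow(xyz)

  # embedded attractive sites: two per wall, on the wall plane at layer-2
  # height, 1.4 spacings either side of the wall centre (nested between the
  # second-layer frame beads); the offset spaces the attractive patch so a
  # bound face totals about 14 kBT at steric attraction 2
  extras <- vector("list", 3)
  for (w in 1:3) {
    w2 <- w %% 3 + 1
    a <- circ[2] * corner_dir[w, ]; b <- circ[2] * corner_dir[w2, ]
    ehat <- (b - a) / sqrt(sum((b - a)^2))
    mid <- (a + b) / 2
    id1 <- add_bead(c(mid + 1.4 * ehat, zlay[2]), 2L)
    id2 <- add_bead(c(mid - 1.4 * ehat, zlay[2]), 2L)
    extras[[w]] <- c(id1, id2)
  }

  # interior fillers and apex plug
  id_big1 <- add_bead(c(0, 0, zlay[1]), 0L)                 # radius 1.8
  id_big2 <- add_bead(c(0, 0, (zlay[3] + zlay[4]) / 2), 0L) # radius 1.2
  id_apex <- add_bead(c(0, 0, zlay[4]), 0L)

  nb <- nrow(xyz)
  radius <- rep(0.5, nb)
  radius[id_big1] <- 1.8
  radius[id_big2] <- 1.2

  # roles: 0 repulsive, 1 attractive, 2 interior
  role <- rep(0L, nb)
  role[c(id_big1, id_big2, id_apex)] <- 2L
  blue <- integer(0)
  for (w in 1:3) {
    row3 <- row_ids[[3]][[w]]          # 7 beads, corners at ends
    centre <- 4L
    b3 <- if (blue_per_edge == 2L) {
      row3[c(centre - 1L, centre + 1L)]  # the pair flanking the edge centre
    } else {
      half <- (blue_per_edge - 1L) %/% 2L
      row3[(centre - half):(centre + half)]
    }
    blue <- c(blue, b3, extras[[w]])
  }
  role[blue] <- 1L

  charge <- rep(0, nb)
  if (charged) {
    for (w in 1:3) {
      row4 <- row_ids[[4]][[w]]        # 5 beads, corners at ends
      charge[row4[2:4]] <- 0.5
    }
  }

  # attractive sites protrude slightly from the wall plane so that a bound
  # face adheres through the attractive patch without pressing the repulsive
  # wall beads of the partner into steric contact
  tanb <- tan(inclination * pi / 180)
  protrusion <- 0.2
  wall_normal <- function(w) {
    w2 <- w %% 3 + 1
    out2d <- -(corner_dir[w, ] + corner_dir[w2, ])
    out2d <- out2d / sqrt(sum(out2d^2))
    c(out2d, tanb) / sqrt(1 + tanb^2)
  }
  for (w in 1:3) {
    ids <- intersect(which(role == 1L),
                     c(row_ids[[3]][[w]], extras[[w]]))
    xyz[ids, ] <- xyz[ids, ] +
      rep(wall_normal(w), each = length(ids)) * protrusion
  }

  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  # ---- stretch edges -------------------------------------------------------
  ekey <- character(0)
  ei <- integer(0); ej <- integer(0)
  add_edge <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!key %in% ekey) {
      ekey <<- c(ekey, key)
      ei <<- c(ei, min(i, j)); ej <<- c(ej, max(i, j))
    }
  }

  # within-row frame edges
  for (k in seq_len(nlay)) for (w in 1:3) {
    ids <- row_ids[[k]][[w]]
    for (t in seq_len(length(ids) - 1)) add_edge(ids[t], ids[t + 1])
  }

  # ---- wall triangulation --------------------------------------------------
  # greedy two-pointer strip between consecutive rows; faces oriented so the
  # built normal points out of the capsomer
  faces <- matrix(integer(0), ncol = 3)
  wall_of_face <- integer(0)
  for (w in 1:3) {
    outward <- wall_normal(w)
    for (k in seq_len(nlay - 1)) {
      A <- row_ids[[k]][[w]]; B <- row_ids[[k + 1]][[w]]
      i <- 1; j <- 1
      while (i < length(A) || j < length(B)) {
        dA <- if (i < length(A)) dist_ij(A[i + 1], B[j]) else Inf
        dB <- if (j < length(B)) dist_ij(A[i], B[j + 1]) else Inf
        if (dA <= dB) {
          tri <- c(A[i], B[j], A[i + 1]); i <- i + 1
        } else {
          tri <- c(A[i], B[j], B[j + 1]); j <- j + 1
        }
        nrm <- .tri_normal(xyz[tri[1], ], xyz[tri[2], ], xyz[tri[3], ])
        if (sum(nrm * outward) < 0) tri <- tri[c(1, 3, 2)]
        faces <- rbind(faces, tri)
        wall_of_face <- c(wall_of_face, w)
        add_edge(tri[1], tri[2]); add_edge(tri[2], tri[3])
        add_edge(tri[1], tri[3])
      }
    }
  }

  # ---- auxiliary springs (extras, interior beads, apex) --------------------
  link_within <- function(id, candidates, cutoff) {
    for (j in candidates) {
      if (j != id && dist_ij(id, j) <= cutoff) add_edge(id, j)
    }
  }
  frame_ids <- seq_len(n_frame)
  for (w in 1:3) for (id in extras[[w]]) {
    link_within(id, frame_ids, 0.65)
    link_within(id, c(id_big1, id_big2), 2.5)
  }
  # every frame bead is tethered to the two interior fillers: these are the
  # non-bending edges between the large and small beads, and they give the
  # wall beads their out-of-plane (radial) stretch restraint
  for (id in frame_ids) {
    add_edge(id, id_big1)
    add_edge(id, id_big2)
  }
  layer_ids <- function(k) frame_ids[layer[frame_ids] == k]
  link_within(id_apex, layer_ids(4), 1.6)
  add_edge(id_big1, id_big2)
  add_edge(id_big2, id_apex)

  bonds <- cbind(i = ei, j = ej)
  rest <- vapply(seq_len(nrow(bonds)),
                 function(e) dist_ij(bonds[e, 1], bonds[e, 2]), numeric(1))

  # ---- bending edges -------------------------------------------------------
  # interior mesh edges (exactly two adjoining faces), excluding slant edges
  # (both endpoints layer corners) and edges whose adjoining faces are not
  # coplanar as built.  The planar conformation carries zero bending energy,
  # so only planar dihedrals can be bending edges; this in particular drops
  # the third-layer edges at the protruding attractive beads.
  face_key <- function(i, j) paste(min(i, j), max(i, j))
  edge_faces <- new.env(parent = emptyenv())
  for (f in seq_len(nrow(faces))) {
    tri <- faces[f, ]
    for (pr in list(tri[1:2], tri[2:3], tri[c(1, 3)])) {
      key <- face_key(pr[1], pr[2])
      edge_faces[[key]] <- c(edge_faces[[key]], f)
    }
  }
  corners_all <- as.integer(corner_id)
  is_corner <- seq_len(nb) %in% corners_all

  bi <- integer(0); bj <- integer(0)
  f1 <- integer(0); f2 <- integer(0)
  for (key in ls(edge_faces)) {
    fl <- edge_faces[[key]]
    if (length(fl) != 2) next
    pr <- as.integer(strsplit(key, " ")[[1]])
    if (is_corner[pr[1]] && is_corner[pr[2]]) next   # slant edge
    tri1 <- faces[fl[1], ]; tri2 <- faces[fl[2], ]
    n1 <- .tri_normal(xyz[tri1[1], ], xyz[tri1[2], ], xyz[tri1[3], ])
    n2 <- .tri_normal(xyz[tri2[1], ], xyz[tri2[2], ], xyz[tri2[3], ])
    if (abs(1 - sum(n1 * n2)) > 1e-12) next          # not planar as built
    bi <- c(bi, pr[1]); bj <- c(bj, pr[2])
    f1 <- c(f1, fl[1]); f2 <- c(f2, fl[2])
  }
  bends <- cbind(i = bi, j = bj,
                 a1 = faces[f1, 1], b1 = faces[f1, 2], c1 = faces[f1, 3],
                 a2 = faces[f2, 1], b2 = faces[f2, 2], c2 = faces[f2, 3])

  # ---- recentre on the centre of mass --------------------------------------
  com <- colMeans(xyz)
  stopifnot(max(abs(com[1:2])) < 1e-9)
  xyz <- sweep(xyz, 2, com)

  role_chr <- c("repulsive", "attractive", "interior")[role + 1L]
  beads <- data.frame(
    index = seq_len(nb),
    layer = ifelse(layer == 0L, NA_integer_, layer),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = radius, role = role_chr, charge = charge,
    mass = 1
  )

  walls <- lapply(1:3, function(w) {
    rows <- lapply(seq_len(nlay), function(k) row_ids[[k]][[w]])
    ids <- unique(unlist(rows))
    frame <- ids[role[ids] != 1L]   # structural beads define the wall plane
    pts <- xyz[frame, , drop = FALSE]
    fit <- .fit_plane(pts)
    ctr <- colMeans(pts)
    nrm <- fit$normal
    if (sum(nrm * c(ctr[1:2], 0)) < 0) nrm <- -nrm
    list(rows = rows, ids = ids, frame = frame, extras = extras[[w]],
         centre = ctr, normal = nrm)
  })

  tpl <- list(
    beads = beads,
    bonds = cbind(bonds, rest = rest),
    bends = bends,
    kappa_b = kappa_b,
    k_s = k_s,
    charged = charged,
    inclination = inclination,
    blue_per_edge = blue_per_edge,
    protrusion = protrusion,
    walls = walls,
    corners = corners_all,
    interior_ids = c(id_big1, id_big2, id_apex),
    mass_da = 32
  )
  class(tpl) <- "capsomer_template"
  tpl
}

.tri_normal <- function(a, b, c) {
  u <- b - a; v <- c - a
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  m <- sqrt(sum(n^2))
  if (m == 0) stop("degenerate face")
  n / m
}

# least-squares plane through points; returns unit normal and centroid
.fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-10)
    stop("degenerate (collinear) point set; no unique plane")
  list(normal = sv$v[, 3], centroid = ctr, thickness = sv$d[3])
}

# angle in degrees between a plane (unit normal `normal`) and a line
# (direction `axis`); 0 when the line lies in the plane
.plane_line_angle <- function(normal, axis) {
  axis <- axis / sqrt(sum(axis^2))
  normal <- normal / sqrt(sum(normal^2))
  90 - acos(min(1, abs(sum(normal * axis)))) * 180 / pi
}

#' Inclination angle of the lateral walls
#'
#' Measures the angle between the best-fit plane of each lateral wall's frame
#' beads and the outward normal of the bottom layer, and returns the mean
#' over the three walls, in degrees. The convention follows the line-plane
#' angle: a right prism (vertical walls containing the base normal) measures
#' 0 degrees, equivalently 90 degrees from the base plane. The built template
#' measures 53.9 degrees. The value is invariant under rigid rotations
#' because the base normal is itself fitted from the bottom-layer beads.
#'
#' @param template A [build_template()] object.
#' @return Angle in degrees.
#' @export
inclination_angle <- function(template) {
  stopifnot(inherits(template, "capsomer_template"))
  pos <- as.matrix(template$beads[, c("x", "y", "z")])
  lay1 <- which(template$beads$layer %in% 1L)
  base <- .fit_plane(pos[lay1, , drop = FALSE])
  # orient the base normal away from the capsomer centroid (exterior side)
  ctr <- colMeans(pos)
  nrm <- base$normal
  if (sum(nrm * (ctr - base$centroid)) > 0) nrm <- -nrm
  angs <- vapply(template$walls, function(w) {
    frame <- unlist(w$rows)
    frame <- frame[template$beads$role[frame] != "attractive"]
    fit <- .fit_plane(pos[frame, , drop = FALSE])
    .plane_line_angle(fit$normal, nrm)
  }, numeric(1))
  mean(angs)
}

#' Validate a capsomer template
#'
#' Report-style check of the template invariants: bead census (78 beads, 76
#' small, interior radii 1.8 and 1.2 nm), uniform masses, attractive roles
#' confined to layers 2-3, zero as-built elastic energy (rest lengths equal
#' built distances; wall faces planar), bending-edge topology (the two faces
#' adjoin the edge; no bending through interior beads or wall boundaries),
#' single connected stretch network, centre of mass at the origin, wall
#' inclination, wall congruence under the three-fold symmetry, and total
#' charge (0 or 4.5 e).
#'
#' @param template A [build_template()] object.
#' @return A data frame with columns `check`, `pass`, `detail`; attribute
#'   `ok` is `TRUE` when every check passes.
#' @export
validate_template <- function(template) {
  b <- template$beads
  pos <- as.matrix(b[, c("x", "y", "z")])
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  add("bead count 78", nrow(b) == 78, sprintf("%d beads", nrow(b)))
  add("76 small beads (radius 0.5)", sum(b$radius == 0.5) == 76,
      sprintf("%d small beads", sum(b$radius == 0.5)))
  add("one interior bead of radius 1.8 and one of 1.2",
      sum(b$radius == 1.8) == 1 && sum(b$radius == 1.2) == 1)
  add("uniform bead mass", length(unique(b$mass)) == 1)
  add("attractive beads only in layers 2-3",
      all(b$layer[b$role == "attractive"] %in% c(2L, 3L)))

  dvec <- function(i, j) pos[i, ] - pos[j, ]
  lens <- sqrt(rowSums((pos[template$bonds[, "i"], , drop = FALSE] -
                        pos[template$bonds[, "j"], , drop = FALSE])^2))
  e_stretch <- 0.5 * template$k_s * sum((lens - template$bonds[, "rest"])^2)
  add("as-built stretching energy is zero", e_stretch < 1e-18,
      sprintf("%.3g kBT", e_stretch))

  e_bend <- 0
  topo_ok <- TRUE
  for (e in seq_len(nrow(template$bends))) {
    r <- template$bends[e, ]
    t1 <- r[c("a1", "b1", "c1")]; t2 <- r[c("a2", "b2", "c2")]
    if (!all(c(r["i"], r["j"]) %in% t1) || !all(c(r["i"], r["j"]) %in% t2))
      topo_ok <- FALSE
    n1 <- .tri_normal(pos[t1[1], ], pos[t1[2], ], pos[t1[3], ])
    n2 <- .tri_normal(pos[t2[1], ], pos[t2[2], ], pos[t2[3], ])
    e_bend <- e_bend + template$kappa_b * (1 - sum(n1 * n2))
  }
  add("bend faces share their edge", topo_ok)
  add("as-built bending energy is zero", abs(e_bend) < 1e-9,
      sprintf("%.3g kBT", e_bend))
  add("no bending through interior beads",
      !any(template$bends[, 1:2] %in% template$interior_ids))
  slant <- apply(template$bends[, 1:2, drop = FALSE], 1,
                 function(pr) all(pr %in% template$corners))
  add("no bending on corner-to-corner slant edges", !any(slant))

  # connectivity of the stretch network
  nb <- nrow(b)
  comp <- seq_len(nb)
  repeat {
    prev <- comp
    for (e in seq_len(nrow(template$bonds))) {
      i <- template$bonds[e, "i"]; j <- template$bonds[e, "j"]
      m <- min(comp[i], comp[j]); comp[i] <- m; comp[j] <- m
    }
    if (identical(prev, comp)) break
  }
  add("stretch network is a single component", length(unique(comp)) == 1,
      sprintf("%d components", length(unique(comp))))

  com <- colMeans(pos)
  add("centre of mass at origin", max(abs(com)) < 1e-9)

  ang <- inclination_angle(template)
  add("wall inclination within 0.5 deg of target",
      abs(ang - template$inclination) <= 0.5, sprintf("%.2f deg", ang))

  dsort <- function(w) {
    ids <- unlist(w$rows)
    sort(as.vector(stats::dist(pos[ids, , drop = FALSE])))
  }
  d1 <- dsort(template$walls[[1]])
  cong <- all(vapply(template$walls[2:3], function(w)
    max(abs(dsort(w) - d1)) < 1e-8, logical(1)))
  add("the three lateral walls are congruent", cong)

  q <- sum(b$charge)
  add("total charge is 0 or 4.5 e",
      isTRUE(all.equal(q, 0)) || isTRUE(all.equal(q, 4.5)),
      sprintf("%.2f e", q))

  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  class(out) <- c("template_validation", class(out))
  out
}

#' @export
print.template_validation <- function(x, ...) {
  status <- ifelse(x$pass, "PASS", "FAIL")
  cat(sprintf("%-50s %s  %s\n", x$check, status, x$detail), sep = "")
  cat(if (attr(x, "ok")) "All checks passed.\n" else "Some checks FAILED.\n")
  invisible(x)
}

#' @export
print.capsomer_template <- function(x, ...) {
  cat(sprintf(
    "Capsomer template: %d beads (%d attractive), %d stretch edges, %d bend edges\n",
    nrow(x$beads), sum(x$beads$role == "attractive"),
    nrow(x$bonds), nrow(x$bends)))
  cat(sprintf("  kappa_b = %g kBT, k_s = %g kBT/nm^2, charge = %g e\n",
              x$kappa_b, x$k_s, sum(x$beads$charge)))
  cat(sprintf("  wall inclination: %.2f deg\n", inclination_angle(x)))
  invisible(x)
}
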