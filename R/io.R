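# Plain-text serialization: template JSON, XYZ and LAMMPS-dump trajectories.

#' Serialize a capsomer template to JSON
#'
#' Writes beads, stretch edges, bending edges (with their adjoining faces)
#' and the elastic moduli to a structured JSON file; [read_template_json()]
#' restores an equivalent template.
#'
#' @param template A [build_template()] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_template_json <- function(template, file) {
  payload <- list(
    beads = template$beads,
    bonds = as.data.frame(template$bonds),
    bends = as.data.frame(template$bends),
    kappa_b = template$kappa_b,
    k_s = template$k_s,
    charged = template$charged,
    inclination = template$inclination,
    blue_per_edge = template$blue_per_edge,
    corners = template$corners,
    interior_ids = template$interior_ids,
    walls = lapply(template$walls, function(w)
      list(rows = w$rows, ids = w$ids, extras = w$extras,
           centre = w$centre, normal = w$normal)),
    mass_da = template$mass_da
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  tpl <- list(
    beads = p$beads,
    bonds = as.matrix(p$bonds),
    bends = as.matrix(p$bends),
    kappa_b = p$kappa_b,
    k_s = p$k_s,
    charged = p$charged,
    inclination = p$inclination,
    blue_per_edge = p$blue_per_edge,
    walls = lapply(seq_len(nrow(p$walls) %||% length(p$walls)), function(i) {
      w <- if (is.data.frame(p$walls)) p$walls[i, ] else p$walls[[i]]
      list(rows = w$rows, ids = unlist(w$ids), extras = unlist(w$extras),
           centre = unlist(w$centre), normal = unlist(w$normal))
    }),
    corners = p$corners,
    interior_ids = p$interior_ids,
    mass_da = p$mass_da
  )
  class(tpl) <- "capsomer_template"
  tpl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# element tag per role for XYZ visualisation
.role_tag <- function(role_code) c("C", "B", "O")[role_code + 1L]

#' Write an XYZ trajectory
#'
#' Multi-frame XYZ with element tags encoding the bead role (C repulsive,
#' B attractive, O interior).
#'
#' @param frames A list of position matrices, a single matrix, or a
#'   `capsomer_system`.
#' @param state The `capsomer_system` supplying roles (optional when
#'   `frames` is itself a state).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(frames, state = NULL, file) {
  if (inherits(frames, "capsomer_system")) {
    state <- frames
    frames <- list(state$pos)
  }
  if (is.matrix(frames)) frames <- list(frames)
  tags <- .role_tag(state$role)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(as.character(nrow(f)), con)
    writeLines("capsomer system frame", con)
    writeLines(sprintf("%s %.8f %.8f %.8f", tags, f[, 1], f[, 2], f[, 3]),
               con)
  }
  invisible(file)
}

#' Write a LAMMPS-style dump trajectory
#'
#' One `ITEM:`-structured block per frame with bead id, capsomer id, role
#' code and unwrapped coordinates.
#'
#' @inheritParams write_xyz
#' @param times Frame times (reduced units) used as timesteps.
#' @return `file`, invisibly.
#' @export
write_lammps_dump <- function(frames, state = NULL, file, times = NULL) {
  if (inherits(frames, "capsomer_system")) {
    state <- frames
    frames <- list(state$pos)
  }
  if (is.matrix(frames)) frames <- list(frames)
  if (is.null(times)) times <- seq_along(frames) - 1
  L <- state$L
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    writeLines(c("ITEM: TIMESTEP", format(times[k]),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(f)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 rep(sprintf("0 %.8f", max(L, 0)), 3),
                 "ITEM: ATOMS id mol type x y z"), con)
    writeLines(sprintf("%d %d %d %.8f %.8f %.8f", seq_len(nrow(f)),
                       state$caps, state$role + 1L,
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(file)
}
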