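# Assembly metrics: cluster detection and Nmax / Nav statistics, assembly-
# state classification, structural fluctuation measures, and the per-face
# binding energy.

#' Assembly-state size thresholds
#'
#' Cluster-size classes used to label assembly products: fluid (Nc <= 3),
#' partial (4 <= Nc <= 15), capsid (16 <= Nc <= 20; a complete T=1 capsid
#' contains 20 trimers), malformed (Nc > 20).
#'
#' @export
assembly_thresholds <- list(fluid = 3L, partial = 15L, capsid = 20L)

#' Detect capsomer clusters in one frame
#'
#' Single-linkage connected components over capsomers: two capsomers are
#' linked when their minimum bead-bead centre distance (minimum image) is
#' below `dcut`. The default cutoff 1.5 sigma comfortably captures bound
#' attractive sites, which sit near 2^(1/6) sigma.
#'
#' @param pos Bead position matrix (beads x 3), or a `capsomer_system`.
#' @param membership Capsomer id per bead (1-based); taken from the state
#'   when `pos` is a `capsomer_system`.
#' @param box_edge Periodic box edge (0 = open); likewise.
#' @param dcut Linking cutoff, nm.
#' @return Integer vector of cluster sizes, decreasing; attribute `labels`
#'   holds the per-capsomer cluster id.
#' @export
find_clusters <- function(pos, membership = NULL, box_edge = NULL,
                          dcut = 1.5) {
  stopifnot(dcut > 0)
  if (inherits(pos, "capsomer_system")) {
    membership <- pos$caps
    box_edge <- pos$L
    pos <- pos$pos
  }
  lab <- cpp_cluster_labels(pos, box_edge, membership - 1L, dcut)
  sizes <- sort(tabulate(lab), decreasing = TRUE)
  sizes <- sizes[sizes > 0]
  attr(sizes, "labels") <- lab
  sizes
}

#' Cluster statistics over a trajectory
#'
#' Applies [find_clusters()] to every sampled frame and records the
#' per-frame cluster-size multisets together with the frame times.
#'
#' @param run An `md_run` from [run_md()] (with `save_frames = TRUE`), or a
#'   list of position matrices.
#' @param state The `capsomer_system` (defaulted from the run).
#' @param dcut Linking cutoff, nm.
#' @param times Frame times in reduced units (defaulted from the run).
#' @return Object of class `cluster_report`: `sizes` (list per frame),
#'   `times`, `n_capsomers`, `dcut`.
#' @export
cluster_report <- function(run, state = NULL, dcut = 1.5, times = NULL) {
  if (inherits(run, "md_run")) {
    frames <- run$frames
    if (is.null(times)) times <- run$samples$time
    if (is.null(state)) state <- run$state
  } else {
    frames <- run
    if (is.null(times)) times <- seq_along(frames) - 1
  }
  stopifnot(!is.null(state), length(frames) >= 1)
  sizes <- lapply(frames, function(f)
    as.integer(find_clusters(f, state$caps, state$L, dcut)))
  out <- list(sizes = sizes, times = times,
              n_capsomers = state$n_capsomers, dcut = dcut)
  class(out) <- "cluster_report"
  out
}

# frames belonging to the trailing averaging window
.window_frames <- function(report, window_ns) {
  us <- unit_system()
  window_red <- window_ns * 1e-9 / us$time_s
  tmax <- max(report$times)
  keep <- which(report$times > tmax - window_red)
  span <- tmax - min(report$times)
  if (span < window_red)
    warning(sprintf(
      "trajectory spans %.3g ns, shorter than the %.3g ns window; using all frames",
      span * us$time_s * 1e9, window_ns))
  keep
}

#' Windowed maximum cluster size Nmax
#'
#' Mean over the frames of the trailing `window` (nanoseconds; 2 ns by
#' default) of the per-frame maximum cluster size.
#'
#' @param report A [cluster_report()].
#' @param window Averaging window in ns.
#' @return Nmax in capsomers.
#' @export
nmax_over_window <- function(report, window = 2) {
  keep <- .window_frames(report, window)
  mean(vapply(report$sizes[keep], max, numeric(1)))
}

#' Windowed cluster-size distribution Nav(Nc)
#'
#' Nav(Nc) is the average number of capsomers aggregated in clusters of size
#' Nc: the window mean of Nc times the number of clusters of that size in
#' the frame. The distribution conserves capsomers: sum over Nc of Nav(Nc)
#' equals the total capsomer count N.
#'
#' @inheritParams nmax_over_window
#' @return Data frame with columns `Nc` (1..N) and `Nav`.
#' @export
nav_distribution <- function(report, window = 2) {
  keep <- .window_frames(report, window)
  N <- report$n_capsomers
  acc <- numeric(N)
  for (s in report$sizes[keep]) {
    tab <- tabulate(s, nbins = N)
    acc <- acc + seq_len(N) * tab
  }
  data.frame(Nc = seq_len(N), Nav = acc / length(keep))
}

#' Classify the assembly state
#'
#' Mixture fractions of the four assembly classes, computed from a
#' [nav_distribution()] table as Nav mass per class divided by the total
#' capsomer count: fluid (Nc <= 3), partial (4-15), capsid (16-20),
#' malformed (> 20).
#'
#' @param nav A data frame with columns `Nc`, `Nav`.
#' @return Named numeric vector of class fractions summing to 1.
#' @export
classify_assembly <- function(nav) {
  th <- assembly_thresholds
  cls <- cut(nav$Nc, c(0, th$fluid, th$partial, th$capsid, Inf),
             labels = c("fluid", "partial", "capsid", "malformed"))
  tot <- sum(nav$Nav)
  vapply(levels(cls), function(l) sum(nav$Nav[cls == l]) / tot, numeric(1))
}

# edge lengths and dihedral normal angles for one frame
.frame_geometry <- function(pos, state) {
  L <- state$L
  mi <- function(d) if (L > 0) d - L * round(d / L) else d
  dl <- mi(pos[state$bonds[, 1], , drop = FALSE] -
           pos[state$bonds[, 2], , drop = FALSE])
  lens <- sqrt(rowSums(dl^2))
  bd <- state$bends
  tri_normals <- function(a, b, c) {
    u <- mi(pos[b, , drop = FALSE] - pos[a, , drop = FALSE])
    v <- mi(pos[c, , drop = FALSE] - pos[a, , drop = FALSE])
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    n / sqrt(rowSums(n^2))
  }
  if (nrow(bd) > 0) {
    n1 <- tri_normals(bd[, "a1"], bd[, "b1"], bd[, "c1"])
    n2 <- tri_normals(bd[, "a2"], bd[, "b2"], bd[, "c2"])
    cosang <- pmin(1, pmax(-1, rowSums(n1 * n2)))
    angles <- acos(cosang)
  } else angles <- numeric(0)
  list(lengths = lens, angles = angles)
}

#' Structural fluctuation measures
#'
#' Root-mean-square deviations, over frames, capsomers and edges, of the
#' stretch-edge lengths from their rest lengths (nm) and of the bending-edge
#' dihedral angles from the planar reference (radians; planarity is the
#' zero-energy state of the bending term). When a `baseline` report is
#' supplied (typically from the rigid moduli (5000, 5000)), the ratios of
#' the two RMS measures to the baseline values are included.
#'
#' @param run An `md_run` with saved frames, or a list of position matrices.
#' @param state The `capsomer_system` (defaulted from the run).
#' @param baseline Optional `fluctuation_report` with the rigid reference.
#' @param discard Fraction of initial frames discarded as burn-in.
#' @return Object of class `fluctuation_report`: `edge_rms` (nm),
#'   `angle_rms` (rad), and `edge_ratio`, `angle_ratio` when a baseline is
#'   given.
#' @export
fluctuations <- function(run, state = NULL, baseline = NULL,
                         discard = 0.25) {
  if (inherits(run, "md_run")) {
    frames <- run$frames
    if (is.null(state)) state <- run$state
  } else frames <- run
  stopifnot(!is.null(state), length(frames) >= 1)
  keep <- frames[max(1, ceiling(length(frames) * discard)):length(frames)]
  se <- 0; ns <- 0; sa <- 0; na <- 0
  for (f in keep) {
    g <- .frame_geometry(f, state)
    se <- se + sum((g$lengths - state$rest)^2); ns <- ns + length(g$lengths)
    sa <- sa + sum(g$angles^2); na <- na + length(g$angles)
  }
  out <- list(edge_rms = sqrt(se / ns),
              angle_rms = if (na > 0) sqrt(sa / na) else NA_real_,
              n_frames = length(keep))
  if (!is.null(baseline)) {
    out$edge_ratio <- out$edge_rms / baseline$edge_rms
    out$angle_ratio <- out$angle_rms / baseline$angle_rms
  }
  class(out) <- "fluctuation_report"
  out
}

#' @export
print.fluctuation_report <- function(x, ...) {
  cat(sprintf("RMS edge-length fluctuation: %.4g nm\n", x$edge_rms))
  cat(sprintf("RMS bending-angle fluctuation: %.4g rad\n", x$angle_rms))
  if (!is.null(x$edge_ratio))
    cat(sprintf("ratios to rigid baseline: edges %.3g x, angles %.3g x\n",
                x$edge_ratio, x$angle_ratio))
  invisible(x)
}

#' Attractive binding energy across one bound capsomer face
#'
#' Sums the attractive-kind Lennard-Jones pair energies between the beads of
#' the two capsomers of a bound dimer (one shared face). Returns 0 with a
#' warning when no attractive pair is in range (unbound input).
#'
#' @param state A two-capsomer `capsomer_system` (see [make_bound_dimer()]).
#' @param pos Optional position matrix overriding `state$pos` (e.g. a
#'   trajectory frame).
#' @return Total attractive energy in kBT (negative when bound); its
#'   magnitude is the binding energy per face.
#' @export
face_binding_energy <- function(state, pos = NULL) {
  if (state$n_capsomers != 2)
    stop("face_binding_energy expects a two-capsomer (dimer) state")
  if (is.null(pos)) pos <- state$pos
  L <- state$L
  mi <- function(d) if (L > 0) d - L * round(d / L) else d
  att <- which(state$role == 1L)
  a1 <- att[state$caps[att] == 1L]
  a2 <- att[state$caps[att] == 2L]
  e <- 0
  tab <- interaction_table(eps_att = state$eps_att)
  entry <- tab[tab$kind == "attractive", ][1, ]
  for (i in a1) {
    d <- mi(sweep(pos[a2, , drop = FALSE], 2, pos[i, ]))
    r <- sqrt(rowSums(d^2))
    inr <- r < entry$r_cut
    if (any(inr)) e <- e + sum(lj_pair_energy(r[inr], entry))
  }
  if (e == 0) warning("no attractive pair within range; dimer is unbound")
  e
}

#' Summarise a trajectory's assembly state
#'
#' Convenience wrapper combining the windowed metrics: Nmax, the Nav(Nc)
#' table, and the assembly-class mixture fractions.
#'
#' @param report A [cluster_report()].
#' @param window Averaging window in ns.
#' @return List with `nmax`, `nav` (data frame), `fractions`.
#' @export
analysis_summary <- function(report, window = 2) {
  nav <- nav_distribution(report, window)
  list(nmax = nmax_over_window(report, window),
       nav = nav,
       fractions = as.list(classify_assembly(nav)))
}

#' Write analysis reports to disk
#'
#' Writes the per-frame cluster sizes and the Nav table as CSV and the run
#' summary (Nmax, assembly-class mixture) as JSON into `dir`.
#'
#' @param report A [cluster_report()].
#' @param dir Output directory (created if needed).
#' @param window Averaging window in ns.
#' @return `dir`, invisibly.
#' @export
write_analysis_reports <- function(report, dir, window = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes_df <- do.call(rbind, lapply(seq_along(report$sizes), function(k)
    data.frame(frame = k, time = report$times[k],
               cluster = seq_along(report$sizes[[k]]),
               size = report$sizes[[k]])))
  utils::write.csv(sizes_df, file.path(dir, "clusters.csv"),
                   row.names = FALSE)
  s <- analysis_summary(report, window)
  utils::write.csv(s$nav, file.path(dir, "nav.csv"), row.names = FALSE)
  jsonlite::write_json(list(nmax = s$nmax, fractions = s$fractions,
                            dcut = report$dcut,
                            n_capsomers = report$n_capsomers),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
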