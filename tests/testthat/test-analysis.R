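# Cluster metrics, assembly classification, fluctuation measures, binding.

# synthetic cluster report: one frame per entry of `sizes_list`, with times
# spread over about 2.2 ns so the default 2 ns window covers most frames
fake_report <- function(sizes_list, N, span_red = 620) {
  structure(list(
    sizes = sizes_list,
    times = seq(0, span_red, length.out = length(sizes_list)),
    n_capsomers = N, dcut = 1.5), class = "cluster_report")
}

test_that("well-separated capsomers are singleton clusters", {
  tpl <- build_template()
  st <- make_planted_clusters(c(1, 1, 1, 1), template = tpl)
  sizes <- find_clusters(st)
  expect_equal(as.integer(sizes), rep(1L, 4))
})

test_that("cluster linkage is transitive (A-B-C chains merge)", {
  pos <- rbind(c(5, 5, 5), c(6.2, 5, 5), c(7.4, 5, 5))  # A-C beyond dcut
  sizes <- find_clusters(pos, membership = 1:3, box_edge = 20, dcut = 1.5)
  expect_equal(as.integer(sizes), 3L)
  # and across the periodic boundary
  pos2 <- rbind(c(0.3, 5, 5), c(19.7, 5, 5))
  expect_equal(as.integer(find_clusters(pos2, 1:2, 20, 1.5)), 2L)
})

test_that("cluster detection equals the brute-force graph oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:12, 1)
    L <- 10
    pos <- matrix(stats::runif(3 * n, 0, L), n, 3)
    got <- as.integer(find_clusters(pos, seq_len(n), L, 1.5))
    want <- oracle_cluster_sizes(pos, seq_len(n), L, 1.5)
    expect_equal(got, want)
  }
})

test_that("Nmax window averages follow the definitions", {
  all_single <- fake_report(rep(list(rep(1L, 10)), 12), 10)
  expect_equal(nmax_over_window(all_single), 1)
  big <- fake_report(rep(list(c(20L, rep(1L, 80))), 12), 100)
  expect_equal(nmax_over_window(big), 20)
  alt <- fake_report(rep(list(c(10L, rep(1L, 90)), c(20L, rep(1L, 80))), 10),
                     100)
  expect_equal(nmax_over_window(alt), 15)
  short <- fake_report(rep(list(rep(1L, 4)), 4), 4, span_red = 10)
  expect_warning(nmax_over_window(short), "shorter")
})

test_that("Nav distribution counts capsomers per cluster size and conserves N", {
  singles <- fake_report(rep(list(rep(1L, 100)), 8), 100)
  nav <- nav_distribution(singles)
  expect_equal(nav$Nav[1], 100)
  expect_equal(sum(nav$Nav[-1]), 0)
  five20 <- fake_report(rep(list(rep(20L, 5)), 8), 100)
  nav2 <- nav_distribution(five20)
  expect_equal(nav2$Nav[20], 100)
  # conservation on random partitions
  for (seed in 1:10) {
    set.seed(seed)
    sizes_list <- replicate(6, {
      s <- integer(0); left <- 60
      while (left > 0) { k <- sample(min(left, 25), 1); s <- c(s, k); left <- left - k }
      s
    }, simplify = FALSE)
    nav <- nav_distribution(fake_report(sizes_list, 60))
    expect_equal(sum(nav$Nav), 60, tolerance = 1e-12)
  }
})

test_that("assembly classification applies the size thresholds", {
  nav <- data.frame(Nc = 1:100, Nav = 0)
  nav$Nav[2] <- 100
  expect_equal(unname(classify_assembly(nav)["fluid"]), 1)
  nav$Nav[] <- 0; nav$Nav[20] <- 100
  expect_equal(unname(classify_assembly(nav)["capsid"]), 1)
  nav$Nav[] <- 0; nav$Nav[2] <- 50; nav$Nav[30] <- 50
  f <- classify_assembly(nav)
  expect_equal(unname(f["fluid"]), 0.5)
  expect_equal(unname(f["malformed"]), 0.5)
  # boundary cases: 3 is fluid, 16 and 20 are capsid, 21 malformed
  nav$Nav[] <- 0; nav$Nav[c(3, 16, 20, 21)] <- 25
  f2 <- classify_assembly(nav)
  expect_equal(unname(f2["fluid"]), 0.25)
  expect_equal(unname(f2["capsid"]), 0.5)
  expect_equal(unname(f2["malformed"]), 0.25)
})

test_that("fluctuations vanish for a frozen template and self-ratios are 1", {
  tpl <- build_template()
  st <- make_system(tpl, list(list(rotation = diag(3),
                                   translation = rep(15, 3))), 30)
  fr <- fluctuations(list(st$pos, st$pos), st)
  expect_lt(fr$edge_rms, 1e-12)
  expect_lt(fr$angle_rms, 1e-6)
  set.seed(1)
  frames <- lapply(1:4, function(i)
    st$pos + matrix(stats::rnorm(length(st$pos), 0, 0.01), ncol = 3))
  a <- fluctuations(frames, st, discard = 0)
  b <- fluctuations(frames, st, baseline = a, discard = 0)
  expect_equal(b$edge_ratio, 1)
  expect_equal(b$angle_ratio, 1)
})

test_that("face binding energy sums attractive pairs and flags unbound input", {
  st <- make_bound_dimer(eps_att = 2, relax = 1000)
  e <- face_binding_energy(st)
  expect_lt(e, -10)
  expect_equal(e, unname(total_energy(st)[["steric_attractive"]]),
               tolerance = 1e-10)
  # linearity in eps_att for a frozen configuration
  st4 <- st
  st4$eps_att <- 4
  expect_equal(face_binding_energy(st4), 2 * e, tolerance = 1e-10)
  # unbound dimer reports zero with a warning
  tpl <- build_template()
  far <- make_system(tpl, list(
    list(rotation = diag(3), translation = c(8, 8, 8)),
    list(rotation = diag(3), translation = c(25, 25, 25))), 34)
  expect_warning(e0 <- face_binding_energy(far), "unbound")
  expect_identical(e0, 0)
  expect_error(face_binding_energy(make_harmonic_pair()), "dimer")
})

test_that("analysis summary and report writers produce consistent output", {
  rep1 <- structure(list(sizes = rep(list(c(5L, 3L, 1L, 1L)), 6),
                         times = seq(0, 620, length.out = 6),
                         n_capsomers = 10, dcut = 1.5),
                    class = "cluster_report")
  s <- analysis_summary(rep1)
  expect_equal(s$nmax, 5)
  expect_equal(sum(s$nav$Nav), 10)
  expect_equal(s$fractions$fluid, 0.5)   # 3 + 1 + 1 of 10
  expect_equal(s$fractions$partial, 0.5) # the 5-cluster
  dir <- file.path(tempdir(), "softcapsid-analysis")
  write_analysis_reports(rep1, dir)
  expect_true(file.exists(file.path(dir, "clusters.csv")))
  expect_true(file.exists(file.path(dir, "nav.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$nmax, 5)
  unlink(dir, recursive = TRUE)
})
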