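# Superposition RMSD, SASA, interface burial and the switched nonbonded
# interaction energy.

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

test_that("superposition removes rigid motion exactly", {
  set.seed(40)
  x <- matrix(rnorm(60), 20)
  sp0 <- superpose(x, x)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  for (k in 1:10) {
    R <- random_rotation()
    t <- rnorm(3)
    y <- x %*% R + matrix(t, 20, 3, byrow = TRUE)
    sp <- superpose(x, y)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # rmsd is invariant under rigid motion of the mobile set
    noisy <- x + matrix(rnorm(60, sd = 0.3), 20)
    expect_equal(superpose(x, noisy)$rmsd,
                 superpose(x, noisy %*% R + matrix(t, 20, 3, byrow = TRUE))$rmsd,
                 tolerance = 1e-9)
  }
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("Kabsch RMSD equals the quaternion-method oracle", {
  set.seed(41)
  for (k in 1:20) {
    x <- matrix(rnorm(30), 10)
    y <- x %*% random_rotation() + matrix(rnorm(30, sd = 0.4), 10)
    expect_equal(superpose(x, y)$rmsd, quaternion_rmsd(x, y),
                 tolerance = 1e-9)
  }
})

test_that("RMSD series: zero at the reference, zero under rigid motion", {
  fx <- make_mixed_template(n_hb = 1L, n_sb = 0L, n_res = 8L, p_occ = 1,
                            n_frames = 5L, jitter_sd = 0)
  run <- generate_trajectory(fx$template, fx$schedule, fx$spec)
  base <- frame_coords(run$trajectory, 1L)
  set.seed(42)
  xyz <- t(vapply(1:5, function(i) {
    as.numeric(t(base %*% random_rotation() +
                   matrix(rnorm(3), nrow(base), 3, byrow = TRUE)))
  }, numeric(3L * nrow(base))))
  rigid <- trajectory(fx$template, xyz)
  rs <- rmsd_series(rigid, selection = "heavy")
  expect_equal(rs[1], 0, tolerance = 1e-9)
  expect_true(all(rs < 1e-6))
})

test_that("jittered trajectories plateau at the noise-model RMSD", {
  # two independently jittered frames differ by N(0, 2*sd^2) per coordinate,
  # so the expected RMSD is sd * sqrt(6)
  fx <- make_mixed_template(n_hb = 0L, n_sb = 0L, n_res = 40L, p_occ = 1,
                            n_frames = 30L, jitter_sd = 0.05, seed = 17L)
  run <- generate_trajectory(fx$template, fx$schedule, fx$spec)
  rs <- rmsd_series(run$trajectory, selection = "heavy")
  plateau <- mean(rs[-1])
  expect_lt(abs(plateau - 0.05 * sqrt(6)) / (0.05 * sqrt(6)), 0.10)
})

test_that("SASA of an isolated sphere matches the analytic area", {
  a <- data.frame(eleno = 1L, elety = "CA", resid = "GLY", chain = "A",
                  resno = 1072L, x = 0, y = 0, z = 0, elesy = "C")
  s <- complex_structure(a)
  r <- sasa(structure = s, n_points = 960L)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(r$total - analytic) / analytic, 1 / sqrt(960))
  expect_error(sasa(structure = s, radii = c(N = 1.55)), "radii error")
})

test_that("overlapping spheres are bounded by the single-sphere area", {
  a <- data.frame(eleno = 1:2, elety = c("CA", "CA"), resid = "GLY",
                  chain = "A", resno = c(1072L, 1073L),
                  x = c(0, 0), y = 0, z = 0, elesy = "C")
  s <- complex_structure(a)
  r <- sasa(structure = s)
  single <- 4 * pi * 3.1^2
  expect_gte(r$total, single * 0.999)
  expect_lte(r$total, 2 * single)
  expect_true(all(r$atom_area >= 0))
})

test_that("SASA self-converges with the point count", {
  set.seed(43)
  n <- 50L
  a <- data.frame(eleno = seq_len(n), elety = "CA", resid = "GLY",
                  chain = "A", resno = 1072L + seq_len(n) - 1L,
                  x = rnorm(n, sd = 4), y = rnorm(n, sd = 4),
                  z = rnorm(n, sd = 4), elesy = "C")
  s <- complex_structure(a)
  lo <- sasa(structure = s, n_points = 960L)$total
  hi <- sasa(structure = s, n_points = 10000L)$total
  expect_lt(abs(lo - hi) / hi, 0.02)
})

test_that("interface burial vanishes on separation and is non-negative", {
  fx <- make_mixed_template(n_hb = 2L, n_sb = 1L, n_res = 6L)
  tmpl <- fx$template
  shifted <- function(dy) {
    x <- coords(tmpl)
    b <- tmpl$atom$domain == "Spacer"
    x[b, 2] <- x[b, 2] + dy
    x
  }
  burials <- vapply(c(0, 2, 5, 100), function(dy)
    interface_sasa(shifted(dy), tmpl, n_points = 240L)$buried_area,
    numeric(1))
  expect_lt(burials[4], 0.5)
  expect_true(all(diff(burials) <= 1e-6))  # monotone non-increasing
  expect_true(all(burials >= -1e-9))
  expect_gt(burials[1], 10)  # designed contacts bury real area
})

test_that("nonbonded energy reproduces its closed forms", {
  two_atoms <- function(r) {
    atom <- data.frame(
      eleno = 1:2, elety = c("NZ", "OD1"), resid = c("LYS", "ASP"),
      chain = c("A", "B"), resno = c(1072L, 556L),
      x = c(0, r), y = 0, z = 0, elesy = c("N", "O"))
    complex_structure(atom)
  }
  coul <- nonbonded_params(data.frame(
    resid = c("LYS", "ASP"), elety = c("NZ", "OD1"),
    charge = c(1, 1), epsilon = 0, rmin2 = 0.5))
  e <- interaction_energy(structure = two_atoms(1), params = coul)
  expect_equal(e$electrostatic, 332.0636, tolerance = 1e-9)
  expect_equal(e$total, e$vdw + e$electrostatic, tolerance = 1e-6)
  lj <- nonbonded_params(data.frame(
    resid = c("LYS", "ASP"), elety = c("NZ", "OD1"),
    charge = 0, epsilon = 0.2, rmin2 = 1.6))
  expect_equal(interaction_energy(structure = two_atoms(3.2),
                                  params = lj)$vdw, -0.2, tolerance = 1e-12)
  # beyond the cutoff both terms vanish exactly
  both <- nonbonded_params(data.frame(
    resid = c("LYS", "ASP"), elety = c("NZ", "OD1"),
    charge = c(1, -1), epsilon = 0.2, rmin2 = 1.6))
  e_far <- interaction_energy(structure = two_atoms(12.5), params = both)
  expect_identical(e_far$total, 0)
  # missing parameters are reported with the atom
  expect_error(interaction_energy(structure = two_atoms(3), params =
    nonbonded_params(data.frame(resid = "LYS", elety = "NZ", charge = 0,
                                epsilon = 0.1, rmin2 = 1.6))),
    "ASP\\|OD1")
})

test_that("the switching function is continuous at both ends", {
  two_atoms <- function(r) {
    atom <- data.frame(
      eleno = 1:2, elety = c("NZ", "OD1"), resid = c("LYS", "ASP"),
      chain = c("A", "B"), resno = c(1072L, 556L),
      x = c(0, r), y = 0, z = 0, elesy = c("N", "O"))
    complex_structure(atom)
  }
  p <- nonbonded_params(data.frame(
    resid = c("LYS", "ASP"), elety = c("NZ", "OD1"),
    charge = c(1, -1), epsilon = 0.2, rmin2 = 1.6))
  en <- function(r) interaction_energy(structure = two_atoms(r),
                                       params = p)$total
  eps <- 1e-6
  expect_lt(abs(en(10 - eps) - en(10 + eps)), 1e-5)
  expect_lt(abs(en(12 - eps) - en(12 + eps)), 1e-5)
  # and the switch is monotone attenuation in between
  expect_gt(abs(en(10.5)), abs(en(11.5)))
})

test_that("energy is symmetric under swapping the domain labels", {
  fx <- make_mixed_template(n_hb = 1L, n_sb = 2L, n_res = 5L)
  tmpl <- fx$template
  p <- toy_nonbonded_params(tmpl)
  e1 <- interaction_energy(structure = tmpl, params = p)
  # rebuild with TSP8/Spacer numbering exchanged between the chains
  atom <- tmpl$atom[, c("eleno", "elety", "resid", "chain", "resno",
                        "x", "y", "z", "elesy")]
  a <- atom$chain == "A"
  atom$resno[a] <- atom$resno[a] - 1072L + 556L
  atom$resno[!a] <- atom$resno[!a] - 556L + 1072L
  swapped <- complex_structure(atom)
  e2 <- interaction_energy(structure = swapped, params = p)
  expect_equal(e1$total, e2$total, tolerance = 1e-9)
  expect_equal(e1$vdw, e2$vdw, tolerance = 1e-9)
})

test_that("metric summaries aggregate per-replicate time averages", {
  fx_hi <- make_mixed_template(n_hb = 2L, n_sb = 0L, n_res = 4L, p_occ = 0.8,
                               n_frames = 100L, seed = 50L)
  fx_lo <- make_mixed_template(n_hb = 2L, n_sb = 0L, n_res = 4L, p_occ = 0.2,
                               n_frames = 100L, seed = 60L)
  hi <- lapply(generate_replicates(fx_hi$template, fx_hi$schedule, fx_hi$spec),
               `[[`, "trajectory")
  lo <- lapply(generate_replicates(fx_lo$template, fx_lo$schedule, fx_lo$spec),
               `[[`, "trajectory")
  ms <- metric_summary(list(high = hi, low = lo), metrics = "nhb")
  expect_equal(nrow(ms), 2L)
  expect_gt(ms$mean[ms$condition == "high"], ms$mean[ms$condition == "low"])
  # aggregation consistency: the summary equals aggregating replicate means
  reps <- unlist(ms[ms$condition == "high", c("rep1", "rep2", "rep3")])
  expect_equal(ms$mean[ms$condition == "high"], mean(reps))
  pop_sem <- sqrt(sum((reps - mean(reps))^2) / 3) / sqrt(3)
  expect_equal(ms$sem[ms$condition == "high"], unname(pop_sem))
})
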