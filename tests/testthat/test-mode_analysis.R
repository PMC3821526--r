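test_that("overlap of a ModeSet with itself is the identity pattern", {
  fix <- hex_fixture()
  ov <- overlap_matrix(fix$mu, fix$mu, n_modes = 15L)
  expect_equal(unname(diag(ov$values)), rep(1, 15L), tolerance = 1e-10)
  expect_equal(ov$best_match, seq_len(15L), ignore_attr = TRUE)
  rep_tab <- reordering_report(ov)
  expect_equal(rep_tab$bound_mode, rep_tab$unbound_mode, ignore_attr = TRUE)
  expect_equal(rep_tab$fraction_bound, rep_tab$fraction_unbound)
  expect_equal(rep_tab$freq_bound, rep_tab$freq_unbound)
})

test_that("overlap entries are bounded and complete bases give unit row sums", {
  fix <- hex_fixture()
  n_all <- length(fix$mu$values)
  ov <- overlap_matrix(fix$mu, fix$mb, n_modes = n_all)
  expect_true(all(ov$values >= 0 & ov$values <= 1 + 1e-12))
  row_sums <- rowSums(ov$values^2)
  col_sums <- colSums(ov$values^2)
  expect_true(all(abs(row_sums - 1) < 1e-8))
  expect_true(all(abs(col_sums - 1) < 1e-8))
})

test_that("overlap is symmetric under swapping the two ModeSets", {
  fix <- hex_fixture()
  ab <- overlap_matrix(fix$mu, fix$mb, n_modes = 12L)
  ba <- overlap_matrix(fix$mb, fix$mu, n_modes = 12L)
  expect_equal(ab$values, t(ba$values), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("best_match recovers a planted eigenvector permutation", {
  fix <- hex_fixture()
  k <- 8L
  perm <- c(3L, 1L, 4L, 2L, 7L, 8L, 5L, 6L)
  U <- fix$mu$vectors[, 1:k]
  bound <- mode_set(fix$mu$values[1:k], U[, perm], rigid_count = 6L)
  ov <- overlap_matrix(mode_set(fix$mu$values[1:k], U, rigid_count = 6L),
                       bound, n_modes = k)
  # unbound mode i now lives at bound column which(perm == i)
  expect_equal(ov$best_match, match(seq_len(k), perm), ignore_attr = TRUE)

  # one-to-one assignment agrees here (the permutation is unambiguous)
  ov1 <- overlap_matrix(mode_set(fix$mu$values[1:k], U, rigid_count = 6L),
                        bound, n_modes = k, one_to_one = TRUE)
  expect_equal(ov1$best_match, match(seq_len(k), perm), ignore_attr = TRUE)

  small <- mode_set(c(1, 2), matrix(diag(6)[, 1:2], ncol = 2), rigid_count = 4L)
  expect_error(overlap_matrix(fix$mu, small), class = "carbanm_comparison_error")
})

test_that("pore profile reproduces analytic ring geometry and full occlusion", {
  n <- 12L
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cg_structure(data.frame(
    chain = "A", resno = seq_len(n), resname = "GLY",
    x = 10 * cos(theta), y = 10 * sin(theta), z = 2 * sin(2 * theta)))
  axis <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  pr <- pore_profile(ring, axis = axis)
  expect_equal(pr$min_radius, 10, tolerance = 1e-9)

  # purely radial inward displacement scaled to the ring radius closes it
  inward <- -cbind(cos(theta), sin(theta), 0)
  v <- as.numeric(t(inward))           # 3N-norm sqrt(n)
  pr0 <- pore_profile(ring, mode = v, amplitude = 10 * sqrt(n), axis = axis)
  expect_equal(pr0$min_radius, 0, tolerance = 1e-9)
  # amplitude 0 reproduces the static profile
  expect_equal(pore_profile(ring, mode = v, amplitude = 0, axis = axis)$min_radius,
               pr$min_radius)
  expect_error(pore_profile(ring, mode = v[-1], amplitude = 1, axis = axis),
               class = "carbanm_comparison_error")
})

test_that("pore radius is monotone in signed amplitude along the closing mode", {
  fix <- hex_fixture()
  cl <- as.integer(closing_mode_index(fix$mu, fix$cg))
  v <- fix$mu$vectors[, cl]
  amps <- seq(0, 10, by = 2)
  radii_pos <- vapply(amps, function(a) pore_profile(fix$cg, v, a)$min_radius, 0)
  radii_neg <- vapply(amps, function(a) pore_profile(fix$cg, v, -a)$min_radius, 0)
  closing_dir <- if (radii_pos[2] < radii_pos[1]) radii_pos else radii_neg
  opening_dir <- if (radii_pos[2] < radii_pos[1]) radii_neg else radii_pos
  expect_true(all(diff(closing_dir) < 0))
  expect_true(all(diff(opening_dir) > 0))
})

test_that("displacement vectors scale correctly and round-trip through NMD", {
  fix <- hex_fixture()
  n <- n_atoms(fix$cg)
  expect_equal(mode_displacement_vectors(fix$cg, fix$mu$vectors[, 1], 0),
               matrix(0, n, 3))
  dv <- mode_displacement_vectors(fix$cg, fix$mu$vectors[, 2], 3)
  expect_equal(sqrt(sum(dv^2)), 3, tolerance = 1e-12)

  dimer <- make_dimer(5)
  md <- compute_modes(build_hessian(build_spring_network(dimer)))
  dv2 <- mode_displacement_vectors(dimer, md$vectors[, 1], 1)
  expect_equal(dv2[1, ], -dv2[2, ], tolerance = 1e-12)
  expect_equal(sqrt(sum(dv2[1, ]^2)), 1 / sqrt(2), tolerance = 1e-12)

  f <- withr::local_tempfile(fileext = ".nmd")
  write_nmd(f, fix$cg, fix$mu, n_modes = 5L)
  back <- read_nmd(f)
  expect_equal(back$coordinates, coords(fix$cg), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(length(back$modes), 5L)
  for (m in 1:5) {
    expect_equal(back$modes[[m]]$vector, fix$mu$vectors[, m], tolerance = 1e-6)
    expect_equal(back$modes[[m]]$scale, 1 / sqrt(fix$mu$values[m]),
                 tolerance = 1e-6)
  }
  expect_equal(back$resids, fix$cg$atoms$resno)
  expect_equal(back$chainids, fix$cg$atoms$chain)
})

test_that("closing_mode_index picks a strongly radial pore-lining mode", {
  fix <- hex_fixture()
  cl <- closing_mode_index(fix$mu, fix$cg)
  expect_gt(attr(cl, "score"), 0.5)
  # the identified mode moves the pore-lining tips more than the wall
  v <- matrix(fix$mu$vectors[, as.integer(cl)], ncol = 3, byrow = TRUE)
  amp <- sqrt(rowSums(v^2))
  tip <- fix$cg$atoms$resno > fix$spec$residues_per_subunit - 8L
  expect_gt(mean(amp[tip]), mean(amp[!tip]))
})
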