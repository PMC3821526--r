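test_that("contact springs follow the inclusive cutoff rule", {
  net <- build_spring_network(make_dimer(5), cutoff = 8, k = 1)
  expect_equal(nrow(net$springs), 1L)
  expect_equal(net$springs$rest_length, 5)
  expect_equal(net$springs$k, 1)
  expect_equal(net$springs$tag, "contact")

  expect_equal(nrow(build_spring_network(make_dimer(8.5), cutoff = 8)$springs), 0L)
  # boundary is inclusive
  expect_equal(nrow(build_spring_network(make_dimer(8), cutoff = 8)$springs), 1L)

  expect_error(build_spring_network(make_dimer(5), cutoff = -1),
               class = "carbanm_parameter_error")
})

test_that("spring count matches the brute-force pairwise oracle", {
  fix <- hex_fixture()
  expect_equal(nrow(fix$net$springs), oracle_spring_count(coords(fix$cg), 8))
  bumpy <- perturb(fix$cg, 0.3, seed = 3L)
  for (cutoff in c(6, 8, 10)) {
    expect_equal(nrow(build_spring_network(bumpy, cutoff = cutoff)$springs),
                 oracle_spring_count(coords(bumpy), cutoff))
  }
})

test_that("two-body Hessian has the closed-form spectrum", {
  for (k in c(1, 2.5)) {
    net <- build_spring_network(make_dimer(5), cutoff = 8, k = k)
    H <- build_hessian(net)
    expect_equal(max(abs(H - t(H))), 0)
    ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    # one stretch mode at 2k, five zeros
    expect_equal(ev[6], 2 * k, tolerance = 1e-12)
    expect_lt(max(abs(ev[1:5])), 1e-12)
  }
})

test_that("Hessian is symmetric, annihilates translations, and matches the oracle spectrum", {
  # a <=30-node bumpy ring tests generic geometry
  set.seed(1)
  theta <- seq(0, 2 * pi, length.out = 25L)[-25L]
  ring <- cg_structure(data.frame(
    chain = "A", resno = seq_len(24L), resname = "GLY",
    x = 6 * cos(theta), y = 6 * sin(theta), z = sin(3 * theta) + 0.1 * seq_len(24L)))
  net <- build_spring_network(ring, cutoff = 4)
  H <- build_hessian(net)
  expect_equal(max(abs(H - t(H))), 0)
  for (axis in 1:3) {
    tr <- rep(0, 72L)
    tr[seq(axis, 72L, by = 3L)] <- 1
    expect_equal(max(abs(H %*% tr)), 0)
  }
  H_oracle <- oracle_hessian(coords(ring), net$springs)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ev_o <- eigen(H_oracle, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev - ev_o)) / max(abs(ev_o)), 1e-8)
  expect_lt(max(abs(H - H_oracle)), 1e-12)
})

test_that("compute_modes flags rigid modes, fixes signs, and detects disconnection", {
  # dimer: exactly one non-rigid mode, antiparallel along the bond
  md <- compute_modes(build_hessian(build_spring_network(make_dimer(5))))
  expect_equal(length(md$values), 1L)
  expect_equal(md$rigid_count, 5L)
  v <- matrix(md$vectors[, 1], ncol = 3, byrow = TRUE)
  expect_equal(v[1, ], -v[2, ], tolerance = 1e-12)
  expect_equal(abs(v[1, 1]), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(abs(v[1, 2]) + abs(v[1, 3]), 0, tolerance = 1e-12)
  # sign convention: largest-magnitude component positive
  expect_gt(md$vectors[which.max(abs(md$vectors[, 1])), 1], 0)

  fix <- hex_fixture()
  expect_equal(fix$mu$rigid_count, 6L)
  expect_equal(length(fix$mu$values), 3L * n_atoms(fix$cg) - 6L)
  # orthonormality
  G <- crossprod(fix$mu$vectors[, 1:25])
  expect_lt(max(abs(G - diag(25))), 1e-8)
  # recomputation is bit-reproducible (deterministic sign convention)
  again <- compute_modes(build_hessian(fix$net))
  expect_identical(again$vectors, fix$mu$vectors)

  # two far-apart dimers: > 6 zero modes
  pieces <- cg_structure(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1:2, 1:2), resname = "GLY",
    x = c(0, 5, 100, 105), y = 0, z = 0))
  expect_error(compute_modes(build_hessian(build_spring_network(pieces))),
               class = "carbanm_disconnected_error")
})

test_that("bridge springs: one per interface, correct rest lengths, errors name the chain", {
  fix <- hex_fixture()
  br <- fix$netb$springs[fix$netb$springs$tag == "bridge", ]
  expect_equal(nrow(br), 6L)
  expect_equal(br$rest_length, rep(fix$spec$target_bridge_distance, 6L),
               tolerance = 1e-9)
  expect_equal(br$k, rep(1, 6L))

  trimer_spec <- oligomer_spec(n_subunits = 3L)
  tri <- make_cn_oligomer(trimer_spec)
  tnet <- add_bridge_springs(build_spring_network(tri), tri,
                             bridge_spec(donor_resno = trimer_spec$donor_index,
                                         acceptor_resno = trimer_spec$acceptor_index))
  expect_equal(sum(tnet$springs$tag == "bridge"), 3L)

  err <- tryCatch(add_bridge_springs(fix$net, fix$cg,
                                     bridge_spec(donor_resno = 9999L)),
                  carbanm_spec_error = function(e) conditionMessage(e))
  expect_match(err, "9999")
  expect_match(err, "chain A")
})

test_that("a bridge on an already-contacted pair is equivalent to incrementing its stiffness", {
  spec <- oligomer_spec(target_bridge_distance = 6.5)  # inside the 8 A cutoff
  cg <- make_cn_oligomer(spec)
  net <- build_spring_network(cg)
  bs <- bridge_spec(donor_resno = spec$donor_index,
                    acceptor_resno = spec$acceptor_index, bridge_k = 1.5)
  netb <- add_bridge_springs(net, cg, bs)
  # manual increment of the duplicate contact rows
  inc <- net
  br <- netb$springs[netb$springs$tag == "bridge", c("i", "j")]
  for (r in seq_len(nrow(br))) {
    hit <- inc$springs$i == br$i[r] & inc$springs$j == br$j[r]
    expect_true(any(hit))   # the contact spring exists at 6.5 < 8
    inc$springs$k[hit] <- inc$springs$k[hit] + 1.5
  }
  expect_lt(max(abs(build_hessian(netb) - build_hessian(inc))), 1e-12)
})

test_that("mode fractions follow inverse-eigenvalue weighting and sum to one", {
  V <- diag(6)[, 1:2]
  ms <- mode_set(c(1, 1), V, rigid_count = 4L)
  expect_equal(mode_fraction(ms), c(0.5, 0.5))
  ms2 <- mode_set(c(1, 4), V, rigid_count = 4L)
  expect_equal(mode_fraction(ms2), c(0.8, 0.2))
  expect_equal(mode_fraction(ms2, 2L), 0.2)
  expect_equal(mode_fraction(ms2, weighting = "inverse_frequency"),
               c(2 / 3, 1 / 3))
  expect_error(mode_fraction(ms2, 0L), class = "carbanm_domain_error")
  expect_error(mode_fraction(ms2, 3L), class = "carbanm_domain_error")

  fix <- hex_fixture()
  expect_equal(sum(mode_fraction(fix$mu)), 1, tolerance = 1e-12)
  expect_equal(sum(mode_fraction(fix$mb)), 1, tolerance = 1e-12)
})

test_that("spectra are PSD, interlace under added bridges, and show C6 degeneracy", {
  fix <- hex_fixture()
  expect_gt(min(fix$mu$values), 0)
  expect_gt(min(fix$mu$rigid_values), -1e-8 * max(fix$mu$values))
  # adding PSD rank-1 springs never lowers an eigenvalue
  expect_true(all(fix$mb$values >= fix$mu$values - 1e-10))
  # C6 symmetry: doubly degenerate pairs agree to 1e-8 relative; no triplets
  vals <- fix$mu$values[1:20]
  rel_gap <- diff(vals) / vals[-1]
  in_pair <- rel_gap < 1e-8
  expect_gte(sum(in_pair), 5L)
  expect_false(any(in_pair[-1] & in_pair[-length(in_pair)]))
})
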