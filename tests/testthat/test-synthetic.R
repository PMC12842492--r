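test_that("toy protein ensembles are deterministic and noise-controlled", {
  spec <- toy_small_spec(seed = 11, n_snapshots = 3)
  a <- make_toy_protein(spec)
  b <- make_toy_protein(spec)
  for (k in 1:3) {
    expect_identical(a$ensemble[[k]]$atoms, b$ensemble[[k]]$atoms)
  }
  # distinct seeds give distinct coordinates
  c <- make_toy_protein(toy_small_spec(seed = 12, n_snapshots = 3))
  expect_false(isTRUE(all.equal(a$ensemble[[2]]$atoms$x,
                                c$ensemble[[2]]$atoms$x)))
  # zero linker noise: every snapshot identical, profile flat at zero
  z <- make_toy_protein(toy_small_spec(seed = 11, n_snapshots = 3, sd = 0))
  expect_identical(z$ensemble[[1]]$atoms[, c("x", "y", "z")],
                   z$ensemble[[3]]$atoms[, c("x", "y", "z")])
  expect_true(all(rmsd_profile(z$ensemble)$rmsd < 1e-10))
  # snapshot labels mirror the 10-ns sampling grid
  expect_equal(vapply(a$ensemble, `[[`, numeric(1), "time_label_ns"),
               c(10, 20, 30))
})

test_that("linker moves while domain geometry stays rigid", {
  tp <- make_toy_protein(toy_small_spec(seed = 5, n_snapshots = 5, sd = 20))
  spec <- toy_small_spec()
  ca <- function(m, idx) {
    at <- m$atoms[m$atoms$name == "CA", ]
    as.matrix(at[at$resid %in% idx, c("x", "y", "z")])
  }
  linker_idx <- (spec$n_domain1 + 1):(spec$n_domain1 + spec$n_linker)
  d1_idx <- 1:spec$n_domain1
  d2_idx <- (spec$n_domain1 + spec$n_linker + 1):
    (spec$n_domain1 + spec$n_linker + spec$n_domain2)
  for (k in 2:5) {
    # linker-only RMSD after superposition is positive
    expect_gt(kabsch_rmsd(ca(tp$ensemble[[k]], linker_idx),
                          ca(tp$ensemble[[1]], linker_idx)), 0.1)
    # per-domain superposition shows rigid domains
    expect_lt(kabsch_rmsd(ca(tp$ensemble[[k]], d1_idx),
                          ca(tp$ensemble[[1]], d1_idx)), 1e-6)
    expect_lt(kabsch_rmsd(ca(tp$ensemble[[k]], d2_idx),
                          ca(tp$ensemble[[1]], d2_idx)), 1e-6)
  }
  # annotation marks the linker residues
  expect_setequal(tp$regions$resid[tp$regions$region == "linker"], linker_idx)
})

test_that("generated geometry passes bond-length and clash invariants", {
  tp <- make_toy_protein(toy_small_spec(seed = 3))
  m <- tp$ensemble[[1]]
  ca <- as.matrix(m$atoms[m$atoms$name == "CA", c("x", "y", "z")])
  d <- as.matrix(dist(ca))
  sep <- abs(outer(seq_len(nrow(ca)), seq_len(nrow(ca)), `-`))
  expect_gte(min(d[sep >= 2]), 3.0)
  # consecutive backbone N-CA / CA-C bond lengths at ideal values
  at <- m$atoms
  n_xyz <- as.matrix(at[at$name == "N", c("x", "y", "z")])
  ca_xyz <- as.matrix(at[at$name == "CA", c("x", "y", "z")])
  c_xyz <- as.matrix(at[at$name == "C", c("x", "y", "z")])
  expect_equal(sqrt(rowSums((n_xyz - ca_xyz)^2)),
               rep(1.458, nrow(n_xyz)), tolerance = 1e-6)
  expect_equal(sqrt(rowSums((ca_xyz - c_xyz)^2)),
               rep(1.525, nrow(ca_xyz)), tolerance = 1e-6)

  for (kind in c("pyranose_like", "rigid_diatomic")) {
    lig <- make_toy_ligand(kind, seed = 2)
    xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
    bonded <- cbind(lig$bonds$a, lig$bonds$b)
    blen <- sqrt(rowSums((xyz[bonded[, 1], , drop = FALSE] -
                            xyz[bonded[, 2], , drop = FALSE])^2))
    expect_true(all(blen > 1.2 & blen < 1.8))
    dmat <- as.matrix(dist(xyz))
    is_bonded <- matrix(FALSE, nrow(xyz), nrow(xyz))
    is_bonded[bonded] <- TRUE
    is_bonded <- is_bonded | t(is_bonded)
    nb <- dmat[!is_bonded & upper.tri(dmat)]
    if (length(nb) > 0) expect_gte(min(nb), 2.4)
  }
})

test_that("toy ligands match their stated topology", {
  probe <- make_toy_ligand("probe_single_atom")
  expect_equal(nrow(probe$atoms), 1)
  expect_equal(nrow(probe$bonds), 0)
  expect_equal(probe$n_rot, 0)
  expect_equal(probe$atoms$class, "hydrophobic")

  di <- make_toy_ligand("rigid_diatomic")
  expect_equal(di$n_rot, 0)

  pyr <- make_toy_ligand("pyranose_like", seed = 9)
  expect_gte(pyr$n_rot, 1)
  # ring bonds are never rotatable: no torsion axis lies on the 6-ring
  ring_pairs <- cbind(1:6, c(2:6, 1))
  for (t4 in pyr$rotatable_torsions) {
    expect_false(any(ring_pairs[, 1] == t4[2] & ring_pairs[, 2] == t4[3]) ||
                   any(ring_pairs[, 1] == t4[3] & ring_pairs[, 2] == t4[2]))
  }
  # at least 5 donors+acceptors from the generated topology
  expect_gte(sum(pyr$atoms$class %in%
                   c("donor", "acceptor", "donor_acceptor")), 5)
  expect_identical(make_toy_ligand("pyranose_like", seed = 9)$atoms,
                   pyr$atoms)
})

test_that("synthetic binding-energy tables recover their parameters", {
  # exact composition with no background
  t2 <- make_dg_table(dg_table_spec(
    n_background = 0,
    planted = list(list(region = "linker", delta_g = -6, round = 1,
                        model_id = "m1"),
                   list(region = "pocket", delta_g = -7, round = 2,
                        model_id = "m1"))))
  expect_equal(nrow(t2), 2)
  expect_equal(t2$delta_g, c(-6, -7))

  tab <- make_dg_table(dg_table_spec(background_mean = -4.5,
                                     background_sd = 0.25,
                                     n_background = 10000, seed = 123))
  expect_lt(abs(mean(tab$delta_g) - (-4.5)), 0.01)
  expect_lt(abs(sd(tab$delta_g) - 0.25), 0.01)
  expect_identical(tab, make_dg_table(dg_table_spec(
    background_mean = -4.5, background_sd = 0.25, n_background = 10000,
    seed = 123)))

  # planted outlier at mean - 5 sd is recovered by the significance flag
  spec <- dg_table_spec(n_background = 100, seed = 4, planted = list(
    list(region = "linker", delta_g = -4.5 - 5 * 0.25, round = 1,
         model_id = "mX")))
  tab <- make_dg_table(spec)
  bg <- compute_background(
    dplyr::rename(tab, category = region) |>
      dplyr::mutate(category = ifelse(category == "other", "nonspecific",
                                      category)))
  expect_true(flag_significant(-4.5 - 5 * 0.25, bg))
})

test_that("hydrogen-bond fixtures are exact ground truth", {
  fx0 <- make_hbond_fixture(0)
  expect_equal(length(fx0$complex$ligand_poses), 0)
  expect_equal(nrow(fx0$expected), 0)

  fx <- make_hbond_fixture(3, seed = 2)
  expect_equal(nrow(fx$expected), 3)
  expect_identical(make_hbond_fixture(3, seed = 2)$expected, fx$expected)
  # planted donor-acceptor separation is exactly 2.9 A
  at <- linkerdock:::complex_atoms(fx$complex)
  for (i in 1:3) {
    d_o <- at[at$unit == paste0("probe", i) & at$name == "O1", ]
    a_o <- at[at$unit == "protein" & at$resid == i & at$name == "O", ]
    expect_equal(as.numeric(sqrt((d_o$x - a_o$x)^2 + (d_o$y - a_o$y)^2 +
                                   (d_o$z - a_o$z)^2)), 2.9,
                 tolerance = 1e-9)
  }
})
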