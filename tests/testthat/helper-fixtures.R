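# In-code fixtures and independent oracles shared across test files.

# ---- small molecule SDF texts (V2000) ---------------------------------------

sdf_text <- function(title, atoms, bonds) {
  # atoms: data.frame(x, y, z, el); bonds: data.frame(a, b, order)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(atoms), nrow(bonds))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$x, atoms$y, atoms$z, atoms$el)
  bond_lines <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a, bonds$b, bonds$order)
  } else character(0)
  paste(c(title, "  test", "", counts, atom_lines, bond_lines, "M  END", "$$$$"),
        collapse = "\n")
}

write_sdf_fixture <- function(name) {
  mol <- switch(
    name,
    ethane = list(
      atoms = data.frame(x = c(0, 1.54), y = 0, z = 0, el = "C"),
      bonds = data.frame(a = 1, b = 2, order = 1)),
    nbutane = list(
      atoms = data.frame(x = c(0, 1.54, 2.3, 3.84), y = c(0, 0, 1.3, 1.3),
                         z = 0, el = "C"),
      bonds = data.frame(a = 1:3, b = 2:4, order = 1)),
    cyclohexane = list(
      atoms = data.frame(x = 1.54 * cos(seq(0, 5) * pi / 3),
                         y = 1.54 * sin(seq(0, 5) * pi / 3),
                         z = 0, el = "C"),
      bonds = data.frame(a = 1:6, b = c(2:6, 1), order = 1)),
    stop("unknown fixture ", name))
  path <- withr::local_tempfile(fileext = ".sdf",
                                .local_envir = parent.frame())
  writeLines(sdf_text(name, mol$atoms, mol$bonds), path)
  path
}

# 3-residue, two-chain PDB text used in IO tests
pdb_fixture_text <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.729   6.768  -4.123  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.580   7.103  -4.423  1.00  0.00           O",
    "ATOM      5  N   SER A   2      11.241   7.014  -2.910  1.00  0.00           N",
    "ATOM      6  CA  SER A   2      10.431   7.662  -1.867  1.00  0.00           C",
    "ATOM      7  C   SER A   2      10.967   7.351  -0.461  1.00  0.00           C",
    "ATOM      8  O   SER A   2      12.161   7.079  -0.290  1.00  0.00           O",
    "ATOM      9  OG  SER A   2      10.455   9.059  -2.110  1.00  0.00           O",
    "TER",
    "ATOM     10  N   GLY B   5       5.000   1.000   2.000  1.00  0.00           N",
    "ATOM     11  CA  GLY B   5       6.458   1.123   2.155  1.00  0.00           C",
    "ATOM     12  C   GLY B   5       7.000   2.500   2.300  1.00  0.00           C",
    "ATOM     13  O   GLY B   5       6.300   3.500   2.200  1.00  0.00           O",
    "END")
}

# ---- independent scoring oracle ---------------------------------------------

# plain double loop over atom pairs, written from the term definitions and
# sharing no code with the package internals
oracle_score <- function(receptor, lig_atoms, n_rot, w = NULL) {
  if (is.null(w)) {
    w <- list(g1 = -0.035579, g2 = -0.005156, rep = 0.840245,
              hyd = -0.035069, hb = -0.587439, rot = 0.05846, cutoff = 8)
  }
  radius <- function(el) {
    switch(el, C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, 1.8)
  }
  is_don <- function(cl) cl %in% c("donor", "donor_acceptor")
  is_acc <- function(cl) cl %in% c("acceptor", "donor_acceptor")
  total <- 0
  for (i in seq_len(nrow(receptor))) {
    for (j in seq_len(nrow(lig_atoms))) {
      d <- sqrt((receptor$x[i] - lig_atoms$x[j])^2 +
                  (receptor$y[i] - lig_atoms$y[j])^2 +
                  (receptor$z[i] - lig_atoms$z[j])^2)
      s <- d - radius(receptor$element[i]) - radius(lig_atoms$element[j])
      if (s > w$cutoff) next
      v <- w$g1 * exp(-(s / 0.5)^2) + w$g2 * exp(-((s - 3) / 2)^2)
      if (s < 0) v <- v + w$rep * s^2
      if (receptor$class[i] == "hydrophobic" &&
          lig_atoms$class[j] == "hydrophobic") {
        ramp <- if (s < 0.5) 1 else if (s > 1.5) 0 else 1.5 - s
        v <- v + w$hyd * ramp
      }
      if ((is_don(receptor$class[i]) && is_acc(lig_atoms$class[j])) ||
          (is_acc(receptor$class[i]) && is_don(lig_atoms$class[j]))) {
        ramp <- if (s < -0.7) 1 else if (s > 0) 0 else -s / 0.7
        v <- v + w$hb * ramp
      }
      total <- total + v
    }
  }
  total / (1 + w$rot * n_rot)
}

random_atom_tibble <- function(n, spread = 4) {
  tibble::tibble(
    serial = seq_len(n), name = paste0("X", seq_len(n)),
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    x = stats::rnorm(n, 0, spread), y = stats::rnorm(n, 0, spread),
    z = stats::rnorm(n, 0, spread),
    class = sample(c("hydrophobic", "donor", "acceptor", "donor_acceptor",
                     "polar_other"), n, replace = TRUE))
}

random_rigid_ligand <- function(n, spread = 1.5) {
  at <- random_atom_tibble(n, spread)
  structure(
    list(ligand_id = "rand", species = "rand", atoms = at,
         bonds = tibble::tibble(a = integer(0), b = integer(0),
                                order = integer(0)),
         rotatable_torsions = list(), n_rot = 0L),
    class = "ligand")
}

# ---- independent affine-gap alignment oracle --------------------------------

# exhaustive enumeration of all global alignments; gap run of length L costs
# open + (L - 1) * extend
oracle_nw_score <- function(a, b, mat, open, extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, mat[A[i], B[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(A)) {
      cost <- if (prev == "x") extend else open
      best <- max(best, -cost + rec(i + 1, j, "x"))
    }
    if (j <= length(B)) {
      cost <- if (prev == "y") extend else open
      best <- max(best, -cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# ---- misc -------------------------------------------------------------------

pose_distance_to_origin <- function(pose) {
  sqrt(sum(colMeans(as.matrix(pose$atoms[, c("x", "y", "z")]))^2))
}

toy_small_spec <- function(seed = 1, n_snapshots = 1, sd = 15) {
  toy_protein_spec(n_domain1 = 12, n_linker = 8, n_domain2 = 14,
                   n_snapshots = n_snapshots, linker_dihedral_sd = sd,
                   seed = seed)
}

quick_docking <- function(seed = 1, n_runs = 2, n_steps = 50) {
  docking_config(n_runs = n_runs, n_steps = n_steps, seed = seed)
}
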