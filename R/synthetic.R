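# Synthetic generators: toy conformer ensembles of a two-domain protein with
# a flexible linker, sugar-like ligands, hydrogen-bond geometry fixtures and
# binding-energy tables with planted structure. Desk-scale stand-ins for MD
# snapshots and PubChem ligands; deterministic under their seeds.

# ---- internal-coordinate chain building (NeRF) ------------------------------

# place atom D bonded to C, given A-B-C, bond length r, angle theta (B-C-D,
# degrees) and dihedral phi (A-B-C-D, degrees)
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone internal coordinates (A, degrees)
BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
  cb_og = 1.417,
  ang_ca_c_n = 116.2, ang_c_n_ca = 121.7, ang_n_ca_c = 111.2,
  ang_ca_c_o = 120.5, ang_c_ca_cb = 110.5, ang_ca_cb_og = 110.8,
  omega = 180
)

HELIX_PHI <- -57; HELIX_PSI <- -47
COIL_PHI <- -120; COIL_PSI <- 130

# Build one chain from per-residue (phi, psi, resname); returns atom tibble.
build_backbone <- function(phi, psi, resname, chain = "A") {
  n_res <- length(phi)
  rows <- vector("list", n_res)
  # bootstrap residue 1 in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(BB$n_ca, 0, 0)
  ang <- deg2rad(180 - BB$ang_n_ca_c)
  C <- CA + BB$ca_c * c(cos(ang), sin(ang), 0)
  prevN <- NULL; prevCA <- NULL; prevC <- NULL
  serial <- 0L
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N <- nerf_place(prevN, prevCA, prevC, BB$c_n, BB$ang_ca_c_n, psi[i - 1])
      CA <- nerf_place(prevCA, prevC, N, BB$n_ca, BB$ang_c_n_ca, BB$omega)
      C <- nerf_place(prevC, N, CA, BB$ca_c, BB$ang_n_ca_c, phi[i])
    }
    O <- nerf_place(N, CA, C, BB$c_o, BB$ang_ca_c_o, psi[i] - 180)
    at <- list(
      list(name = "N", element = "N", xyz = N),
      list(name = "CA", element = "C", xyz = CA),
      list(name = "C", element = "C", xyz = C),
      list(name = "O", element = "O", xyz = O)
    )
    if (resname[i] != "GLY") {
      CB <- nerf_place(N, C, CA, BB$ca_cb, BB$ang_c_ca_cb, 122.55)
      at <- c(at, list(list(name = "CB", element = "C", xyz = CB)))
      if (resname[i] == "SER") {
        OG <- nerf_place(N, CA, CB, BB$cb_og, BB$ang_ca_cb_og, 60)
        at <- c(at, list(list(name = "OG", element = "O", xyz = OG)))
      }
    }
    rows[[i]] <- tibble(
      serial = serial + seq_along(at),
      name = vapply(at, `[[`, character(1), "name"),
      element = vapply(at, `[[`, character(1), "element"),
      x = vapply(at, function(a) a$xyz[1], numeric(1)),
      y = vapply(at, function(a) a$xyz[2], numeric(1)),
      z = vapply(at, function(a) a$xyz[3], numeric(1)),
      chain = chain, resid = i, icode = "", resname = resname[i],
      class = NA_character_
    )
    serial <- serial + length(at)
    prevN <- N; prevCA <- CA; prevC <- C
  }
  dplyr::bind_rows(rows)
}

#' Specification of a synthetic two-domain linker protein ensemble
#'
#' @param n_domain1,n_linker,n_domain2 Residue counts of the first helical
#'   domain, the flexible linker and the second helical domain.
#' @param n_snapshots Number of conformers (snapshot labels 10, 20, ... ns,
#'   mirroring a 10-ns MD sampling grid).
#' @param linker_dihedral_sd SD (degrees) of the normal perturbation applied
#'   to linker backbone dihedrals per snapshot; 0 gives identical snapshots.
#' @param seed RNG seed; the same seed reproduces the ensemble bitwise.
#' @return A `toy_protein_spec` list.
#' @export
toy_protein_spec <- function(n_domain1 = 30, n_linker = 20, n_domain2 = 40,
                             n_snapshots = 5, linker_dihedral_sd = 15,
                             seed = 1) {
  stopifnot(n_domain1 >= 1, n_linker >= 1, n_domain2 >= 1, n_snapshots >= 1)
  structure(
    list(n_domain1 = n_domain1, n_linker = n_linker, n_domain2 = n_domain2,
         n_snapshots = n_snapshots, linker_dihedral_sd = linker_dihedral_sd,
         seed = seed),
    class = "toy_protein_spec"
  )
}

#' Generate a toy conformer ensemble of a two-domain linker protein
#'
#' Each snapshot has two ideal alpha-helical domains (phi = -57, psi = -47)
#' joined by a coil linker whose backbone dihedrals are resampled per
#' snapshot from a normal law around extended-coil values (phi = -120,
#' psi = 130). Linker residues are serine (hydroxyl donors for H-bond
#' geometry); domain residues are alanine. Snapshots failing the CA-CA
#' clash check (< 3.0 A for non-bonded pairs) are resampled. The returned
#' annotation marks the linker residues as region "linker" and a small
#' domain-2 patch as region "pocket" so all binding-site categories can be
#' exercised.
#'
#' @param spec A [toy_protein_spec()].
#' @return A list with `ensemble` (list of `protein_model`, interaction
#'   classes assigned) and `regions` (annotation tibble).
#' @export
make_toy_protein <- function(spec = toy_protein_spec()) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  n1 <- spec$n_domain1; nl <- spec$n_linker; n2 <- spec$n_domain2
  n_res <- n1 + nl + n2
  resname <- c(rep("ALA", n1), rep("SER", nl), rep("ALA", n2))
  linker_idx <- (n1 + 1):(n1 + nl)
  base_phi <- c(rep(HELIX_PHI, n1), rep(COIL_PHI, nl), rep(HELIX_PHI, n2))
  base_psi <- c(rep(HELIX_PSI, n1), rep(COIL_PSI, nl), rep(HELIX_PSI, n2))
  build_snapshot <- function(k) {
    for (attempt in seq_len(1000)) {
      phi <- base_phi; psi <- base_psi
      if (spec$linker_dihedral_sd > 0) {
        phi[linker_idx] <- phi[linker_idx] +
          rnorm(nl, 0, spec$linker_dihedral_sd)
        psi[linker_idx] <- psi[linker_idx] +
          rnorm(nl, 0, spec$linker_dihedral_sd)
      }
      atoms <- build_backbone(phi, psi, resname)
      ca <- as.matrix(atoms[atoms$name == "CA", c("x", "y", "z")])
      d <- as.matrix(stats::dist(ca))
      sep <- abs(outer(seq_len(n_res), seq_len(n_res), `-`))
      if (min(d[sep >= 2]) >= 3.0) {
        return(new_protein_model(atoms, model_id = sprintf("toy_%02d", k),
                                 time_label_ns = 10 * k))
      }
      if (spec$linker_dihedral_sd == 0) {
        stop("toy protein clashes with zero linker noise; ",
             "adjust domain sizes")
      }
    }
    stop("clash-free linker resampling failed after 1000 attempts; ",
         "try a smaller linker_dihedral_sd")
  }
  ensemble <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_snapshots), build_snapshot)
  })
  ensemble <- lapply(ensemble, assign_interaction_classes)
  pocket_mid <- n1 + nl + max(1, floor(n2 / 2) - 3)
  pocket_hi <- min(n_res, pocket_mid + 7)
  regions <- regions_from_spans(list(
    linker = sprintf("A:%d-%d", n1 + 1, n1 + nl),
    pocket = sprintf("A:%d-%d", pocket_mid, pocket_hi)
  ))
  list(ensemble = ensemble, regions = regions)
}

# ---- toy ligands ------------------------------------------------------------

#' Generate a toy ligand
#'
#' Three kinds: `probe_single_atom` (one hydrophobic carbon, no bonds),
#' `rigid_diatomic` (an ethane-like C-C pair, no rotatable bonds) and
#' `pyranose_like` (a 6-membered ring of 5 C + 1 O carrying four hydroxyl
#' oxygens and one exocyclic CH2OH arm, giving at least one rotatable bond
#' and at least five H-bond donors/acceptors — a sugar stand-in).
#'
#' @param kind Ligand kind.
#' @param seed Seed for the small deterministic coordinate jitter applied to
#'   the pyranose ring (distinct seeds give distinct conformers).
#' @return A `ligand` with interaction classes assigned.
#' @export
make_toy_ligand <- function(kind = c("pyranose_like", "probe_single_atom",
                                     "rigid_diatomic"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "probe_single_atom") {
    atoms <- tibble(serial = 1L, name = "C1", element = "C",
                    x = 0, y = 0, z = 0, class = NA_character_)
    bonds <- tibble(a = integer(0), b = integer(0), order = integer(0))
    lig <- new_ligand("probe", "probe_single_atom", atoms, bonds)
    return(assign_interaction_classes(lig))
  }
  if (kind == "rigid_diatomic") {
    atoms <- tibble(serial = 1:2, name = c("C1", "C2"), element = "C",
                    x = c(0, 1.53), y = 0, z = 0, class = NA_character_)
    bonds <- tibble(a = 1L, b = 2L, order = 1L)
    lig <- new_ligand("diatomic", "rigid_diatomic", atoms, bonds)
    return(assign_interaction_classes(lig))
  }
  # pyranose_like: regular hexagon ring (side 1.5 A) in the xy-plane;
  # substituents lean 30 degrees out of plane with alternating sign
  ring_angle <- seq(0, by = 60, length.out = 6)
  rx <- 1.5 * cos(deg2rad(ring_angle))
  ry <- 1.5 * sin(deg2rad(ring_angle))
  names_ring <- c("C1", "C2", "C3", "C4", "C5", "O5")
  el_ring <- c(rep("C", 5), "O")
  atoms <- tibble(serial = 1:6, name = names_ring, element = el_ring,
                  x = rx, y = ry, z = 0, class = NA_character_)
  bonds <- tibble(a = 1:6, b = c(2:6, 1L), order = 1L)
  add_atom <- function(atoms, name, element, xyz) {
    dplyr::bind_rows(atoms, tibble(
      serial = nrow(atoms) + 1L, name = name, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], class = NA_character_))
  }
  lean <- function(i, len, sign_z) {
    u <- c(rx[i], ry[i], 0) / 1.5
    c(rx[i], ry[i], 0) + len * (cos(deg2rad(30)) * u +
                                  sin(deg2rad(30)) * c(0, 0, sign_z))
  }
  # hydroxyls on C1..C4
  for (i in 1:4) {
    atoms <- add_atom(atoms, paste0("O", i), "O", lean(i, 1.43, (-1)^i))
    bonds <- dplyr::bind_rows(bonds,
                              tibble(a = i, b = nrow(atoms), order = 1L))
  }
  # exocyclic CH2OH arm on C5
  c6 <- lean(5, 1.52, -1)
  atoms <- add_atom(atoms, "C6", "C", c6)
  bonds <- dplyr::bind_rows(bonds, tibble(a = 5L, b = nrow(atoms), order = 1L))
  u5 <- c(rx[5], ry[5], 0) / 1.5
  o6 <- c6 + 1.43 * (cos(deg2rad(60)) * u5 + sin(deg2rad(60)) * c(0, 0, -1))
  atoms <- add_atom(atoms, "O6", "O", o6)
  bonds <- dplyr::bind_rows(bonds,
                            tibble(a = nrow(atoms) - 1L, b = nrow(atoms),
                                   order = 1L))
  jit <- withr::with_seed(seed, matrix(rnorm(nrow(atoms) * 3, 0, 0.02),
                                       ncol = 3))
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  lig <- new_ligand("pyranose", "pyranose_like", atoms, bonds)
  assign_interaction_classes(lig)
}

# ---- synthetic binding-energy tables ----------------------------------------

#' Specification of a synthetic binding-energy table
#'
#' @param background_mean,background_sd Normal law (kcal/mol) for the
#'   nonspecific background records. Defaults -4.5 and 0.25 kcal/mol sit in
#'   the regime typical of nonspecific carbohydrate surface binding.
#' @param n_background Number of background records.
#' @param planted List of planted records, each a list with fields `region`,
#'   `delta_g`, `round`, `model_id` — inserted verbatim.
#' @param seed RNG seed.
#' @return A `dg_table_spec` list.
#' @export
dg_table_spec <- function(background_mean = -4.5, background_sd = 0.25,
                          n_background = 100, planted = list(), seed = 1) {
  stopifnot(background_sd > 0, n_background >= 0)
  structure(
    list(background_mean = background_mean, background_sd = background_sd,
         n_background = n_background, planted = planted, seed = seed),
    class = "dg_table_spec"
  )
}

#' Generate a synthetic binding-energy table with planted binders
#'
#' Background records are drawn from Normal(background_mean, background_sd)
#' and labelled region "other" (nonspecific surface binding); planted
#' records are inserted verbatim. Reproducible under the seed.
#'
#' @param spec A [dg_table_spec()].
#' @return A tibble with columns `model_id`, `round`, `delta_g`, `region`.
#' @export
make_dg_table <- function(spec = dg_table_spec()) {
  stopifnot(inherits(spec, "dg_table_spec"))
  bg <- if (spec$n_background > 0) {
    dg <- withr::with_seed(spec$seed, {
      rnorm(spec$n_background, spec$background_mean, spec$background_sd)
    })
    tibble(
      model_id = sprintf("bg%05d", seq_len(spec$n_background)),
      round = 1L, delta_g = dg, region = "other"
    )
  } else {
    tibble(model_id = character(0), round = integer(0),
           delta_g = numeric(0), region = character(0))
  }
  pl <- purrr::map(spec$planted, function(p) {
    tibble(model_id = as.character(p$model_id), round = as.integer(p$round),
           delta_g = as.numeric(p$delta_g), region = as.character(p$region))
  }) |> dplyr::bind_rows()
  dplyr::bind_rows(bg, pl)
}

# ---- hydrogen-bond ground-truth fixture -------------------------------------

#' Construct a complex with a known set of hydrogen bonds
#'
#' Builds a synthetic protein of well-separated glycine sites (20 A apart)
#' and places one hydroxyl-probe ligand per requested bond with its hydroxyl
#' oxygen exactly 2.9 A from a backbone carbonyl oxygen; all other polar
#' pairs are at least 5 A apart. The construction is the ground truth for
#' the H-bond detector.
#'
#' @param n_bonds Number of hydrogen bonds to plant (>= 0).
#' @param seed Seed (placement order is deterministic; kept for interface
#'   symmetry with the other generators).
#' @return A list with `complex` (a `docked_complex`) and `expected` (tibble
#'   of planted bonds: ligand_id, donor_name, acceptor_resid, distance).
#' @export
make_hbond_fixture <- function(n_bonds, seed = 1) {
  stopifnot(n_bonds >= 0)
  n_sites <- max(n_bonds, 1)
  rows <- vector("list", n_sites)
  serial <- 0L
  for (i in seq_len(n_sites)) {
    x0 <- 20 * (i - 1)
    xyz <- rbind(
      N = c(x0 - 1.46, 0, 0),
      CA = c(x0, 0, 0),
      C = c(x0 + 1.52, 0, 0),
      O = c(x0 + 1.52, 1.23, 0)
    )
    rows[[i]] <- tibble(
      serial = serial + 1:4,
      name = rownames(xyz), element = c("N", "C", "C", "O"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      chain = "A", resid = i, icode = "", resname = "GLY",
      class = NA_character_
    )
    serial <- serial + 4L
  }
  protein <- new_protein_model(dplyr::bind_rows(rows),
                               model_id = "hbond_fixture")
  protein <- assign_interaction_classes(protein)
  poses <- list()
  expected <- tibble(ligand_id = character(0), donor_name = character(0),
                     acceptor_resid = integer(0), distance = numeric(0))
  for (i in seq_len(n_bonds)) {
    x0 <- 20 * (i - 1)
    o_prot <- c(x0 + 1.52, 1.23, 0)
    o_lig <- o_prot + c(0, 2.9, 0)
    c_lig <- o_lig + c(0, 1.43, 0)
    atoms <- tibble(
      serial = 1:2, name = c("O1", "C1"), element = c("O", "C"),
      x = c(o_lig[1], c_lig[1]), y = c(o_lig[2], c_lig[2]),
      z = c(o_lig[3], c_lig[3]), class = NA_character_
    )
    bonds <- tibble(a = 1L, b = 2L, order = 1L)
    lig <- assign_interaction_classes(
      new_ligand(paste0("probe", i), "hydroxyl_probe", atoms, bonds))
    poses[[i]] <- list(ligand_id = lig$ligand_id, species = lig$species,
                       atoms = lig$atoms, n_rot = lig$n_rot)
    expected <- dplyr::bind_rows(expected, tibble(
      ligand_id = lig$ligand_id, donor_name = "O1",
      acceptor_resid = i, distance = 2.9))
  }
  cx <- structure(list(protein = protein, ligand_poses = poses),
                  class = "docked_complex")
  list(complex = cx, expected = expected)
}
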