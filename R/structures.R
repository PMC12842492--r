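#' @import tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number distinct pull across all_of first
#' @importFrom rlang .data
NULL

# Elements with fixed van der Waals radii (A). Others fall back to 1.8.
VDW_RADII <- c(
  C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, H = 1.2,
  F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2,
  Na = 1.2, Mg = 1.2, K = 1.35, Ca = 1.35, Zn = 1.2, Fe = 1.2, Mn = 1.2
)
METAL_ELEMENTS <- c("Na", "Mg", "K", "Ca", "Zn", "Fe", "Mn")
KNOWN_ELEMENTS <- names(VDW_RADII)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.8
  unname(r)
}

INTERACTION_CLASSES <- c("hydrophobic", "donor", "acceptor", "donor_acceptor",
                         "polar_other", "metal", "none")

# ---- protein model ----------------------------------------------------------

new_protein_model <- function(atoms, model_id = "model", time_label_ns = 0) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0) stop("protein model has no atoms")
  structure(
    list(model_id = model_id, time_label_ns = time_label_ns,
         atoms = as_tibble(atoms)),
    class = "protein_model"
  )
}

#' @export
print.protein_model <- function(x, ...) {
  res <- dplyr::distinct(x$atoms, .data$chain, .data$resid, .data$icode)
  cat("<protein_model> ", x$model_id,
      " (t = ", x$time_label_ns, " ns): ",
      nrow(x$atoms), " atoms, ", nrow(res), " residues, chains ",
      paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read a protein conformer from a PDB file
#'
#' Parses ATOM and HETATM records into an atom tibble. Water molecules
#' (HOH/WAT/H2O) are dropped; metal ions are kept and later classed as
#' `metal`. Residue identity is (chain, author seq number, insertion code),
#' preserving 1-based author numbering. Coordinates are in Angstroms.
#'
#' @param path Path to a PDB file.
#' @param model For multi-MODEL files, which model to return (default 1).
#' @param model_id Identifier stored on the returned object; defaults to the
#'   file name without extension.
#' @param time_label_ns Snapshot time label in nanoseconds (default 0).
#' @return A `protein_model`: a list with `model_id`, `time_label_ns` and an
#'   `atoms` tibble (serial, name, element, x, y, z, chain, resid, icode,
#'   resname, class).
#' @export
read_pdb <- function(path, model = 1, model_id = NULL, time_label_ns = 0) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) >= 1) {
    if (model > length(model_starts)) {
      stop("requested MODEL ", model, " but file has ", length(model_starts))
    }
    start <- model_starts[model]
    ends <- grep("^ENDMDL", lines)
    end <- ends[ends > start][1]
    if (is.na(end)) end <- length(lines)
    lines <- lines[start:end]
  }
  keep <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no ATOM/HETATM records in ", path)
  recs <- lines[idx]
  bad <- which(nchar(recs) < 54)
  if (length(bad) > 0) {
    stop("malformed ATOM/HETATM record at line ", idx[bad[1]],
         " of ", path, " (record shorter than coordinate fields)")
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- tibble(
    serial  = as.integer(num(substr(recs, 7, 11))),
    name    = trimws(substr(recs, 13, 16)),
    resname = trimws(substr(recs, 18, 20)),
    chain   = trimws(substr(recs, 22, 22)),
    resid   = as.integer(num(substr(recs, 23, 26))),
    icode   = trimws(substr(recs, 27, 27)),
    x       = num(substr(recs, 31, 38)),
    y       = num(substr(recs, 39, 46)),
    z       = num(substr(recs, 47, 54)),
    element = trimws(substr(recs, 77, 78))
  )
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad) > 0) {
    stop("malformed coordinates at line ", idx[bad[1]], " of ", path)
  }
  # infer element from the atom name where columns 77-78 are blank
  blank <- atoms$element == ""
  if (any(blank)) {
    guess <- sub("^[0-9]*", "", atoms$name[blank])
    two <- substr(guess, 1, 2)
    two <- paste0(substr(two, 1, 1), tolower(substr(two, 2, 2)))
    atoms$element[blank] <- ifelse(two %in% KNOWN_ELEMENTS, two,
                                   substr(guess, 1, 1))
  }
  atoms <- dplyr::filter(atoms, !(.data$resname %in% c("HOH", "WAT", "H2O")))
  if (nrow(atoms) == 0) stop("empty model after removing waters: ", path)
  atoms$class <- NA_character_
  if (is.null(model_id)) model_id <- tools::file_path_sans_ext(basename(path))
  new_protein_model(atoms, model_id = model_id, time_label_ns = time_label_ns)
}

#' Write a protein conformer (optionally with placed ligands) to PDB
#'
#' Protein atoms are written as ATOM records; ligand copies from a docked
#' complex are written as HETATM with one chain id per copy and a
#' configurable residue name.
#'
#' @param model A `protein_model` or `docked_complex`.
#' @param path Output file path.
#' @param ligand_resname 3-letter residue name used for ligand HETATM records
#'   (default "LIG"; e.g. "GLC" for glucose-like ligands).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path, ligand_resname = "LIG") {
  fmt_atom <- function(rec, a, serial, chain, resid, resname) {
    name <- a$name
    # PDB alignment: 1-3 letter names start in column 14
    name_f <- if (nchar(name) >= 4) substr(name, 1, 4) else paste0(" ", name)
    sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial %% 100000, name_f, resname, chain, resid %% 10000,
            ifelse(is.na(a$icode) || a$icode == "", " ", a$icode),
            a$x, a$y, a$z, 1.0, 0.0, a$element)
  }
  lines <- character(0)
  serial <- 0L
  if (inherits(model, "docked_complex")) {
    prot <- model$protein
  } else {
    prot <- model
  }
  at <- prot$atoms
  for (i in seq_len(nrow(at))) {
    serial <- serial + 1L
    a <- as.list(at[i, ])
    lines <- c(lines, fmt_atom("ATOM", a, serial, a$chain, a$resid, a$resname))
  }
  lines <- c(lines, "TER")
  if (inherits(model, "docked_complex")) {
    lig_chains <- c(letters, LETTERS, 0:9)
    for (k in seq_along(model$ligand_poses)) {
      lp <- model$ligand_poses[[k]]
      ch <- lig_chains[((k - 1) %% length(lig_chains)) + 1]
      la <- lp$atoms
      for (i in seq_len(nrow(la))) {
        serial <- serial + 1L
        a <- list(name = la$name[i], icode = "", x = la$x[i], y = la$y[i],
                  z = la$z[i], element = la$element[i])
        lines <- c(lines, fmt_atom("HETATM", a, serial, ch, k, ligand_resname))
      }
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# ---- ligands ----------------------------------------------------------------

new_ligand <- function(ligand_id, species, atoms, bonds) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  unknown <- setdiff(unique(atoms$element), KNOWN_ELEMENTS)
  if (length(unknown) > 0) {
    stop("unknown element(s) in ligand: ", paste(unknown, collapse = ", "))
  }
  if (nrow(atoms) > 1) {
    comp <- bond_components(nrow(atoms), bonds)
    if (length(unique(comp)) > 1) {
      stop("ligand bond graph is disconnected (", length(unique(comp)),
           " components)")
    }
  }
  tor <- detect_rotatable_torsions(atoms, bonds)
  lig <- structure(
    list(ligand_id = ligand_id, species = species, atoms = atoms,
         bonds = bonds, rotatable_torsions = tor, n_rot = length(tor)),
    class = "ligand"
  )
  lig
}

#' @export
print.ligand <- function(x, ...) {
  cat("<ligand> ", x$ligand_id, " (", x$species, "): ",
      nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, n_rot = ",
      x$n_rot, "\n", sep = "")
  invisible(x)
}

# connected components of the bond graph by union-find
bond_components <- function(n_atoms, bonds) {
  parent <- seq_len(n_atoms)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(bonds))) {
    ra <- find(bonds$a[k]); rb <- find(bonds$b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n_atoms), find, integer(1))
}

# a bond is in a ring iff removing it leaves its endpoints connected
bond_in_ring <- function(bonds, k) {
  sub <- bonds[-k, , drop = FALSE]
  a <- bonds$a[k]; b <- bonds$b[k]
  n <- max(bonds$a, bonds$b)
  comp <- bond_components(n, sub)
  comp[a] == comp[b]
}

# Rotatable bonds: acyclic single bonds between heavy atoms, each endpoint
# bearing at least one further heavy-atom neighbour. Returns a list of
# 4-atom-id torsion tuples (neighbour, a, b, neighbour).
detect_rotatable_torsions <- function(atoms, bonds) {
  if (nrow(bonds) == 0) return(list())
  heavy <- atoms$element != "H"
  adj <- lapply(seq_len(nrow(atoms)), function(i) {
    nb <- c(bonds$b[bonds$a == i], bonds$a[bonds$b == i])
    nb[heavy[nb]]
  })
  tor <- list()
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    if (bonds$order[k] != 1) next
    if (!heavy[a] || !heavy[b]) next
    na <- setdiff(adj[[a]], b)
    nb <- setdiff(adj[[b]], a)
    if (length(na) == 0 || length(nb) == 0) next
    if (bond_in_ring(bonds, k)) next
    tor[[length(tor) + 1]] <- c(min(na), a, b, min(nb))
  }
  tor
}

#' Read a small-molecule ligand from SDF (V2000) or MOL2
#'
#' Populates atoms, bonds and rotatable torsions. Rotatable bonds are
#' acyclic single bonds between heavy atoms where each endpoint carries at
#' least one further heavy-atom neighbour (so terminal methyls and hydroxyl
#' O-H bonds do not count, and ring bonds never rotate).
#'
#' @param path Path to the ligand file.
#' @param format "sdf" or "mol2"; guessed from the file extension if missing.
#' @param species Species label (e.g. "D-glucose"); defaults to the molecule
#'   title in the file, or the file name.
#' @return A `ligand` object with `atoms`, `bonds`, `rotatable_torsions` and
#'   `n_rot`.
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2"),
                        species = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mol2", "ml2")) "mol2" else "sdf"
  }
  if (!file.exists(path)) stop("ligand file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "sdf") parse_sdf(lines, path, species)
  else parse_mol2(lines, path, species)
}

parse_sdf <- function(lines, path, species) {
  if (length(lines) < 4) stop("truncated SDF file: ", path)
  title <- trimws(lines[1])
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds)) {
    stop("malformed SDF counts line in ", path)
  }
  atom_lines <- lines[5:(4 + n_atoms)]
  atoms <- tibble(
    serial = seq_len(n_atoms),
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    element = trimws(substr(atom_lines, 32, 34))
  )
  atoms$name <- paste0(atoms$element, atoms$serial)
  atoms$class <- NA_character_
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- tibble(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- tibble(a = integer(0), b = integer(0), order = integer(0))
  }
  if (is.null(species)) {
    species <- if (nzchar(title)) title else
      tools::file_path_sans_ext(basename(path))
  }
  new_ligand(species, species, atoms, bonds)
}

parse_mol2 <- function(lines, path, species) {
  sec <- function(tag) {
    i <- grep(paste0("^@<TRIPOS>", tag, "$"), lines)
    if (length(i) == 0) return(character(0))
    j <- grep("^@<TRIPOS>", lines)
    j <- j[j > i[1]]
    end <- if (length(j) > 0) j[1] - 1 else length(lines)
    out <- lines[(i[1] + 1):end]
    out[nzchar(trimws(out))]
  }
  atom_lines <- sec("ATOM")
  bond_lines <- sec("BOND")
  if (length(atom_lines) == 0) stop("no ATOM section in MOL2 file: ", path)
  parse_row <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  arows <- lapply(atom_lines, parse_row)
  atoms <- tibble(
    serial = vapply(arows, function(r) as.integer(r[1]), integer(1)),
    name = vapply(arows, function(r) r[2], character(1)),
    x = vapply(arows, function(r) as.numeric(r[3]), numeric(1)),
    y = vapply(arows, function(r) as.numeric(r[4]), numeric(1)),
    z = vapply(arows, function(r) as.numeric(r[5]), numeric(1)),
    element = vapply(arows, function(r) sub("\\..*$", "", r[6]), character(1))
  )
  atoms$class <- NA_character_
  brows <- lapply(bond_lines, parse_row)
  order_of <- function(s) {
    if (s %in% c("ar", "am")) 1L
    else suppressWarnings(as.integer(s))
  }
  bonds <- tibble(
    a = vapply(brows, function(r) as.integer(r[2]), integer(1)),
    b = vapply(brows, function(r) as.integer(r[3]), integer(1)),
    order = vapply(brows, function(r) order_of(r[4]), integer(1))
  )
  if (is.null(species)) species <- tools::file_path_sans_ext(basename(path))
  new_ligand(species, species, atoms, bonds)
}

# ---- interaction classes ----------------------------------------------------

# Protein atom typing by residue/atom name (PLIP/LigPlot-style rule table).
PROTEIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1",
  ASN = "ND2", GLN = "NE2"
)
PROTEIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", MET = character(0)
)
PROTEIN_DONOR_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

classify_protein_atom <- function(resname, name, element) {
  if (element %in% METAL_ELEMENTS) return("metal")
  if (element == "H") return("none")
  if (name == "N") {
    return(if (resname == "PRO") "polar_other" else "donor")
  }
  if (name %in% c("O", "OXT")) return("acceptor")
  da <- PROTEIN_DONOR_ACCEPTORS[[resname]]
  if (!is.null(da) && name %in% da) return("donor_acceptor")
  d <- PROTEIN_DONORS[[resname]]
  if (!is.null(d) && name %in% d) return("donor")
  a <- PROTEIN_ACCEPTORS[[resname]]
  if (!is.null(a) && name %in% a) return("acceptor")
  if (element == "C") {
    # backbone carbons sit next to polar atoms; side-chain carbons bonded to
    # heteroatoms are listed per residue
    polar_c <- list(
      SER = "CB", THR = "CB", CYS = "CB", ASN = "CG", GLN = "CD",
      ASP = "CG", GLU = "CD", ARG = "CZ", TYR = "CZ",
      HIS = c("CG", "CD2", "CE1"), TRP = c("CD1", "CE2")
    )
    if (name %in% c("C", "CA")) return("polar_other")
    pc <- polar_c[[resname]]
    if (!is.null(pc) && name %in% pc) return("polar_other")
    return("hydrophobic")
  }
  if (element %in% c("N", "O", "S")) return("polar_other")
  "none"
}

classify_ligand_atoms <- function(atoms, bonds) {
  n <- nrow(atoms)
  nb <- lapply(seq_len(n), function(i) {
    c(bonds$b[bonds$a == i], bonds$a[bonds$b == i])
  })
  bond_order_to <- function(i, j) {
    o <- bonds$order[(bonds$a == i & bonds$b == j) |
                     (bonds$a == j & bonds$b == i)]
    if (length(o) == 0) 0L else o[1]
  }
  in_ring <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      if (bond_in_ring(bonds, k)) in_ring[c(bonds$a[k], bonds$b[k])] <- TRUE
    }
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    nbi <- nb[[i]]
    heavy_nb <- nbi[atoms$element[nbi] != "H"]
    has_h <- any(atoms$element[nbi] == "H")
    if (el %in% METAL_ELEMENTS) cls[i] <- "metal"
    else if (el == "H") cls[i] <- "none"
    else if (el == "O") {
      dbl <- any(vapply(heavy_nb, function(j) bond_order_to(i, j) >= 2,
                        logical(1)))
      if (dbl) cls[i] <- "acceptor"                    # carbonyl/carboxylate
      else if (in_ring[i]) cls[i] <- "acceptor"        # pyranose ring O
      else if (length(heavy_nb) == 1) cls[i] <- "donor_acceptor"  # hydroxyl
      else cls[i] <- "acceptor"                        # ether
    } else if (el == "N") {
      cls[i] <- if (has_h || length(heavy_nb) <= 2) "donor" else "acceptor"
    } else if (el == "C") {
      polar_nb <- any(atoms$element[heavy_nb] %in% c("N", "O", "S", "P"))
      cls[i] <- if (polar_nb) "polar_other" else "hydrophobic"
    } else if (el %in% c("S", "P")) cls[i] <- "polar_other"
    else cls[i] <- "none"
  }
  cls
}

#' Assign hydrogen-bonding/hydrophobicity classes to atoms
#'
#' Every atom receives one of `hydrophobic`, `donor`, `acceptor`,
#' `donor_acceptor`, `polar_other`, `metal` or `none`. Protein atoms are
#' typed by a residue/atom-name rule table (hydroxyls are donor_acceptor,
#' backbone N donor except proline, backbone O acceptor); ligand atoms are
#' typed from element and bond topology (hydroxyl O donor_acceptor, ring and
#' carbonyl O acceptor, apolar C hydrophobic). All downstream geometry works
#' without hydrogens.
#'
#' @param x A `protein_model` or `ligand`.
#' @return The same object with the `class` column of its atom tibble filled.
#' @export
assign_interaction_classes <- function(x) {
  if (inherits(x, "protein_model")) {
    at <- x$atoms
    at$class <- vapply(seq_len(nrow(at)), function(i) {
      classify_protein_atom(at$resname[i], at$name[i], at$element[i])
    }, character(1))
    x$atoms <- at
    x
  } else if (inherits(x, "ligand")) {
    x$atoms$class <- classify_ligand_atoms(x$atoms, x$bonds)
    x
  } else {
    stop("assign_interaction_classes() expects a protein_model or ligand")
  }
}

# ---- RMSD profile -----------------------------------------------------------

#' RMSD profile of a conformer ensemble against a reference snapshot
#'
#' Matches CA atoms across conformers by (chain, residue number), superposes
#' each conformer on the reference with [kabsch_rmsd()] and reports the RMSD
#' over simulation-time labels, emulating trajectory stability profiles.
#'
#' @param ensemble A list of `protein_model` objects.
#' @param reference_index 1-based index of the reference conformer.
#' @param selection Atom name used for matching (default "CA").
#' @return A tibble (class `rmsd_profile`) with columns `time_label_ns` and
#'   `rmsd`; the row for the reference is exactly 0.
#' @export
rmsd_profile <- function(ensemble, reference_index = 1, selection = "CA") {
  stopifnot(length(ensemble) >= 1)
  if (reference_index < 1 || reference_index > length(ensemble)) {
    stop("reference_index out of range")
  }
  key <- function(m) {
    a <- dplyr::filter(m$atoms, .data$name == selection)
    a <- dplyr::arrange(a, .data$chain, .data$resid, .data$icode)
    a
  }
  ref <- key(ensemble[[reference_index]])
  ref_ids <- paste(ref$chain, ref$resid, ref$icode)
  rows <- purrr::map(ensemble, function(m) {
    a <- key(m)
    ids <- paste(a$chain, a$resid, a$icode)
    missing <- setdiff(ref_ids, ids)
    if (length(missing) > 0) {
      stop("conformer ", m$model_id, " lacks ", selection,
           " atoms for residues: ", paste(missing, collapse = ", "))
    }
    a <- a[match(ref_ids, ids), ]
    tibble(
      time_label_ns = m$time_label_ns,
      rmsd = kabsch_rmsd(as.matrix(a[, c("x", "y", "z")]),
                         as.matrix(ref[, c("x", "y", "z")]))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rmsd_profile", class(out))
  out
}

# ---- region annotations -----------------------------------------------------

#' Build a region annotation table from residue spans
#'
#' @param spans A named list mapping region names (e.g. "linker", "pocket")
#'   to character vectors of spans "chain:start-end" (or "chain:pos").
#' @return A tibble with columns `region`, `chain`, `resid` — one row per
#'   annotated residue.
#' @examples
#' regions_from_spans(list(linker = "A:61-94", pocket = "A:120-140"))
#' @export
regions_from_spans <- function(spans) {
  stopifnot(is.list(spans), !is.null(names(spans)))
  if (anyDuplicated(names(spans))) stop("region names must be unique")
  rows <- purrr::imap(spans, function(sp, nm) {
    purrr::map(sp, function(s) {
      m <- regmatches(s, regexec("^([^:]+):(-?[0-9]+)(?:-(-?[0-9]+))?$", s))[[1]]
      if (length(m) == 0) stop("bad span '", s, "' (expected chain:start-end)")
      from <- as.integer(m[3])
      to <- if (m[4] == "") from else as.integer(m[4])
      tibble(region = nm, chain = m[2], resid = seq(from, to))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Read region annotations from a JSON config
#'
#' The config maps region names to lists of "chain:start-end" spans, e.g.
#' `{"linker": ["A:61-94"], "pocket": ["A:120-140"]}`.
#'
#' @param path Path to a JSON file.
#' @return A region tibble as from [regions_from_spans()].
#' @export
read_regions <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions_from_spans(as.list(cfg))
}

#' Write region annotations to JSON
#' @param regions A region tibble (columns region, chain, resid).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  spans <- regions |>
    dplyr::group_by(.data$region, .data$chain) |>
    dplyr::summarise(spans = list({
      r <- sort(unique(.data$resid))
      brk <- c(0, which(diff(r) != 1), length(r))
      vapply(seq_len(length(brk) - 1), function(i) {
        seg <- r[(brk[i] + 1):brk[i + 1]]
        paste0(dplyr::first(.data$chain), ":", min(seg), "-", max(seg))
      }, character(1))
    }), .groups = "drop")
  out <- split(unlist(spans$spans, use.names = FALSE),
               rep(spans$region, lengths(spans$spans)))
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# check that all annotated residues exist in the model
validate_regions <- function(model, regions) {
  res <- dplyr::distinct(model$atoms, .data$chain, .data$resid)
  have <- paste(res$chain, res$resid)
  want <- paste(regions$chain, regions$resid)
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    stop("annotated residues absent from model ", model$model_id, ": ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  invisible(TRUE)
}
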