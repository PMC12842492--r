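test_that("PDB reading preserves records, chains and residue numbering", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_fixture_text(), path)
  m <- read_pdb(path)
  expect_s3_class(m, "protein_model")
  expect_equal(nrow(m$atoms), 13)           # one row per ATOM line
  expect_equal(unique(m$atoms$chain), c("A", "B"))
  expect_equal(unique(m$atoms$resid[m$atoms$chain == "B"]), 5)

  # independent fixed-width re-parse of the same fixture as the oracle
  recs <- grep("^ATOM", pdb_fixture_text(), value = TRUE)
  oracle <- data.frame(
    name = trimws(substring(recs, 13, 16)),
    chain = substring(recs, 22, 22),
    resid = as.integer(substring(recs, 23, 26)),
    x = as.numeric(substring(recs, 31, 38)))
  expect_equal(m$atoms$name, oracle$name)
  expect_equal(m$atoms$chain, oracle$chain)
  expect_equal(m$atoms$resid, oracle$resid)
  expect_equal(m$atoms$x, oracle$x)
})

test_that("PDB write -> read round-trips coordinates and residue identity", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_fixture_text(), path)
  m <- read_pdb(path)
  out <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, out)
  m2 <- read_pdb(out)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$y, m$atoms$y, tolerance = 1e-3)
  expect_equal(m2$atoms$z, m$atoms$z, tolerance = 1e-3)
  expect_identical(m2$atoms$resname, m$atoms$resname)
  expect_identical(m2$atoms$chain, m$atoms$chain)
  expect_identical(m2$atoms$resid, m$atoms$resid)
})

test_that("malformed and empty PDB inputs raise parse errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      bad"), path)
  expect_error(read_pdb(path), "line 1")
  writeLines(c("HEADER    EMPTY", "END"), path)
  expect_error(read_pdb(path), "no ATOM")
})

test_that("waters are dropped on read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_fixture_text()[2],
    "HETATM   20  O   HOH A  99      1.000   2.000   3.000  1.00  0.00           O",
    "END"), path)
  m <- read_pdb(path)
  expect_equal(nrow(m$atoms), 1)
})

test_that("rotatable-bond detection follows the heavy-neighbour rule", {
  ethane <- read_ligand(write_sdf_fixture("ethane"))
  expect_equal(ethane$n_rot, 0)             # terminal methyls excluded
  butane <- read_ligand(write_sdf_fixture("nbutane"))
  expect_equal(butane$n_rot, 1)             # only the C2-C3 bond
  expect_equal(butane$rotatable_torsions[[1]][2:3], c(2, 3))
  cyclo <- read_ligand(write_sdf_fixture("cyclohexane"))
  expect_equal(cyclo$n_rot, 0)              # ring bonds never rotate

  # exhaustive independent application of the rule over all bonds
  for (lig in list(ethane, butane, cyclo)) {
    heavy_deg <- function(i) {
      nb <- c(lig$bonds$b[lig$bonds$a == i], lig$bonds$a[lig$bonds$b == i])
      sum(lig$atoms$element[nb] != "H")
    }
    expected <- 0
    for (k in seq_len(nrow(lig$bonds))) {
      a <- lig$bonds$a[k]; b <- lig$bonds$b[k]
      if (lig$bonds$order[k] != 1) next
      if (heavy_deg(a) < 2 || heavy_deg(b) < 2) next
      sub <- lig$bonds[-k, , drop = FALSE]
      # in a ring iff endpoints stay connected without this bond (BFS)
      seen <- a
      repeat {
        nxt <- unique(c(sub$b[sub$a %in% seen], sub$a[sub$b %in% seen]))
        nxt <- setdiff(nxt, seen)
        if (length(nxt) == 0) break
        seen <- c(seen, nxt)
      }
      if (!(b %in% seen)) expected <- expected + 1
    }
    expect_equal(lig$n_rot, expected)
  }
})

test_that("ligand reading rejects broken inputs", {
  bad <- sdf_text("two pieces",
                  data.frame(x = c(0, 5), y = 0, z = 0, el = "C"),
                  data.frame(a = integer(0), b = integer(0),
                             order = integer(0)))
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(bad, path)
  expect_error(read_ligand(path), "disconnected")
  bad2 <- sdf_text("mystery", data.frame(x = 0, y = 0, z = 0, el = "Xx"),
                   data.frame(a = integer(0), b = integer(0),
                              order = integer(0)))
  writeLines(bad2, path)
  expect_error(read_ligand(path), "unknown element")
})

test_that("MOL2 parsing agrees with SDF on the same molecule", {
  mol2 <- c("@<TRIPOS>MOLECULE", "butane", " 4 3 0 0 0", "SMALL",
            "NO_CHARGES", "@<TRIPOS>ATOM",
            "1 C1 0.0 0.0 0.0 C.3", "2 C2 1.54 0.0 0.0 C.3",
            "3 C3 2.3 1.3 0.0 C.3", "4 C4 3.84 1.3 0.0 C.3",
            "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 1", "3 3 4 1")
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(mol2, path)
  lig <- read_ligand(path)
  ref <- read_ligand(write_sdf_fixture("nbutane"))
  expect_equal(lig$n_rot, ref$n_rot)
  expect_equal(lig$atoms$element, ref$atoms$element)
  expect_equal(nrow(lig$bonds), nrow(ref$bonds))
})

test_that("interaction classes follow the rule table", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_fixture_text(), path)
  m <- assign_interaction_classes(read_pdb(path))
  cls <- function(chain, resid, name) {
    m$atoms$class[m$atoms$chain == chain & m$atoms$resid == resid &
                    m$atoms$name == name]
  }
  expect_equal(cls("A", 2, "OG"), "donor_acceptor")  # serine hydroxyl
  expect_equal(cls("A", 1, "O"), "acceptor")         # backbone carbonyl
  expect_equal(cls("A", 1, "N"), "donor")            # backbone amide
  expect_equal(cls("A", 1, "CA"), "polar_other")

  # leucine side-chain carbon is hydrophobic
  expect_equal(
    linkerdock:::classify_protein_atom("LEU", "CD1", "C"), "hydrophobic")
  # every atom gets some class
  expect_true(all(m$atoms$class %in%
                    c("hydrophobic", "donor", "acceptor", "donor_acceptor",
                      "polar_other", "metal", "none")))
})

test_that("kabsch_rmsd satisfies identity, rigid-motion and symmetry laws", {
  set.seed(42)
  P <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(P, P), 0, tolerance = 1e-10)

  # 90-degree rotation about z plus a translation is removed exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
  Q <- sweep(P %*% t(Rz), 2, c(3, -2, 7), `+`)
  expect_equal(kabsch_rmsd(P, Q), 0, tolerance = 1e-8)

  # symmetry and invariance under random rigid motions of either argument
  for (i in 1:5) {
    Q2 <- P + matrix(rnorm(30, 0, 0.3), ncol = 3)
    r0 <- kabsch_rmsd(P, Q2)
    expect_equal(kabsch_rmsd(Q2, P), r0, tolerance = 1e-8)
    R <- linkerdock:::random_rotation_matrix()
    moved <- sweep(Q2 %*% t(R), 2, rnorm(3, 0, 5), `+`)
    expect_equal(kabsch_rmsd(P, moved), r0, tolerance = 1e-8)
  }
})

test_that("kabsch_rmsd two-point case matches the closed form", {
  P <- matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  Q <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  # centred, optimal rotation is the identity: sqrt((0.5^2 + 0.5^2) / 2)
  expect_equal(kabsch_rmsd(P, Q), 0.5, tolerance = 1e-12)
  expect_error(kabsch_rmsd(P, matrix(0, 3, 3)), "differ in size")
})

test_that("rmsd_profile matches per-frame Kabsch and zeroes the reference", {
  tp <- make_toy_protein(toy_small_spec(seed = 7, n_snapshots = 3))
  prof <- rmsd_profile(tp$ensemble)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$rmsd[1], 0, tolerance = 1e-10)
  # brute-force oracle per frame
  ca <- function(m) as.matrix(m$atoms[m$atoms$name == "CA",
                                      c("x", "y", "z")])
  for (k in 2:3) {
    expect_equal(prof$rmsd[k],
                 kabsch_rmsd(ca(tp$ensemble[[k]]), ca(tp$ensemble[[1]])),
                 tolerance = 1e-10)
  }
  # translated copies profile to zero
  shifted <- lapply(seq_along(tp$ensemble), function(k) {
    m <- tp$ensemble[[1]]
    m$atoms$x <- m$atoms$x + k
    m$time_label_ns <- 10 * k
    m
  })
  expect_true(all(rmsd_profile(shifted)$rmsd < 1e-8))
})

test_that("region span parsing and JSON round-trip work", {
  rg <- regions_from_spans(list(linker = "A:61-94", pocket = c("A:120-125",
                                                               "A:130")))
  expect_equal(sum(rg$region == "linker"), 34)
  expect_equal(sum(rg$region == "pocket"), 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_regions(rg, path)
  rg2 <- read_regions(path)
  expect_equal(dplyr::arrange(rg2, region, resid),
               dplyr::arrange(rg, region, resid))
  expect_error(regions_from_spans(list(linker = "A61-94")), "bad span")
})
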