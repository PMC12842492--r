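# Stochastic flexible-ligand, rigid-receptor pose search: iterated Monte
# Carlo with Metropolis acceptance over rigid-body + torsion moves, each
# run's best pose polished by derivative-free local optimization. Blind
# whole-surface docking over an axis-aligned box by default.

#' Docking search configuration
#'
#' @param n_runs Independent Monte Carlo restarts (analog of
#'   "exhaustiveness"); run `r` uses seed `seed + r`, so serial and parallel
#'   execution agree.
#' @param n_steps Monte Carlo steps per run.
#' @param temperature_like Metropolis acceptance scale in kcal/mol.
#' @param seed Base RNG seed; the same seed reproduces the pose list bitwise.
#' @param max_poses Maximum number of ranked poses returned.
#' @param clash_floor Minimum allowed receptor-ligand heavy-atom distance in
#'   a returned pose (Angstroms).
#' @return A `docking_config` list.
#' @export
docking_config <- function(n_runs = 8, n_steps = 120, temperature_like = 1.2,
                           seed = 1, max_poses = 5, clash_floor = 2.0) {
  stopifnot(n_runs >= 1, n_steps >= 1, temperature_like > 0, max_poses >= 1,
            clash_floor > 0)
  structure(
    list(n_runs = n_runs, n_steps = n_steps,
         temperature_like = temperature_like, seed = seed,
         max_poses = max_poses, clash_floor = clash_floor),
    class = "docking_config"
  )
}

#' Search box for blind docking
#'
#' @param center 3-vector, box center (Angstroms).
#' @param dims 3-vector, box edge lengths (Angstroms), all positive.
#' @return A `search_box` list.
#' @export
search_box <- function(center, dims) {
  center <- as.numeric(center); dims <- as.numeric(dims)
  stopifnot(length(center) == 3, length(dims) == 3, all(dims > 0))
  structure(list(center = center, dims = dims), class = "search_box")
}

#' Default blind-docking box around a receptor
#'
#' Axis-aligned bounding box of all atoms, expanded by `margin` on each side.
#'
#' @param model A `protein_model` or atom tibble.
#' @param margin Expansion per side in Angstroms (default 6).
#' @return A [search_box()].
#' @export
default_box <- function(model, margin = 6) {
  at <- if (inherits(model, "protein_model")) model$atoms else model
  if (nrow(at) == 0) stop("default_box(): empty model")
  lo <- c(min(at$x), min(at$y), min(at$z)) - margin
  hi <- c(max(at$x), max(at$y), max(at$z)) + margin
  search_box(center = (lo + hi) / 2, dims = hi - lo)
}

# ---- pose machinery ---------------------------------------------------------

# atoms moved by torsion k: the b-side of the rotatable bond
torsion_moving_sets <- function(ligand) {
  lapply(ligand$rotatable_torsions, function(t4) {
    a <- t4[2]; b <- t4[3]
    keep <- !((ligand$bonds$a == a & ligand$bonds$b == b) |
                (ligand$bonds$a == b & ligand$bonds$b == a))
    comp <- bond_components(nrow(ligand$atoms),
                            ligand$bonds[keep, , drop = FALSE])
    setdiff(which(comp == comp[b]), b)
  })
}

# reference coords -> posed coords for (translation, quaternion, torsions)
pose_coords <- function(ref, ligand, moving_sets, translation, quat,
                        torsions_deg) {
  X <- ref
  for (k in seq_along(torsions_deg)) {
    th <- torsions_deg[k]
    if (abs(th) < 1e-12) next
    t4 <- ligand$rotatable_torsions[[k]]
    a <- t4[2]; b <- t4[3]
    axis <- X[b, ] - X[a, ]
    mv <- moving_sets[[k]]
    X[mv, ] <- sweep(rotate_about_axis(sweep(X[mv, , drop = FALSE], 2,
                                             X[a, ]),
                                       axis, deg2rad(th)), 2, X[a, ], `+`)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sweep(Xc %*% t(quat_to_mat(quat)), 2, translation, `+`)
}

box_bounds <- function(box) {
  list(lo = box$center - box$dims / 2, hi = box$center + box$dims / 2)
}

# centroid inside the box; atoms may protrude at most 2 A past any face
pose_contained <- function(X, box, protrusion = 2) {
  b <- box_bounds(box)
  ctr <- colMeans(X)
  if (any(ctr < b$lo) || any(ctr > b$hi)) return(FALSE)
  all(sweep(X, 2, b$lo - protrusion, `>=`)) &&
    all(sweep(X, 2, b$hi + protrusion, `<=`))
}

new_pose <- function(ligand, translation, quat, torsions_deg, atoms,
                     breakdown) {
  structure(
    list(ligand_id = ligand$ligand_id, species = ligand$species,
         translation = translation, orientation = quat_normalize(quat),
         torsion_angles = torsions_deg, atoms = atoms, n_rot = ligand$n_rot,
         delta_g = breakdown$delta_g, breakdown = breakdown),
    class = "pose"
  )
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s (%s): delta_g = %.4f kcal/mol at (%.2f, %.2f, %.2f)\n",
              x$ligand_id, x$species, x$delta_g,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# build a pose object (posed atom tibble + fresh score) from parameters
realize_pose <- function(ligand, ref, moving_sets, translation, quat,
                         torsions_deg, scorer, li, weights) {
  X <- pose_coords(ref, ligand, moving_sets, translation, quat, torsions_deg)
  heavy <- ligand$atoms$element != "H"
  terms <- scorer(X[heavy, , drop = FALSE], li$rad, li$hyd, li$don, li$acc)
  bd <- breakdown_from_terms(terms, weights, ligand$n_rot)
  atoms <- ligand$atoms
  atoms$x <- X[, 1]; atoms$y <- X[, 2]; atoms$z <- X[, 3]
  new_pose(ligand, translation, quat, torsions_deg, atoms, bd)
}

min_receptor_distance <- function(receptor_atoms, X) {
  if (nrow(receptor_atoms) == 0 || nrow(X) == 0) return(Inf)
  R <- as.matrix(receptor_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(R^2), rowSums(X^2), `+`) - 2 * (R %*% t(X))
  sqrt(max(0, min(d2)))
}

# ---- search -----------------------------------------------------------------

pose_objective <- function(ligand, ref, moving_sets, scorer, li, weights,
                           box) {
  n_tor <- length(ligand$rotatable_torsions)
  heavy <- ligand$atoms$element != "H"
  function(par, q0) {
    translation <- par[1:3]
    quat <- quat_multiply(rotvec_to_quat(par[4:6]), q0)
    torsions <- if (n_tor > 0) par[7:(6 + n_tor)] else numeric(0)
    X <- pose_coords(ref, ligand, moving_sets, translation, quat, torsions)
    if (!is.null(box) && !pose_contained(X, box)) return(1e6)
    terms <- scorer(X[heavy, , drop = FALSE], li$rad, li$hyd, li$don, li$acc)
    breakdown_from_terms(terms, weights, ligand$n_rot)$delta_g
  }
}

#' Dock a flexible ligand into a box against a rigid receptor
#'
#' Runs `n_runs` independent Monte Carlo searches over rigid-body
#' translations/rotations and rotatable-torsion angles with Metropolis
#' acceptance, locally optimizes each run's best pose, removes poses that
#' clash with the receptor (any heavy-atom pair below `clash_floor`), and
#' returns up to `max_poses` poses ranked by predicted binding energy
#' (most negative first; ties broken by lexicographic translation order).
#' Deterministic under `config$seed`.
#'
#' @param receptor_atoms Atom tibble of the rigid receptor (may be empty),
#'   classes assigned. A `protein_model` is also accepted.
#' @param ligand A `ligand` with classes assigned.
#' @param box A [search_box()]; defaults to [default_box()] of the receptor.
#' @param weights [scoring_weights()].
#' @param config [docking_config()].
#' @return A list of `pose` objects sorted best-first.
#' @export
dock <- function(receptor_atoms, ligand, box = NULL,
                 weights = scoring_weights(), config = docking_config()) {
  if (inherits(receptor_atoms, "protein_model")) {
    receptor_atoms <- receptor_atoms$atoms
  }
  if (is.null(box)) {
    if (nrow(receptor_atoms) == 0) stop("dock(): need a box for an empty receptor")
    box <- default_box(receptor_atoms)
  }
  ref <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  diam <- if (nrow(ref) > 1) max(stats::dist(ref)) else 0
  if (diam > min(box$dims) + 4) {
    stop("dock(): box too small to contain the ligand (diameter ",
         round(diam, 1), " A vs smallest box edge ", round(min(box$dims), 1),
         " A)")
  }
  moving_sets <- torsion_moving_sets(ligand)
  scorer <- make_scorer(receptor_atoms, weights)
  li <- ligand_score_inputs(ligand$atoms)
  # score positions only heavy atoms, but containment applies to all atoms;
  # ref here is all atoms, li$L derives from posed coordinates of heavy ones
  heavy <- ligand$atoms$element != "H"
  n_tor <- length(ligand$rotatable_torsions)
  b <- box_bounds(box)
  eval_state <- function(translation, quat, torsions) {
    X <- pose_coords(ref, ligand, moving_sets, translation, quat, torsions)
    if (!pose_contained(X, box)) return(list(ok = FALSE))
    terms <- scorer(X[heavy, , drop = FALSE], li$rad, li$hyd, li$don, li$acc)
    bd <- breakdown_from_terms(terms, weights, ligand$n_rot)
    list(ok = TRUE, dg = bd$delta_g, X = X)
  }
  run_best <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run_best[[r]] <- withr::with_seed(config$seed + r, {
      # random containment-valid start; with a non-empty receptor the start
      # is biased to the surface (random receptor atom + 2-6 A offset) so
      # short blind-docking runs always sample contact geometry
      st <- NULL
      for (try in seq_len(100)) {
        if (nrow(receptor_atoms) > 0) {
          anchor <- receptor_atoms[sample.int(nrow(receptor_atoms), 1), ]
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          translation <- c(anchor$x, anchor$y, anchor$z) + runif(1, 2, 6) * u
          translation <- pmin(pmax(translation, b$lo), b$hi)
        } else {
          translation <- b$lo + runif(3) * box$dims
        }
        quat <- random_unit_quat()
        torsions <- if (n_tor > 0) runif(n_tor, -180, 180) else numeric(0)
        st <- eval_state(translation, quat, torsions)
        if (st$ok) break
      }
      if (!st$ok) {
        translation <- box$center
        quat <- c(1, 0, 0, 0)
        torsions <- rep(0, n_tor)
        st <- eval_state(translation, quat, torsions)
        if (!st$ok) stop("dock(): could not place ligand inside the box")
      }
      cur <- list(translation = translation, quat = quat,
                  torsions = torsions, dg = st$dg)
      best <- cur
      for (step in seq_len(config$n_steps)) {
        cand <- cur
        kind <- sample.int(if (n_tor > 0) 3 else 2, 1)
        if (kind == 1) {
          cand$translation <- cur$translation + rnorm(3, 0, 0.75)
        } else if (kind == 2) {
          cand$quat <- quat_normalize(
            quat_multiply(rotvec_to_quat(rnorm(3, 0, deg2rad(15))), cur$quat))
        } else {
          k <- sample.int(n_tor, 1)
          cand$torsions[k] <- cur$torsions[k] + rnorm(1, 0, 30)
        }
        st <- eval_state(cand$translation, cand$quat, cand$torsions)
        if (!st$ok) next
        cand$dg <- st$dg
        if (cand$dg <= cur$dg ||
            runif(1) < exp(-(cand$dg - cur$dg) / config$temperature_like)) {
          cur <- cand
        }
        if (cur$dg < best$dg) best <- cur
      }
      best
    })
  }
  # local optimization of each run's best, then rank
  obj <- pose_objective(ligand, ref, moving_sets, scorer, li, weights, box)
  poses <- list()
  for (r in seq_len(config$n_runs)) {
    bst <- run_best[[r]]
    par0 <- c(bst$translation, 0, 0, 0, bst$torsions)
    opt <- stats::optim(par0, obj, q0 = bst$quat, method = "Nelder-Mead",
                        control = list(maxit = 300))
    par <- if (opt$value <= bst$dg) opt$par else par0
    translation <- par[1:3]
    quat <- quat_normalize(quat_multiply(rotvec_to_quat(par[4:6]), bst$quat))
    torsions <- if (n_tor > 0) par[7:(6 + n_tor)] else numeric(0)
    p <- realize_pose(ligand, ref, moving_sets, translation, quat, torsions,
                      scorer, li, weights)
    Xh <- as.matrix(p$atoms[heavy, c("x", "y", "z")])
    if (min_receptor_distance(receptor_atoms, Xh) < config$clash_floor) next
    if (!pose_contained(as.matrix(p$atoms[, c("x", "y", "z")]), box)) next
    poses[[length(poses) + 1]] <- p
  }
  if (length(poses) == 0) {
    stop("dock(): no clash-free contained pose found in ", config$n_runs,
         " runs")
  }
  dg <- vapply(poses, function(p) round(p$delta_g, 6), numeric(1))
  tr <- t(vapply(poses, function(p) p$translation, numeric(3)))
  ord <- order(dg, tr[, 1], tr[, 2], tr[, 3])
  poses <- poses[ord]
  poses[seq_len(min(config$max_poses, length(poses)))]
}

#' Locally optimize a pose
#'
#' Derivative-free (Nelder-Mead) refinement of a pose's translation,
#' orientation and torsion angles against the fixed receptor. Never returns
#' a pose worse than the input.
#'
#' @param pose A `pose`.
#' @param receptor_atoms Receptor atom tibble (classes assigned).
#' @param weights [scoring_weights()].
#' @param budget Maximum optimizer iterations.
#' @param ligand The `ligand` the pose belongs to (topology provider).
#' @param box Optional [search_box()]; if given, containment is enforced.
#' @return An optimized `pose` with `delta_g <=` the input's.
#' @export
local_optimize <- function(pose, receptor_atoms, weights = scoring_weights(),
                           budget = 300, ligand = NULL, box = NULL) {
  if (inherits(receptor_atoms, "protein_model")) {
    receptor_atoms <- receptor_atoms$atoms
  }
  if (is.null(ligand)) {
    # rebuild topology from the pose payload (no torsion refinement possible)
    ligand <- structure(
      list(ligand_id = pose$ligand_id, species = pose$species,
           atoms = pose$atoms, bonds = tibble(a = integer(0), b = integer(0),
                                              order = integer(0)),
           rotatable_torsions = list(), n_rot = pose$n_rot),
      class = "ligand")
  }
  ref <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  moving_sets <- torsion_moving_sets(ligand)
  scorer <- make_scorer(receptor_atoms, weights)
  li <- ligand_score_inputs(ligand$atoms)
  n_tor <- length(ligand$rotatable_torsions)
  tor0 <- if (n_tor > 0) pose$torsion_angles else numeric(0)
  obj <- pose_objective(ligand, ref, moving_sets, scorer, li, weights, box)
  par0 <- c(pose$translation, 0, 0, 0, tor0)
  dg0 <- obj(par0, pose$orientation)
  opt <- stats::optim(par0, obj, q0 = pose$orientation,
                      method = "Nelder-Mead", control = list(maxit = budget))
  par <- if (opt$value <= dg0) opt$par else par0
  translation <- par[1:3]
  quat <- quat_normalize(quat_multiply(rotvec_to_quat(par[4:6]),
                                       pose$orientation))
  torsions <- if (n_tor > 0) par[7:(6 + n_tor)] else numeric(0)
  realize_pose(ligand, ref, moving_sets, translation, quat, torsions,
               scorer, li, weights)
}
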