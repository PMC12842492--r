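# Empirical pairwise scoring on the AutoDock-Vina functional form. All
# terms act on the surface distance s = d - r_i - r_j; pair terms are zero
# for s beyond the cutoff.

#' Scoring weights for the empirical binding-energy function
#'
#' Defaults are the published weights of the Vina scoring function, so that
#' predicted binding energies land in the familiar -4 to -7 kcal/mol regime
#' of blind carbohydrate docking. All weights are overridable.
#'
#' @param w_gauss1,w_gauss2,w_repulsion,w_hydrophobic,w_hbond Term weights.
#' @param w_rot Rotatable-bond penalty coefficient.
#' @param cutoff Surface-distance cutoff in Angstroms; pair terms are zero
#'   beyond it.
#' @return A `scoring_weights` list.
#' @export
scoring_weights <- function(w_gauss1 = -0.035579, w_gauss2 = -0.005156,
                            w_repulsion = 0.840245, w_hydrophobic = -0.035069,
                            w_hbond = -0.587439, w_rot = 0.05846,
                            cutoff = 8) {
  stopifnot(cutoff > 0)
  structure(
    list(w_gauss1 = w_gauss1, w_gauss2 = w_gauss2, w_repulsion = w_repulsion,
         w_hydrophobic = w_hydrophobic, w_hbond = w_hbond, w_rot = w_rot,
         cutoff = cutoff),
    class = "scoring_weights"
  )
}

#' Surface distance between two atoms
#'
#' @param d Interatomic distance in Angstroms.
#' @param r_i,r_j Van der Waals radii of the two atoms.
#' @return `d - r_i - r_j` (negative when the surfaces interpenetrate).
#' @export
surface_distance <- function(d, r_i, r_j) d - r_i - r_j

# linear ramp: 1 below lo, 0 above hi
lin_ramp <- function(s, lo, hi) pmin(1, pmax(0, (hi - s) / (hi - lo)))

donorish <- function(cls) cls %in% c("donor", "donor_acceptor")
acceptorish <- function(cls) cls %in% c("acceptor", "donor_acceptor")

# Precompile a receptor into a fast scorer closure: takes ligand coordinates
# (m x 3), radii, and class flags; returns unweighted per-term sums.
make_scorer <- function(receptor_atoms, weights) {
  n <- nrow(receptor_atoms)
  if (n > 0 && any(is.na(receptor_atoms$class))) {
    stop("receptor atoms lack interaction classes; ",
         "run assign_interaction_classes() first")
  }
  R <- if (n > 0) as.matrix(receptor_atoms[, c("x", "y", "z")]) else
    matrix(numeric(0), ncol = 3)
  r_rad <- vdw_radius(receptor_atoms$element)
  r_hyd <- receptor_atoms$class == "hydrophobic"
  r_don <- donorish(receptor_atoms$class)
  r_acc <- acceptorish(receptor_atoms$class)
  cutoff <- weights$cutoff
  function(L, l_rad, l_hyd, l_don, l_acc) {
    empty <- list(gauss1 = 0, gauss2 = 0, repulsion = 0,
                  hydrophobic = 0, hbond = 0)
    if (n == 0 || nrow(L) == 0) return(empty)
    d2 <- outer(rowSums(R^2), rowSums(L^2), `+`) - 2 * (R %*% t(L))
    d <- sqrt(pmax(d2, 0))
    s <- d - outer(r_rad, l_rad, `+`)
    keep <- s <= cutoff
    if (!any(keep)) return(empty)
    sk <- s[keep]
    g1 <- exp(-(sk / 0.5)^2)
    g2 <- exp(-((sk - 3) / 2)^2)
    rep_t <- ifelse(sk < 0, sk^2, 0)
    hyd_gate <- outer(r_hyd, l_hyd, `&`)[keep]
    hb_gate <- (outer(r_don, l_acc, `&`) | outer(r_acc, l_don, `&`))[keep]
    hyd_t <- ifelse(hyd_gate, lin_ramp(sk, 0.5, 1.5), 0)
    hb_t <- ifelse(hb_gate, lin_ramp(sk, -0.7, 0), 0)
    list(gauss1 = sum(g1), gauss2 = sum(g2), repulsion = sum(rep_t),
         hydrophobic = sum(hyd_t), hbond = sum(hb_t))
  }
}

ligand_score_inputs <- function(ligand_atoms) {
  if (any(is.na(ligand_atoms$class))) {
    stop("ligand atoms lack interaction classes; ",
         "run assign_interaction_classes() first")
  }
  heavy <- ligand_atoms$element != "H"
  la <- ligand_atoms[heavy, , drop = FALSE]
  list(
    L = as.matrix(la[, c("x", "y", "z")]),
    rad = vdw_radius(la$element),
    hyd = la$class == "hydrophobic",
    don = donorish(la$class),
    acc = acceptorish(la$class)
  )
}

breakdown_from_terms <- function(terms, weights, n_rot) {
  c_inter <- weights$w_gauss1 * terms$gauss1 +
    weights$w_gauss2 * terms$gauss2 +
    weights$w_repulsion * terms$repulsion +
    weights$w_hydrophobic * terms$hydrophobic +
    weights$w_hbond * terms$hbond
  delta_g <- c_inter / (1 + weights$w_rot * n_rot)
  structure(
    list(gauss1 = terms$gauss1, gauss2 = terms$gauss2,
         repulsion = terms$repulsion, hydrophobic = terms$hydrophobic,
         hbond = terms$hbond, c_inter = c_inter, n_rot = n_rot,
         delta_g = delta_g),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "<score_breakdown> delta_g = %.4f kcal/mol (c_inter = %.4f, n_rot = %d)\n",
    x$delta_g, x$c_inter, x$n_rot))
  invisible(x)
}

#' Score a ligand pose against a receptor
#'
#' Sums steric (two attractive gaussians and a quadratic clash repulsion),
#' hydrophobic and hydrogen-bond terms over all receptor-ligand heavy-atom
#' pairs whose surface distance is within the cutoff, then converts the
#' weighted intermolecular sum to a predicted binding free energy with the
#' rotatable-bond entropy penalty: delta_g = c_inter / (1 + w_rot * n_rot).
#' More negative means stronger predicted binding.
#'
#' @param receptor_atoms Atom tibble of the rigid receptor (protein atoms,
#'   plus any frozen ligand copies), with interaction classes assigned.
#' @param ligand A `ligand` whose `atoms` carry pose coordinates and classes.
#' @param weights A [scoring_weights()] object.
#' @return A `score_breakdown` with per-term sums, `c_inter` and `delta_g`
#'   in kcal/mol.
#' @export
score_pose <- function(receptor_atoms, ligand, weights = scoring_weights()) {
  scorer <- make_scorer(receptor_atoms, weights)
  li <- ligand_score_inputs(ligand$atoms)
  terms <- scorer(li$L, li$rad, li$hyd, li$don, li$acc)
  breakdown_from_terms(terms, weights, ligand$n_rot)
}

#' Single-pair score profile
#'
#' The weighted kcal/mol contribution of one receptor-ligand atom pair at
#' surface distance `s`, consistent with [score_pose()] on the equivalent
#' two-atom system (with `n_rot = 0`).
#'
#' @param class_i,class_j Interaction classes of the two atoms.
#' @param s Surface distance(s) in Angstroms (vectorised).
#' @param weights A [scoring_weights()] object.
#' @return Numeric vector of contributions, zero beyond the cutoff.
#' @export
score_pair_profile <- function(class_i, class_j, s,
                               weights = scoring_weights()) {
  out <- numeric(length(s))
  within <- s <= weights$cutoff
  sk <- s[within]
  g1 <- exp(-(sk / 0.5)^2)
  g2 <- exp(-((sk - 3) / 2)^2)
  rep_t <- ifelse(sk < 0, sk^2, 0)
  hyd <- if (class_i == "hydrophobic" && class_j == "hydrophobic")
    lin_ramp(sk, 0.5, 1.5) else 0
  hb <- if ((donorish(class_i) && acceptorish(class_j)) ||
            (acceptorish(class_i) && donorish(class_j)))
    lin_ramp(sk, -0.7, 0) else 0
  out[within] <- weights$w_gauss1 * g1 + weights$w_gauss2 * g2 +
    weights$w_repulsion * rep_t + weights$w_hydrophobic * hyd +
    weights$w_hbond * hb
  out
}
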