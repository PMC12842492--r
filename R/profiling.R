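# Geometric interaction profiling of docked complexes: protein-ligand and
# ligand-ligand hydrogen bonds, and ligand cluster detection over the
# contact graph.

#' Profiling parameters
#'
#' @param d_max Maximum donor-acceptor heavy-atom distance for a hydrogen
#'   bond (default 3.6 A — conservative because docked poses carry no
#'   hydrogens).
#' @param angle_min Minimum D-H...A angle in degrees, applied only when
#'   hydrogens are present near the donor (default 120).
#' @param contact_max Maximum heavy-atom distance for a ligand-ligand
#'   contact edge and for region contact (default 4.0 A).
#' @param min_size Minimum connected-component size reported as a cluster
#'   (default 3).
#' @return A `profiling_params` list.
#' @export
profiling_params <- function(d_max = 3.6, angle_min = 120, contact_max = 4.0,
                             min_size = 3) {
  stopifnot(d_max > 0, contact_max > 0, min_size >= 1)
  structure(list(d_max = d_max, angle_min = angle_min,
                 contact_max = contact_max, min_size = min_size),
            class = "profiling_params")
}

#' Detect hydrogen bonds in a docked complex
#'
#' Heavy-atom geometric criterion: every donor-acceptor pair (classes
#' donor/donor_acceptor vs acceptor/donor_acceptor) across distinct units
#' (protein vs ligand copy, or two different ligand copies) at distance
#' `<= d_max` is reported once. When hydrogen atoms are present within
#' covalent range (1.2 A) of the donor, the D-H...A angle must additionally
#' be `>= angle_min`. Pairs where both atoms are donor_acceptor are
#' reported with the lower-serial partner as donor.
#'
#' @param cx A `docked_complex`.
#' @param params [profiling_params()].
#' @return A tibble, one row per bond: donor/acceptor unit, serial, name,
#'   residue fields, `distance` (A) and `partner_kind`
#'   ("protein-ligand" or "ligand-ligand").
#' @export
detect_hbonds <- function(cx, params = profiling_params()) {
  stopifnot(inherits(cx, "docked_complex"))
  at <- complex_atoms(cx)
  if (any(is.na(at$class))) {
    stop("complex atoms lack interaction classes; assign them first")
  }
  at$row <- seq_len(nrow(at))
  don <- at[donorish(at$class), ]
  acc <- at[acceptorish(at$class), ]
  empty <- tibble(
    donor_unit = character(0), donor_serial = integer(0),
    donor_name = character(0), donor_resid = integer(0),
    donor_resname = character(0),
    acceptor_unit = character(0), acceptor_serial = integer(0),
    acceptor_name = character(0), acceptor_resid = integer(0),
    acceptor_resname = character(0),
    distance = numeric(0), partner_kind = character(0))
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty)
  D <- as.matrix(don[, c("x", "y", "z")])
  A <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- outer(rowSums(D^2), rowSums(A^2), `+`) - 2 * (D %*% t(A))
  d <- sqrt(pmax(d2, 0))
  idx <- which(d <= params$d_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  di <- don[idx[, 1], ]; aj <- acc[idx[, 2], ]
  keep <- di$unit != aj$unit &
    !(di$unit == "protein" & aj$unit == "protein")
  # both donor_acceptor: report once, lower atom row as donor
  dd <- di$class == "donor_acceptor" & aj$class == "donor_acceptor"
  keep <- keep & (!dd | di$row < aj$row)
  di <- di[keep, ]; aj <- aj[keep, ]
  dist <- d[idx][keep]
  if (nrow(di) == 0) return(empty)
  # angle gate where explicit hydrogens flank the donor
  hyd <- at[at$element == "H", ]
  ang_ok <- rep(TRUE, nrow(di))
  if (nrow(hyd) > 0) {
    H <- as.matrix(hyd[, c("x", "y", "z")])
    for (i in seq_len(nrow(di))) {
      dxyz <- c(di$x[i], di$y[i], di$z[i])
      axyz <- c(aj$x[i], aj$y[i], aj$z[i])
      dh <- sqrt(rowSums(sweep(H, 2, dxyz)^2))
      near <- which(dh <= 1.2 & hyd$unit == di$unit[i])
      if (length(near) == 0) next
      angs <- vapply(near, function(h) {
        hxyz <- c(hyd$x[h], hyd$y[h], hyd$z[h])
        v1 <- dxyz - hxyz; v2 <- axyz - hxyz
        rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))))
      }, numeric(1))
      ang_ok[i] <- any(angs >= params$angle_min)
    }
  }
  di <- di[ang_ok, ]; aj <- aj[ang_ok, ]; dist <- dist[ang_ok]
  tibble(
    donor_unit = di$unit, donor_serial = di$serial, donor_name = di$name,
    donor_resid = di$resid, donor_resname = di$resname,
    acceptor_unit = aj$unit, acceptor_serial = aj$serial,
    acceptor_name = aj$name, acceptor_resid = aj$resid,
    acceptor_resname = aj$resname,
    distance = dist,
    partner_kind = ifelse(di$unit == "protein" | aj$unit == "protein",
                          "protein-ligand", "ligand-ligand")
  ) |> dplyr::arrange(.data$donor_unit, .data$donor_serial,
                      .data$acceptor_unit, .data$acceptor_serial)
}

#' Hydrogen bonds between distinct ligand copies
#'
#' @inheritParams detect_hbonds
#' @return The [detect_hbonds()] tibble restricted to
#'   `partner_kind == "ligand-ligand"`.
#' @export
ligand_ligand_bonds <- function(cx, params = profiling_params()) {
  detect_hbonds(cx, params) |>
    dplyr::filter(.data$partner_kind == "ligand-ligand")
}

# min heavy-atom distance between every pair of ligand copies
ligand_pair_distances <- function(cx) {
  coords <- purrr::map(cx$ligand_poses, function(lp) {
    as.matrix(lp$atoms[lp$atoms$element != "H", c("x", "y", "z")])
  })
  n <- length(coords)
  out <- matrix(Inf, n, n)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), `+`) -
        2 * (coords[[i]] %*% t(coords[[j]]))
      out[i, j] <- out[j, i] <- sqrt(max(0, min(d2)))
    }
  }
  out
}

#' Find ligand clusters in a docked complex
#'
#' Builds a graph over ligand copies with an edge when a ligand-ligand
#' hydrogen bond exists or any heavy-atom pair lies within `contact_max`,
#' and reports connected components of size `>= min_size`, largest first.
#'
#' @inheritParams detect_hbonds
#' @return A tibble with one row per cluster: `cluster`, `size` and a
#'   `members` list-column of ligand copy ids. The contact edge list is
#'   attached as attribute `"edges"`.
#' @export
find_clusters <- function(cx, params = profiling_params()) {
  stopifnot(inherits(cx, "docked_complex"))
  ids <- vapply(cx$ligand_poses, `[[`, character(1), "ligand_id")
  n <- length(ids)
  empty <- tibble(cluster = integer(0), size = integer(0),
                  members = list())
  if (n == 0) return(empty)
  dmat <- ligand_pair_distances(cx)
  hb <- ligand_ligand_bonds(cx, params)
  edges <- tibble(from = character(0), to = character(0), type = character(0))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        contact <- dmat[i, j] <= params$contact_max
        hbond <- any((hb$donor_unit == ids[i] & hb$acceptor_unit == ids[j]) |
                       (hb$donor_unit == ids[j] & hb$acceptor_unit == ids[i]))
        if (contact || hbond) {
          edges <- dplyr::bind_rows(edges, tibble(
            from = ids[i], to = ids[j],
            type = if (hbond) "hbond" else "contact"))
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  keep <- which(sizes >= params$min_size)
  if (length(keep) == 0) {
    out <- empty
  } else {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    out <- tibble(
      cluster = seq_along(keep),
      size = sizes[keep],
      members = purrr::map(keep, function(k) {
        sort(names(comp$membership)[comp$membership == k])
      })
    )
  }
  attr(out, "edges") <- edges
  out
}

#' Full interaction profile of a complex as a JSON-ready list
#'
#' @inheritParams detect_hbonds
#' @return A list with `hbonds` (tibble), `clusters` (tibble) and the
#'   parameters used; serializable with [jsonlite::toJSON()].
#' @export
profile_complex <- function(cx, params = profiling_params()) {
  hb <- detect_hbonds(cx, params)
  cl <- find_clusters(cx, params)
  list(hbonds = hb, clusters = cl, params = unclass(params))
}
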