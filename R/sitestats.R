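# Region assignment of poses, background statistics of nonspecific surface
# binding, the 3-SD significance criterion, occupancy summaries and the
# group-comparison tests.

# ---- region assignment ------------------------------------------------------

region_category <- function(touched) {
  if (length(touched) == 0) return("nonspecific")
  if ("linker" %in% touched) {
    if (length(touched) > 1) "bridging" else "linker"
  } else {
    # non-linker annotated regions are pocket-class (CTD-side) sites
    "pocket"
  }
}

#' Assign a binding-site region label to a placed ligand
#'
#' A region is "touched" when any ligand heavy atom lies within
#' `contact_max` of any atom of a region residue (hydrogen bonds at the
#' default parameters always satisfy this contact criterion). Categories:
#' linker only -> "linker"; linker plus any other region -> "bridging";
#' non-linker regions only -> "pocket"; nothing touched -> "nonspecific".
#'
#' @param ligand_atoms Atom tibble of the placed ligand copy (or a `pose`).
#' @param model The `protein_model` the regions annotate.
#' @param regions Region tibble from [regions_from_spans()]/[read_regions()].
#' @param params [profiling_params()] (uses `contact_max`).
#' @return A list with `category` and `regions_touched`.
#' @export
assign_region <- function(ligand_atoms, model, regions,
                          params = profiling_params()) {
  if (inherits(ligand_atoms, "pose")) ligand_atoms <- ligand_atoms$atoms
  if (nrow(regions) == 0 || any(!nzchar(regions$region))) {
    stop("assign_region(): empty or unnamed regions")
  }
  validate_regions(model, regions)
  L <- as.matrix(ligand_atoms[ligand_atoms$element != "H",
                              c("x", "y", "z")])
  touched <- character(0)
  for (rg in unique(regions$region)) {
    rr <- regions[regions$region == rg, ]
    sel <- paste(model$atoms$chain, model$atoms$resid) %in%
      paste(rr$chain, rr$resid)
    if (!any(sel)) next
    R <- as.matrix(model$atoms[sel, c("x", "y", "z")])
    d2 <- outer(rowSums(R^2), rowSums(L^2), `+`) - 2 * (R %*% t(L))
    if (sqrt(max(0, min(d2))) <= params$contact_max) {
      touched <- c(touched, rg)
    }
  }
  list(category = region_category(touched), regions_touched = touched)
}

#' Label every round of one or more sequential runs
#'
#' The tidy entry point for region statistics: flattens runs into one record
#' per (model, round) with the predicted binding energy and its region
#' category.
#'
#' @param runs A `sequential_run` or list of them.
#' @param regions Region annotation tibble.
#' @param params [profiling_params()].
#' @return A tibble: model_id, time_label_ns, ligand_species, round,
#'   delta_g, category, regions_touched (list-column).
#' @export
label_rounds <- function(runs, regions, params = profiling_params()) {
  if (inherits(runs, "sequential_run")) runs <- list(runs)
  purrr::map(runs, function(run) {
    model <- run$final_complex$protein
    purrr::map(run$rounds, function(r) {
      lab <- assign_region(r$pose, model, regions, params)
      tibble(
        model_id = run$model_id, time_label_ns = run$time_label_ns,
        ligand_species = run$ligand_species, round = r$round_index,
        delta_g = r$delta_g, category = lab$category,
        regions_touched = list(lab$regions_touched))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

# ---- background statistics and significance ---------------------------------

#' Background statistics of nonspecific surface binding
#'
#' Pools the binding energies of all records labelled "nonspecific" (ligands
#' attached outside annotated linkers and pockets; bridging records are
#' also excluded) across the conformers of one protein-ligand pair, and
#' reports their mean, sample SD (n - 1 denominator) and count.
#'
#' @param records Labelled record tibble from [label_rounds()] (columns
#'   `delta_g`, `category`; optionally `ligand_species`).
#' @return A `dg_background` object with `mean`, `sd`, `n`,
#'   `ligand_species`.
#' @export
compute_background <- function(records) {
  bg <- records[records$category == "nonspecific", , drop = FALSE]
  if (nrow(bg) < 2) {
    stop("compute_background(): need at least 2 nonspecific records, got ",
         nrow(bg))
  }
  species <- if ("ligand_species" %in% names(records)) {
    paste(unique(bg$ligand_species), collapse = "+")
  } else NA_character_
  structure(
    list(mean = mean(bg$delta_g), sd = stats::sd(bg$delta_g),
         n = nrow(bg), ligand_species = species),
    class = "dg_background")
}

#' @export
print.dg_background <- function(x, ...) {
  cat(sprintf("<dg_background> %s: %.2f +/- %.2f kcal/mol (n = %d)\n",
              x$ligand_species, x$mean, x$sd, x$n))
  invisible(x)
}

#' Flag binding energies significantly stronger than the background
#'
#' A binding energy is significant when it is at least `k` standard
#' deviations stronger (more negative) than the nonspecific background
#' mean: `delta_g <= mean - k * sd`, boundary inclusive. With a degenerate
#' zero-SD background only strictly stronger energies are flagged.
#'
#' @param delta_g Numeric vector of binding energies (kcal/mol).
#' @param bg A `dg_background`.
#' @param k SD multiplier (default 3, the conventional p < 0.05 analog).
#' @return Logical vector.
#' @export
flag_significant <- function(delta_g, bg, k = 3) {
  stopifnot(inherits(bg, "dg_background"))
  if (bg$sd == 0) return(delta_g < bg$mean)
  delta_g <= bg$mean - k * bg$sd
}

#' Region occupancy over docking rounds
#'
#' Counts, per conformer, how many rounds were labelled with the region
#' category (bridging records count toward linker occupancy), and reports
#' the mean and sample SD over conformers — the "x.x +/- y.y molecules"
#' summary format.
#'
#' @param records Labelled record tibble from [label_rounds()].
#' @param region_name Category to count ("linker" or "pocket").
#' @return A one-row tibble: region, mean_count, sd_count, n_models.
#' @export
occupancy_summary <- function(records, region_name) {
  counts <- records |>
    dplyr::mutate(hit = .data$category == region_name |
                    (region_name == "linker" &
                       .data$category == "bridging")) |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(count = sum(.data$hit), .groups = "drop")
  tibble(
    region = region_name,
    mean_count = mean(counts$count),
    sd_count = if (nrow(counts) > 1) stats::sd(counts$count) else 0,
    n_models = nrow(counts))
}

# ---- hypothesis tests -------------------------------------------------------

new_ld_test <- function(statistic, p_value, method, n1, n2) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n1 = n1, n2 = n2),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat(sprintf("<ld_test> %s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))                       # midranks for ties
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a shift between two groups of binding energies. The
#' statistic is U of the first group with midrank ties. Exact mode
#' enumerates all C(n1+n2, n1) group labelings of the pooled sample and
#' reports the two-sided tail probability
#' P(|U - n1 n2 / 2| >= |u - n1 n2 / 2|); the normal approximation applies
#' the tie correction and a 0.5 continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param mode "exact" (requires n1 + n2 <= 12), "normal_approx", or "auto"
#'   (exact when feasible).
#' @return An `ld_test` with `statistic`, `p_value`, `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("mann_whitney(): empty group")
  if (mode == "auto") mode <- if (n1 + n2 <= 12) "exact" else "normal_approx"
  u <- mw_u_statistic(a, b)
  mu <- n1 * n2 / 2
  if (mode == "exact") {
    if (n1 + n2 > 12) stop("exact mode limited to n1 + n2 <= 12")
    pooled <- c(a, b)
    r <- rank(pooled)
    labelings <- utils::combn(n1 + n2, n1)
    u_all <- apply(labelings, 2, function(ix) {
      sum(r[ix]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    return(new_ld_test(u, p, "Mann-Whitney U (exact)", n1, n2))
  }
  n <- n1 + n2
  r <- rank(c(a, b))
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_corr))
  if (sigma == 0) {
    return(new_ld_test(u, 1, "Mann-Whitney U (normal approximation)", n1, n2))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_ld_test(u, p, "Mann-Whitney U (normal approximation)", n1, n2)
}

#' Shapiro-Wilk normality test
#'
#' Backed by the standard routine; used to decide whether pooled binding
#' energies can be compared parametrically (they typically cannot, hence
#' the Mann-Whitney default).
#'
#' @param values Numeric vector, 3 <= n <= 5000, not all equal.
#' @return An `ld_test` with W as the statistic.
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3) stop("normality_test(): need at least 3 values")
  if (n > 5000) stop("normality_test(): at most 5000 values supported")
  if (length(unique(values)) == 1) {
    stop("normality_test(): all values identical; W undefined")
  }
  sw <- stats::shapiro.test(values)
  new_ld_test(unname(sw$statistic), sw$p.value, "Shapiro-Wilk", n, 0L)
}

# ---- heat-map style export --------------------------------------------------

#' Heat-map table of a labelled record set
#'
#' Rows are docking rounds, columns are conformer time labels, and each
#' cell is "deltaG|category" with a trailing "*" for records flagged
#' significant against the nonspecific background (the bold analog).
#'
#' @param records Labelled record tibble from [label_rounds()] for one
#'   protein-ligand pair.
#' @param bg Optional `dg_background`; computed from `records` when NULL
#'   (requires >= 2 nonspecific records).
#' @param k SD multiplier for significance.
#' @return A tibble with a `round` column and one column per time label.
#' @export
heatmap_table <- function(records, bg = NULL, k = 3) {
  if (is.null(bg)) bg <- compute_background(records)
  records |>
    dplyr::mutate(
      sig = flag_significant(.data$delta_g, bg, k),
      cell = sprintf("%.2f|%s%s", .data$delta_g, .data$category,
                     ifelse(.data$sig, "|*", ""))) |>
    dplyr::select("round", "time_label_ns", "cell") |>
    dplyr::arrange(.data$time_label_ns) |>
    tidyr::pivot_wider(names_from = "time_label_ns",
                       values_from = "cell",
                       names_prefix = "t") |>
    dplyr::arrange(.data$round)
}
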