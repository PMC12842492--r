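# broom-style tidiers and ggplot2 visualisations for result objects

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text scale_fill_gradient labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.sequential_run <- function(x, ...) {
  purrr::map(x$rounds, function(r) {
    tibble(
      model_id = x$model_id, time_label_ns = x$time_label_ns,
      ligand_species = x$ligand_species, round = r$round_index,
      ligand_id = r$ligand_id, delta_g = r$delta_g)
  }) |> dplyr::bind_rows()
}

#' @exportS3Method generics::glance
glance.sequential_run <- function(x, ...) {
  dg <- vapply(x$rounds, function(r) r$delta_g, numeric(1))
  tibble(
    model_id = x$model_id, time_label_ns = x$time_label_ns,
    ligand_species = x$ligand_species, n_rounds = length(x$rounds),
    best_delta_g = min(dg), mean_delta_g = mean(dg),
    n_retained = x$n_initial)
}

#' @exportS3Method generics::tidy
tidy.ld_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' @exportS3Method generics::glance
glance.ld_test <- function(x, ...) tidy(x)

#' @exportS3Method generics::tidy
tidy.dg_background <- function(x, ...) {
  tibble(ligand_species = x$ligand_species, mean = x$mean, sd = x$sd,
         n = x$n)
}

#' @exportS3Method generics::tidy
tidy.alignment_result <- function(x, ...) {
  tibble(score = x$score, identity_fraction = x$identity_fraction,
         alignment_length = nchar(x$aligned_a))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rmsd_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$time_label_ns, y = .data$rmsd)) +
    geom_line() +
    geom_point() +
    labs(x = "time (ns)", y = "RMSD (Å)",
         title = "Conformer ensemble RMSD profile") +
    theme_minimal()
}

#' Heat-map plot of labelled docking rounds
#'
#' Tiles are (conformer time label x round) cells coloured by predicted
#' binding energy; significant binders are marked with an asterisk and the
#' region category is printed in each cell.
#'
#' @param records Labelled record tibble from [label_rounds()].
#' @param bg Optional `dg_background` for significance stars.
#' @param k SD multiplier for significance.
#' @return A ggplot object.
#' @export
plot_dg_heatmap <- function(records, bg = NULL, k = 3) {
  if (is.null(bg)) {
    bg <- tryCatch(compute_background(records), error = function(e) NULL)
  }
  df <- records
  df$sig <- if (!is.null(bg)) flag_significant(df$delta_g, bg, k) else FALSE
  df$label <- paste0(substr(df$category, 1, 1), ifelse(df$sig, "*", ""))
  ggplot(df, aes(x = factor(.data$time_label_ns), y = factor(.data$round),
                 fill = .data$delta_g)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient(low = "firebrick", high = "lightyellow",
                        name = expression(Delta * G ~ "(kcal/mol)")) +
    labs(x = "conformer time label (ns)", y = "docking round",
         title = "Sequential docking heat map") +
    theme_minimal()
}
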