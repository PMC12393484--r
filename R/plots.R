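#' Plot a brightness map
#'
#' Renders the per-pixel apparent brightness (and optionally the mean
#' intensity) as a raster.
#'
#' @param object a [brightness_map].
#' @param layer `"B"`, `"mean_F"`, `"var_F"` or `"n_apparent"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot brightness_map
#' @export
autoplot.brightness_map <- function(object, layer = "B", ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data[[layer]])) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey80") +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = layer,
         title = sprintf("Apparent %s map", layer)) +
    theme_minimal()
}

#' Plot an oligomeric-state class map
#'
#' @param object an `oligomer_fractions` result from [classify_pixels].
#' @param ... unused.
#' @return A ggplot raster of the pixel classes.
#' @method autoplot oligomer_fractions
#' @export
autoplot.oligomer_fractions <- function(object, ...) {
  cm <- object$class_map
  lv <- c("background", "monomer", "dimer", "oligomer")
  df <- tibble(
    row = rep(seq_len(nrow(cm)), ncol(cm)),
    col = rep(seq_len(ncol(cm)), each = nrow(cm)),
    class = factor(lv[as.vector(cm)], levels = lv)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$class)) +
    geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(background = "grey85", monomer = "#1b7837",
                 dimer = "#a6dba0", oligomer = "#d73027"),
      na.value = "white", drop = FALSE) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "state",
         title = "Oligomeric-state map") +
    theme_minimal()
}

#' Plot a diffusion (mobility) profile
#'
#' Histogram/density of per-trajectory log10 diffusion coefficients with
#' the confined/non-confined threshold marked.
#'
#' @param d_table output of [diffusion_coefficients].
#' @param threshold optional threshold from [mobility_threshold].
#' @return A ggplot.
#' @export
plot_mobility_profile <- function(d_table, threshold = NULL) {
  p <- ggplot(d_table, aes(x = .data$log10_D)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    labs(x = expression(log[10] ~ D ~ (mu * m^2 / s)), y = "density",
         title = "Diffusion profile") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = as.numeric(threshold),
                        linetype = "dashed")
  }
  p
}

#' @rdname residence_analysis
#' @param object a `residence_fit`.
#' @method autoplot residence_fit
#' @export
autoplot.residence_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$survival, c("S", "S_fit"),
                            names_to = "curve", values_to = "survival")
  df$curve <- ifelse(df$curve == "S", "Kaplan-Meier", "two-exponential fit")
  ggplot(df, aes(x = .data$t, y = .data$survival, colour = .data$curve)) +
    geom_step(data = ~ dplyr::filter(.x, .data$curve == "Kaplan-Meier")) +
    geom_line(data = ~ dplyr::filter(.x, .data$curve != "Kaplan-Meier")) +
    ggplot2::scale_y_log10() +
    labs(x = "dwell time (s)", y = "survival S(t)", colour = NULL,
         title = "Residence-time survival") +
    theme_minimal()
}

#' @rdname fit_classify
#' @param object a `miel_fit`.
#' @method autoplot miel_fit
#' @export
autoplot.miel_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$predicted, y = .data$true,
                 fill = .data$percent)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f", .data$percent)), size = 3) +
    scale_fill_gradient(low = "white", high = "#2166ac", limits = c(0, 100)) +
    labs(x = "predicted", y = "true", fill = "%",
         title = sprintf("Confusion matrix (accuracy %.1f%%)",
                         100 * object$report$accuracy)) +
    theme_minimal()
}

#' @rdname bootstrap_condensation
#' @param object a `bootstrap_report`.
#' @method autoplot bootstrap_report
#' @export
autoplot.bootstrap_report <- function(object, ...) {
  ggplot(object$summary,
         aes(x = factor(.data$candidate_n), y = .data$frac_pass)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = object$settings$success_quantile,
               linetype = "dashed") +
    labs(x = "condensation number n",
         y = sprintf("fraction of iterations with accuracy >= %g",
                     object$settings$accuracy_criterion),
         title = "Bootstrap optimization of the condensation number") +
    theme_minimal()
}
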