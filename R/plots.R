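# 24-h activity visualisations built from ensemble-averaged postures.

posture_fill_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(reclining = "#4575b4", sitting_or_standing = "#fdae61",
               walking = "#d73027"),
    breaks = posture_levels(), name = "posture")
}

epoch_hours <- function(grid) {
  ((seq_len(grid$epochs_per_day) - 1) * grid$epoch_length) / 3600
}

#' Population 24-h posture pattern
#'
#' Stacked time-of-day curves of the population ratio of each posture:
#' at each epoch the fraction of input series showing that posture, where
#' 1 represents the total number of measurements (so missing data leave
#' the stack below 1).
#'
#' @param days list of [posture_day()] objects (e.g. hard-label views of
#'   per-subject ensembles via [hard_labels()]).
#' @param file optional output image path (png/svg/pdf by extension); if
#'   `NULL` the ggplot object is returned unwritten.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_population_24h <- function(days, file = NULL, width = 8, height = 4) {
  if (!length(days)) stop("no input series", call. = FALSE)
  stopifnot(all(vapply(days, inherits, logical(1), "posture_day")))
  grid <- days[[1]]$grid
  lab <- vapply(days, function(d) d$labels, character(grid$epochs_per_day))
  lab <- matrix(lab, nrow = grid$epochs_per_day)
  n <- length(days)
  df <- do.call(rbind, lapply(posture_levels(), function(l)
    data.frame(hour = epoch_hours(grid), posture = l,
               ratio = rowSums(lab == l) / n)))
  df$posture <- factor(df$posture, levels = rev(posture_levels()))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$ratio,
                                        fill = .data$posture)) +
    ggplot2::geom_area(position = "stack") +
    posture_fill_scale() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4),
                                labels = sprintf("%d:00", seq(0, 24, 4)),
                                expand = c(0, 0)) +
    ggplot2::scale_y_continuous(limits = c(0, 1), expand = c(0, 0)) +
    ggplot2::labs(x = "time of day", y = "population ratio") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' Per-week 24-h posture panels with totals
#'
#' For a series of weekly ensembles of one subject, draws stacked 24-h
#' posture-period panels (one per week) and a companion bar chart of the
#' total-period ratios per week.
#'
#' @param ensembles named list of [ensemble_categorical()] results, one
#'   per week (names used as panel titles).
#' @param file optional output image path.
#' @param width,height device size in inches.
#' @return list with ggplot components `panels` and `totals`, invisibly
#'   when written to file.
#' @export
plot_individual_weeks <- function(ensembles, file = NULL,
                                  width = 9, height = 6) {
  if (!length(ensembles)) stop("no input ensembles", call. = FALSE)
  stopifnot(all(vapply(ensembles, inherits, logical(1),
                       "categorical_ensemble")))
  if (is.null(names(ensembles)))
    names(ensembles) <- paste("week", seq_along(ensembles))
  grid <- attr(ensembles[[1]], "grid")
  mins <- grid$epoch_length / 60
  long <- do.call(rbind, lapply(names(ensembles), function(w) {
    e <- ensembles[[w]]
    do.call(rbind, lapply(posture_levels(), function(l)
      data.frame(week = w, hour = epoch_hours(grid), posture = l,
                 frac = ifelse(is.na(e[[paste0("p_", l)]]), 0,
                               e[[paste0("p_", l)]] / mins))))
  }))
  long$posture <- factor(long$posture, levels = rev(posture_levels()))
  long$week <- factor(long$week, levels = names(ensembles))
  panels <- ggplot2::ggplot(long, ggplot2::aes(x = .data$hour,
                                               y = .data$frac,
                                               fill = .data$posture)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~week) +
    posture_fill_scale() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6),
                                labels = sprintf("%d:00", seq(0, 24, 6)),
                                expand = c(0, 0)) +
    ggplot2::scale_y_continuous(limits = c(0, 1), expand = c(0, 0)) +
    ggplot2::labs(x = "time of day", y = "posture period fraction") +
    ggplot2::theme_minimal()
  tot <- do.call(rbind, lapply(names(ensembles), function(w)
    cbind(week = w, total_periods(ensembles[[w]]))))
  tot$week <- factor(tot$week, levels = names(ensembles))
  tot$posture <- factor(tot$posture, levels = rev(posture_levels()))
  totals <- ggplot2::ggplot(tot, ggplot2::aes(x = .data$week,
                                              y = .data$ratio,
                                              fill = .data$posture)) +
    ggplot2::geom_col(position = "stack") +
    posture_fill_scale() +
    ggplot2::labs(x = NULL, y = "ratio of total period") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                  pdf = grDevices::pdf,
                  stop("unsupported figure format: ", ext, call. = FALSE))
    if (ext == "png") dev(file, width = width, height = height,
                          units = "in", res = 150)
    else dev(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    # week panels on top, totals bar below
    print(panels + ggplot2::theme(legend.position = "none"),
          vp = grid::viewport(y = 0.65, height = 0.7))
    print(totals, vp = grid::viewport(y = 0.15, height = 0.3))
    return(invisible(list(panels = panels, totals = totals)))
  }
  list(panels = panels, totals = totals)
}
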