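SUBGROUP_COLORS <- c(
  "C_C" = "#08306b",  # strong cooperators, dark blue
  "C_D" = "#6baed6",  # weak cooperators, light blue
  "D_D" = "#67000d",  # strong defectors, dark red
  "D_C" = "#fb6a4a"   # weak defectors, light red
)

#' Plot a lattice snapshot
#'
#' Renders the strategy grid as colored tiles.  When a [memory_config()] is
#' supplied and the state carries a strategy history, sites are colored by
#' weak/strong subgroup: dark (strong) and light (weak) blue for
#' cooperators, dark and light red for defectors; otherwise plain
#' blue/red by strategy.
#'
#' @param state A `lattice_state`.
#' @param mem Optional [memory_config()] enabling subgroup coloring.
#' @return A ggplot object.
#' @export
plot_lattice <- function(state, mem = NULL) {
  dat <- as_tibble(state)
  if (!is.null(mem)) {
    L <- state$L
    dat$fill <- vapply(seq_len(nrow(dat)), function(k) {
      classify_subgroup(state, c(dat$row[k], dat$col[k]), mem)
    }, character(1))
    cols <- SUBGROUP_COLORS
  } else {
    dat$fill <- dat$strategy
    cols <- c(C = "#08306b", D = "#67000d")
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a cooperator-fraction trajectory
#'
#' @param run A `game_run`.
#' @return A ggplot object of `rho_C` versus MCS.
#' @export
plot_trajectory <- function(run) {
  ggplot2::ggplot(tidy(run), ggplot2::aes(x = .data$mcs, y = .data$rho_c)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Monte Carlo steps", y = expression(rho[C])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot invasion rates between subgroups
#'
#' @param invasion A tibble from [run_invasion()] (or a ledger with a
#'   `count` column, which is renamed).
#' @param channels Channels to show; defaults to all 8.
#' @return A ggplot object of per-MCS rates by channel.
#' @export
plot_ledger <- function(invasion, channels = NULL) {
  if ("count" %in% names(invasion) && !"rate" %in% names(invasion))
    invasion <- dplyr::rename(invasion, rate = "count")
  if (!is.null(channels))
    invasion <- dplyr::filter(invasion, .data$channel %in% !!channels)
  ggplot2::ggplot(invasion, ggplot2::aes(x = .data$mcs, y = .data$rate,
                                         color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Monte Carlo steps", y = "successful adoptions / MCS") +
    ggplot2::theme_minimal()
}

#' Heat map of a T-S sweep
#'
#' Tiles the `(T, S)` plane with the replicate-mean stationary cooperator
#' fraction, faceted by memory parameter when several were swept.
#'
#' @param object A `mem_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mem_sweep <- function(object, ...) {
  par_col <- if (object$variant[1] == "averaged") "alpha" else "tau"
  cells <- dplyr::summarise(
    dplyr::group_by(object, .data$T, .data$S,
                    par = .data[[par_col]]),
    rho = mean(.data$rho_c), .groups = "drop")
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$T, y = .data$S,
                                           fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(rho[C]),
                                  limits = c(0, 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::theme_minimal()
  if (length(unique(cells$par)) > 1)
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$par))
  p
}
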