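#' Plotting helpers
#'
#' ggplot2-based views of states and trajectories: a tile map of the grid
#' (cells colored by id or type), the cell-count time series, and per-cell
#' protein dynamics.
#'
#' @name plotting
NULL

state_tiles <- function(space, state) {
  if (length(space$dims) != 2L) {
    rlang::abort("tile plots support 2D spaces only.", class = "cpm_io_error")
  }
  type_by_id <- integer(max(1L, state$table$id))
  type_by_id[state$table$id] <- state$table$type_index
  names_by_idx <- unique(state$table$type_name[order(state$table$type_index)])
  id <- state$cell_id
  tibble::tibble(
    row = space$coords[, 1],
    col = space$coords[, 2],
    cell = id,
    type = ifelse(id > 0L, names_by_idx[type_by_id[pmax(id, 1L)]], "medium")
  )
}

#' Tile map of a state
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param color_by `"id"` (each cell its own color) or `"type"`.
#' @return A ggplot object.
#' @export
plot_state <- function(space, state, color_by = c("id", "type")) {
  color_by <- match.arg(color_by)
  df <- state_tiles(space, state)
  df$fill <- if (color_by == "id") factor(df$cell) else df$type
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$fill)) +
    ggplot2::geom_tile(show.legend = color_by == "type") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = color_by) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile map of a recorded trajectory at one MCS
#'
#' @param object a `cpm_history`.
#' @param mcs MCS to draw (default: final).
#' @param color_by `"id"` or `"type"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cpm_history <- function(object, mcs = NULL, color_by = "id", ...) {
  if (is.null(mcs)) mcs <- object$n_mcs
  plot_state(object$space, reconstruct(object, mcs), color_by = color_by) +
    ggplot2::ggtitle(paste0("MCS ", mcs))
}

#' Cell count over time
#'
#' @param history a `cpm_history`.
#' @return A ggplot object.
#' @export
plot_cell_count <- function(history) {
  ggplot2::ggplot(history$summary, ggplot2::aes(x = .data$mcs, y = .data$n_cells)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "MCS", y = "cells") +
    ggplot2::theme_minimal()
}

#' Per-cell protein dynamics
#'
#' @param history a `cpm_history` recorded with `record_ode = TRUE`.
#' @param component ODE component column to draw (default first).
#' @param cells optional cell ids to restrict to.
#' @return A ggplot object.
#' @export
plot_protein <- function(history, component = "X1", cells = NULL) {
  tr <- history$ode_trace
  if (is.null(tr)) {
    rlang::abort("this history has no recorded ODE trace.", class = "cpm_io_error")
  }
  if (!is.null(cells)) tr <- dplyr::filter(tr, .data$cell_id %in% cells)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data[[component]],
                                   group = .data$cell_id,
                                   color = factor(.data$cell_id))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time", y = component) +
    ggplot2::theme_minimal()
}
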