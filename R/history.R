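#' Delta-compressed trajectories
#'
#' A `cpm_history` stores a full initial snapshot (grid + cell table) and,
#' per MCS, only the accepted flips (node, old id, new id) and discrete
#' events (division, death), plus periodic full checkpoints. Any past state
#' is reconstructed bit-exactly by replaying deltas forward from the nearest
#' prior checkpoint; storage grows with the number of accepted flips, not
#' with duration times grid size.
#'
#' @name cpm_history
NULL

new_history <- function(model, state, checkpoint_every) {
  structure(list(
    space = model$space,
    model = model,
    initial = list(cell_id = state$cell_id, table = state$table),
    deltas = list(),
    events = list(),
    checkpoints = list(),
    summary = list(),
    ode_trace = list(),
    checkpoint_every = as.integer(checkpoint_every),
    n_mcs = 0L,
    final_state = NULL,
    final_intracellular = NULL
  ), class = "cpm_history")
}

finalize_history <- function(hist) {
  hist$summary <- dplyr::bind_rows(hist$summary)
  hist$ode_trace <- if (length(hist$ode_trace)) dplyr::bind_rows(hist$ode_trace) else NULL
  hist
}

#' @export
print.cpm_history <- function(x, ...) {
  n_flips <- sum(vapply(x$deltas, nrow, integer(1)))
  n_events <- sum(lengths(x$events))
  cat("<cpm_history> ", x$n_mcs, " MCS, ", n_flips, " accepted flips, ",
      n_events, " events, ", length(x$checkpoints), " checkpoints\n", sep = "")
  invisible(x)
}

# apply one MCS worth of deltas and events to (cell_id, table)
replay_mcs <- function(cell_id, table, deltas, events) {
  if (nrow(deltas)) cell_id[deltas[, 1L]] <- deltas[, 3L]
  for (ev in events) {
    if (ev$kind == "division") {
      cell_id[unlist(ev$daughter_nodes)] <- ev$daughter
      row <- match(ev$parent, table$id)
      for (nm in names(ev$parent_props)) table[row, nm] <- ev$parent_props[[nm]]
      table <- dplyr::bind_rows(table, tibble::as_tibble(ev$daughter_row))
    } else if (ev$kind == "death") {
      cell_id[unlist(ev$nodes)] <- 0L
      table <- table[table$id != ev$id, ]
    }
  }
  list(cell_id = cell_id, table = table)
}

#' Reconstruct a past state
#'
#' Starts from the nearest prior checkpoint (or the initial snapshot) and
#' replays deltas and events forward.
#'
#' @param history a `cpm_history`.
#' @param mcs Monte Carlo step to reconstruct, between 0 and the recorded
#'   length.
#' @return A [cpm_state] (including the cell table) identical to what the
#'   live simulation held at that MCS.
#' @export
reconstruct <- function(history, mcs) {
  if (mcs < 0L || mcs > history$n_mcs) {
    rlang::abort(paste0("`mcs` must be in [0, ", history$n_mcs, "]."),
                 class = "cpm_range_error")
  }
  cps <- as.integer(names(history$checkpoints))
  cps <- cps[cps <= mcs]
  if (length(cps)) {
    from <- max(cps)
    snap <- history$checkpoints[[as.character(from)]]
  } else {
    from <- 0L
    snap <- history$initial
  }
  cell_id <- as.integer(snap$cell_id)
  table <- validate_cell_table(snap$table)
  for (m in seq_len(mcs - from) + from) {
    step <- replay_mcs(cell_id, table, history$deltas[[m]], history$events[[m]])
    cell_id <- step$cell_id
    table <- step$table
  }
  recompute_statistics(history$space, new_cpm_state(cell_id, table))
}

#' Per-MCS summary time series
#'
#' @param history a `cpm_history`.
#' @param path optional CSV path to write the table to.
#' @return A tibble with one row per MCS: cell count, accepted/vetoed flip
#'   counts, boundary lengths (interaction-order edges between differing ids
#'   and between differing nonzero types), and per-type mean volumes. The
#'   per-cell ODE trace, if recorded, is attached as attribute `"ode_trace"`.
#' @export
export_summary <- function(history, path = NULL) {
  out <- history$summary
  if (!is.null(history$ode_trace)) attr(out, "ode_trace") <- history$ode_trace
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname export_summary
#' @param x a `cpm_history`.
#' @param ... unused.
#' @export
tidy.cpm_history <- function(x, ...) x$summary

#' One-row run summary
#'
#' @param x a `cpm_history`.
#' @param ... unused.
#' @return A tibble with the run length, final cell count, total accepted and
#'   vetoed flips, and final boundary lengths.
#' @export
glance.cpm_history <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_mcs = x$n_mcs,
    n_cells = utils::tail(s$n_cells, 1L),
    total_accepted = sum(s$accepted),
    total_vetoed = sum(s$vetoed),
    boundary_total = utils::tail(s$boundary_total, 1L),
    boundary_hetero_type = utils::tail(s$boundary_hetero_type, 1L),
    n_divisions = sum(vapply(x$events, function(evs) {
      sum(vapply(evs, function(e) e$kind == "division", logical(1)))
    }, numeric(1)))
  )
}

#' Export a grid frame
#'
#' Writes the cell-id grid at one MCS as CSV (raw ids) or PNG (ids mapped to
#' colors deterministically; medium is black).
#'
#' @param history a `cpm_history`.
#' @param mcs MCS to export.
#' @param path output path ending in `.csv` or `.png`.
#' @return The path, invisibly.
#' @export
export_frame <- function(history, mcs, path) {
  state <- reconstruct(history, mcs)
  arr <- state_as_array(history$space, state)
  if (length(dim(arr)) != 2L) {
    rlang::abort("frame export supports 2D spaces only.", class = "cpm_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(arr, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (ext == "png") {
    img <- array(0, c(nrow(arr), ncol(arr), 3L))
    ids <- arr
    ids[is.na(ids)] <- 0L
    golden <- (sqrt(5) - 1) / 2 # id -> hue, deterministic and well spread
    hue <- (ids * golden) %% 1
    on <- ids > 0L
    rgb <- grDevices::hsv(hue, 0.65, 0.95)
    for (ch in 1:3) {
      plane <- matrix(0, nrow(arr), ncol(arr))
      plane[on] <- grDevices::col2rgb(rgb[on])[ch, ] / 255
      img[, , ch] <- plane
    }
    png::writePNG(img, path)
  } else {
    rlang::abort(paste0("unsupported frame format: .", ext), class = "cpm_io_error")
  }
  invisible(path)
}

history_file_magic <- "graphcpm-history"
history_file_version <- 1L

#' Save / load a recorded trajectory
#'
#' The history is stored as a single versioned JSON container holding the
#' model specification, the initial snapshot, the per-MCS delta stream and
#' event records, checkpoints, and the summary time series. Reconstruction
#' from the loaded file is bit-exact.
#'
#' @param history a `cpm_history`.
#' @param path file path.
#' @return `save_history` returns the path invisibly; `load_history` the
#'   history.
#' @export
save_history <- function(history, path) {
  payload <- list(
    format = history_file_magic,
    version = history_file_version,
    model = serialize_model(history$model),
    initial = list(cell_id = history$initial$cell_id,
                   table = history$initial$table),
    deltas = lapply(history$deltas, function(m) if (nrow(m)) unclass(m) else NULL),
    events = history$events,
    checkpoints = lapply(history$checkpoints, function(cp)
      list(cell_id = cp$cell_id, table = cp$table)),
    summary = history$summary,
    ode_trace = history$ode_trace,
    checkpoint_every = history$checkpoint_every,
    n_mcs = history$n_mcs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_history
#' @export
load_history <- function(path) {
  payload <- tryCatch(suppressWarnings(jsonlite::read_json(path, simplifyVector = FALSE)),
                      error = function(e) {
    rlang::abort(paste0("cannot read history file: ", conditionMessage(e)),
                 class = "cpm_load_error")
  })
  if (!identical(payload$format, history_file_magic)) {
    rlang::abort("not a history file (magic string mismatch).", class = "cpm_load_error")
  }
  if (!identical(as.integer(payload$version), history_file_version)) {
    rlang::abort(paste0("unsupported history version ", payload$version, "."),
                 class = "cpm_load_error")
  }
  model <- deserialize_model(payload$model)
  table <- json_table(payload$initial$table)
  state <- new_cpm_state(unlist_int(payload$initial$cell_id), table)
  hist <- new_history(model, state, as.integer(payload$checkpoint_every))
  hist$deltas <- lapply(payload$deltas, json_delta_matrix)
  hist$events <- lapply(payload$events, function(evs) lapply(evs, json_event))
  hist$checkpoints <- lapply(payload$checkpoints, function(cp)
    list(cell_id = unlist_int(cp$cell_id), table = json_table(cp$table)))
  hist$summary <- dplyr::bind_rows(lapply(payload$summary, tibble::as_tibble))
  hist$ode_trace <- if (is.null(payload$ode_trace)) NULL else
    dplyr::bind_rows(lapply(payload$ode_trace, tibble::as_tibble))
  hist$n_mcs <- as.integer(payload$n_mcs)
  hist$final_state <- reconstruct(hist, hist$n_mcs)
  hist
}

unlist_int <- function(x) as.integer(unlist(x))

# JSON loses the matrix shape: rebuild an n x 3 integer matrix from nested rows
json_delta_matrix <- function(rows) {
  if (is.null(rows) || !length(rows)) return(matrix(integer(0), 0, 3))
  do.call(rbind, lapply(rows, unlist_int))
}

json_table <- function(rows) {
  tab <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  for (col in c("id", "type_index", "target_volume", "target_perimeter",
                "x", "y", "z")) {
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  }
  validate_cell_table(tab)
}

json_event <- function(ev) {
  if (!is.null(ev$parent)) ev$parent <- as.integer(ev$parent)
  if (!is.null(ev$daughter)) ev$daughter <- as.integer(ev$daughter)
  if (!is.null(ev$daughter_nodes)) ev$daughter_nodes <- unlist_int(ev$daughter_nodes)
  if (!is.null(ev$nodes)) ev$nodes <- unlist_int(ev$nodes)
  if (!is.null(ev$id)) ev$id <- as.integer(ev$id)
  if (!is.null(ev$daughter_row)) {
    row <- lapply(ev$daughter_row, function(v) if (is.null(v)) NA else unlist(v))
    for (col in c("id", "type_index", "target_volume", "target_perimeter",
                  "x", "y", "z")) {
      if (col %in% names(row)) row[[col]] <- as.integer(row[[col]])
    }
    ev$daughter_row <- row
  }
  if (!is.null(ev$parent_props)) {
    ev$parent_props <- lapply(ev$parent_props, function(v)
      if (is.null(v)) NA_real_ else as.numeric(unlist(v)))
  }
  ev
}
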