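#' Lattice state: the integer grid plus cached per-cell statistics
#'
#' A `cpm_state` holds the per-node cell identifier (`cell_id`, 0 = medium),
#' cached per-cell statistics (`volume` = node count, `perimeter` = count of
#' interaction-order edges from the cell's nodes to nodes of any other id),
#' per-node protrusive activity (used by the migration penalty), and the cell
#' table. Cached statistics are maintained incrementally by the engine and can
#' always be checked against [recompute_statistics()].
#'
#' @name cpm_state
NULL

new_cpm_state <- function(cell_id, table, activity = NULL) {
  max_id <- max(0L, table$id)
  st <- structure(
    list(
      cell_id = as.integer(cell_id),
      volume = integer(max_id),
      perimeter = integer(max_id),
      activity = if (is.null(activity)) numeric(length(cell_id)) else activity,
      table = table
    ),
    class = "cpm_state"
  )
  st
}

# 0-based offsets of a "most-square" block of v sites: sites are filled
# row-major inside a side^d bounding box, so every prefix is connected under
# the von Neumann order.
block_offsets <- function(v, ndim) {
  side <- ceiling(v^(1 / ndim))
  # guard against numeric fuzz in the root, e.g. 27^(1/3) = 3 - eps
  while ((side - 1L)^ndim >= v) side <- side - 1L
  coords <- rowmajor_coords(rep(as.integer(side), ndim))
  coords[seq_len(v), , drop = FALSE]
}

#' Place cells on a space
#'
#' Each cell initially occupies a connected, most-square block of exactly its
#' target volume. Cells with an explicit anchor position are placed there
#' (block corner at the anchor); the rest are placed at random non-overlapping
#' anchors by rejection sampling with a bounded number of retries.
#'
#' @param space a [cpm_space].
#' @param table a cell table from [cell_table()].
#' @param seed optional integer seed; if supplied the R RNG is seeded before
#'   placement so the initial state is reproducible.
#' @param max_tries retries per randomly placed cell before a crowding error.
#' @return A `cpm_state` with consistent cached statistics.
#' @examples
#' sp <- cpm_space(c(10, 10), periodic = FALSE)
#' st <- initialize_cells(sp, cell_table("A", 2, target_volume = 9), seed = 1)
#' state_summary(sp, st)
#' @export
initialize_cells <- function(space, table, seed = NULL, max_tries = 10000L) {
  table <- validate_cell_table(table)
  if (sum(table$target_volume) > space$n_nodes) {
    rlang::abort("total requested volume exceeds the number of lattice sites.",
                 class = "cpm_crowding_error")
  }
  if (!is.null(seed)) set.seed(seed)
  nd <- length(space$dims)
  cell_id <- integer(space$n_nodes)

  place <- function(row) {
    offs <- block_offsets(row$target_volume, nd)
    anchor_cols <- c("x", "y", "z")[seq_len(nd)]
    if (!is.na(row$x)) {
      anchor <- as.integer(unlist(row[anchor_cols]))
      if (anyNA(anchor)) {
        rlang::abort("anchor position must give every coordinate.",
                     class = "cpm_placement_conflict")
      }
      nodes <- coord_to_node(space, sweep(offs, 2L, anchor, "+"))
      if (any(nodes == 0L) || any(cell_id[nodes] != 0L) || anyDuplicated(nodes)) {
        rlang::abort(
          paste0("cell ", row$id, " cannot be placed at its anchor (outside the ",
                 "domain or overlapping another cell)."),
          class = "cpm_placement_conflict")
      }
      return(nodes)
    }
    for (try in seq_len(max_tries)) {
      anchor <- vapply(space$dims, function(d) sample.int(d, 1L) - 1L, integer(1))
      nodes <- coord_to_node(space, sweep(offs, 2L, anchor, "+"))
      if (all(nodes > 0L) && !any(cell_id[nodes] != 0L) && !anyDuplicated(nodes)) {
        return(nodes)
      }
    }
    rlang::abort(
      paste0("no room for cell ", row$id, " after ", max_tries, " placement tries."),
      class = "cpm_crowding_error")
  }

  for (i in seq_len(nrow(table))) {
    nodes <- place(table[i, ])
    cell_id[nodes] <- table$id[i]
  }
  recompute_statistics(space, new_cpm_state(cell_id, table))
}

#' Recompute cached statistics from scratch
#'
#' Rebuilds `volume` and `perimeter` directly from the grid; the engine keeps
#' them incrementally, and this function is the ground truth they are audited
#' against.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @return The state with `volume` and `perimeter` recomputed.
#' @export
recompute_statistics <- function(space, state) {
  max_id <- max(0L, state$table$id, state$cell_id)
  state$volume <- tabulate(state$cell_id, nbins = max_id)
  deg <- diff(space$int_ptr)
  u <- rep.int(seq_len(space$n_nodes), deg)
  cu <- state$cell_id[u]
  cv <- state$cell_id[space$int_idx]
  het <- cu != cv & cu > 0L
  state$perimeter <- tabulate(cu[het], nbins = max_id)
  state
}

# total boundary edges between differing ids / differing nonzero types
boundary_lengths <- function(space, state) {
  deg <- diff(space$int_ptr)
  u <- rep.int(seq_len(space$n_nodes), deg)
  cu <- state$cell_id[u]
  cv <- state$cell_id[space$int_idx]
  type_of <- integer(max(1L, state$table$id))
  type_of[state$table$id] <- state$table$type_index
  tu <- ifelse(cu > 0L, type_of[pmax(cu, 1L)], 0L)
  tv <- ifelse(cv > 0L, type_of[pmax(cv, 1L)], 0L)
  c(
    total = sum(cu != cv) / 2,
    hetero_type = sum(cu > 0L & cv > 0L & tu != tv) / 2
  )
}

#' One-row summary of a state
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @return A tibble with cell count, per-type mean volume (one column per
#'   type, `mean_volume_<type>`), and boundary lengths (interaction-order
#'   edges between differing cell ids, and between differing nonzero types).
#' @export
state_summary <- function(space, state) {
  tab <- state$table
  bl <- boundary_lengths(space, state)
  out <- tibble::tibble(
    n_cells = nrow(tab),
    boundary_total = bl[["total"]],
    boundary_hetero_type = bl[["hetero_type"]]
  )
  if (nrow(tab)) {
    mv <- tapply(state$volume[tab$id], tab$type_name, mean)
    for (ty in names(mv)) out[[paste0("mean_volume_", ty)]] <- unname(mv[ty])
  }
  out
}

#' @export
print.cpm_state <- function(x, ...) {
  occ <- sum(x$cell_id > 0L)
  cat("<cpm_state> ", nrow(x$table), " cells on ", length(x$cell_id),
      " nodes (", occ, " occupied)\n", sep = "")
  invisible(x)
}

#' Grid of cell ids as a matrix or array
#'
#' Mask-domain sites outside the domain are `NA`.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @return An integer matrix (2D) or array (3D) in row-major layout: first
#'   coordinate = row.
#' @export
state_as_array <- function(space, state) {
  full <- rep(NA_integer_, prod(space$dims))
  if (is.null(space$node_lookup)) {
    full <- state$cell_id
  } else {
    full[space$node_lookup > 0L] <- state$cell_id[space$node_lookup[space$node_lookup > 0L]]
  }
  # stored row-major; aperm from column-major fill of reversed dims
  aperm(array(full, dim = rev(space$dims)), rev(seq_along(space$dims)))
}
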