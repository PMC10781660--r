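#' Simulation spaces as graphs
#'
#' A `cpm_space` encodes the simulation domain as an undirected graph. Nodes
#' are lattice sites; edges are stored twice, once at the *connectivity* order
#' (which decides what "a connected cell" means, default von Neumann /
#' 6-neighborhood in 3D) and once at the *interaction* order (which node pairs
#' enter the adhesion and perimeter sums, default Moore / 26-neighborhood).
#' Periodic boundaries are realised purely as extra edges joining opposite
#' faces, so every downstream algorithm (guards, partitioning, statistics) is
#' independent of the domain geometry.
#'
#' Adjacency is held in compressed sparse row form: the neighbors of node `i`
#' under the connectivity order are `conn_idx[conn_ptr[i]:(conn_ptr[i+1]-1)]`.
#' Node ids are 1-based; coordinates are 0-based row-major integer tuples, so
#' node `i` sits at linear index `i - 1` of the enclosing rectangle (mask
#' domains keep their enclosing-rectangle coordinates but renumber nodes
#' contiguously over foreground pixels).
#'
#' @name cpm_space
NULL

neighborhood_orders <- c("von_neumann", "moore")

lattice_offsets <- function(ndim, order) {
  order <- match.arg(order, neighborhood_orders)
  g <- as.matrix(expand.grid(rep(list(-1L:1L), ndim)))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (order == "von_neumann") {
    g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  unname(g)
}

# 0-based row-major coordinates for linear indices 0:(n-1)
rowmajor_coords <- function(dims) {
  n <- prod(dims)
  nd <- length(dims)
  coords <- matrix(0L, n, nd)
  rem <- 0:(n - 1)
  for (k in nd:1) {
    coords[, k] <- as.integer(rem %% dims[k])
    rem <- rem %/% dims[k]
  }
  coords
}

rowmajor_index <- function(coords, dims) {
  idx <- coords[, 1]
  for (k in seq_along(dims)[-1]) idx <- idx * dims[k] + coords[, k]
  as.integer(idx)
}

# Adjacency in CSR form over an arbitrary subset of a rectangle.
# node_map: full-grid linear index (1-based) -> node number, 0 = absent.
subset_adjacency <- function(coords, dims, periodic, offsets, node_map) {
  n <- nrow(coords)
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2L, offsets[r, ], "+")
    valid <- rep(TRUE, n)
    for (k in seq_along(dims)) {
      if (periodic[k]) {
        nb[, k] <- nb[, k] %% dims[k]
      } else {
        valid <- valid & nb[, k] >= 0L & nb[, k] < dims[k]
      }
    }
    if (!any(valid)) next
    tgt <- node_map[rowmajor_index(nb[valid, , drop = FALSE], dims) + 1L]
    src <- which(valid)[tgt > 0L]
    tgt <- tgt[tgt > 0L]
    keep <- src != tgt # no self-loops (periodic axis of length 1 is rejected upstream)
    from <- c(from, src[keep])
    to <- c(to, tgt[keep])
  }
  # dedupe: a periodic axis of length 2 reaches the same neighbor via +1 and -1
  key <- (as.double(from) - 1) * n + as.double(to)
  keep <- !duplicated(key)
  from <- from[keep]
  to <- to[keep]
  ord <- order(from, to)
  from <- from[ord]
  to <- to[ord]
  counts <- tabulate(from, nbins = n)
  list(ptr = c(1L, 1L + cumsum(counts)), idx = to)
}

new_cpm_space <- function(n_nodes, coords, dims, periodic, mask, conn, int,
                          connectivity_order, interaction_order) {
  structure(
    list(
      n_nodes = n_nodes,
      coords = coords,
      dims = dims,
      periodic = periodic,
      mask = mask,
      conn_ptr = conn$ptr, conn_idx = conn$idx,
      int_ptr = int$ptr, int_idx = int$idx,
      connectivity_order = connectivity_order,
      interaction_order = interaction_order
    ),
    class = "cpm_space"
  )
}

#' Build a rectangular lattice space
#'
#' Construct the default simulation domain: a rectangular 2D or 3D integer
#' grid, with periodic or closed boundaries per axis. Periodic boundaries are
#' implemented by adding edges between nodes on opposite faces.
#'
#' @param dims integer vector of length 2 or 3 giving the grid dimensions.
#' @param periodic logical; either a single flag or one flag per axis. A
#'   periodic axis must have length at least 2.
#' @param connectivity_order,interaction_order `"von_neumann"` or `"moore"`.
#'   Connectivity governs cell contiguity (default von Neumann, i.e. 4/6
#'   neighbors); interaction governs adhesion/perimeter sums (default Moore,
#'   i.e. 8/26 neighbors).
#' @return A `cpm_space` object.
#' @examples
#' sp <- cpm_space(c(10, 10), periodic = TRUE)
#' sp
#' @export
cpm_space <- function(dims, periodic = TRUE,
                      connectivity_order = "von_neumann",
                      interaction_order = "moore") {
  dims <- as.integer(dims)
  if (length(dims) < 2L || length(dims) > 3L) {
    rlang::abort("`dims` must have 2 or 3 entries.", class = "cpm_unsupported_dimension")
  }
  if (any(dims < 1L)) {
    rlang::abort("all dimensions must be at least 1.", class = "cpm_invalid_size")
  }
  periodic <- rep_len(as.logical(periodic), length(dims))
  if (any(periodic & dims < 2L)) {
    rlang::abort("a periodic axis must have length at least 2.", class = "cpm_invalid_size")
  }
  connectivity_order <- match.arg(connectivity_order, neighborhood_orders)
  interaction_order <- match.arg(interaction_order, neighborhood_orders)
  n <- prod(dims)
  coords <- rowmajor_coords(dims)
  node_map <- seq_len(n)
  conn <- subset_adjacency(coords, dims, periodic,
                           lattice_offsets(length(dims), connectivity_order), node_map)
  int <- subset_adjacency(coords, dims, periodic,
                          lattice_offsets(length(dims), interaction_order), node_map)
  new_cpm_space(n, coords, dims, periodic, NULL, conn, int,
                connectivity_order, interaction_order)
}

#' Build a space from a binary mask
#'
#' Define an arbitrary simulation domain (for example traced from an image)
#' from a 2D logical mask: foreground pixels become nodes, and edges join
#' adjacent foreground pixels under each neighborhood order. Mask domains are
#' always closed (no wrapping).
#'
#' @param mask a logical or 0/1 matrix; `TRUE`/nonzero marks the domain.
#' @inheritParams cpm_space
#' @return A `cpm_space` object with `dims` set to the mask dimensions and a
#'   `mask` field recording the foreground pattern.
#' @examples
#' m <- matrix(FALSE, 5, 5)
#' m[2:4, 2:4] <- TRUE
#' cpm_space_from_mask(m)
#' @export
cpm_space_from_mask <- function(mask,
                                connectivity_order = "von_neumann",
                                interaction_order = "moore") {
  if (!is.matrix(mask)) {
    rlang::abort("`mask` must be a 2D matrix.", class = "cpm_unsupported_dimension")
  }
  mask <- matrix(as.logical(mask) & !is.na(mask), nrow(mask), ncol(mask))
  if (!any(mask)) {
    rlang::abort("mask has no foreground pixels.", class = "cpm_empty_domain")
  }
  connectivity_order <- match.arg(connectivity_order, neighborhood_orders)
  interaction_order <- match.arg(interaction_order, neighborhood_orders)
  dims <- dim(mask)
  full <- rowmajor_coords(dims)
  # mask[r+1, c+1] for 0-based row-major coordinate (r, c)
  fg <- mask[cbind(full[, 1] + 1L, full[, 2] + 1L)]
  node_map <- integer(prod(dims))
  node_map[fg] <- seq_len(sum(fg))
  coords <- full[fg, , drop = FALSE]
  periodic <- c(FALSE, FALSE)
  conn <- subset_adjacency(coords, dims, periodic,
                           lattice_offsets(2L, connectivity_order), node_map)
  int <- subset_adjacency(coords, dims, periodic,
                          lattice_offsets(2L, interaction_order), node_map)
  sp <- new_cpm_space(sum(fg), coords, dims, periodic, mask, conn, int,
                      connectivity_order, interaction_order)
  sp$node_lookup <- node_map
  sp
}

# Map 0-based coordinates (matrix, one row per site) to node ids; 0 where the
# site is outside the domain. Periodic axes wrap, closed axes go out of range.
coord_to_node <- function(space, coords) {
  coords <- matrix(as.integer(coords), ncol = length(space$dims))
  valid <- rep(TRUE, nrow(coords))
  for (k in seq_along(space$dims)) {
    if (space$periodic[k]) {
      coords[, k] <- coords[, k] %% space$dims[k]
    } else {
      valid <- valid & coords[, k] >= 0L & coords[, k] < space$dims[k]
    }
  }
  out <- integer(nrow(coords))
  idx <- rowmajor_index(coords[valid, , drop = FALSE], space$dims) + 1L
  out[valid] <- if (is.null(space$node_lookup)) idx else space$node_lookup[idx]
  out
}

#' Read a binary mask from a PNG or CSV file
#'
#' PNG masks treat any nonzero pixel (max over channels) as foreground; CSV
#' masks must contain 0/1 values.
#'
#' @param path file path ending in `.png` or `.csv`.
#' @return A logical matrix suitable for [cpm_space_from_mask()].
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
    img > 0
  } else if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    storage.mode(m) <- "double"
    m != 0
  } else {
    rlang::abort(paste0("unsupported mask format: .", ext), class = "cpm_io_error")
  }
}

#' Neighbors of a node
#'
#' @param space a `cpm_space`.
#' @param node node id (1-based).
#' @param order `"connectivity"` or `"interaction"`.
#' @return Integer vector of neighboring node ids.
#' @export
space_neighbors <- function(space, node, order = c("connectivity", "interaction")) {
  order <- match.arg(order)
  if (order == "connectivity") {
    space$conn_idx[space$conn_ptr[node]:(space$conn_ptr[node + 1L] - 1L)]
  } else {
    if (space$int_ptr[node] > space$int_ptr[node + 1L] - 1L) return(integer(0))
    space$int_idx[space$int_ptr[node]:(space$int_ptr[node + 1L] - 1L)]
  }
}

#' @export
print.cpm_space <- function(x, ...) {
  dom <- if (is.null(x$mask)) {
    paste0(paste(x$dims, collapse = "x"),
           if (any(x$periodic)) " (periodic)" else " (closed)")
  } else {
    paste0("mask ", paste(x$dims, collapse = "x"), ", ", x$n_nodes, " foreground nodes")
  }
  cat("<cpm_space> ", dom, "\n", sep = "")
  cat("  nodes: ", x$n_nodes,
      "  connectivity: ", x$connectivity_order,
      "  interaction: ", x$interaction_order, "\n", sep = "")
  invisible(x)
}

#' Node degrees of a space
#'
#' @inheritParams space_neighbors
#' @return Integer vector of per-node degrees under the given order.
#' @export
space_degrees <- function(space, order = c("connectivity", "interaction")) {
  order <- match.arg(order)
  ptr <- if (order == "connectivity") space$conn_ptr else space$int_ptr
  as.integer(diff(ptr))
}
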