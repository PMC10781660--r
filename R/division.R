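#' Cell division by balanced connected graph bipartition
#'
#' A dividing cell's induced subgraph (connectivity order) is split into two
#' connected parts of near-equal size. Because the split is a graph
#' bipartition rather than a geometric cut, it works for arbitrary shapes,
#' including concave ones. The algorithm: pick two far-apart seed nodes (BFS
#' double sweep), grow the two parts by alternating breadth-first accretion
#' (the smaller part grows first; a stuck part yields), then refine by moving
#' boundary nodes from the larger to the smaller part, accepting only moves
#' that keep the donor connected, preferring moves that shrink the cut.
#' Several seedings are tried and the most balanced valid partition wins.
#'
#' @name division
NULL

# adjacency restricted to `nodes` as a list of integer index vectors
induced_adjacency <- function(space, nodes) {
  pos <- integer(space$n_nodes)
  pos[nodes] <- seq_along(nodes)
  lapply(nodes, function(u) {
    nb <- space_neighbors(space, u, "connectivity")
    pos[nb[pos[nb] > 0L]]
  })
}

bfs_order <- function(adj, start) {
  n <- length(adj)
  seen <- logical(n)
  order <- integer(0)
  frontier <- start
  seen[start] <- TRUE
  while (length(frontier)) {
    order <- c(order, frontier)
    nxt <- unique(unlist(adj[frontier]))
    frontier <- nxt[!seen[nxt]]
    seen[frontier] <- TRUE
  }
  order
}

subset_connected <- function(adj, members) {
  if (!length(members)) return(FALSE)
  keep <- logical(length(adj))
  keep[members] <- TRUE
  seen <- logical(length(adj))
  frontier <- members[1L]
  seen[frontier] <- TRUE
  count <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[keep[nxt] & !seen[nxt]]
    seen[nxt] <- TRUE
    count <- count + length(nxt)
    frontier <- nxt
  }
  count == length(members)
}

# alternating BFS growth from two seeds; returns integer labels 1/2.
# randomize = sample among a node's free neighbors instead of taking the
# first, which diversifies restarts on awkward (thin, branched) shapes
grow_two_parts <- function(adj, seed1, seed2, randomize = FALSE) {
  n <- length(adj)
  label <- integer(n)
  label[seed1] <- 1L
  label[seed2] <- 2L
  queues <- list(seed1, seed2)
  sizes <- c(1L, 1L)
  alive <- c(TRUE, TRUE)
  while (any(alive)) {
    p <- if (alive[1L] && (!alive[2L] || sizes[1L] <= sizes[2L])) 1L else 2L
    grown <- FALSE
    while (length(queues[[p]])) {
      head <- queues[[p]][1L]
      free <- adj[[head]][label[adj[[head]]] == 0L]
      if (length(free)) {
        pick <- if (randomize && length(free) > 1L) {
          free[sample.int(length(free), 1L)]
        } else free[1L]
        label[pick] <- p
        sizes[p] <- sizes[p] + 1L
        queues[[p]] <- c(queues[[p]], pick)
        grown <- TRUE
        break
      }
      queues[[p]] <- queues[[p]][-1L]
    }
    if (!grown) alive[p] <- FALSE
  }
  label
}

# a random DFS spanning tree cut: every connected bipartition of a graph is
# some spanning tree minus one edge, so sampling tree cuts searches the whole
# space of valid partitions and converges on the attainable optimum for
# awkward (thin, nearly tree-like) shapes
random_tree_cut <- function(adj) {
  n <- length(adj)
  parent <- integer(n)
  visit_order <- integer(n)
  root <- sample.int(n, 1L)
  visited <- logical(n)
  visited[root] <- TRUE
  stack <- root
  k <- 0L
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    visit_order[k] <- u
    nb <- adj[[u]]
    nb <- nb[!visited[nb]]
    if (length(nb) > 1L) nb <- sample(nb)
    for (v in nb) {
      visited[v] <- TRUE
      parent[v] <- u
      stack <- c(stack, v)
    }
  }
  size <- rep(1L, n)
  for (i in n:1) {
    u <- visit_order[i]
    if (parent[u] > 0L) size[parent[u]] <- size[parent[u]] + size[u]
  }
  gaps <- abs(n - 2L * size)
  gaps[root] <- NA_integer_
  u_best <- which.min(gaps)
  children <- split(which(parent > 0L), parent[parent > 0L])
  label <- rep(2L, n)
  frontier <- u_best
  label[u_best] <- 1L
  while (length(frontier)) {
    kids <- unlist(children[as.character(frontier)], use.names = FALSE)
    label[kids] <- 1L
    frontier <- kids
  }
  label
}

# move boundary nodes from the larger part to the smaller until balanced
rebalance <- function(adj, label, tol) {
  repeat {
    sizes <- tabulate(label, 2L)
    if (abs(sizes[1L] - sizes[2L]) <= tol) break
    big <- which.max(sizes)
    small <- 3L - big
    movable <- which(label == big &
                       vapply(adj, function(nb) any(label[nb] == small), logical(1)))
    moved <- FALSE
    best <- NULL
    best_cut <- Inf
    for (u in movable) {
      rest <- setdiff(which(label == big), u)
      if (!subset_connected(adj, rest)) next
      # cut change if u moves: edges to big become cut, edges to small leave it
      dcut <- sum(label[adj[[u]]] == big) - sum(label[adj[[u]]] == small)
      if (dcut < best_cut) {
        best <- u
        best_cut <- dcut
      }
    }
    if (!is.null(best)) {
      label[best] <- small
      moved <- TRUE
    }
    if (!moved) break
  }
  label
}

#' Bipartition a connected node set
#'
#' @param space a [cpm_space].
#' @param nodes integer vector of node ids forming a connected set (>= 2).
#' @param tries number of seedings to attempt; the most balanced valid
#'   partition is returned.
#' @return A list of two integer vectors of node ids, each connected, with
#'   sizes differing by at most `max(1, 5%)` of the input whenever such a
#'   partition is found by the heuristic.
#' @export
bipartition_nodes <- function(space, nodes, tries = 64L) {
  n <- length(nodes)
  stopifnot(n >= 2L)
  adj <- induced_adjacency(space, nodes)
  tol <- max(1L, floor(0.05 * n))
  best <- NULL
  best_gap <- Inf
  for (k in seq_len(tries)) {
    if (k == 1L) {
      a <- utils::tail(bfs_order(adj, 1L), 1L) # double sweep: far apart seeds
      b <- utils::tail(bfs_order(adj, a), 1L)
    } else if (k %% 2L == 0L) {
      a <- sample.int(n, 1L) # far pair from a random start
      b <- utils::tail(bfs_order(adj, a), 1L)
    } else {
      ab <- sample.int(n, min(n, 2L)) # fully random pair
      a <- ab[1L]
      b <- ab[length(ab)]
    }
    if (a == b) b <- if (a == 1L) n else 1L
    label <- grow_two_parts(adj, a, b, randomize = k > 1L)
    if (any(label == 0L)) next # cannot happen for a connected input
    label <- rebalance(adj, label, tol)
    gap <- abs(diff(tabulate(label, 2L)))
    if (subset_connected(adj, which(label == 1L)) &&
        subset_connected(adj, which(label == 2L)) && gap < best_gap) {
      best <- label
      best_gap <- gap
    }
    if (best_gap <= tol) break
  }
  if (best_gap > tol) {
    # exhaust the remaining freedom with spanning-tree cuts (see above); for
    # shapes whose optimum exceeds the nominal tolerance (no balanced
    # connected bipartition exists) this returns the most balanced one found
    for (k in seq_len(200L)) {
      label <- random_tree_cut(adj)
      label <- rebalance(adj, label, tol)
      gap <- abs(diff(tabulate(label, 2L)))
      if (gap < best_gap &&
          subset_connected(adj, which(label == 1L)) &&
          subset_connected(adj, which(label == 2L))) {
        best <- label
        best_gap <- gap
      }
      if (best_gap <= tol) break
    }
  }
  if (is.null(best)) {
    rlang::abort("no valid bipartition found.", class = "cpm_partition_error")
  }
  list(nodes[best == 1L], nodes[best == 2L])
}

#' Randomly apportion numeric properties between daughters
#'
#' Each conserved property `x` is split as `f * x` and `x - f * x` with `f`
#' drawn uniformly on (0, 1) independently per property, so the two shares
#' sum to the parent value exactly. Non-conserved properties are copied to
#' both daughters.
#'
#' @param props named numeric vector of parent properties.
#' @param conserved names of the properties to split (default: all).
#' @return A list with numeric vectors `daughter1` and `daughter2` and the
#'   split fractions `f` (NA for copied properties).
#' @export
apportion_properties <- function(props, conserved = names(props)) {
  p1 <- p2 <- props
  f <- rep(NA_real_, length(props))
  names(f) <- names(props)
  for (nm in intersect(names(props), conserved)) {
    f[nm] <- stats::runif(1)
    p1[nm] <- f[nm] * props[nm]
    p2[nm] <- props[nm] - p1[nm]
  }
  list(daughter1 = p1, daughter2 = p2, f = f)
}

#' Divide a cell in two
#'
#' The cell's sites are bipartitioned into two connected, size-balanced
#' parts. Daughter 1 keeps the parent id; daughter 2 receives a fresh id and
#' a new cell-table row inheriting the parent's type and (by default,
#' unhalved) targets. Conserved custom properties are randomly apportioned;
#' the rest are copied.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param cell_id id of the dividing cell (must occupy >= 2 sites).
#' @param conserved names of custom properties to split between daughters
#'   (default: all custom properties).
#' @param halve_targets if `TRUE`, both daughters get half the parent's
#'   target volume (rounded up) instead of inheriting it unchanged.
#' @return A list with the updated `state`, the ids `daughters`, and an
#'   `event` record sufficient to replay the division.
#' @export
divide_cell <- function(space, state, cell_id, conserved = NULL,
                        halve_targets = FALSE) {
  tab <- state$table
  row <- match(cell_id, tab$id)
  if (is.na(row)) {
    rlang::abort(paste0("no cell with id ", cell_id, "."), class = "cpm_missing_cell")
  }
  nodes <- which(state$cell_id == cell_id)
  if (length(nodes) < 2L) {
    rlang::abort(paste0("cell ", cell_id, " occupies a single site and cannot divide."),
                 class = "cpm_too_small_to_divide")
  }
  parts <- bipartition_nodes(space, nodes)
  new_id <- max(tab$id, length(state$volume)) + 1L

  props <- custom_properties(tab)
  if (is.null(conserved)) conserved <- props
  parent_props <- unlist(tab[row, props, drop = FALSE])
  split <- if (length(props)) apportion_properties(parent_props, conserved) else
    list(daughter1 = numeric(0), daughter2 = numeric(0), f = numeric(0))

  daughter_row <- tab[row, ]
  daughter_row$id <- new_id
  for (nm in props) {
    tab[row, nm] <- split$daughter1[[nm]]
    daughter_row[[nm]] <- split$daughter2[[nm]]
  }
  if (halve_targets) {
    half <- as.integer(ceiling(tab$target_volume[row] / 2))
    tab$target_volume[row] <- half
    daughter_row$target_volume <- half
  }
  tab <- dplyr::bind_rows(tab, daughter_row)

  state$table <- tab
  state$cell_id[parts[[2L]]] <- new_id
  state <- recompute_statistics(space, state)

  event <- list(
    kind = "division", parent = cell_id, daughter = new_id,
    daughter_nodes = parts[[2L]],
    parent_props = as.list(tab[row, props, drop = FALSE]),
    daughter_row = as.list(daughter_row)
  )
  list(state = state, daughters = c(cell_id, new_id), event = event)
}

#' Remove a cell from the simulation
#'
#' All the cell's sites become medium and its table row is removed.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param cell_id id of the cell to remove.
#' @return A list with the updated `state` and an `event` record.
#' @export
kill_cell <- function(space, state, cell_id) {
  row <- match(cell_id, state$table$id)
  if (is.na(row)) {
    rlang::abort(paste0("no cell with id ", cell_id, "."), class = "cpm_missing_cell")
  }
  nodes <- which(state$cell_id == cell_id)
  state$cell_id[nodes] <- 0L
  state$table <- state$table[-row, ]
  state <- recompute_statistics(space, state)
  event <- list(kind = "death", id = cell_id, nodes = nodes)
  list(state = state, event = event)
}
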