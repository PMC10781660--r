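# Independent oracles: brute-force Hamiltonians recomputed over the whole
# grid, and igraph-based connectivity checks. These deliberately share no
# code with the package's incremental delta computations.

# full adhesion energy: sum over undirected interaction edges of J for
# differing-id pairs
full_H_adhesion <- function(space, state, J) {
  H <- 0
  for (u in seq_len(space$n_nodes)) {
    for (v in space_neighbors(space, u, "interaction")) {
      if (v <= u) next
      cu <- state$cell_id[u]
      cv <- state$cell_id[v]
      if (cu != cv) {
        tu <- if (cu > 0) state$table$type_index[match(cu, state$table$id)] else 0L
        tv <- if (cv > 0) state$table$type_index[match(cv, state$table$id)] else 0L
        H <- H + J[tu + 1L, tv + 1L]
      }
    }
  }
  H
}

full_H_volume <- function(state, lambda) {
  tab <- state$table
  vols <- vapply(tab$id, function(id) sum(state$cell_id == id), numeric(1))
  lam <- if (length(lambda) == 1L) rep(lambda, nrow(tab)) else lambda[tab$type_index]
  sum(lam * (vols - tab$target_volume)^2)
}

full_H_perimeter <- function(space, state, lambda) {
  tab <- state$table
  perims <- vapply(tab$id, function(id) {
    p <- 0
    for (u in which(state$cell_id == id)) {
      p <- p + sum(state$cell_id[space_neighbors(space, u, "interaction")] != id)
    }
    p
  }, numeric(1))
  lam <- if (length(lambda) == 1L) rep(lambda, nrow(tab)) else lambda[tab$type_index]
  sum(lam * (perims - tab$target_perimeter)^2)
}

# apply a flip without any incremental bookkeeping, then rebuild stats
flip_and_recompute <- function(space, state, proposal) {
  state$cell_id[proposal$target] <- proposal$new_id
  recompute_statistics(space, state)
}

# a random two-type state on a small grid: every node drawn independently
# from {medium, cells 1..k}; cells may be ragged or fragmented, which is
# fine for delta oracles (no dynamics run on these)
random_two_type_state <- function(space, n_cells = 4L, target_volume = 8L,
                                  target_perimeter = 12L) {
  tab <- cell_table(name = rep(c("A", "B"), length.out = n_cells),
                    count = 1L, target_volume = target_volume,
                    target_perimeter = target_perimeter)
  tab <- tab[order(tab$id), ]
  cell_id <- sample(0:n_cells, space$n_nodes, replace = TRUE)
  recompute_statistics(space, graphcpm:::new_cpm_state(cell_id, tab))
}

# a random valid proposal (heterotypic connectivity edge) on a state
random_proposal <- function(space, state) {
  propose(space, state)
}

# number of connected components of a node set, via igraph
oracle_components <- function(space, nodes) {
  if (!length(nodes)) return(0L)
  pos <- match(nodes, nodes)
  edges <- integer(0)
  for (i in seq_along(nodes)) {
    nb <- space_neighbors(space, nodes[i], "connectivity")
    for (v in intersect(nb, nodes)) {
      j <- match(v, nodes)
      if (j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::count_components(g)
}

cell_is_connected <- function(space, state, id) {
  nodes <- which(state$cell_id == id)
  length(nodes) > 0L && oracle_components(space, nodes) == 1L
}

all_cells_connected <- function(space, state) {
  all(vapply(state$table$id, function(id) cell_is_connected(space, state, id),
             logical(1)))
}

# shared small fixtures
grid8 <- function() cpm_space(c(8, 8), periodic = TRUE)

expect_no_fragmentation <- function(space, history, every = 10L) {
  for (m in seq(0L, history$n_mcs, by = every)) {
    st <- reconstruct(history, m)
    expect_true(all_cells_connected(space, st),
                label = paste0("all cells connected at MCS ", m))
  }
}
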