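#' Demonstration models and test shapes
#'
#' Ready-made models exercising the whole stack with no external data: the
#' classic two-type cell-sorting system (differential adhesion), a growing
#' cell population driven by an intracellular protein that triggers division
#' at a threshold, and a random-blob generator for arbitrary (often concave)
#' connected shapes. All are pure functions of their arguments, seed
#' included.
#'
#' @name fixtures
NULL

#' Two-type cell-sorting model
#'
#' Adhesion + volume penalties with heterotypic contact costlier than
#' homotypic contact, the regime in which mixed cells sort into homotypic
#' clusters. Cells start as a dense aggregate (a centered block grid) with
#' types assigned to block positions at random, the classic randomly mixed
#' initial condition: the heterotypic interface starts at the mixing level,
#' stays there under type-symmetric (neutral) contact energies, and collapses
#' under differential adhesion. Default contact energies: homotypic 4,
#' heterotypic 11, cell-medium 8.
#'
#' @param grid 2D grid dimensions (periodic).
#' @param n_per_type cells of each of the two types.
#' @param target_volume per-cell target size in sites.
#' @param J optional 3x3 contact-energy matrix (medium, type A, type B).
#' @param temperature Boltzmann temperature.
#' @param lambda_v volume-constraint weight.
#' @param seed RNG seed.
#' @return A [cpm_model] with its YAML-ready configuration in `$config`.
#' @export
make_cell_sorting_model <- function(grid = c(50, 50), n_per_type = 20,
                                    target_volume = 25, J = NULL,
                                    temperature = 20, lambda_v = 5, seed = 1L) {
  if (is.null(J)) {
    J <- matrix(c(0, 8, 8,
                  8, 4, 11,
                  8, 11, 4), 3, 3, byrow = TRUE)
  }
  side <- ceiling(sqrt(target_volume))
  n_cells <- 2L * n_per_type
  ncols <- ceiling(sqrt(n_cells))
  nrows <- ceiling(n_cells / ncols)
  if (nrows * side > grid[1] || ncols * side > grid[2]) {
    rlang::abort("grid too small for the mixed aggregate.", class = "cpm_crowding_error")
  }
  r0 <- (grid[1] - nrows * side) %/% 2L
  c0 <- (grid[2] - ncols * side) %/% 2L
  slots <- expand.grid(i = seq_len(nrows) - 1L, j = seq_len(ncols) - 1L)
  set.seed(seed)
  pick <- slots[sample.int(nrow(slots), n_cells), ]
  pick$type <- sample(rep(c("A", "B"), n_per_type))
  pick <- pick[order(pick$type), ] # type indices: A = 1, B = 2
  table <- cell_table(name = pick$type, count = 1L,
                      target_volume = target_volume,
                      x = r0 + pick$i * side, y = c0 + pick$j * side)
  # type indices follow first appearance: ensure A = 1, B = 2
  table$type_index <- match(table$type_name, c("A", "B"))

  space <- cpm_space(grid, periodic = TRUE)
  state <- initialize_cells(space, table, seed = seed)
  params <- cpm_params(temperature = temperature, seed = seed)
  penalties <- list(adhesion_penalty(J), volume_penalty(lambda_v))

  config <- list(
    space = list(dims = as.integer(grid), periodic = TRUE,
                 connectivity = "von_neumann", interaction = "moore"),
    cells = list(groups = lapply(seq_len(nrow(table)), function(k)
      list(name = table$type_name[k], count = 1L,
           target_volume = target_volume,
           x = table$x[k], y = table$y[k])),
      placement_seed = as.integer(seed)),
    penalties = list(adhesion = list(J = apply(J, 1L, as.numeric, simplify = FALSE)),
                     volume = list(lambda = lambda_v)),
    engine = list(temperature = temperature, seed = as.integer(seed))
  )
  cpm_model(space, state, penalties, params, config = config)
}

#' Growing-population model
#'
#' One founder type under adhesion + volume penalties, each cell carrying a
#' protein X with exponential accumulation (`dX/dt = alpha * X`, X(0) drawn
#' uniformly on (0, 0.5)); when X reaches 1 the cell divides and X is
#' randomly apportioned between the daughters, which makes subsequent
#' divisions asynchronous.
#'
#' @param grid 2D grid dimensions (periodic).
#' @param founders number of founder cells.
#' @param alpha protein accumulation rate per time unit (1 MCS = 1 unit). The
#'   default 0.05 spaces division rounds about `log(2)/alpha ~ 14` MCS apart,
#'   so the population staircase is resolvable and cells stay near their
#'   target size over a few hundred MCS.
#' @param target_volume per-cell target size in sites.
#' @param temperature Boltzmann temperature.
#' @param lambda_v volume-constraint weight.
#' @param threshold protein level triggering division.
#' @param seed RNG seed.
#' @return A [cpm_model] with an intracellular layer and its configuration.
#' @export
make_growing_population_model <- function(grid = c(60, 60), founders = 1L,
                                          alpha = 0.05, target_volume = 25,
                                          temperature = 20, lambda_v = 5,
                                          threshold = 1, seed = 1L) {
  stopifnot(founders >= 1L)
  J <- matrix(c(0, 8,
                8, 4), 2, 2, byrow = TRUE)
  space <- cpm_space(grid, periodic = TRUE)
  table <- cell_table(name = "Cell", count = founders,
                      target_volume = target_volume)
  state <- initialize_cells(space, table, seed = seed)
  params <- cpm_params(temperature = temperature, seed = seed)
  intra <- intracellular_model(
    rhs = rhs_exponential(alpha), n_components = 1L,
    init = init_uniform(0, 0.5),
    events = list(ode_event(1L, threshold, "up", "divide")),
    mcs_duration = 1, conserved = TRUE, component_names = "X")
  config <- list(
    space = list(dims = as.integer(grid), periodic = TRUE,
                 connectivity = "von_neumann", interaction = "moore"),
    cells = list(groups = list(list(name = "Cell", count = as.integer(founders),
                                    target_volume = target_volume)),
                 placement_seed = as.integer(seed)),
    penalties = list(adhesion = list(J = apply(J, 1L, as.numeric, simplify = FALSE)),
                     volume = list(lambda = lambda_v)),
    engine = list(temperature = temperature, seed = as.integer(seed)),
    ode = list(rhs = "exponential", alpha = alpha, n_components = 1L,
               init = list(uniform = c(0, 0.5)),
               events = list(list(component = 1L, threshold = threshold,
                                  direction = "up", action = "divide")),
               mcs_duration = 1)
  )
  cpm_model(space, state, list(adhesion_penalty(J), volume_penalty(lambda_v)),
            params, intracellular = intra, config = config)
}

#' Random connected blob
#'
#' Grows a connected set of `n` lattice nodes by randomized accretion:
#' starting from a central node, a uniformly random boundary site is annexed
#' until the target size is reached. Produces irregular and, with nonzero
#' probability, concave shapes — the stress cases for the fragmentation guard
#' and the division bipartition.
#'
#' @param n number of nodes (>= 1).
#' @param connectivity_order neighborhood order defining adjacency.
#' @param seed optional RNG seed.
#' @param space optional [cpm_space] to grow in; by default a closed square
#'   grid comfortably larger than the blob.
#' @return A list with the `space` and the sorted integer `nodes`.
#' @export
make_random_blob <- function(n, connectivity_order = "von_neumann", seed = NULL,
                             space = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(space)) {
    side <- max(8L, ceiling(3 * sqrt(n)))
    space <- cpm_space(c(side, side), periodic = FALSE,
                       connectivity_order = connectivity_order)
  }
  center <- coord_to_node(space, matrix(space$dims %/% 2L, 1L))
  if (center == 0L) center <- 1L
  members <- logical(space$n_nodes)
  members[center] <- TRUE
  nodes <- center
  boundary <- setdiff(space_neighbors(space, center, "connectivity"), nodes)
  while (length(nodes) < n) {
    if (!length(boundary)) {
      rlang::abort("space too small for the requested blob.", class = "cpm_crowding_error")
    }
    pick <- boundary[sample.int(length(boundary), 1L)]
    members[pick] <- TRUE
    nodes <- c(nodes, pick)
    nb <- space_neighbors(space, pick, "connectivity")
    boundary <- union(setdiff(boundary, pick), nb[!members[nb]])
  }
  list(space = space, nodes = sort(nodes))
}
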