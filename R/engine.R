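#' Metropolis-Hastings dynamics
#'
#' The engine evolves a state by repeatedly (i) sampling a uniform random
#' connectivity-order edge whose endpoints carry different cell ids and
#' proposing to copy one endpoint's id onto the other, (ii) vetoing the flip
#' if it would disconnect the losing cell (articulation-point guard with a
#' local-topology fast path), (iii) scoring it with the total energy change
#' over all penalties, and (iv) accepting with the Boltzmann probability
#' \eqn{\min(1, e^{-\Delta H / T})}. One Monte Carlo step (MCS) is
#' `flips_per_mcs` flip attempts (default: one per lattice site).
#'
#' @name engine
NULL

#' Engine parameters
#'
#' @param temperature positive Boltzmann temperature `T`.
#' @param flips_per_mcs flip attempts per Monte Carlo step; default (`NULL`)
#'   is the node count of the space.
#' @param seed integer RNG seed fixing the whole trajectory.
#' @return A `cpm_params` object.
#' @export
cpm_params <- function(temperature = 20, flips_per_mcs = NULL, seed = 1L) {
  if (temperature <= 0) {
    rlang::abort("`temperature` must be > 0.", class = "cpm_parameter_error")
  }
  if (!is.null(flips_per_mcs) && flips_per_mcs < 1) {
    rlang::abort("`flips_per_mcs` must be >= 1.", class = "cpm_parameter_error")
  }
  structure(list(temperature = temperature,
                 flips_per_mcs = if (is.null(flips_per_mcs)) NULL else as.integer(flips_per_mcs),
                 seed = as.integer(seed)),
            class = "cpm_params")
}

#' Propose a single flip
#'
#' Samples a uniform random connectivity-order edge whose endpoints carry
#' different ids and proposes copying the source id onto the target (the two
#' directions of an edge are equally likely).
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @return A [cpm_proposal], or `NULL` if the grid is uniform.
#' @export
propose <- function(space, state) {
  conn_from <- rep.int(seq_len(space$n_nodes), diff(space$conn_ptr))
  het <- which(state$cell_id[conn_from] != state$cell_id[space$conn_idx])
  if (!length(het)) return(NULL)
  slot <- het[sample.int(length(het), 1L)]
  target <- conn_from[slot]
  source <- space$conn_idx[slot]
  cpm_proposal(target, source, state$cell_id[target], state$cell_id[source])
}

#' Boltzmann acceptance probability
#'
#' @param delta_H energy change of the proposal.
#' @param temperature positive temperature.
#' @return `min(1, exp(-delta_H / temperature))`.
#' @export
accept_probability <- function(delta_H, temperature) {
  if (temperature <= 0) {
    rlang::abort("`temperature` must be > 0.", class = "cpm_parameter_error")
  }
  pmin(1, exp(-delta_H / temperature))
}

#' Local topology fast path of the fragmentation guard
#'
#' Examines only the occupancy pattern around `node`: it returns `"safe"` when
#' every same-cell connectivity neighbor of `node` is joined to the others
#' through same-cell nodes of the surrounding interaction ring (so any path
#' through `node` reroutes locally), `"unsafe"` when the node is its cell's
#' last site, and `"inconclusive"` otherwise. It never contradicts the exact
#' connectivity check.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param node a node currently belonging to a cell.
#' @return `"safe"`, `"unsafe"`, or `"inconclusive"`.
#' @export
local_topology_check <- function(space, state, node) {
  id <- state$cell_id[node]
  if (id == 0L) {
    rlang::abort("`node` is medium; the guard applies to cell sites only.",
                 class = "cpm_contract_violation")
  }
  conn_nb <- space_neighbors(space, node, "connectivity")
  same <- conn_nb[state$cell_id[conn_nb] == id]
  if (length(same) == 0L) return("unsafe") # last node of the cell
  if (length(same) == 1L) return("safe")   # leaf site
  ring <- space_neighbors(space, node, "interaction")
  ring <- unique(c(ring[state$cell_id[ring] == id & ring != node], same))
  # BFS over the ring's same-cell nodes using connectivity adjacency
  reached <- same[1L]
  frontier <- same[1L]
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(u) {
      nb <- space_neighbors(space, u, "connectivity")
      intersect(nb, ring)
    })))
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
  }
  if (all(same %in% reached)) "safe" else "inconclusive"
}

# exact check: does the cell stay connected when `node` is removed?
exact_removal_check <- function(space, state, node, id) {
  vol <- sum(state$cell_id == id)
  conn_nb <- space_neighbors(space, node, "connectivity")
  start <- conn_nb[state$cell_id[conn_nb] == id]
  if (!length(start)) return(FALSE)
  reached <- rep(FALSE, space$n_nodes)
  reached[node] <- TRUE # excluded
  reached[start[1L]] <- TRUE
  frontier <- start[1L]
  count <- 1L
  while (length(frontier)) {
    nxt <- unlist(lapply(frontier, space_neighbors, space = space))
    nxt <- nxt[!reached[nxt] & state$cell_id[nxt] == id]
    nxt <- unique(nxt)
    reached[nxt] <- TRUE
    count <- count + length(nxt)
    frontier <- nxt
  }
  count == vol - 1L
}

#' Is it safe to remove a node from its cell?
#'
#' `TRUE` iff flipping `node` away leaves the rest of its cell connected under
#' the connectivity order. A cell's last node is never safe to remove (cells
#' cannot vanish through flips). Uses [local_topology_check()] first and falls
#' back to an exact connectivity check when the local pattern is inconclusive.
#'
#' @inheritParams local_topology_check
#' @return Logical.
#' @export
is_safe_removal <- function(space, state, node) {
  id <- state$cell_id[node]
  if (id == 0L) {
    rlang::abort("`node` is medium; the guard applies to cell sites only.",
                 class = "cpm_contract_violation")
  }
  verdict <- local_topology_check(space, state, node)
  if (verdict == "safe") return(TRUE)
  if (verdict == "unsafe") return(FALSE)
  exact_removal_check(space, state, node, id)
}

# apply an accepted flip, updating cached statistics incrementally
apply_flip <- function(space, state, proposal) {
  dp <- perimeter_changes(space, state, proposal)
  state$cell_id[proposal$target] <- proposal$new_id
  if (proposal$old_id > 0L) {
    state$volume[proposal$old_id] <- state$volume[proposal$old_id] - 1L
    state$perimeter[proposal$old_id] <- state$perimeter[proposal$old_id] + dp[["old"]]
  }
  if (proposal$new_id > 0L) {
    state$volume[proposal$new_id] <- state$volume[proposal$new_id] + 1L
    state$perimeter[proposal$new_id] <- state$perimeter[proposal$new_id] + dp[["new"]]
  }
  state
}

#' One propose-guard-score-accept cycle
#'
#' Guard vetoes count as rejections regardless of the energy change. On
#' acceptance, cached statistics and penalty internal state are updated
#' incrementally.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param penalties list of penalty objects.
#' @param temperature positive temperature.
#' @return A list with elements `state`, `accepted` (logical), `vetoed`
#'   (logical), and `proposal` (`NULL` if the grid was uniform).
#' @export
cpm_step <- function(space, state, penalties, temperature) {
  prop <- propose(space, state)
  if (is.null(prop)) {
    return(list(state = state, accepted = FALSE, vetoed = FALSE, proposal = NULL))
  }
  if (prop$old_id > 0L && !is_safe_removal(space, state, prop$target)) {
    return(list(state = state, accepted = FALSE, vetoed = TRUE, proposal = prop))
  }
  dH <- total_delta(penalties, space, state, prop)
  if (stats::runif(1) < accept_probability(dH, temperature)) {
    state <- apply_flip(space, state, prop)
    for (p in penalties) state <- penalty_after_accept(p, space, state, prop)
    list(state = state, accepted = TRUE, vetoed = FALSE, proposal = prop)
  } else {
    list(state = state, accepted = FALSE, vetoed = FALSE, proposal = prop)
  }
}

#' Assemble a model
#'
#' Bundles the three ingredients of a CPM — a space, an initial state (grid +
#' cell table), and a penalty list — with engine parameters and an optional
#' intracellular ODE layer.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state] from [initialize_cells()].
#' @param penalties list of penalty objects.
#' @param params a [cpm_params].
#' @param intracellular optional [intracellular_model()].
#' @param division_rate_property optional name of a custom property holding a
#'   per-MCS division probability; cells then divide stochastically at that
#'   rate, independently of any ODE events.
#' @param config optional named list recording how the model was built (kept
#'   for serialization).
#' @return A `cpm_model` object.
#' @export
cpm_model <- function(space, state, penalties = list(), params = cpm_params(),
                      intracellular = NULL, division_rate_property = NULL,
                      config = NULL) {
  if (inherits(penalties, "cpm_penalty")) penalties <- list(penalties)
  stopifnot(inherits(space, "cpm_space"), inherits(state, "cpm_state"),
            inherits(params, "cpm_params"))
  for (p in penalties) {
    if (!inherits(p, "cpm_penalty")) {
      rlang::abort("`penalties` must be a list of penalty objects.",
                   class = "cpm_config_error")
    }
    if (p$kind == "adhesion" && nrow(p$J) < max(0L, state$table$type_index) + 1L) {
      rlang::abort("adhesion matrix `J` is smaller than the number of types + medium.",
                   class = "cpm_config_error")
    }
    if (p$kind == "perimeter") {
      lam <- lambda_of(p$lambda, state$table$type_index)
      if (any(lam > 0 & is.na(state$table$target_perimeter))) {
        rlang::abort("perimeter penalty requires target_perimeter for weighted types.",
                     class = "cpm_config_error")
      }
    }
  }
  structure(list(space = space, state = state, penalties = penalties,
                 params = params, intracellular = intracellular,
                 division_rate_property = division_rate_property,
                 config = config),
            class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat("<cpm_model>\n")
  print(x$space)
  print(x$state)
  kinds <- vapply(x$penalties, function(p) p$kind, character(1))
  cat("  penalties: ", if (length(kinds)) paste(kinds, collapse = ", ") else "(none)",
      "\n  temperature: ", x$params$temperature,
      "  seed: ", x$params$seed, "\n", sep = "")
  if (!is.null(x$intracellular)) cat("  intracellular ODE layer attached\n")
  invisible(x)
}

# gather C++ sweep arguments from a builtin-only penalty list; NULL if any
# custom penalty (or duplicated kind) forces the R path
builtin_args <- function(penalties, state) {
  kinds <- vapply(penalties, function(p) p$kind, character(1))
  if (any(kinds == "custom") || anyDuplicated(kinds)) return(NULL)
  ntype <- max(0L, state$table$type_index)
  args <- list(J = matrix(numeric(0), 0, 0), lambda_v = numeric(0),
               lambda_p = numeric(0), lambda_act = -1, max_act = 1L,
               lambda_chem = numeric(0), chem_field = numeric(0))
  for (p in penalties) {
    switch(p$kind,
      adhesion = { args$J <- p$J },
      volume = {
        args$lambda_v <- if (length(p$lambda) == 1L) p$lambda else p$lambda[seq_len(ntype)]
      },
      perimeter = {
        args$lambda_p <- if (length(p$lambda) == 1L) p$lambda else p$lambda[seq_len(ntype)]
      },
      migration = { args$lambda_act <- p$lambda; args$max_act <- p$max_act },
      chemotaxis = {
        args$lambda_chem <- if (length(p$lambda) == 1L) p$lambda else p$lambda[seq_len(ntype)]
        args$chem_field <- p$field
      })
  }
  args
}

# per-id lookup vectors padded with a slot for medium (id 0)
per_id_vectors <- function(state) {
  max_id <- length(state$volume)
  type_by_id <- integer(max_id + 1L)
  tv_by_id <- integer(max_id + 1L)
  tp_by_id <- integer(max_id + 1L)
  type_by_id[state$table$id + 1L] <- state$table$type_index
  tv_by_id[state$table$id + 1L] <- state$table$target_volume
  tp <- state$table$target_perimeter
  tp_by_id[state$table$id + 1L] <- ifelse(is.na(tp), 0L, tp)
  list(type = type_by_id, target_volume = tv_by_id, target_perimeter = tp_by_id)
}

# one MCS through the compiled core
cpp_sweep <- function(space, state, args, temperature, flips) {
  ids <- per_id_vectors(state)
  res <- cpp_mcs_sweep(
    space$conn_ptr, space$conn_idx, space$conn_from, space$int_ptr,
    space$int_idx, state$cell_id, c(0L, state$volume), c(0L, state$perimeter),
    state$activity, ids$type, ids$target_volume, ids$target_perimeter,
    args$J, args$lambda_v, args$lambda_p, args$lambda_act, args$max_act,
    args$lambda_chem, args$chem_field, temperature, as.integer(flips))
  state$cell_id <- res$cell_id
  state$volume <- res$volume[-1L]
  state$perimeter <- res$perimeter[-1L]
  state$activity <- res$activity
  list(state = state, deltas = res$deltas, accepted = res$accepted,
       vetoed = res$vetoed,
       boundary_total = res$boundary_total,
       boundary_hetero_type = res$boundary_hetero_type)
}

# one MCS through the interpreted path (needed for custom penalties)
r_sweep <- function(space, state, penalties, temperature, flips) {
  deltas <- matrix(integer(0), 0, 3)
  accepted <- 0L
  vetoed <- 0L
  for (f in seq_len(flips)) {
    out <- cpm_step(space, state, penalties, temperature)
    state <- out$state
    if (is.null(out$proposal)) break
    if (out$accepted) {
      accepted <- accepted + 1L
      deltas <- rbind(deltas, c(out$proposal$target, out$proposal$old_id,
                                out$proposal$new_id))
    }
    if (out$vetoed) vetoed <- vetoed + 1L
  }
  state <- penalties_end_mcs(penalties, state)
  bl <- boundary_lengths(space, state)
  list(state = state, deltas = deltas, accepted = accepted, vetoed = vetoed,
       boundary_total = bl[["total"]], boundary_hetero_type = bl[["hetero_type"]])
}

#' Run a model
#'
#' Executes `n_mcs` Monte Carlo steps, interleaving ODE advancement and
#' division events between steps, and records the trajectory as deltas (see
#' [cpm_history]). The trajectory is fully reproducible from the model's
#' seed.
#'
#' @param model a [cpm_model].
#' @param n_mcs number of Monte Carlo steps (>= 0).
#' @param checkpoint_every store a full snapshot every this many MCS (speeds
#'   up [reconstruct()] at the cost of history size).
#' @param record_ode record every cell's ODE components at each MCS.
#' @param quiet suppress per-MCS progress on standard error.
#' @return A `cpm_history`.
#' @examples
#' sp <- cpm_space(c(12, 12))
#' st <- initialize_cells(sp, cell_table("A", 2, target_volume = 9), seed = 1)
#' mdl <- cpm_model(sp, st, list(adhesion_penalty(matrix(c(0, 4, 4, 2), 2)),
#'                               volume_penalty(5)),
#'                  cpm_params(temperature = 15, seed = 1))
#' h <- cpm_run(mdl, 20)
#' tail(tidy(h), 3)
#' @export
cpm_run <- function(model, n_mcs, checkpoint_every = 100L, record_ode = TRUE,
                    quiet = TRUE) {
  stopifnot(inherits(model, "cpm_model"), n_mcs >= 0)
  space <- model$space
  if (is.null(space$conn_from)) {
    space$conn_from <- rep.int(seq_len(space$n_nodes), diff(space$conn_ptr))
  }
  set.seed(model$params$seed)
  state <- recompute_statistics(space, model$state)
  penalties <- model$penalties
  flips <- model$params$flips_per_mcs
  if (is.null(flips)) flips <- space$n_nodes
  temperature <- model$params$temperature
  intra <- model$intracellular
  intra_state <- if (!is.null(intra)) intracellular_init(intra, state) else NULL

  hist <- new_history(model, state, checkpoint_every)
  hist$summary[[1L]] <- run_summary_row(space, state, 0L, 0L, 0L)
  if (!is.null(intra_state) && record_ode) {
    hist$ode_trace[[1L]] <- ode_trace_rows(intra_state, 0L, 0)
  }

  args <- builtin_args(penalties, state)
  t_now <- 0
  for (m in seq_len(n_mcs)) {
    sw <- if (!is.null(args)) {
      cpp_sweep(space, state, args, temperature, flips)
    } else {
      r_sweep(space, state, penalties, temperature, flips)
    }
    state <- sw$state
    events_m <- list()

    if (!is.null(model$division_rate_property)) {
      res <- rate_divisions(space, state, model$division_rate_property, m)
      state <- res$state
      events_m <- c(events_m, res$events)
    }
    if (!is.null(intra_state)) {
      t_next <- t_now + intra$mcs_duration
      adv <- advance_with_events(space, state, intra, intra_state, t_now, t_next, m)
      state <- adv$state
      intra_state <- adv$intra_state
      events_m <- c(events_m, adv$events)
      t_now <- t_next
      if (record_ode) {
        hist$ode_trace[[length(hist$ode_trace) + 1L]] <-
          ode_trace_rows(intra_state, m, t_now)
      }
    }

    hist$deltas[[m]] <- sw$deltas
    hist$events[[m]] <- events_m
    hist$summary[[m + 1L]] <- run_summary_row(space, state, m, sw$accepted, sw$vetoed,
                                              sw$boundary_total, sw$boundary_hetero_type)
    if (checkpoint_every > 0L && m %% checkpoint_every == 0L) {
      hist$checkpoints[[as.character(m)]] <-
        list(cell_id = state$cell_id, table = state$table)
    }
    if (!quiet) {
      message(sprintf("mcs %d: %d accepted, %d vetoed, %d cells",
                      m, sw$accepted, sw$vetoed, nrow(state$table)))
    }
  }
  hist$n_mcs <- n_mcs
  hist$final_state <- state
  hist$final_intracellular <- intra_state
  finalize_history(hist)
}

run_summary_row <- function(space, state, mcs, accepted, vetoed,
                            boundary_total = NULL, boundary_hetero = NULL) {
  if (is.null(boundary_total)) {
    bl <- boundary_lengths(space, state)
    boundary_total <- bl[["total"]]
    boundary_hetero <- bl[["hetero_type"]]
  }
  row <- tibble::tibble(
    mcs = as.integer(mcs),
    n_cells = nrow(state$table),
    accepted = as.integer(accepted),
    vetoed = as.integer(vetoed),
    boundary_total = boundary_total,
    boundary_hetero_type = boundary_hetero
  )
  tab <- state$table
  if (nrow(tab)) {
    mv <- tapply(state$volume[tab$id], tab$type_name, mean)
    for (ty in names(mv)) row[[paste0("mean_volume_", ty)]] <- unname(mv[ty])
  }
  row
}

# probabilistic division: each cell divides with its per-MCS rate
rate_divisions <- function(space, state, property, mcs) {
  events <- list()
  ids <- state$table$id
  rates <- state$table[[property]]
  if (is.null(rates)) {
    rlang::abort(paste0("cell table has no `", property, "` column."),
                 class = "cpm_config_error")
  }
  draws <- stats::runif(length(ids))
  for (k in seq_along(ids)) {
    if (draws[k] < rates[k] && state$volume[ids[k]] >= 2L) {
      div <- divide_cell(space, state, ids[k])
      state <- div$state
      events[[length(events) + 1L]] <- div$event
    }
  }
  list(state = state, events = events)
}
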