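#' Per-cell intracellular ODE layer
#'
#' Each living cell carries a continuous-time state vector advanced between
#' Monte Carlo steps by error-controlled integration (adaptive step size with
#' root-finding for events, via [deSolve::lsodar]). An event is a component
#' crossing a threshold in a given direction; its action (division, death)
#' fires at the located event time, integration stops, the set of state
#' vectors changes, and integration resumes. One MCS corresponds to
#' `mcs_duration` continuous time units.
#'
#' @name ode_coupling
NULL

#' Define an intracellular model
#'
#' @param rhs `function(t, x, cell)` returning `dx/dt`; `cell` is the cell's
#'   table row. See [rhs_constant()] and [rhs_exponential()] for built-ins.
#' @param n_components length of each cell's state vector.
#' @param init initial condition: a numeric vector (shared by all founder
#'   cells) or a `function(cell)` returning one (drawn per cell, e.g. random
#'   initial protein).
#' @param events list of [ode_event()] specifications.
#' @param mcs_duration continuous time units per Monte Carlo step.
#' @param conserved logical per component: conserved components are randomly
#'   split between daughters at division, others are copied.
#' @param component_names optional names for the components.
#' @param rtol,atol relative/absolute integration tolerances. The defaults
#'   keep located event times accurate to about 1e-6 time units.
#' @return An `intracellular_model` object.
#' @export
intracellular_model <- function(rhs, n_components = 1L, init = 0,
                                events = list(), mcs_duration = 1,
                                conserved = TRUE, component_names = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.function(rhs), n_components >= 1L)
  for (ev in events) {
    if (!inherits(ev, "ode_event")) {
      rlang::abort("`events` must be a list of ode_event() specs.",
                   class = "cpm_config_error")
    }
    if (!is.finite(ev$threshold)) {
      rlang::abort("event thresholds must be finite.", class = "cpm_config_error")
    }
  }
  structure(list(
    rhs = rhs, n_components = as.integer(n_components), init = init,
    events = events, mcs_duration = mcs_duration,
    conserved = rep_len(as.logical(conserved), n_components),
    component_names = component_names %||%
      paste0("X", seq_len(n_components)),
    rtol = rtol, atol = atol
  ), class = "intracellular_model")
}

#' Threshold-crossing event specification
#'
#' @param component index of the watched component.
#' @param threshold finite threshold value.
#' @param direction `"up"` (crossing from below), `"down"`, or `"both"`.
#' @param action `"divide"` or `"kill"`.
#' @return An `ode_event` object.
#' @export
ode_event <- function(component = 1L, threshold = 1, direction = "up",
                      action = "divide") {
  direction <- match.arg(direction, c("up", "down", "both"))
  action <- match.arg(action, c("divide", "kill"))
  structure(list(component = as.integer(component), threshold = threshold,
                 direction = direction, action = action),
            class = "ode_event")
}

#' Built-in right-hand sides
#'
#' `rhs_constant` accumulates at a fixed rate (`dX/dt = rate`);
#' `rhs_exponential` grows proportionally (`dX/dt = alpha * X`).
#'
#' @param rate,alpha rate constants.
#' @return A function usable as `rhs` in [intracellular_model()].
#' @export
rhs_constant <- function(rate = 0.1) {
  force(rate)
  f <- function(t, x, cell) rep(rate, length(x))
  attr(f, "spec") <- list(name = "constant", rate = rate)
  f
}

#' @rdname rhs_constant
#' @export
rhs_exponential <- function(alpha = 0.2) {
  force(alpha)
  f <- function(t, x, cell) alpha * x
  attr(f, "spec") <- list(name = "exponential", alpha = alpha)
  f
}

#' Uniform random initial condition
#'
#' Each founder cell's components are drawn independently and uniformly on
#' `(min, max)`.
#'
#' @param min,max range of the uniform draw.
#' @return A function usable as `init` in [intracellular_model()].
#' @export
init_uniform <- function(min = 0, max = 0.5) {
  force(min); force(max)
  f <- function(cell) stats::runif(1, min, max)
  attr(f, "spec") <- list(name = "uniform", min = min, max = max)
  f
}

# state vectors for the founder cells
intracellular_init <- function(intra, state) {
  xs <- list()
  for (k in seq_len(nrow(state$table))) {
    cell <- state$table[k, ]
    x <- if (is.function(intra$init)) intra$init(cell) else intra$init
    x <- rep_len(as.numeric(x), intra$n_components)
    xs[[as.character(cell$id)]] <- x
  }
  xs
}

ode_trace_rows <- function(intra_state, mcs, time) {
  if (!length(intra_state)) return(NULL)
  ids <- as.integer(names(intra_state))
  m <- do.call(rbind, intra_state)
  out <- tibble::tibble(mcs = as.integer(mcs), time = time, cell_id = ids)
  for (j in seq_len(ncol(m))) out[[paste0("X", j)]] <- m[, j]
  out
}

# events whose condition already holds at the current state (deferred or
# initial-condition triggers); returns list of (id, event index)
pending_events <- function(intra, intra_state, skip = character(0)) {
  hits <- list()
  for (id in setdiff(names(intra_state), skip)) {
    x <- intra_state[[id]]
    for (e in seq_along(intra$events)) {
      ev <- intra$events[[e]]
      v <- x[ev$component]
      hit <- switch(ev$direction,
        up = v >= ev$threshold,
        down = v <= ev$threshold,
        both = v == ev$threshold)
      if (hit) hits[[length(hits) + 1L]] <- list(id = id, event = e)
    }
  }
  hits
}

#' Split a parent's ODE state between its daughters
#'
#' Conserved components are split as `f * x` and `x - f * x` with `f` uniform
#' on (0, 1) per component; others are copied to both daughters. The parent's
#' vector is removed.
#'
#' @param intra an [intracellular_model()].
#' @param intra_state named list of per-cell state vectors.
#' @param parent,daughters parent id and the two daughter ids (the first
#'   daughter keeps the parent id).
#' @return The updated state list.
#' @export
on_division_event <- function(intra, intra_state, parent, daughters) {
  x <- intra_state[[as.character(parent)]]
  x1 <- x2 <- x
  for (j in which(intra$conserved)) {
    f <- stats::runif(1)
    x1[j] <- f * x[j]
    x2[j] <- x[j] - x1[j]
  }
  intra_state[[as.character(parent)]] <- NULL
  intra_state[[as.character(daughters[1L])]] <- x1
  intra_state[[as.character(daughters[2L])]] <- x2
  intra_state
}

# fire one event's action; returns list(state, intra_state, event or NULL,
# deferred logical)
fire_event <- function(space, state, intra, intra_state, id, ev_idx, time, mcs) {
  ev <- intra$events[[ev_idx]]
  id_int <- as.integer(id)
  if (ev$action == "divide") {
    if (state$volume[id_int] < 2L) {
      return(list(state = state, intra_state = intra_state, event = NULL,
                  deferred = TRUE)) # re-armed next MCS
    }
    div <- divide_cell(space, state, id_int)
    intra_state <- on_division_event(intra, intra_state, id_int, div$daughters)
    event <- div$event
    event$time <- time
    event$trigger <- list(component = ev$component, threshold = ev$threshold)
    list(state = div$state, intra_state = intra_state, event = event,
         deferred = FALSE)
  } else {
    kl <- kill_cell(space, state, id_int)
    intra_state[[as.character(id_int)]] <- NULL
    event <- kl$event
    event$time <- time
    list(state = kl$state, intra_state = intra_state, event = event,
         deferred = FALSE)
  }
}

#' Advance every cell's ODE over a time interval
#'
#' Integrates all living cells' ODEs jointly from `t_from` to `t_to` with
#' adaptive error control, locating threshold crossings by root-finding.
#' Integration stops at each event time, the action fires (changing the set
#' of state vectors), and integration resumes. Events whose condition
#' already holds at `t_from` (e.g. a division deferred because the cell was
#' too small) fire immediately.
#'
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param intra an [intracellular_model()].
#' @param intra_state named list of per-cell state vectors.
#' @param t_from,t_to time interval (`t_to >= t_from`).
#' @param mcs MCS index stamped on event records.
#' @return A list with the updated `state`, `intra_state`, and the fired
#'   `events` in time order.
#' @export
advance_with_events <- function(space, state, intra, intra_state, t_from, t_to,
                                mcs = NA_integer_) {
  stopifnot(t_to >= t_from)
  events_out <- list()
  deferred <- character(0)
  t <- t_from

  handle_pending <- function() {
    repeat {
      hits <- pending_events(intra, intra_state, skip = deferred)
      if (!length(hits)) break
      for (h in hits) {
        if (is.null(intra_state[[h$id]])) next # removed by an earlier action
        res <- fire_event(space, state, intra, intra_state, h$id, h$event, t, mcs)
        state <<- res$state
        intra_state <<- res$intra_state
        if (res$deferred) deferred <<- union(deferred, h$id)
        if (!is.null(res$event)) events_out[[length(events_out) + 1L]] <<- res$event
      }
    }
  }

  handle_pending()
  if (!length(intra_state)) {
    return(list(state = state, intra_state = intra_state, events = events_out))
  }

  while (t < t_to) {
    ids <- names(intra_state)
    k <- intra$n_components
    y0 <- unlist(intra_state, use.names = FALSE)
    rows <- match(as.integer(ids), state$table$id)

    derivs <- function(tt, y, parms) {
      dy <- numeric(length(y))
      for (i in seq_along(ids)) {
        sl <- ((i - 1L) * k + 1L):(i * k)
        d <- intra$rhs(tt, y[sl], state$table[rows[i], ])
        if (!all(is.finite(d))) {
          rlang::abort(paste0("non-finite derivative for cell ", ids[i], "."),
                       class = "cpm_integration_failure")
        }
        dy[sl] <- d
      }
      list(dy)
    }
    groot <- if (length(intra$events)) {
      function(tt, y, parms) {
        g <- numeric(length(ids) * length(intra$events))
        for (i in seq_along(ids)) {
          for (e in seq_along(intra$events)) {
            ev <- intra$events[[e]]
            g[(i - 1L) * length(intra$events) + e] <-
              y[(i - 1L) * k + ev$component] - ev$threshold
          }
        }
        g
      }
    } else NULL

    out <- deSolve::lsodar(y = y0, times = c(t, t_to), func = derivs,
                           rootfunc = groot, rtol = intra$rtol,
                           atol = intra$atol)
    last <- out[nrow(out), -1L]
    t_stop <- out[nrow(out), 1L]
    for (i in seq_along(ids)) {
      intra_state[[ids[i]]] <- unname(last[((i - 1L) * k + 1L):(i * k)])
    }
    iroot <- attr(out, "iroot")
    stalled <- t_stop <= t
    t <- t_stop
    if (!is.null(iroot) && any(iroot > 0)) {
      nev <- length(intra$events)
      for (r in which(iroot > 0)) {
        i <- (r - 1L) %/% nev + 1L
        e <- (r - 1L) %% nev + 1L
        id <- ids[i]
        if (is.null(intra_state[[id]])) next
        ev <- intra$events[[e]]
        # direction filter via the drift at the root
        d <- intra$rhs(t, intra_state[[id]],
                       state$table[match(as.integer(id), state$table$id), ])
        dirn_ok <- switch(ev$direction,
          up = d[ev$component] > 0,
          down = d[ev$component] < 0,
          both = TRUE)
        if (!dirn_ok) {
          deferred <- union(deferred, id)
          next
        }
        res <- fire_event(space, state, intra, intra_state, id, e, t, mcs)
        state <- res$state
        intra_state <- res$intra_state
        if (res$deferred) deferred <- union(deferred, id)
        if (!is.null(res$event)) events_out[[length(events_out) + 1L]] <- res$event
      }
      if (!length(intra_state)) break
    } else if (stalled) {
      break # integrator made no progress and reported no event
    } else if (t >= t_to) {
      break
    }
    if (stalled) {
      # a filtered root at an unchanged time would loop forever; nudge past it
      t <- t + max(1e-12, 1e-12 * abs(t_to))
    }
  }
  list(state = state, intra_state = intra_state, events = events_out)
}
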