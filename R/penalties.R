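#' Energy penalties
#'
#' A CPM evolves by proposing single-node id flips and scoring them with the
#' change in a total energy \eqn{H}. Each penalty contributes one term and can
#' compute the exact change \eqn{\Delta H} induced by one proposed flip from
#' the flipped node's neighborhood alone. Built-in terms:
#'
#' * **adhesion** — \eqn{H = \sum_{\{i,j\}} J[\tau(\sigma_i), \tau(\sigma_j)]
#'   (1 - \delta(\sigma_i, \sigma_j))} over interaction-order node pairs:
#'   contacts between differing cell ids pay the contact energy for their type
#'   pair (type 0 = medium).
#' * **volume** — \eqn{\sum_c \lambda_v(\tau_c) (v_c - V_c)^2}, the squared
#'   deviation of each cell's size from its target.
#' * **perimeter** — the same quadratic form on the cell boundary length
#'   (interaction-order edges to differing ids).
#' * **migration** — protrusive activity memory: recently gained nodes carry
#'   an activity that decays by 1 per Monte Carlo step, and a flip is favored
#'   by the difference of geometric-mean activity around source and target.
#' * **chemotaxis** — extensions of a cell are favored in proportion to the
#'   concentration difference between target and source node; positive weight
#'   moves cells up-gradient.
#'
#' User-defined terms are added with [custom_penalty()]: a pure `delta`
#' function plus an optional `after_accept` hook called exactly once per
#' accepted proposal.
#'
#' @name penalties
NULL

new_penalty <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = c(paste0("cpm_", kind), "cpm_penalty"))
}

#' @export
print.cpm_penalty <- function(x, ...) {
  cat("<cpm_penalty: ", x$kind, ">\n", sep = "")
  invisible(x)
}

#' Adhesion (contact energy) penalty
#'
#' @param J symmetric matrix of contact energies indexed by type pairs.
#'   `J[1, 1]` is the medium–medium energy (type 0); row/column `k + 1`
#'   corresponds to type index `k`.
#' @return A penalty object.
#' @export
adhesion_penalty <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J) || !isTRUE(all.equal(J, t(J)))) {
    rlang::abort("`J` must be a symmetric square matrix.", class = "cpm_config_error")
  }
  new_penalty("adhesion", list(J = J))
}

#' Volume constraint penalty
#'
#' @param lambda nonnegative weight; a scalar or one weight per type index.
#' @return A penalty object.
#' @export
volume_penalty <- function(lambda) {
  if (any(lambda < 0)) rlang::abort("volume weights must be >= 0.", class = "cpm_config_error")
  new_penalty("volume", list(lambda = as.numeric(lambda)))
}

#' Perimeter constraint penalty
#'
#' Cells carrying a nonzero weight must have `target_perimeter` set in the
#' cell table.
#'
#' @inheritParams volume_penalty
#' @return A penalty object.
#' @export
perimeter_penalty <- function(lambda) {
  if (any(lambda < 0)) rlang::abort("perimeter weights must be >= 0.", class = "cpm_config_error")
  new_penalty("perimeter", list(lambda = as.numeric(lambda)))
}

#' Protrusive migration (activity memory) penalty
#'
#' Nodes gained by a cell are marked with activity `max_act`, which decays by
#' one per Monte Carlo step. A flip copying from source to target changes the
#' energy by \eqn{-(\lambda/\mathrm{max.act})(\mathrm{GM}_{src} -
#' \mathrm{GM}_{tgt})}, where GM is the geometric mean of activity over the
#' node and its same-cell connectivity neighbors (0 for medium), so active
#' fronts keep protruding.
#'
#' @param lambda nonnegative weight.
#' @param max_act positive integer memory length (in Monte Carlo steps).
#' @return A penalty object.
#' @export
migration_penalty <- function(lambda, max_act = 20L) {
  if (lambda < 0) rlang::abort("`lambda` must be >= 0.", class = "cpm_config_error")
  if (max_act < 1L) rlang::abort("`max_act` must be >= 1.", class = "cpm_config_error")
  new_penalty("migration", list(lambda = as.numeric(lambda), max_act = as.integer(max_act)))
}

#' Chemotaxis penalty
#'
#' @param lambda weight; a scalar or one weight per type index (applied to the
#'   gaining cell's type). Positive weights move cells up-gradient.
#' @param field numeric concentration, one finite value per node.
#' @return A penalty object.
#' @export
chemotaxis_penalty <- function(lambda, field) {
  field <- as.numeric(field)
  if (!all(is.finite(field))) {
    rlang::abort("concentration field must be finite at every node.", class = "cpm_config_error")
  }
  new_penalty("chemotaxis", list(lambda = as.numeric(lambda), field = field))
}

#' User-defined penalty
#'
#' @param delta `function(space, state, proposal)` returning the energy change
#'   of the proposal; must be pure (no side effects).
#' @param after_accept optional `function(space, state, proposal)` returning
#'   an updated state, called exactly once per accepted proposal.
#' @param name label used in printing and configuration files.
#' @return A penalty object.
#' @export
custom_penalty <- function(delta, after_accept = NULL, name = "custom") {
  stopifnot(is.function(delta), is.null(after_accept) || is.function(after_accept))
  p <- new_penalty("custom", list(delta = delta, after_accept = after_accept, name = name))
  p
}

# weight lookup: scalar recycled over types, else indexed by type_index
lambda_of <- function(lambda, type_idx) {
  if (length(lambda) == 1L) rep_len(lambda, length(type_idx)) else lambda[type_idx]
}

# type index of cell ids (0 for medium)
id_type <- function(state, ids) {
  type_of <- integer(max(1L, state$table$id, ids))
  type_of[state$table$id] <- state$table$type_index
  ifelse(ids > 0L, type_of[pmax(ids, 1L)], 0L)
}

#' A proposed single-node flip
#'
#' @param target node whose id would change.
#' @param source adjacent node whose id is copied.
#' @param old_id,new_id current ids at target and source.
#' @return A `cpm_proposal` object.
#' @export
cpm_proposal <- function(target, source, old_id, new_id) {
  structure(list(target = as.integer(target), source = as.integer(source),
                 old_id = as.integer(old_id), new_id = as.integer(new_id)),
            class = "cpm_proposal")
}

#' Energy change of one penalty for one proposal
#'
#' Dispatches on the penalty type; every method computes the exact global
#' energy difference from the flipped node's neighborhood alone.
#'
#' @param penalty a penalty object.
#' @param space a [cpm_space].
#' @param state a [cpm_state].
#' @param proposal a [cpm_proposal].
#' @return The scalar energy change.
#' @export
penalty_delta <- function(penalty, space, state, proposal) {
  UseMethod("penalty_delta")
}

#' @export
penalty_delta.cpm_adhesion <- function(penalty, space, state, proposal) {
  J <- penalty$J
  nb <- space_neighbors(space, proposal$target, "interaction")
  nb_id <- state$cell_id[nb]
  nb_type <- id_type(state, nb_id)
  types <- id_type(state, c(proposal$old_id, proposal$new_id))
  if (max(nb_type, types) + 1L > nrow(J)) {
    rlang::abort("type index outside the adhesion matrix `J`.", class = "cpm_config_error")
  }
  before <- sum(J[cbind(types[1] + 1L, nb_type + 1L)] * (nb_id != proposal$old_id))
  after <- sum(J[cbind(types[2] + 1L, nb_type + 1L)] * (nb_id != proposal$new_id))
  after - before
}

#' @export
penalty_delta.cpm_volume <- function(penalty, space, state, proposal) {
  tab <- state$table
  d <- 0
  for (side in c(-1L, 1L)) {
    id <- if (side < 0L) proposal$old_id else proposal$new_id
    if (id == 0L) next
    row <- match(id, tab$id)
    lam <- lambda_of(penalty$lambda, tab$type_index[row])
    v <- state$volume[id]
    V <- tab$target_volume[row]
    d <- d + lam * ((v + side - V)^2 - (v - V)^2)
  }
  d
}

# perimeter changes of the losing / gaining cell induced by flipping target
perimeter_changes <- function(space, state, proposal) {
  nb_id <- state$cell_id[space_neighbors(space, proposal$target, "interaction")]
  c(old = sum(nb_id == proposal$old_id) - sum(nb_id != proposal$old_id),
    new = sum(nb_id != proposal$new_id) - sum(nb_id == proposal$new_id))
}

#' @export
penalty_delta.cpm_perimeter <- function(penalty, space, state, proposal) {
  tab <- state$table
  dp <- perimeter_changes(space, state, proposal)
  d <- 0
  for (side in c("old", "new")) {
    id <- proposal[[paste0(side, "_id")]]
    if (id == 0L) next
    row <- match(id, tab$id)
    lam <- lambda_of(penalty$lambda, tab$type_index[row])
    if (lam == 0) next
    P <- tab$target_perimeter[row]
    if (is.na(P)) {
      rlang::abort(paste0("cell ", id, " has no target_perimeter but a nonzero ",
                          "perimeter weight."), class = "cpm_config_error")
    }
    p <- state$perimeter[id]
    d <- d + lam * ((p + dp[[side]] - P)^2 - (p - P)^2)
  }
  d
}

# geometric mean of activity over a node and its same-cell connectivity
# neighbors; 0 if the node is medium
activity_gm <- function(space, state, node) {
  id <- state$cell_id[node]
  if (id == 0L) return(0)
  nb <- space_neighbors(space, node, "connectivity")
  acts <- state$activity[c(node, nb[state$cell_id[nb] == id])]
  if (any(acts <= 0)) 0 else exp(mean(log(acts)))
}

#' @export
penalty_delta.cpm_migration <- function(penalty, space, state, proposal) {
  if (penalty$lambda == 0) return(0)
  gm_s <- activity_gm(space, state, proposal$source)
  gm_t <- activity_gm(space, state, proposal$target)
  -(penalty$lambda / penalty$max_act) * (gm_s - gm_t)
}

#' @export
penalty_delta.cpm_chemotaxis <- function(penalty, space, state, proposal) {
  if (proposal$new_id == 0L) return(0)
  ty <- id_type(state, proposal$new_id)
  lam <- lambda_of(penalty$lambda, ty)
  -lam * (penalty$field[proposal$target] - penalty$field[proposal$source])
}

#' @export
penalty_delta.cpm_custom <- function(penalty, space, state, proposal) {
  penalty$delta(space, state, proposal)
}

#' Total energy change of a proposal under a penalty list
#'
#' @param penalties list of penalty objects.
#' @inheritParams penalty_delta
#' @return Sum of the individual penalty deltas (order-independent).
#' @export
total_delta <- function(penalties, space, state, proposal) {
  if (!length(penalties)) return(0)
  sum(vapply(penalties, penalty_delta, numeric(1),
             space = space, state = state, proposal = proposal))
}

# state update hooks, called once per accepted proposal
penalty_after_accept <- function(penalty, space, state, proposal) {
  UseMethod("penalty_after_accept")
}

#' @export
penalty_after_accept.default <- function(penalty, space, state, proposal) state

#' @export
penalty_after_accept.cpm_migration <- function(penalty, space, state, proposal) {
  state$activity[proposal$target] <- if (proposal$new_id > 0L) penalty$max_act else 0
  state
}

#' @export
penalty_after_accept.cpm_custom <- function(penalty, space, state, proposal) {
  if (is.null(penalty$after_accept)) state else penalty$after_accept(space, state, proposal)
}

# per-MCS bookkeeping (activity decay)
penalties_end_mcs <- function(penalties, state) {
  if (any(vapply(penalties, function(p) p$kind == "migration", logical(1)))) {
    state$activity <- pmax(state$activity - 1, 0)
  }
  state
}
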