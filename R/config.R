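#' Model specifications on disk
#'
#' Two text formats are supported. [save_model()]/[load_model()] write a
#' complete, versioned JSON snapshot of a model — space, initial grid, cell
#' table, penalties, engine parameters, and the intracellular layer — such
#' that running the loaded model reproduces the original trajectory
#' bit-exactly from the same seed. [model_from_config()] builds a model from
#' a human-editable YAML run configuration with blocks `space`, `cells`,
#' `penalties`, `engine`, `ode`, `division`, and `recording`.
#'
#' @name model_io
NULL

model_file_magic <- "graphcpm-model"
model_file_version <- 1L

serialize_space <- function(space) {
  list(dims = space$dims, periodic = space$periodic,
       connectivity_order = space$connectivity_order,
       interaction_order = space$interaction_order,
       mask = if (is.null(space$mask)) NULL else apply(space$mask, 1L, as.integer,
                                                       simplify = FALSE))
}

deserialize_space <- function(sp) {
  if (!is.null(sp$mask)) {
    mask <- do.call(rbind, lapply(sp$mask, unlist_int)) > 0
    cpm_space_from_mask(mask, sp$connectivity_order, sp$interaction_order)
  } else {
    cpm_space(unlist_int(sp$dims), as.logical(unlist(sp$periodic)),
              sp$connectivity_order, sp$interaction_order)
  }
}

serialize_fun <- function(f) {
  if (is.null(f) || !is.function(f)) return(f)
  spec <- attr(f, "spec")
  if (!is.null(spec)) list(builtin = spec) else list(src = deparse(f))
}

deserialize_fun <- function(x, kind = c("rhs", "init")) {
  kind <- match.arg(kind)
  if (is.null(x) || !is.list(x)) return(x)
  if (!is.null(x$builtin)) {
    b <- x$builtin
    return(switch(paste(kind, b$name),
      "rhs constant" = rhs_constant(b$rate),
      "rhs exponential" = rhs_exponential(b$alpha),
      "init uniform" = init_uniform(b$min, b$max),
      rlang::abort(paste0("unknown builtin ", kind, " `", b$name, "`."),
                   class = "cpm_config_error")))
  }
  eval(parse(text = paste(unlist(x$src), collapse = "\n")))
}

serialize_penalty <- function(p) {
  switch(p$kind,
    adhesion = list(kind = "adhesion", J = apply(p$J, 1L, as.numeric, simplify = FALSE)),
    volume = list(kind = "volume", lambda = p$lambda),
    perimeter = list(kind = "perimeter", lambda = p$lambda),
    migration = list(kind = "migration", lambda = p$lambda, max_act = p$max_act),
    chemotaxis = list(kind = "chemotaxis", lambda = p$lambda, field = p$field),
    custom = list(kind = "custom", name = p$name,
                  delta = serialize_fun(p$delta),
                  after_accept = serialize_fun(p$after_accept)))
}

deserialize_penalty <- function(p) {
  kind <- p$kind
  known <- c("adhesion", "volume", "perimeter", "migration", "chemotaxis", "custom")
  if (is.null(kind) || !kind %in% known) {
    rlang::abort(paste0("unknown penalty `", kind %||% "(unnamed)", "` in model file."),
                 class = "cpm_config_error")
  }
  switch(kind,
    adhesion = adhesion_penalty(do.call(rbind, lapply(p$J, function(r) as.numeric(unlist(r))))),
    volume = volume_penalty(as.numeric(unlist(p$lambda))),
    perimeter = perimeter_penalty(as.numeric(unlist(p$lambda))),
    migration = migration_penalty(as.numeric(p$lambda), as.integer(p$max_act)),
    chemotaxis = chemotaxis_penalty(as.numeric(unlist(p$lambda)),
                                    as.numeric(unlist(p$field))),
    custom = custom_penalty(deserialize_fun(p$delta),
                            if (is.null(p$after_accept)) NULL else
                              deserialize_fun(p$after_accept),
                            name = p$name %||% "custom"))
}

serialize_intracellular <- function(intra) {
  if (is.null(intra)) return(NULL)
  list(rhs = serialize_fun(intra$rhs), n_components = intra$n_components,
       init = serialize_fun(intra$init),
       events = lapply(intra$events, unclass),
       mcs_duration = intra$mcs_duration, conserved = intra$conserved,
       component_names = intra$component_names,
       rtol = intra$rtol, atol = intra$atol)
}

deserialize_intracellular <- function(x) {
  if (is.null(x)) return(NULL)
  intracellular_model(
    rhs = deserialize_fun(x$rhs, "rhs"),
    n_components = as.integer(x$n_components),
    init = if (is.list(x$init)) deserialize_fun(x$init, "init") else as.numeric(unlist(x$init)),
    events = lapply(x$events, function(e)
      ode_event(as.integer(e$component), as.numeric(e$threshold),
                e$direction, e$action)),
    mcs_duration = as.numeric(x$mcs_duration),
    conserved = as.logical(unlist(x$conserved)),
    component_names = as.character(unlist(x$component_names)),
    rtol = as.numeric(x$rtol), atol = as.numeric(x$atol))
}

serialize_model <- function(model) {
  list(
    format = model_file_magic,
    version = model_file_version,
    space = serialize_space(model$space),
    cell_id = model$state$cell_id,
    table = model$state$table,
    penalties = lapply(model$penalties, serialize_penalty),
    params = unclass(model$params),
    intracellular = serialize_intracellular(model$intracellular),
    division_rate_property = model$division_rate_property,
    config = model$config
  )
}

deserialize_model <- function(payload) {
  if (!identical(payload$format, model_file_magic)) {
    rlang::abort("not a model file (magic string mismatch).", class = "cpm_load_error")
  }
  if (!identical(as.integer(payload$version), model_file_version)) {
    rlang::abort(paste0("unsupported model version ", payload$version, "."),
                 class = "cpm_load_error")
  }
  space <- deserialize_space(payload$space)
  table <- json_table(payload$table)
  state <- recompute_statistics(space, new_cpm_state(unlist_int(payload$cell_id), table))
  params <- cpm_params(
    temperature = as.numeric(payload$params$temperature),
    flips_per_mcs = if (is.null(payload$params$flips_per_mcs)) NULL else
      as.integer(payload$params$flips_per_mcs),
    seed = as.integer(payload$params$seed))
  cpm_model(space, state,
            penalties = lapply(payload$penalties, deserialize_penalty),
            params = params,
            intracellular = deserialize_intracellular(payload$intracellular),
            division_rate_property = payload$division_rate_property,
            config = payload$config)
}

#' @rdname model_io
#' @param model a [cpm_model].
#' @param path file path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname model_io
#' @export
load_model <- function(path) {
  payload <- tryCatch(suppressWarnings(jsonlite::read_json(path, simplifyVector = FALSE)),
                      error = function(e) {
    rlang::abort(paste0("cannot read model file: ", conditionMessage(e)),
                 class = "cpm_load_error")
  })
  deserialize_model(payload)
}

#' Build a model from a YAML run configuration
#'
#' The configuration has blocks:
#' * `space`: `dims`, `periodic`, `connectivity`, `interaction`, or
#'   `mask_csv`/`mask_png`;
#' * `cells`: either `csv` (path to a cell table CSV) or `groups` (a list of
#'   group entries with `name`, `count`, `target_volume`, optional
#'   `target_perimeter`, `x`/`y`/`z`, and custom properties), plus optional
#'   `placement_seed`;
#' * `penalties`: named sub-blocks `adhesion` (`J`), `volume` (`lambda`),
#'   `perimeter` (`lambda`), `migration` (`lambda`, `max_act`), `chemotaxis`
#'   (`lambda`, `field` or `field_csv`);
#' * `engine`: `temperature`, `flips_per_mcs`, `seed`;
#' * `ode` (optional): `rhs` (`"constant"`/`"exponential"`), `rate`/`alpha`,
#'   `init` (a number or `{uniform: [min, max]}`), `events`, `mcs_duration`,
#'   `conserved`, `rtol`, `atol`;
#' * `division` (optional): `rate_property`;
#' * `recording` (optional): `checkpoint_every`, `record_ode` (read by the
#'   command-line driver).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return A [cpm_model] (the raw configuration is kept in `$config`).
#' @export
model_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sp_cfg <- config$space %||% list()
  space <- if (!is.null(sp_cfg$mask_csv) || !is.null(sp_cfg$mask_png)) {
    cpm_space_from_mask(read_mask(sp_cfg$mask_csv %||% sp_cfg$mask_png),
                        sp_cfg$connectivity %||% "von_neumann",
                        sp_cfg$interaction %||% "moore")
  } else {
    cpm_space(unlist(sp_cfg$dims), as.logical(sp_cfg$periodic %||% TRUE),
              sp_cfg$connectivity %||% "von_neumann",
              sp_cfg$interaction %||% "moore")
  }

  cells_cfg <- config$cells %||% list()
  table <- if (!is.null(cells_cfg$csv)) {
    read_cell_table(cells_cfg$csv)
  } else {
    groups <- cells_cfg$groups
    if (is.null(groups)) {
      rlang::abort("config block `cells` needs `csv` or `groups`.",
                   class = "cpm_config_error")
    }
    fields <- unique(unlist(lapply(groups, names)))
    args <- lapply(fields, function(f)
      unlist(lapply(groups, function(g) g[[f]] %||% NA)))
    names(args) <- fields
    do.call(cell_table, args)
  }

  eng <- config$engine %||% list()
  params <- cpm_params(temperature = eng$temperature %||% 20,
                       flips_per_mcs = eng$flips_per_mcs,
                       seed = eng$seed %||% 1L)

  penalties <- list()
  for (nm in names(config$penalties %||% list())) {
    blk <- config$penalties[[nm]]
    penalties[[length(penalties) + 1L]] <- switch(nm,
      adhesion = adhesion_penalty(do.call(rbind, lapply(blk$J, unlist))),
      volume = volume_penalty(unlist(blk$lambda)),
      perimeter = perimeter_penalty(unlist(blk$lambda)),
      migration = migration_penalty(blk$lambda, blk$max_act %||% 20L),
      chemotaxis = chemotaxis_penalty(
        unlist(blk$lambda),
        if (!is.null(blk$field_csv)) {
          as.numeric(as.matrix(utils::read.csv(blk$field_csv, header = FALSE)))
        } else as.numeric(unlist(blk$field))),
      rlang::abort(paste0("unknown penalty block `", nm, "`."),
                   class = "cpm_config_error"))
  }

  intra <- NULL
  if (!is.null(config$ode)) {
    oc <- config$ode
    rhs <- switch(oc$rhs %||% "constant",
      constant = rhs_constant(oc$rate %||% 0.1),
      exponential = rhs_exponential(oc$alpha %||% 0.2),
      rlang::abort(paste0("unknown ode rhs `", oc$rhs, "`."),
                   class = "cpm_config_error"))
    init <- oc$init %||% 0
    if (is.list(init) && !is.null(init$uniform)) {
      u <- unlist(init$uniform)
      init <- init_uniform(u[1], u[2])
    }
    events <- lapply(oc$events %||% list(), function(e)
      ode_event(e$component %||% 1L, e$threshold %||% 1,
                e$direction %||% "up", e$action %||% "divide"))
    intra <- intracellular_model(
      rhs = rhs, n_components = oc$n_components %||% 1L, init = init,
      events = events, mcs_duration = oc$mcs_duration %||% 1,
      conserved = oc$conserved %||% TRUE,
      rtol = oc$rtol %||% 1e-8, atol = oc$atol %||% 1e-10)
  }

  state <- initialize_cells(space, table,
                            seed = cells_cfg$placement_seed %||% params$seed)
  cpm_model(space, state, penalties = penalties, params = params,
            intracellular = intra,
            division_rate_property = config$division$rate_property,
            config = config)
}

#' Write a run configuration to YAML
#'
#' @param config a configuration list (e.g. the `$config` of a fixture model).
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
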