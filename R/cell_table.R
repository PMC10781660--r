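#' Describe the cells to place in a space
#'
#' The cell table is the second ingredient of a model: one row per cell,
#' giving its type name, a per-type index (medium is type 0 and has no row),
#' the desired size (`target_volume`, in lattice sites), an optional desired
#' boundary length (`target_perimeter`, in interaction-order edges), an
#' optional anchor position, and arbitrary numeric custom properties (for
#' example a division rate or a protein amount) carried as extra columns.
#'
#' `cell_table()` takes one entry per cell *group* and expands it to per-cell
#' rows; groups with `count > 1` cannot carry an explicit position.
#'
#' @param name character vector of type names, one per group.
#' @param count integer, cells per group.
#' @param target_volume integer, desired size in lattice sites (>= 1).
#' @param target_perimeter optional integer, desired boundary length.
#' @param x,y,z optional 0-based anchor coordinates (only for `count == 1`).
#' @param ... further numeric vectors (one value per group), stored as custom
#'   properties on every cell of the group.
#' @return A tibble with one row per cell and columns `id`, `type_name`,
#'   `type_index`, `target_volume`, `target_perimeter`, `x`, `y`, `z`, plus
#'   one column per custom property.
#' @examples
#' cell_table(name = c("Epithelial", "Mesenchymal"), count = c(2, 3),
#'            target_volume = 25, division_rate = c(0.1, 0.2))
#' @export
cell_table <- function(name, count = 1L, target_volume,
                       target_perimeter = NA_integer_,
                       x = NA_integer_, y = NA_integer_, z = NA_integer_,
                       ...) {
  groups <- tibble::tibble(
    type_name = as.character(name),
    count = as.integer(count),
    target_volume = as.integer(target_volume),
    target_perimeter = as.integer(target_perimeter),
    x = as.integer(x), y = as.integer(y), z = as.integer(z)
  )
  extra <- list(...)
  if (length(extra)) {
    extra <- lapply(extra, function(v) rep_len(as.numeric(v), nrow(groups)))
    groups <- dplyr::bind_cols(groups, tibble::as_tibble(extra))
  }
  if (any(groups$count < 1L)) {
    rlang::abort("group counts must be at least 1.", class = "cpm_invalid_table")
  }
  if (any(groups$target_volume < 1L)) {
    rlang::abort("target volumes must be at least 1.", class = "cpm_invalid_table")
  }
  if (any(groups$count > 1L & !is.na(groups$x))) {
    rlang::abort("explicit positions require count == 1.", class = "cpm_invalid_table")
  }
  tab <- groups[rep(seq_len(nrow(groups)), groups$count), , drop = FALSE]
  tab$count <- NULL
  tab <- tibble::add_column(tab,
    id = seq_len(nrow(tab)),
    type_index = match(tab$type_name, unique(groups$type_name)),
    .before = 1L
  )
  validate_cell_table(tab)
}

validate_cell_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  tab <- tibble::as_tibble(tab)
  needed <- c("id", "type_name", "type_index", "target_volume")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    rlang::abort(paste("cell table lacks columns:", paste(missing, collapse = ", ")),
                 class = "cpm_invalid_table")
  }
  if (anyDuplicated(tab$id)) {
    rlang::abort("cell ids must be unique.", class = "cpm_invalid_table")
  }
  if (any(tab$id < 1L)) {
    rlang::abort("cell ids must be positive (0 is reserved for medium).",
                 class = "cpm_invalid_table")
  }
  by_type <- tapply(tab$type_index, tab$type_name, function(v) length(unique(v)))
  if (any(by_type != 1L)) {
    rlang::abort("type_index must be constant within a type_name.",
                 class = "cpm_invalid_table")
  }
  for (col in c("target_perimeter", "x", "y", "z")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_integer_
  }
  tab
}

#' Names of the custom property columns of a cell table
#'
#' @param tab a cell table.
#' @return Character vector of custom property column names (possibly empty).
#' @export
custom_properties <- function(tab) {
  setdiff(names(tab), c("id", "type_name", "type_index", "target_volume",
                        "target_perimeter", "x", "y", "z"))
}

#' Read a cell table from CSV
#'
#' Expected columns: `name`, `count`, `target_volume`, optionally
#' `target_perimeter` and anchor coordinates `x`, `y`, `z`; any other numeric
#' column is imported as a custom property.
#'
#' @param path CSV file path.
#' @return A per-cell tibble as from [cell_table()].
#' @export
read_cell_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "target_volume") %in% names(raw))) {
    rlang::abort("cell table CSV needs at least `name` and `target_volume` columns.",
                 class = "cpm_invalid_table")
  }
  args <- list(
    name = raw$name,
    count = if ("count" %in% names(raw)) raw$count else 1L,
    target_volume = raw$target_volume,
    target_perimeter = if ("target_perimeter" %in% names(raw)) raw$target_perimeter else NA_integer_,
    x = if ("x" %in% names(raw)) raw$x else NA_integer_,
    y = if ("y" %in% names(raw)) raw$y else NA_integer_,
    z = if ("z" %in% names(raw)) raw$z else NA_integer_
  )
  extras <- setdiff(names(raw), c("name", "count", "target_volume",
                                  "target_perimeter", "x", "y", "z"))
  for (col in extras) args[[col]] <- as.numeric(raw[[col]])
  do.call(cell_table, args)
}
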