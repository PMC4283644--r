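# Field maps: the bindings between point-model variables and field
# components. A map set derives the DOF "pattern" (the spatial locations at
# which model instances live), checks location compatibility across all
# mapped components, and backs the per-DOF model instances with four fields:
# models (integer selector; 0 = no model), state, parameters, intermediates.

#' Create a map set
#'
#' @param env a `pm_environment` with at least one imported model.
#' @return an object of class `fp_map_set`.
#' @export
map_set <- function(env) {
  stopifnot(inherits(env, "pm_environment"))
  if (length(env$models) == 0L) stop("environment has no imported models", call. = FALSE)
  ms <- new.env(parent = emptyenv())
  ms$env <- env
  ms$maps <- list()
  ms$finished <- FALSE
  ms$pattern <- NULL
  class(ms) <- "fp_map_set"
  ms
}

#' Add a field map
#'
#' A `field_to_model` map feeds a field component into a known-flagged model
#' variable; a `model_to_field` map exports a wanted-flagged variable into a
#' field component. A given (model, variable) may be the target of at most
#' one map per direction.
#'
#' @param mapset an `fp_map_set` (not finished).
#' @param direction "field_to_model" or "model_to_field".
#' @param component an `fp_component`.
#' @param model_index model index in the map set's environment.
#' @param variable model variable name.
#' @return the map set, invisibly.
#' @export
add_map <- function(mapset, direction, component, model_index, variable) {
  stopifnot(inherits(mapset, "fp_map_set"))
  if (mapset$finished) stop("map set is finished", call. = FALSE)
  direction <- match.arg(direction, c("field_to_model", "model_to_field"))
  if (!inherits(component, "fp_component")) stop("unknown component", call. = FALSE)
  env <- mapset$env
  if (model_index < 1L || model_index > length(env$models))
    stop(sprintf("no model with index %s", model_index), call. = FALSE)
  defn <- env$models[[model_index]]
  if (!(variable %in% pm_variable_names(defn)))
    stop(sprintf("no variable %s in model '%s'", variable, defn$name), call. = FALSE)
  fl <- pm_get_flag(env, model_index, variable)
  if (direction == "field_to_model" && !isTRUE(fl$known))
    stop(sprintf("variable '%s' must be flagged known for a field_to_model map", variable),
         call. = FALSE)
  if (direction == "model_to_field" && !isTRUE(fl$wanted))
    stop(sprintf("variable '%s' must be flagged wanted for a model_to_field map", variable),
         call. = FALSE)
  for (m in mapset$maps)
    if (m$direction == direction && m$model_index == model_index && m$variable == variable)
      stop(sprintf("variable '%s' already has a %s map", variable, direction), call. = FALSE)
  mapset$maps[[length(mapset$maps) + 1L]] <-
    list(direction = direction, component = component,
         model_index = as.integer(model_index), variable = variable)
  invisible(mapset)
}

#' Finish a map set and derive the DOF pattern
#'
#' The pattern is the ordered list of DOF locations of the mapped components.
#' All mapped components must have their DOFs at the same spatial locations
#' (absolute tolerance 1e-12), though not necessarily with the same DOF ids:
#' a per-map DOF permutation is derived by location matching.
#'
#' @param mapset an `fp_map_set` with at least one map.
#' @return the derived `fp_dof_pattern`.
#' @export
finish_maps <- function(mapset) {
  stopifnot(inherits(mapset, "fp_map_set"))
  if (mapset$finished) return(mapset$pattern)
  if (length(mapset$maps) == 0L) stop("map set has no maps", call. = FALSE)
  pats <- lapply(mapset$maps, function(m) dof_locations(m$component))
  ref <- pats[[1L]]
  undef_ref <- isTRUE(attr(ref, "undefined_location"))
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    if (isTRUE(attr(p, "undefined_location")) != undef_ref || nrow(p) != nrow(ref))
      stop(sprintf("incompatible DOF pattern for map %d (variable '%s'): %d DOFs vs %d in the reference",
                   i, mapset$maps[[i]]$variable, nrow(p), nrow(ref)), call. = FALSE)
    perm <- if (undef_ref) seq_len(nrow(ref)) else fp_match_locations(ref, p, i, mapset$maps[[i]]$variable)
    mapset$maps[[i]]$perm <- perm
  }
  mapset$pattern <- ref
  mapset$finished <- TRUE
  ref
}

# match pattern rows of `ref` to rows of `p` by location (tolerance 1e-12);
# fast path: identical ordering
fp_match_locations <- function(ref, p, map_id, variable, tol = 1e-12) {
  dx <- abs(ref$x - p$x); dy <- abs(ref$y - p$y)
  if (all(dx <= tol & dy <= tol)) return(seq_len(nrow(ref)))
  perm <- integer(nrow(ref))
  for (k in seq_len(nrow(ref))) {
    hit <- which(abs(p$x - ref$x[k]) <= tol & abs(p$y - ref$y[k]) <= tol)
    if (length(hit) == 0L)
      stop(sprintf("map %d (variable '%s') has no DOF at pattern location %d (%.6g, %.6g)",
                   map_id, variable, k, ref$x[k], ref$y[k]), call. = FALSE)
    perm[k] <- hit[1L]
  }
  perm
}

#' @exportS3Method base::print
print.fp_map_set <- function(x, ...) {
  cat(sprintf("<fp_map_set>: %d map(s)%s\n", length(x$maps),
              if (x$finished) sprintf(", pattern of %d DOF(s)", nrow(x$pattern)) else ""))
  invisible(x)
}

## ---- model-backing fields ----------------------------------------------

#' Create the model-backing fields for a finished map set
#'
#' Builds the four backing structures over the DOF pattern: the integer
#' `models` selector (initialised to the first imported model everywhere),
#' and the state / parameters / intermediates stores with one column per
#' model vector slot. With several imported models the column layout is the
#' union of the models' variable names; slots unused by the model active at
#' a DOF hold `NA`. States start at each model's initial values, parameters
#' at the compiled default known values, intermediates at zero.
#'
#' With `shared = TRUE`, any mapped component whose DOF ordering coincides
#' with the pattern backs its column directly (same store, no copying during
#' transfer).
#'
#' @param mapset a finished `fp_map_set` whose environment has been
#'   instantiated (see [instantiate()]).
#' @param shared logical; enable shared-storage optimisation.
#' @return an object of class `fp_model_fields`.
#' @export
create_model_fields <- function(mapset, shared = FALSE) {
  stopifnot(inherits(mapset, "fp_map_set"))
  if (!mapset$finished) stop("finish the map set first", call. = FALSE)
  env <- mapset$env
  if (!env$finished) instantiate(env)
  models <- env$compiled
  n <- nrow(mapset$pattern)

  state_cols <- unique(unlist(lapply(models, function(m) m$state_order)))
  param_cols <- unique(unlist(lapply(models, function(m) m$known_order)))
  inter_cols <- unique(unlist(lapply(models, function(m) m$wanted_order)))

  mf <- new.env(parent = emptyenv())
  mf$mapset <- mapset
  mf$env <- env
  mf$n_dof <- n
  mf$models <- rep(1L, n)
  mf$shared <- isTRUE(shared)
  mf$state_cols <- state_cols; mf$param_cols <- param_cols; mf$inter_cols <- inter_cols

  make_cells <- function(cols, kind) {
    cells <- list()
    for (nm in cols) {
      cell <- NULL
      if (isTRUE(shared)) {
        # a map on this variable whose component ordering matches the pattern
        # can back the column directly
        for (m in mapset$maps) {
          if (m$variable == nm && identical(m$perm, seq_len(n)) &&
              m$component$n_dofs == n) { cell <- m$component; break }
        }
      }
      if (is.null(cell)) {
        cell <- new.env(parent = emptyenv())
        cell$values <- rep(NA_real_, n)
        class(cell) <- "fp_cell"
      }
      cells[[nm]] <- cell
    }
    cells
  }
  mf$state_cells <- make_cells(state_cols, "state")
  mf$param_cells <- make_cells(param_cols, "param")
  mf$inter_cells <- make_cells(inter_cols, "inter")
  # a shared column whose variable is fed from a field (field_to_model map)
  # must keep the field's current content: initialising it from model
  # defaults would differ from copy mode, where transfer_in overwrites the
  # defaults with the field values anyway
  f2m_vars <- unique(vapply(Filter(function(m) m$direction == "field_to_model", mapset$maps),
                            function(m) m$variable, character(1L)))
  mf$skip_init <- character(0)
  for (nm in c(state_cols, param_cols, inter_cols)) {
    cell <- fp_find_cell_quiet(mf, nm)
    if (inherits(cell, "fp_component") && nm %in% f2m_vars)
      mf$skip_init <- c(mf$skip_init, nm)
  }
  class(mf) <- "fp_model_fields"

  # initialise all DOFs for the default model (index 1)
  fp_init_rows(mf, seq_len(n), 1L)
  mf
}

# (re)initialise rows for a given model index
fp_init_rows <- function(mf, rows, model_index) {
  m <- mf$env$compiled[[model_index]]
  for (j in seq_along(m$state_order))
    if (!(m$state_order[j] %in% mf$skip_init))
      fp_cell_write(mf$state_cells[[m$state_order[j]]], rows, m$initial_state[j])
  for (j in seq_along(m$known_order))
    if (!(m$known_order[j] %in% mf$skip_init))
      fp_cell_write(mf$param_cells[[m$known_order[j]]], rows, m$default_known[j])
  for (nm in m$wanted_order)
    if (!(nm %in% mf$skip_init))
      fp_cell_write(mf$inter_cells[[nm]], rows, 0)
  invisible(mf)
}

fp_find_cell_quiet <- function(mf, variable) {
  for (cells in list(mf$state_cells, mf$param_cells, mf$inter_cells))
    if (!is.null(cells[[variable]])) return(cells[[variable]])
  NULL
}

fp_cell_read <- function(cell) cell$values
fp_cell_write <- function(cell, rows, vals) { cell$values[rows] <- vals; invisible(cell) }

#' Set the models-field value at a DOF
#'
#' Value 0 disables the point model at that DOF: its rows are skipped by all
#' transfers and solves (frozen). Switching a DOF to a different model
#' re-initialises that row from the new model's defaults.
#'
#' @param mf an `fp_model_fields`.
#' @param dof DOF id(s) in the pattern.
#' @param value model index, or 0 for no model.
#' @return the object, invisibly.
#' @export
set_models_value <- function(mf, dof, value) {
  stopifnot(inherits(mf, "fp_model_fields"))
  if (any(dof < 1L | dof > mf$n_dof)) stop("dof id out of range", call. = FALSE)
  value <- as.integer(value)
  if (value < 0L || value > length(mf$env$models))
    stop(sprintf("no model with index %d", value), call. = FALSE)
  changed <- dof[mf$models[dof] != value]
  mf$models[dof] <- value
  if (value > 0L && length(changed)) fp_init_rows(mf, changed, value)
  invisible(mf)
}

#' Read the models-field vector
#' @param mf an `fp_model_fields`.
#' @return integer vector over the pattern DOFs.
#' @export
get_models_field <- function(mf) mf$models

#' Read a state/parameters/intermediates column
#' @param mf an `fp_model_fields`.
#' @param kind "state", "param" or "inter".
#' @param variable column (variable) name.
#' @return numeric vector over the pattern DOFs.
#' @export
mf_column <- function(mf, kind, variable) {
  cells <- switch(match.arg(kind, c("state", "param", "inter")),
                  state = mf$state_cells, param = mf$param_cells, inter = mf$inter_cells)
  cell <- cells[[variable]]
  if (is.null(cell)) stop(sprintf("no %s column '%s'", kind, variable), call. = FALSE)
  fp_cell_read(cell)
}

# locate the cell backing a model variable, searching state, then param,
# then intermediates
fp_find_cell <- function(mf, variable) {
  for (cells in list(mf$state_cells, mf$param_cells, mf$inter_cells))
    if (!is.null(cells[[variable]])) return(cells[[variable]])
  stop(sprintf("variable '%s' has no backing column", variable), call. = FALSE)
}

#' @exportS3Method base::print
print.fp_model_fields <- function(x, ...) {
  cat(sprintf("<fp_model_fields>: %d DOF(s); state [%s]; parameters [%s]; intermediates [%s]\n",
              x$n_dof, paste(x$state_cols, collapse = ","),
              paste(x$param_cols, collapse = ","), paste(x$inter_cols, collapse = ",")))
  invisible(x)
}

## ---- transfer -----------------------------------------------------------

#' Transfer mapped field values into the model-backing fields
#'
#' Copies each `field_to_model` mapped component value into the parameter or
#' state column for its variable, at every pattern DOF whose models value
#' matches the map's model (DOFs with models value 0 are skipped). Columns
#' backed by shared storage need no copy.
#'
#' @param mapset a finished `fp_map_set`.
#' @param mf the `fp_model_fields`.
#' @return `mf`, invisibly.
#' @export
transfer_in <- function(mapset, mf) {
  fp_transfer(mapset, mf, "field_to_model")
}

#' Transfer model-backing field values out to mapped fields
#'
#' Copies wanted columns (intermediates and states) to their
#' `model_to_field` targets; DOFs with models value 0 are skipped.
#'
#' @inheritParams transfer_in
#' @return `mf`, invisibly.
#' @export
transfer_out <- function(mapset, mf) {
  fp_transfer(mapset, mf, "model_to_field")
}

fp_transfer <- function(mapset, mf, direction) {
  stopifnot(inherits(mapset, "fp_map_set"), inherits(mf, "fp_model_fields"))
  if (!mapset$finished) stop("finish the map set first", call. = FALSE)
  for (m in mapset$maps) {
    if (m$direction != direction) next
    cell <- fp_find_cell(mf, m$variable)
    if (identical(cell, m$component)) next   # shared storage: same store
    rows <- which(mf$models == m$model_index)
    if (!length(rows)) next
    if (direction == "field_to_model") {
      cell$values[rows] <- m$component$values[m$perm[rows]]
    } else {
      m$component$values[m$perm[rows]] <- cell$values[rows]
    }
  }
  invisible(mf)
}
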