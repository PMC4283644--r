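# The field data model: structured 2D meshes, 1D vessel networks, the
# Field -> FieldVariable -> FieldComponent hierarchy with per-component DOF
# structures (constant / element / node / gauss_point / data_point), DOF
# patterns (spatial locations of DOFs) and bilinear Lagrange interpolation.
#
# Single-process contract: the distributed decomposition and ghost-DOF
# exchange of a parallel code are represented by the no-op update_field()
# hook so application code mirrors the usual call sequence.

#' Create a structured 2D quadrilateral mesh
#'
#' Nodes are numbered row-major from the bottom-left corner; node (i, j)
#' (0-based) sits at (i*lx/nx, j*ly/ny). Element connectivity follows
#' bilinear Lagrange ordering (bottom-left, bottom-right, top-left,
#' top-right).
#'
#' @param nx,ny element counts (>= 1).
#' @param lx,ly physical side lengths (> 0).
#' @return an object of class `fp_mesh_2d` with `nodes` ((nx+1)(ny+1) x 2
#'   coordinate matrix), `elements` (nx*ny x 4 node-index matrix) and sizes.
#' @export
#' @examples
#' m <- create_structured_mesh(25, 25, 10, 10)
#' nrow(m$nodes)     # 676
create_structured_mesh <- function(nx, ny, lx, ly) {
  if (nx < 1L || ny < 1L) stop("element counts must be >= 1", call. = FALSE)
  if (lx <= 0 || ly <= 0) stop("side lengths must be > 0", call. = FALSE)
  nnx <- nx + 1L; nny <- ny + 1L
  xs <- seq(0, lx, length.out = nnx)
  ys <- seq(0, ly, length.out = nny)
  nodes <- cbind(x = rep(xs, times = nny), y = rep(ys, each = nnx))
  elements <- matrix(0L, nrow = nx * ny, ncol = 4L)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      bl <- (j - 1L) * nnx + i
      elements[k, ] <- c(bl, bl + 1L, bl + nnx, bl + nnx + 1L)
    }
  }
  structure(list(nx = nx, ny = ny, lx = lx, ly = ly,
                 n_nodes = nnx * nny, n_elements = nx * ny,
                 nodes = nodes, elements = elements),
            class = "fp_mesh_2d")
}

#' @exportS3Method base::print
print.fp_mesh_2d <- function(x, ...) {
  cat(sprintf("<fp_mesh_2d>: %dx%d elements (%d nodes) on %.3g x %.3g\n",
              x$nx, x$ny, x$n_nodes, x$lx, x$ly))
  invisible(x)
}

#' Create a 1D vessel network
#'
#' A directed graph of compliant 1D segments. Each segment has a length,
#' a uniform grid, a reference area `A0` and a wall stiffness coefficient
#' `beta` (tube law p = p_ext + beta*(sqrt(A) - sqrt(A0))/A0).
#'
#' @param segments data.frame with columns `length`, `n`, `A0`, `beta`
#'   (one row per segment; `n` = number of grid points, >= 3).
#' @param junctions list of integer vectors; each vector lists the segments
#'   meeting at one junction, with negative sign meaning the segment's
#'   *start* joins there and positive its *end* (e.g. `c(1, -2, -3)`:
#'   segment 1 ends where 2 and 3 begin).
#' @param inlet segment whose start is the network inlet.
#' @param outlets segments whose ends are terminal outlets.
#' @return an object of class `fp_network_1d`.
#' @export
vessel_network <- function(segments, junctions = list(), inlet = 1L, outlets = integer(0)) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("length", "n", "A0", "beta") %in% names(segments)))
  if (any(segments$n < 3L)) stop("each segment needs >= 3 grid points", call. = FALSE)
  if (any(segments$length <= 0 | segments$A0 <= 0 | segments$beta <= 0))
    stop("segment length, A0 and beta must be positive", call. = FALSE)
  for (j in junctions) {
    if (length(j) < 2L) stop("each junction must join >= 2 segments", call. = FALSE)
    if (any(abs(j) < 1L | abs(j) > nrow(segments)))
      stop("junction references unknown segment", call. = FALSE)
  }
  segments$dx <- segments$length / (segments$n - 1L)
  structure(list(segments = segments, junctions = junctions,
                 inlet = as.integer(inlet), outlets = as.integer(outlets),
                 n_segments = nrow(segments)),
            class = "fp_network_1d")
}

#' @exportS3Method base::print
print.fp_network_1d <- function(x, ...) {
  cat(sprintf("<fp_network_1d>: %d segment(s), %d junction(s), %d outlet(s)\n",
              x$n_segments, length(x$junctions), length(x$outlets)))
  invisible(x)
}

## ---- fields -------------------------------------------------------------

.fp_structures <- c("constant", "element", "node", "gauss_point", "data_point")

#' Create a field over a mesh
#'
#' A field holds one or more field variables; a variable holds one or more
#' components; each component has a DOF structure and a value store. Fields
#' are mutable (environment-backed): [set_dof()] writes in place.
#'
#' @param name field name.
#' @param mesh an `fp_mesh_2d` (or NULL for purely data-point fields).
#' @return an object of class `fp_field`.
#' @export
new_field <- function(name, mesh = NULL) {
  f <- new.env(parent = emptyenv())
  f$name <- name
  f$mesh <- mesh
  f$variables <- list()
  class(f) <- "fp_field"
  f
}

#' Add a variable (with components) to a field
#'
#' @param field an `fp_field`.
#' @param name variable name.
#' @param components named list: each entry is `list(structure =, default =,
#'   locations =)` where `structure` is one of "constant", "element", "node",
#'   "gauss_point", "data_point"; `default` (default 0) initialises the value
#'   store; `locations` (n x 2 matrix) is required for "data_point".
#' @return the field, invisibly.
#' @export
add_field_variable <- function(field, name, components) {
  stopifnot(inherits(field, "fp_field"))
  if (!is.null(field$variables[[name]]))
    stop(sprintf("field '%s' already has variable '%s'", field$name, name), call. = FALSE)
  comps <- list()
  for (cn in names(components)) {
    spec <- components[[cn]]
    structure_ <- match.arg(spec$structure, .fp_structures)
    default <- spec$default %||% 0
    nd <- switch(structure_,
                 constant = 1L,
                 element = field$mesh$n_elements,
                 node = field$mesh$n_nodes,
                 gauss_point = 4L * field$mesh$n_elements,
                 data_point = {
                   if (is.null(spec$locations)) stop("data_point structure needs locations", call. = FALSE)
                   nrow(spec$locations)
                 })
    if (is.null(nd)) stop(sprintf("component '%s': structure '%s' needs a mesh", cn, structure_), call. = FALSE)
    comp <- new.env(parent = emptyenv())
    comp$name <- cn
    comp$field_name <- field$name
    comp$variable_name <- name
    comp$structure <- structure_
    comp$n_dofs <- nd
    comp$default <- default
    comp$values <- rep(as.numeric(default), nd)
    comp$locations <- spec$locations
    comp$mesh <- field$mesh
    class(comp) <- "fp_component"
    comps[[cn]] <- comp
  }
  field$variables[[name]] <- list(name = name, components = comps)
  invisible(field)
}

#' @exportS3Method base::print
print.fp_field <- function(x, ...) {
  cat(sprintf("<fp_field '%s'>: %d variable(s)\n", x$name, length(x$variables)))
  for (v in x$variables)
    cat(sprintf("  %s: %s\n", v$name,
                paste(vapply(v$components, function(c) sprintf("%s[%s:%d]", c$name, c$structure, c$n_dofs), character(1L)),
                      collapse = ", ")))
  invisible(x)
}

#' Fetch a component of a field variable
#' @param field an `fp_field`.
#' @param variable variable name.
#' @param component component name.
#' @return an `fp_component`.
#' @export
get_component <- function(field, variable, component) {
  v <- field$variables[[variable]]
  if (is.null(v)) stop(sprintf("no variable '%s' in field '%s'", variable, field$name), call. = FALSE)
  cm <- v$components[[component]]
  if (is.null(cm)) stop(sprintf("no component '%s' in variable '%s'", component, variable), call. = FALSE)
  cm
}

#' Read one DOF value
#' @param component an `fp_component`.
#' @param dof integer DOF id (1-based).
#' @return numeric value.
#' @export
get_dof <- function(component, dof) {
  stopifnot(inherits(component, "fp_component"))
  if (any(dof < 1L | dof > component$n_dofs))
    stop(sprintf("dof id out of range 1..%d", component$n_dofs), call. = FALSE)
  component$values[dof]
}

#' Write one DOF value (in place)
#' @param component an `fp_component`.
#' @param dof integer DOF id (1-based; vectorised).
#' @param value numeric value(s).
#' @return the component, invisibly.
#' @export
set_dof <- function(component, dof, value) {
  stopifnot(inherits(component, "fp_component"))
  if (any(dof < 1L | dof > component$n_dofs))
    stop(sprintf("dof id out of range 1..%d", component$n_dofs), call. = FALSE)
  component$values[dof] <- value
  invisible(component)
}

#' Set every DOF of a component
#' @param component an `fp_component`.
#' @param values numeric scalar or vector of length `n_dofs`.
#' @return the component, invisibly.
#' @export
set_all_dofs <- function(component, values) {
  stopifnot(inherits(component, "fp_component"))
  if (length(values) == 1L) values <- rep(as.numeric(values), component$n_dofs)
  if (length(values) != component$n_dofs)
    stop(sprintf("expected %d values, got %d", component$n_dofs, length(values)), call. = FALSE)
  component$values <- as.numeric(values)
  invisible(component)
}

#' Ghost-DOF update hook
#'
#' In a distributed run this would exchange ghosted DOF values between
#' computational domains; in this single-process implementation it is a
#' no-op kept so application code mirrors the standard call sequence.
#' @param field an `fp_field`.
#' @return the field, invisibly.
#' @export
update_field <- function(field) invisible(field)

## ---- DOF patterns -------------------------------------------------------

# 2-point Gauss abscissae mapped from [-1,1] to [0,1]
.gauss2 <- (1 + c(-1, 1) / sqrt(3)) / 2

#' Spatial locations of a component's DOFs
#'
#' Node structure gives node coordinates, element structure element
#' centroids, gauss_point the 2x2 tensor Gauss points per element,
#' data_point the user-supplied locations. Constant structure yields a
#' single entry with an undefined-location flag.
#'
#' @param component an `fp_component`.
#' @return an object of class `fp_dof_pattern`: data.frame (dof, x, y) plus
#'   attribute `undefined_location`.
#' @export
dof_locations <- function(component) {
  stopifnot(inherits(component, "fp_component"))
  mesh <- component$mesh
  undef <- FALSE
  loc <- switch(component$structure,
    node = mesh$nodes,
    element = {
      t(apply(mesh$elements, 1L, function(en) colMeans(mesh$nodes[en, , drop = FALSE])))
    },
    gauss_point = {
      out <- matrix(0, nrow = 4L * mesh$n_elements, ncol = 2L)
      k <- 0L
      for (e in seq_len(mesh$n_elements)) {
        en <- mesh$elements[e, ]
        x0 <- mesh$nodes[en[1L], 1L]; y0 <- mesh$nodes[en[1L], 2L]
        hx <- mesh$nodes[en[2L], 1L] - x0; hy <- mesh$nodes[en[3L], 2L] - y0
        for (gy in .gauss2) for (gx in .gauss2) {
          k <- k + 1L
          out[k, ] <- c(x0 + gx * hx, y0 + gy * hy)
        }
      }
      out
    },
    data_point = as.matrix(component$locations),
    constant = {
      undef <- TRUE
      matrix(NA_real_, nrow = 1L, ncol = 2L)
    })
  pat <- data.frame(dof = seq_len(nrow(loc)), x = loc[, 1L], y = loc[, 2L])
  attr(pat, "undefined_location") <- undef
  class(pat) <- c("fp_dof_pattern", "data.frame")
  pat
}

#' Bilinear Lagrange interpolation inside an element
#'
#' @param field an `fp_field`.
#' @param variable variable name (node-structured components).
#' @param element element id.
#' @param xi length-2 local coordinates in the unit square.
#' @return named numeric vector of interpolated component values.
#' @export
interpolate <- function(field, variable, element, xi) {
  stopifnot(inherits(field, "fp_field"), length(xi) == 2L)
  if (any(xi < 0 | xi > 1)) stop("xi outside [0,1]^2", call. = FALSE)
  v <- field$variables[[variable]]
  if (is.null(v)) stop(sprintf("no variable '%s'", variable), call. = FALSE)
  mesh <- field$mesh
  if (element < 1L || element > mesh$n_elements) stop("element id out of range", call. = FALSE)
  en <- mesh$elements[element, ]
  phi <- bilinear_basis(xi[1L], xi[2L])
  out <- vapply(v$components, function(comp) {
    if (comp$structure != "node")
      stop(sprintf("component '%s' is not node-structured", comp$name), call. = FALSE)
    sum(phi * comp$values[en])
  }, numeric(1L))
  out
}

#' Bilinear Lagrange basis on the unit square
#' @param x,y local coordinates in [0,1].
#' @return length-4 vector in node order (bl, br, tl, tr).
#' @export
bilinear_basis <- function(x, y) {
  c((1 - x) * (1 - y), x * (1 - y), (1 - x) * y, x * y)
}

## ---- export -------------------------------------------------------------

#' Write a node-structured component as legacy VTK (structured grid)
#'
#' @param component a node-structured `fp_component` on an `fp_mesh_2d`.
#' @param path output file.
#' @param name data array name (default: the component name).
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(component, path, name = component$name) {
  stopifnot(inherits(component, "fp_component"))
  if (component$structure != "node") stop("VTK export supports node structure", call. = FALSE)
  mesh <- component$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("fieldpoint field %s/%s", component$field_name, name),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$nx + 1L, mesh$ny + 1L),
               sprintf("POINTS %d double", mesh$n_nodes)), con)
  writeLines(sprintf("%s %s 0", fp_num(mesh$nodes[, 1L]), fp_num(mesh$nodes[, 2L])), con)
  writeLines(c(sprintf("POINT_DATA %d", mesh$n_nodes),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(fp_num(component$values), con)
  invisible(path)
}

#' Write a component's DOFs as CSV (dof, x, y, value)
#' @param component an `fp_component`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(component, path) {
  pat <- dof_locations(component)
  df <- data.frame(dof = pat$dof, x = fp_num(pat$x), y = fp_num(pat$y),
                   value = fp_num(component$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed numeric formatting (12 significant digits) for byte-stable outputs
fp_num <- function(x) trimws(formatC(x, digits = 12, format = "g"))
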