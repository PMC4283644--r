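# Point models: a small declarative text format for 0D DAE systems
# (ODEs + algebraic intermediates + constants), compiled into "black box"
# evaluation objects with the standard contract
#     evaluate(voi, states, known) -> list(rates, wanted)
# Variables can be flagged "known" (value supplied from outside) and/or
# "wanted" (value exported); unflagged constants are baked into the
# compiled expressions.

# Functions an expression may call. Anything else is rejected at parse time,
# so a model file can never execute arbitrary code.
.pm_allowed_calls <- c("+", "-", "*", "/", "^", "(",
                       "exp", "log", "sqrt", "pow", "abs",
                       "piecewise",
                       "<", ">", "<=", ">=", "==", "!=", "&", "|", "!")

#' Vectorised piecewise selection for model expressions
#'
#' `piecewise(cond1, val1, cond2, val2, ..., default)` returns, elementwise,
#' the first `val` whose condition holds, else `default`.
#'
#' @param ... alternating condition/value pairs followed by a default value.
#' @return numeric vector of the common length of the arguments.
#' @export
piecewise <- function(...) {
  args <- list(...)
  if (length(args) < 3L || length(args) %% 2L != 1L)
    stop("piecewise() needs condition/value pairs plus a default", call. = FALSE)
  out <- args[[length(args)]]
  # apply pairs last-to-first so earlier conditions win
  for (i in rev(seq_len((length(args) - 1L) / 2L))) {
    cond <- args[[2L * i - 1L]]
    out <- ifelse(cond, args[[2L * i]], out)
  }
  out
}

pow <- function(a, b) a^b

# Evaluation parent environment: only whitelisted functions resolve.
.pm_base_env <- local({
  e <- new.env(parent = baseenv())
  assign("piecewise", piecewise, envir = e)
  assign("pow", pow, envir = e)
  e
})

## ---- expression handling ------------------------------------------------

# all symbols referenced by a language object
pm_expr_symbols <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) {
    return(unique(unlist(lapply(as.list(e)[-1L], pm_expr_symbols))))
  }
  character(0)
}

pm_check_calls <- function(e, where) {
  if (is.call(e)) {
    fn <- e[[1L]]
    if (!is.symbol(fn))
      stop(sprintf("in '%s': only named functions may be called", where), call. = FALSE)
    if (!(as.character(fn) %in% .pm_allowed_calls))
      stop(sprintf("in '%s': function '%s' is not permitted in model expressions",
                   where, as.character(fn)), call. = FALSE)
    lapply(as.list(e)[-1L], pm_check_calls, where = where)
  }
  invisible(NULL)
}

pm_parse_expr <- function(txt, where) {
  e <- tryCatch(str2lang(txt),
                error = function(err) stop(sprintf("cannot parse expression in '%s': %s",
                                                   where, conditionMessage(err)), call. = FALSE))
  if (!(is.call(e) || is.symbol(e) || is.numeric(e)))
    stop(sprintf("invalid expression in '%s'", where), call. = FALSE)
  pm_check_calls(e, where)
  e
}

# substitute symbols by numeric values (used for constant baking)
pm_subst <- function(e, values) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(values)) return(values[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- pm_subst(e[[i]], values)
    return(e)
  }
  e
}

## ---- model definition ---------------------------------------------------

#' Parse a point-model definition
#'
#' Reads the plain-text model format: one statement per line, `#` comments.
#' Statements are `const <name> = <number> [<unit>]`, `init <state> = <number>`,
#' `ode <state> = <expr>`, `alg <name> = <expr>` and `independent <name>`.
#' Expressions use arithmetic, comparisons, `exp`, `log`, `sqrt`, `pow`,
#' `abs` and `piecewise`.
#'
#' @param text character scalar (whole file) or character vector of lines.
#' @param name model identifier; defaults to "model".
#' @return an object of class `pm_definition` with elements `name`, `odes`
#'   (named list of rate expressions in declaration order), `algebraics`
#'   (named list, topologically ordered), `constants`, `units`,
#'   `initial_values`, `independent` and `decl_order`.
#' @export
#' @examples
#' d <- parse_model("const k = 0.5\ninit x = 2\node x = -k*x", name = "decay")
#' names(d$odes)
parse_model <- function(text, name = "model") {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1L]]
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty model definition", call. = FALSE)

  constants <- list(); units <- list(); inits <- list()
  odes <- list(); algs <- list()
  independent <- "t"
  decl_order <- character(0)
  seen <- function(nm, what) {
    if (nm %in% decl_order)
      stop(sprintf("duplicate definition of '%s' (as %s)", nm, what), call. = FALSE)
  }
  ident <- "[A-Za-z_][A-Za-z0-9_]*"

  for (ln in lines) {
    m <- regmatches(ln, regexec(sprintf("^const\\s+(%s)\\s*=\\s*(\\S+)(\\s+(\\S+))?\\s*$", ident), ln))[[1L]]
    if (length(m)) {
      nm <- m[2L]; seen(nm, "const")
      val <- suppressWarnings(as.numeric(m[3L]))
      if (is.na(val)) stop(sprintf("const '%s': '%s' is not a number", nm, m[3L]), call. = FALSE)
      constants[[nm]] <- val
      if (length(m) >= 5L && !is.na(m[5L]) && nzchar(m[5L])) units[[nm]] <- m[5L]
      decl_order <- c(decl_order, nm)
      next
    }
    m <- regmatches(ln, regexec(sprintf("^init\\s+(%s)\\s*=\\s*(\\S+)\\s*$", ident), ln))[[1L]]
    if (length(m)) {
      nm <- m[2L]
      val <- suppressWarnings(as.numeric(m[3L]))
      if (is.na(val)) stop(sprintf("init '%s': '%s' is not a number", nm, m[3L]), call. = FALSE)
      if (!is.null(inits[[nm]])) stop(sprintf("duplicate init for '%s'", nm), call. = FALSE)
      inits[[nm]] <- val
      next
    }
    m <- regmatches(ln, regexec(sprintf("^ode\\s+(%s)\\s*=\\s*(.+)$", ident), ln))[[1L]]
    if (length(m)) {
      nm <- m[2L]; seen(nm, "ode")
      odes[[nm]] <- pm_parse_expr(m[3L], paste0("ode ", nm))
      decl_order <- c(decl_order, nm)
      next
    }
    m <- regmatches(ln, regexec(sprintf("^alg\\s+(%s)\\s*=\\s*(.+)$", ident), ln))[[1L]]
    if (length(m)) {
      nm <- m[2L]; seen(nm, "alg")
      algs[[nm]] <- pm_parse_expr(m[3L], paste0("alg ", nm))
      decl_order <- c(decl_order, nm)
      next
    }
    m <- regmatches(ln, regexec(sprintf("^independent\\s+(%s)\\s*$", ident), ln))[[1L]]
    if (length(m)) { independent <- m[2L]; next }
    stop(sprintf("cannot parse model statement: '%s'", ln), call. = FALSE)
  }

  known_names <- c(names(constants), names(odes), names(algs), independent)
  # every symbol must resolve
  for (nm in names(odes)) {
    undef <- setdiff(pm_expr_symbols(odes[[nm]]), known_names)
    if (length(undef)) stop(sprintf("undefined symbol %s in ode %s", undef[1L], nm), call. = FALSE)
  }
  for (nm in names(algs)) {
    undef <- setdiff(pm_expr_symbols(algs[[nm]]), known_names)
    if (length(undef)) stop(sprintf("undefined symbol %s in alg %s", undef[1L], nm), call. = FALSE)
  }
  # every state needs an initial value; stray inits are errors
  for (nm in names(odes)) if (is.null(inits[[nm]]))
    stop(sprintf("state '%s' has no init statement", nm), call. = FALSE)
  stray <- setdiff(names(inits), names(odes))
  if (length(stray)) stop(sprintf("init given for non-state '%s'", stray[1L]), call. = FALSE)

  algs <- pm_toposort_algs(algs)

  structure(list(name = name,
                 odes = odes,
                 algebraics = algs,
                 constants = constants,
                 units = units,
                 initial_values = inits[names(odes)],
                 independent = independent,
                 decl_order = decl_order),
            class = "pm_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn topological sort of the algebraic definitions; error on cycles.
pm_toposort_algs <- function(algs) {
  if (length(algs) <= 1L) return(algs)
  nms <- names(algs)
  deps <- lapply(algs, function(e) intersect(pm_expr_symbols(e), nms))
  ordered <- character(0)
  remaining <- nms
  repeat {
    ready <- remaining[vapply(remaining, function(n) all(deps[[n]] %in% ordered), logical(1L))]
    if (!length(ready)) {
      if (!length(remaining)) break
      stop(sprintf("algebraic cycle involving '%s'", remaining[1L]), call. = FALSE)
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  algs[ordered]
}

#' Read a point-model definition from a file
#'
#' @param path path to a `.pm` model file.
#' @param name model identifier; defaults to the file name without extension.
#' @return a `pm_definition` (see [parse_model()]).
#' @export
read_model <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  parse_model(readLines(path, warn = FALSE), name = name)
}

#' Path to a model file shipped with the package
#'
#' @param name one of "decay", "hodgkin_huxley_1952", "fitzhugh_nagumo",
#'   "windkessel_rcr", "mooney_rivlin".
#' @return file path.
#' @export
shipped_model_path <- function(name) {
  p <- system.file("extdata", "models", paste0(name, ".pm"), package = "fieldpoint")
  if (!nzchar(p)) p <- file.path("inst", "extdata", "models", paste0(name, ".pm"))
  if (!file.exists(p)) stop(sprintf("no shipped model '%s'", name), call. = FALSE)
  p
}

#' Override a constant in a model definition
#'
#' Returns a copy of the definition with the named constant set to `value`.
#' Useful for building problem-specific variants (e.g. material parameters)
#' before import, without flagging the constant as known.
#'
#' @param defn a `pm_definition`.
#' @param name constant name.
#' @param value new numeric value.
#' @return modified `pm_definition`.
#' @export
pm_set_constant <- function(defn, name, value) {
  stopifnot(inherits(defn, "pm_definition"))
  if (!(name %in% names(defn$constants)))
    stop(sprintf("no constant '%s' in model '%s'", name, defn$name), call. = FALSE)
  defn$constants[[name]] <- value
  defn
}

#' @exportS3Method base::print
print.pm_definition <- function(x, ...) {
  cat(sprintf("<pm_definition '%s'>: %d state(s), %d constant(s), %d intermediate(s); independent '%s'\n",
              x$name, length(x$odes), length(x$constants), length(x$algebraics), x$independent))
  invisible(x)
}

## ---- model environment --------------------------------------------------

#' Create a point-model environment
#'
#' A mutable container for imported model definitions and their variable
#' flags. Models are imported with [import_model()], variables flagged with
#' [flag_variable()], and the environment is finished (and every model
#' compiled) with [instantiate()].
#'
#' @return an object of class `pm_environment`.
#' @export
pm_environment <- function() {
  env <- new.env(parent = emptyenv())
  env$models <- list()
  env$flags <- list()     # per model: named list of list(known, wanted)
  env$finished <- FALSE
  env$compiled <- NULL
  class(env) <- "pm_environment"
  env
}

#' @exportS3Method base::print
print.pm_environment <- function(x, ...) {
  cat(sprintf("<pm_environment>: %d model(s)%s\n", length(x$models),
              if (x$finished) ", finished" else ""))
  invisible(x)
}

#' Import a model definition into an environment
#'
#' The returned integer model index is 1-based, stable, and used to reference
#' the model in maps and fields. On import, all state variables and the
#' independent variable are flagged known and wanted; nothing else is flagged.
#'
#' @param env a `pm_environment`.
#' @param defn a `pm_definition`.
#' @return integer model index.
#' @export
import_model <- function(env, defn) {
  stopifnot(inherits(env, "pm_environment"), inherits(defn, "pm_definition"))
  if (env$finished) stop("cannot import into a finished environment", call. = FALSE)
  idx <- length(env$models) + 1L
  env$models[[idx]] <- defn
  fl <- list()
  for (nm in c(names(defn$odes), defn$independent))
    fl[[nm]] <- list(known = TRUE, wanted = TRUE)
  env$flags[[idx]] <- fl
  idx
}

pm_variable_names <- function(defn) {
  unique(c(names(defn$constants), names(defn$odes), names(defn$algebraics), defn$independent))
}

#' Flag a model variable as known and/or wanted
#'
#' A "known" variable receives its value from outside the black box (a field,
#' or the `known` argument of the evaluate call); a "wanted" variable is
#' exported from the box. Unflagged constants are baked into the compiled
#' code. The independent variable must remain known (it is always supplied).
#'
#' @param env a `pm_environment` (not finished).
#' @param model_index integer index returned by [import_model()].
#' @param name variable name in that model.
#' @param known,wanted logical flags.
#' @return the environment, invisibly.
#' @export
flag_variable <- function(env, model_index, name, known = FALSE, wanted = FALSE) {
  stopifnot(inherits(env, "pm_environment"))
  if (env$finished) stop("cannot flag variables in a finished environment", call. = FALSE)
  if (model_index < 1L || model_index > length(env$models))
    stop(sprintf("no model with index %s", model_index), call. = FALSE)
  defn <- env$models[[model_index]]
  if (!(name %in% pm_variable_names(defn)))
    stop(sprintf("no variable %s in model '%s'", name, defn$name), call. = FALSE)
  if (identical(name, defn$independent) && !known)
    stop("the independent variable is always supplied and cannot be flagged unknown",
         call. = FALSE)
  env$flags[[model_index]][[name]] <- list(known = isTRUE(known), wanted = isTRUE(wanted))
  invisible(env)
}

pm_get_flag <- function(env, model_index, name) {
  fl <- env$flags[[model_index]][[name]]
  if (is.null(fl)) list(known = FALSE, wanted = FALSE) else fl
}

## ---- compilation --------------------------------------------------------

#' Instantiate every imported model as a compiled black box
#'
#' Finishes the environment (no further imports or flag changes) and compiles
#' each model: unflagged constants are substituted numerically into the
#' expressions; flagged-known non-state variables form the `known` input
#' vector (in declaration order); flagged-wanted intermediates form the
#' `wanted` output vector (in declaration order).
#'
#' @param env a `pm_environment`.
#' @return list of `pm_compiled` objects, one per imported model (also stored
#'   in `env$compiled`).
#' @export
instantiate <- function(env) {
  stopifnot(inherits(env, "pm_environment"))
  if (env$finished) return(env$compiled)
  compiled <- vector("list", length(env$models))
  for (i in seq_along(env$models))
    compiled[[i]] <- pm_compile(env$models[[i]], env$flags[[i]])
  env$compiled <- compiled
  env$finished <- TRUE
  compiled
}

pm_compile <- function(defn, flags) {
  getf <- function(nm) flags[[nm]] %||% list(known = FALSE, wanted = FALSE)
  state_order <- names(defn$odes)
  for (nm in state_order) {
    fl <- getf(nm)
    if (!isTRUE(fl$known) && !isTRUE(fl$wanted))
      warning(sprintf("state '%s' in model '%s' is flagged neither known nor wanted; it is still integrated",
                      nm, defn$name), call. = FALSE)
  }
  # only constants can be knowns: states enter through the STATE vector and
  # intermediates are always computed inside the box
  non_state <- intersect(defn$decl_order, names(defn$constants))
  known_order <- non_state[vapply(non_state, function(nm) isTRUE(getf(nm)$known), logical(1L))]
  inter_names <- names(defn$algebraics)
  wanted_order <- defn$decl_order[defn$decl_order %in% inter_names &
                                  vapply(defn$decl_order, function(nm) isTRUE(getf(nm)$wanted), logical(1L))]

  # bake all constants that are not flagged known
  baked <- defn$constants[setdiff(names(defn$constants), known_order)]
  bake <- function(e) pm_subst(e, baked)
  algs <- lapply(defn$algebraics, bake)
  odes <- lapply(defn$odes, bake)

  default_known <- vapply(known_order, function(nm) {
    if (nm %in% names(defn$constants)) defn$constants[[nm]] else NA_real_
  }, numeric(1L))

  model <- structure(list(
    name = defn$name,
    n_states = length(state_order),
    n_known = length(known_order),
    n_wanted = length(wanted_order),
    state_order = state_order,
    known_order = known_order,
    wanted_order = wanted_order,
    initial_state = vapply(state_order, function(nm) defn$initial_values[[nm]], numeric(1L)),
    default_known = default_known,
    independent = defn$independent,
    algs = algs,
    odes = odes
  ), class = "pm_compiled")
  model$fast <- pm_codegen(model)
  model
}

# generate the evaluation routine for a compiled model: a single R function
# with the model expressions as its body (states/known columns unpacked into
# locals), evaluated in the whitelisted base environment
pm_codegen <- function(model) {
  stmts <- list()
  add <- function(e) stmts[[length(stmts) + 1L]] <<- e
  add(bquote(.n <- nrow(.states)))
  add(call("<-", as.symbol(model$independent), quote(.voi)))
  for (j in seq_along(model$state_order))
    add(call("<-", as.symbol(model$state_order[j]), bquote(.states[, .(j)])))
  for (j in seq_along(model$known_order))
    add(call("<-", as.symbol(model$known_order[j]), bquote(.known[, .(j)])))
  for (nm in names(model$algs))
    add(call("<-", as.symbol(nm), model$algs[[nm]]))
  add(bquote(.rates <- matrix(0, .n, .(model$n_states))))
  for (j in seq_len(model$n_states))
    add(call("<-", bquote(.rates[, .(j)]), model$odes[[j]]))
  add(bquote(.wanted <- matrix(0, .n, .(model$n_wanted))))
  for (j in seq_len(model$n_wanted))
    add(call("<-", bquote(.wanted[, .(j)]), as.symbol(model$wanted_order[j])))
  add(quote(list(rates = .rates, wanted = .wanted)))
  body <- as.call(c(quote(`{`), stmts))
  f <- eval(call("function", as.pairlist(alist(.voi = , .states = , .known = )), body),
            .pm_base_env)
  f
}

#' @exportS3Method base::print
print.pm_compiled <- function(x, ...) {
  cat(sprintf("<pm_compiled '%s'>: %d state(s) [%s], %d known [%s], %d wanted [%s]\n",
              x$name, x$n_states, paste(x$state_order, collapse = ","),
              x$n_known, paste(x$known_order, collapse = ","),
              x$n_wanted, paste(x$wanted_order, collapse = ",")), ...)
  invisible(x)
}

#' Evaluate a compiled point model (the black box contract)
#'
#' Pure function of its inputs: computes the rate vector and the wanted
#' intermediates from the independent variable value, the state vector and
#' the known-parameter vector.
#'
#' @param model a `pm_compiled`.
#' @param voi value of the independent variable.
#' @param states numeric vector, length `model$n_states`.
#' @param known numeric vector, length `model$n_known`.
#' @return `list(rates = <numeric>, wanted = <named numeric>)`.
#' @export
evaluate_model <- function(model, voi, states = model$initial_state,
                           known = model$default_known) {
  stopifnot(inherits(model, "pm_compiled"))
  if (length(states) != model$n_states)
    stop(sprintf("model '%s': expected %d states, got %d", model$name,
                 model$n_states, length(states)), call. = FALSE)
  if (length(known) != model$n_known)
    stop(sprintf("model '%s': expected %d known values, got %d", model$name,
                 model$n_known, length(known)), call. = FALSE)
  res <- pm_eval_batch(model, voi,
                       matrix(states, nrow = 1L),
                       matrix(known, nrow = 1L))
  list(rates = as.numeric(res$rates), wanted = stats::setNames(as.numeric(res$wanted), model$wanted_order))
}

# Batch evaluation over n instances: states is n x n_states, known n x n_known.
# All model expressions are elementwise, so evaluation vectorises across rows.
pm_eval_batch <- function(model, voi, states, known) {
  model$fast(voi, states, known)
}
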