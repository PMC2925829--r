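#' @title Kinetic model construction
#' @description Assemble a kinetic model from a reaction list: species with
#'   initial concentrations, parameters, rate laws (mass-action templates by
#'   default), exact conservation laws, and the reduced ODE system in which
#'   one dependent species per law is replaced by an algebraic assignment.
#' @name model
NULL

#' Build a kinetic model
#'
#' @param reactions reaction-list text (see [parse_reaction_list()]) or a
#'   list of [reaction()] objects
#' @param initial named numeric vector of initial concentrations
#'   (concentration units are model-defined); species not listed start at 0
#' @param parameters named numeric vector of parameter values; mass-action
#'   rate constants are auto-registered with value 1 and may be overridden
#'   here
#' @param rates named character vector of rate-law expressions overriding
#'   the mass-action template, by reaction id
#' @param rhs optional program text with auxiliary assignments evaluated
#'   before the rate laws on every right-hand-side call (may contain
#'   `if/else` blocks; their switching is handled by event location during
#'   integration)
#' @param functions named character vector of explicitly defined functions
#'   (expression text), evaluated on demand by [scan_explicit()]
#' @param time_symbol reserved symbol bound to model time (default `"t"`)
#' @param reduce eliminate one dependent species per conservation law
#'   (default `TRUE`); with `FALSE` the full unreduced ODE system is
#'   integrated, useful for cross-checking the reduction
#' @return object of class `kinetic_model`
#' @examples
#' m <- kinetic_model("v1: A => B", initial = c(A = 1),
#'                    parameters = c(kf_v1 = 0.5))
#' m
#' @export
kinetic_model <- function(reactions, initial = NULL, parameters = NULL,
                          rates = NULL, rhs = NULL, functions = NULL,
                          time_symbol = "t", reduce = TRUE) {
  if (is.character(reactions)) reactions <- parse_reaction_list(reactions)
  stopifnot(all(vapply(reactions, inherits, TRUE, "reaction")))
  S <- stoichiometric_matrix(reactions)
  species <- rownames(S)
  extra_species <- setdiff(names(initial), species)
  if (length(extra_species))
    stop("initial values given for unknown species: ",
         paste(extra_species, collapse = ", "))
  init <- stats::setNames(numeric(length(species)), species)
  if (!is.null(initial)) init[names(initial)] <- initial

  # rate laws: explicit per-reaction override > `rates` argument > template
  templates <- mass_action_rates(reactions)
  pars <- numeric()
  rate_text <- character()
  for (rx in reactions) {
    if (!is.null(rx$rate)) rate_text[[rx$id]] <- rx$rate
    else if (!is.null(rates) && rx$id %in% names(rates))
      rate_text[[rx$id]] <- rates[[rx$id]]
    else {
      rate_text[[rx$id]] <- templates[[rx$id]]$rate
      pars <- c(pars, templates[[rx$id]]$parameters)
    }
  }
  if (!is.null(parameters)) pars[names(parameters)] <- parameters

  laws <- conservation_laws(S)
  for (k in seq_along(laws))
    laws[[k]]$total_value <- sum(laws[[k]]$coefficients * init)
  red <- if (reduce) reduction_pivots(laws, species)
         else list(laws = list(), dependent = character())
  dependent <- red$dependent
  independent <- setdiff(species, dependent)
  if (reduce)
    stopifnot(length(independent) == length(species) - length(laws))

  totals <- numeric()
  dep_assign_text <- character()
  for (k in seq_along(red$laws)) {
    v <- red$laws[[k]]
    dep <- dependent[[k]]
    tot_sym <- paste0("RTotal_", k)
    totals[[tot_sym]] <- sum(v * init)
    others <- v[names(v) != dep & v != 0]
    terms <- if (length(others))
      paste(vapply(seq_along(others), function(i)
        sprintf(" - (%s)*%s", format(others[[i]]), names(others)[[i]]), ""),
        collapse = "")
    else ""
    dep_assign_text[[dep]] <-
      sprintf("(%s%s)/(%s)", tot_sym, terms, format(v[[dep]]))
  }

  rate_ast <- lapply(rate_text, parse_expression)
  rhs_prog <- if (!is.null(rhs) && nzchar(trimws(rhs))) parse_program(rhs)
  fun_ast <- lapply(as.list(functions %||% character()), parse_expression)
  dep_ast <- lapply(dep_assign_text, parse_expression)

  model <- structure(list(
    species = species, initial = init, parameters = pars,
    reactions = reactions, S = S,
    rate_text = rate_text, rate_ast = rate_ast,
    conservation_laws = laws,
    reduction = list(laws = red$laws, totals = totals,
                     assignments = dep_assign_text),
    independent = independent, dependent = dependent,
    rhs_program = rhs_prog,
    explicit_functions = fun_ast,
    time_symbol = time_symbol,
    compiled = list(
      rates = lapply(rate_ast, compile_expression),
      dep = lapply(dep_ast, compile_expression),
      rhs = if (!is.null(rhs_prog)) compile_program(rhs_prog),
      functions = lapply(fun_ast, compile_expression),
      conditions = collect_condition_margins(c(
        rate_ast, if (!is.null(rhs_prog)) list(rhs_prog)))
    )), class = "kinetic_model")
  check_model_symbols(model)
  # dependent species reconstructed at t=0 must reproduce declared initials
  st <- eval_model_state(model, model$initial[independent], t = 0)
  for (d in dependent) {
    ref <- max(abs(init[[d]]), 1e-300)
    if (abs(st$species[[d]] - init[[d]]) > 1e-12 * max(1, ref))
      stop(sprintf("dependent species '%s' inconsistent with initial values", d))
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Collect condition margins (lhs - rhs as compiled expressions) from every
# comparison node in the given ASTs/programs; used for event location.
collect_condition_margins <- function(nodes) {
  margins <- list()
  walk_expr <- function(node) {
    if (!is.list(node)) return()
    if (identical(node$type, "cmp"))
      margins[[length(margins) + 1L]] <<- call(
        "-", compile_expression(node$args[[1]]),
        compile_expression(node$args[[2]]))
    if (!is.null(node$args)) lapply(node$args, walk_expr)
  }
  walk_stmts <- function(stmts) for (st in stmts) {
    if (st$type == "assign") walk_expr(st$expr)
    else { walk_expr(st$cond); walk_stmts(st$then); walk_stmts(st$else_branch) }
  }
  for (n in nodes) {
    if (inherits(n, "dsl_program")) walk_stmts(n$statements) else walk_expr(n)
  }
  margins
}

check_model_symbols <- function(model) {
  rhs_targets <- if (!is.null(model$rhs_program))
    program_targets(model$rhs_program) else character()
  known <- c(model$species, names(model$parameters),
             names(model$reduction$totals), model$time_symbol, rhs_targets)
  check <- function(ast, what) {
    bad <- setdiff(expr_symbols(ast), known)
    if (length(bad))
      stop(sprintf("%s references unknown symbol(s): %s", what,
                   paste(bad, collapse = ", ")))
  }
  for (id in names(model$rate_ast))
    check(model$rate_ast[[id]], sprintf("rate law of '%s'", id))
  if (!is.null(model$rhs_program)) {
    d <- validate_program(model$rhs_program, known, model$time_symbol)
    err <- d[d$severity == "error", , drop = FALSE]
    if (nrow(err)) stop("invalid auxiliary program: ", err$message[[1]])
  }
  fun_known <- known
  for (nm in names(model$explicit_functions)) {
    check(model$explicit_functions[[nm]],
          sprintf("explicit function '%s'", nm))
    fun_known <- c(fun_known, nm)
  }
  invisible(TRUE)
}

## ---- evaluation machinery ---------------------------------------------------

# Fresh evaluation environment preloaded with parameters and totals.
model_env <- function(model) {
  env <- new.env(parent = baseenv())
  for (nm in names(model$parameters)) assign(nm, model$parameters[[nm]], env)
  for (nm in names(model$reduction$totals))
    assign(nm, model$reduction$totals[[nm]], env)
  env
}

# Full model state at given independent-species values: dependent species
# from conservation laws, auxiliary assignments, all reaction fluxes.
eval_model_state <- function(model, y, t = 0, env = NULL) {
  if (is.null(env)) env <- model_env(model)
  assign(model$time_symbol, t, env)
  ind <- model$independent
  for (i in seq_along(ind)) assign(ind[[i]], y[[i]], env)
  for (d in names(model$compiled$dep))
    assign(d, eval(model$compiled$dep[[d]], env), env)
  if (!is.null(model$compiled$rhs)) evaluate_into(model$compiled$rhs, env)
  v <- vapply(model$compiled$rates, eval, 0, env)
  sp <- vapply(model$species, get, 0, envir = env)
  list(species = sp, fluxes = v, env = env)
}

# Right-hand side of the reduced ODE system plus fluxes; returns a closure
# suitable for deSolve and Newton iteration.  The closure reuses one
# environment across calls.
model_rhs_function <- function(model) {
  env <- model_env(model)
  S_ind <- model$S[model$independent, , drop = FALSE]
  force(S_ind)
  function(t, y) {
    st <- eval_model_state(model, y, t, env)
    dy <- as.numeric(S_ind %*% st$fluxes)
    list(dy = dy, fluxes = st$fluxes, species = st$species)
  }
}

# Condition margins evaluated at (t, y); used as root functions so the
# integrator restarts exactly at conditional switching points.
model_condition_function <- function(model) {
  if (length(model$compiled$conditions) == 0L) return(NULL)
  env <- model_env(model)
  margins <- model$compiled$conditions
  ind <- model$independent
  function(t, y) {
    assign(model$time_symbol, t, env)
    for (i in seq_along(ind)) assign(ind[[i]], y[[i]], env)
    for (d in names(model$compiled$dep))
      assign(d, eval(model$compiled$dep[[d]], env), env)
    vapply(margins, eval, 0, env)
  }
}

## ---- functional updates ------------------------------------------------------

#' Update parameter values
#' @param model a `kinetic_model`
#' @param values named numeric vector; names must be existing parameters
#' @return updated model
#' @export
set_parameters <- function(model, values) {
  bad <- setdiff(names(values), names(model$parameters))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  model$parameters[names(values)] <- values
  model
}

#' Update initial concentrations (conserved totals are recomputed)
#' @param model a `kinetic_model`
#' @param values named numeric vector; names must be existing species
#' @return updated model
#' @export
set_initial <- function(model, values) {
  bad <- setdiff(names(values), model$species)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  model$initial[names(values)] <- values
  for (k in seq_along(model$conservation_laws))
    model$conservation_laws[[k]]$total_value <-
      sum(model$conservation_laws[[k]]$coefficients * model$initial)
  for (k in seq_along(model$reduction$laws))
    model$reduction$totals[[k]] <-
      sum(model$reduction$laws[[k]] * model$initial)
  model
}

#' Scale a reaction rate by a constant factor
#'
#' Used by metabolic control analysis: multiplies the rate law of one
#' reaction by `factor`, emulating a proportional change in enzyme activity.
#'
#' @param model a `kinetic_model`
#' @param reaction_id reaction to scale
#' @param factor positive multiplier
#' @return updated model
#' @export
scale_rate <- function(model, reaction_id, factor) {
  if (!reaction_id %in% names(model$rate_ast))
    stop("unknown reaction: ", reaction_id)
  old <- model$compiled$rates[[reaction_id]]
  model$compiled$rates[[reaction_id]] <- call("*", factor, old)
  model
}

## ---- printing ----------------------------------------------------------------

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model: %d species (%d independent), %d reactions, %d parameters\n",
              length(x$species), length(x$independent),
              length(x$reactions), length(x$parameters)))
  for (rx in x$reactions)
    cat("  ", format(rx), "   v =", x$rate_text[[rx$id]], "\n")
  if (length(x$conservation_laws)) {
    cat("Conservation laws:\n")
    for (l in x$conservation_laws) cat("  ", format(l), "\n")
    cat("Dependent species:", paste(x$dependent, collapse = ", "), "\n")
  }
  if (length(x$explicit_functions))
    cat("Explicit functions:",
        paste(names(x$explicit_functions), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy summary of model species
#' @param model a `kinetic_model`
#' @return tibble with columns `species`, `initial`, `role`
#' @export
model_species <- function(model)
  tibble::tibble(species = model$species,
                 initial = unname(model$initial[model$species]),
                 role = ifelse(model$species %in% model$dependent,
                               "dependent", "independent"))
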