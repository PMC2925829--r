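#' @title Time-course, scan and steady-state solvers
#' @description Stiff-capable integration of the reduced ODE system (LSODA
#'   automatic stiff/non-stiff switching, dense output exactly at the
#'   requested time points), grid scans of explicitly defined functions, and
#'   damped-Newton steady-state location.
#' @name solvers
NULL

#' Integrate the model over user-defined output times
#'
#' Fluxes are recomputed from the states at every output time.  When the
#' model contains conditional (`if/else`) constructs, their comparison
#' margins are tracked as integrator root functions and integration is
#' restarted exactly at each switching point, so piecewise-continuous
#' right-hand sides are handled without step-size breakdown.
#'
#' @param model a `kinetic_model`
#' @param times strictly increasing output times; the first entry is the
#'   initial time at which `model$initial` applies
#' @param rtol,atol requested accuracy of the result (defaults 1e-6, 1e-9).
#'   Because the integrator's local error control under-delivers global
#'   accuracy, the tolerances actually passed to LSODA include a fixed
#'   safety factor of 1/50.
#' @return tibble of class `kin_timecourse`: column `time`, one column per
#'   species (concentrations), one per reaction (fluxes)
#' @examples
#' m <- kinetic_model("v1: A => B", initial = c(A = 1),
#'                    parameters = c(kf_v1 = 1))
#' tc <- simulate_timecourse(m, times = c(0, 1))
#' tc$A[2]  # exp(-1)
#' @export
simulate_timecourse <- function(model, times, rtol = 1e-6, atol = 1e-9) {
  stopifnot(length(times) >= 2L, all(diff(times) > 0))
  y0 <- model$initial[model$independent]
  if (any(!is.finite(y0))) stop("initial values must be finite")
  rhs <- model_rhs_function(model)
  dfun <- function(t, y, parms) list(rhs(t, y)$dy)
  condfun <- model_condition_function(model)
  rtol_i <- rtol / 50; atol_i <- atol / 50   # global-accuracy safety factor

  if (is.null(condfun)) {
    out <- run_lsoda(dfun, y0, times, rtol_i, atol_i)
  } else {
    rootfun <- function(t, y, parms) condfun(t, y)
    rows <- matrix(NA_real_, nrow = length(times),
                   ncol = length(y0) + 1L)
    rows[1L, ] <- c(times[[1L]], y0)
    tcur <- times[[1L]]; ycur <- y0
    remaining <- times[-1L]
    guard <- 0L
    while (length(remaining) > 0L) {
      guard <- guard + 1L
      if (guard > 1000L) stop("too many conditional switching events")
      seg <- deSolve::lsodar(y = ycur, times = c(tcur, remaining),
                             func = dfun, parms = NULL,
                             rootfunc = rootfun,
                             rtol = rtol_i, atol = atol_i)
      check_desolve(seg)
      troot <- attr(seg, "troot")
      seg_t <- seg[, 1L]
      hit <- !is.null(troot) && length(troot) > 0L &&
        troot[[1L]] < remaining[[length(remaining)]] - 1e-12
      done <- seg_t[-1L]
      reached <- remaining[remaining <= max(seg_t) + 1e-12]
      for (tt in reached) {
        k <- which.min(abs(seg_t - tt))
        rows[match(tt, times), ] <- as.numeric(seg[k, seq_len(ncol(rows))])
        rows[match(tt, times), 1L] <- tt
      }
      remaining <- remaining[remaining > max(seg_t) + 1e-12]
      if (!hit && length(remaining) > 0L)
        stop(sprintf("integration stopped at t = %g", max(seg_t)))
      if (length(remaining) > 0L) {
        # restart a hair past the switching point so the new branch is active
        tcur <- troot[[1L]]
        ycur <- as.numeric(seg[nrow(seg), 1L + seq_along(y0)])
        names(ycur) <- names(y0)
        tcur <- tcur + max(1e-9, abs(tcur) * 1e-12)
      }
    }
    out <- rows
  }

  conc <- matrix(NA_real_, nrow = length(times), ncol = length(model$species),
                 dimnames = list(NULL, model$species))
  flux <- matrix(NA_real_, nrow = length(times),
                 ncol = length(model$reactions),
                 dimnames = list(NULL, vapply(model$reactions,
                                              function(r) r$id, "")))
  env <- model_env(model)
  for (i in seq_along(times)) {
    st <- eval_model_state(model, out[i, -1L], t = out[i, 1L], env = env)
    conc[i, ] <- st$species[model$species]
    flux[i, ] <- st$fluxes
  }
  res <- tibble::as_tibble(cbind(data.frame(time = times), conc, flux))
  attr(res, "species") <- model$species
  attr(res, "reactions") <- colnames(flux)
  attr(res, "independent_label") <- model$time_symbol
  class(res) <- c("kin_timecourse", class(res))
  res
}

run_lsoda <- function(dfun, y0, times, rtol, atol) {
  out <- withCallingHandlers(
    deSolve::lsoda(y = y0, times = times, func = dfun, parms = NULL,
                   rtol = rtol, atol = atol),
    warning = function(w) invokeRestart("muffleWarning"))
  check_desolve(out)
  if (nrow(out) < length(times))
    stop(sprintf("integration stopped at t = %g", out[nrow(out), 1L]))
  out
}

check_desolve <- function(out) {
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[[1L]] < 0 && istate[[1L]] != -1)
    stop(sprintf("integrator failure (istate = %d) at t = %g",
                 istate[[1L]], out[nrow(out), 1L]))
  invisible(out)
}

#' Scan explicitly defined functions over a parameter grid
#'
#' Evaluates each named explicit function on the fixed-step grid
#' `seq(lo, hi, by = initial_step)`; all other symbols are taken from the
#' model's current parameter and initial values.  A grid point at which
#' evaluation fails (domain error) is recorded as `NA` and the scan
#' continues.
#'
#' @param model a `kinetic_model` with explicit functions
#' @param function_names functions to evaluate (default: all)
#' @param variable symbol to vary: a parameter or a species
#' @param lo,hi scan interval, `lo < hi`
#' @param initial_step grid step
#' @return tibble of class `kin_scan`: the varied symbol plus one column per
#'   function
#' @export
scan_explicit <- function(model, function_names = NULL, variable, lo, hi,
                          initial_step) {
  stopifnot(lo < hi, initial_step > 0)
  if (is.null(function_names)) function_names <- names(model$explicit_functions)
  missing_f <- setdiff(function_names, names(model$explicit_functions))
  if (length(missing_f))
    stop("not an explicit function: ", paste(missing_f, collapse = ", "))
  if (!(variable %in% c(model$species, names(model$parameters))))
    stop("unknown scan variable: ", variable)
  grid <- seq(lo, hi, by = initial_step)
  vals <- matrix(NA_real_, nrow = length(grid), ncol = length(function_names),
                 dimnames = list(NULL, function_names))
  env <- model_env(model)
  for (sp in model$species) assign(sp, model$initial[[sp]], env)
  assign(model$time_symbol, 0, env)
  all_names <- names(model$explicit_functions)
  for (i in seq_along(grid)) {
    assign(variable, grid[[i]], env)
    ok <- TRUE
    for (nm in all_names) {        # earlier functions usable by later ones
      v <- tryCatch(suppressWarnings(eval(model$compiled$functions[[nm]],
                                           env)),
                    error = function(e) NA_real_)
      if (!is.finite(v)) v <- NA_real_
      assign(nm, v, env)
      if (nm %in% function_names) vals[i, nm] <- v
    }
  }
  if (all(is.na(vals))) stop("explicit scan failed at every grid point")
  res <- tibble::as_tibble(cbind(stats::setNames(data.frame(grid), variable),
                                 vals))
  class(res) <- c("kin_scan", class(res))
  res
}

## ---- steady state -----------------------------------------------------------

# Finite-difference Jacobian of the reduced RHS: forward differences with
# relative perturbation 1e-7 and absolute floor 1e-10.
reduced_jacobian <- function(rhs, y, f0 = NULL) {
  n <- length(y)
  if (is.null(f0)) f0 <- rhs(0, y)$dy
  J <- matrix(0, n, n, dimnames = list(names(y), names(y)))
  for (j in seq_len(n)) {
    h <- max(1e-7 * abs(y[[j]]), 1e-10)
    yp <- y; yp[[j]] <- yp[[j]] + h
    J[, j] <- (rhs(0, yp)$dy - f0) / h
  }
  J
}

#' Locate a steady state by damped Newton iteration
#'
#' Iterates on the reduced right-hand side until the residual infinity norm
#' drops below `tol`.  Dependent species are reconstructed from the
#' conservation laws at the solution.
#'
#' @param model a `kinetic_model`
#' @param initial_guess named vector over independent species (default: the
#'   model's initial values)
#' @param tol residual tolerance, infinity norm (default 1e-9)
#' @param max_iter maximum Newton iterations (default 50)
#' @return object of class `kin_steady_state`: `state` (all species),
#'   `independent`, `fluxes`, `jacobian` (reduced, finite differences),
#'   `residual`, `iterations`
#' @export
steady_state <- function(model, initial_guess = NULL, tol = 1e-9,
                         max_iter = 50L) {
  y <- if (is.null(initial_guess)) model$initial[model$independent]
       else initial_guess[model$independent]
  if (any(!is.finite(y))) stop("initial guess must be finite")
  rhs <- model_rhs_function(model)
  f <- rhs(0, y)$dy
  best <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) <= tol) break
    J <- reduced_jacobian(rhs, y, f)
    delta <- tryCatch(solve(J, -f), error = function(e) {
      stop(sprintf(
        "singular Jacobian in Newton iteration (reciprocal condition ~ %.2e)",
        rcond_est(J)))
    })
    lambda <- 1
    repeat {
      y_new <- y + lambda * delta
      f_new <- tryCatch(rhs(0, y_new)$dy, error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          max(abs(f_new)) < max(abs(f))) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop(sprintf(
          "steady state did not converge: best residual %.3e after %d iterations",
          best, it))
    }
    y <- y_new; f <- f_new
    best <- min(best, max(abs(f)))
  }
  if (max(abs(f)) > tol)
    stop(sprintf(
      "steady state did not converge: best residual %.3e after %d iterations",
      best, max_iter))
  stopifnot(max(abs(f)) <= tol)   # contract: residual within tol on return
  J <- reduced_jacobian(rhs, y, f)
  st <- eval_model_state(model, y, t = 0)
  structure(list(state = st$species, independent = y, fluxes = st$fluxes,
                 jacobian = J, residual = max(abs(f)),
                 iterations = it),
            class = "kin_steady_state")
}

rcond_est <- function(J) tryCatch(rcond(J), error = function(e) NA_real_)

#' @export
print.kin_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (residual %.2e, %d Newton iterations)\n",
              x$residual, x$iterations))
  print(round(x$state, 8))
  invisible(x)
}
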