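#' @title Parameter fitting
#' @description Fit model parameters to experimental data of three kinds -
#'   time courses (ODE), steady state versus a parameter (implicit) and
#'   explicitly defined functions - with four objective functions (squares,
#'   modulus, relative squares, relative modulus), direct-search or
#'   quasi-Newton optimization, and post-fit statistics (standard
#'   deviations, confidence intervals, ANOVA).
#' @name fitter
NULL

#' Construct a dataset for fitting
#'
#' @param kind `"ode"` (time course), `"implicit"` (steady state vs
#'   parameter) or `"explicit"` (explicit function vs scanned symbol)
#' @param data data frame: one independent column plus one column per
#'   observed variable; missing observations as `NA` (skipped in the
#'   objective)
#' @param independent name of the independent column: time for `"ode"`, the
#'   swept parameter for `"implicit"`, the scanned symbol for `"explicit"`
#' @param weight nonnegative dataset weight (default 1); weights combine
#'   heterogeneous dataset kinds in one objective
#' @return object of class `fit_dataset`
#' @export
fit_dataset <- function(kind = c("ode", "implicit", "explicit"), data,
                        independent, weight = 1) {
  kind <- match.arg(kind)
  data <- tibble::as_tibble(data)
  stopifnot(independent %in% names(data), weight >= 0)
  x <- data[[independent]]
  if (kind == "ode" && any(diff(x) <= 0))
    stop("time values must be strictly increasing for an ode dataset")
  structure(list(kind = kind, data = data, independent = independent,
                 variables = setdiff(names(data), independent),
                 weight = weight),
            class = "fit_dataset")
}

#' Read a delimited experimental data table
#'
#' Comma- or tab-delimited (auto-detected), header row naming the
#' independent column and observed variables, empty fields as missing.
#'
#' @param path file path
#' @return tibble
#' @export
read_data_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      na.strings = c("", "NA"),
                                      check.names = FALSE,
                                      comment.char = "#"))
}

#' Define a fit problem
#'
#' @param model a `kinetic_model`
#' @param datasets list of [fit_dataset()] objects (a single dataset is
#'   accepted)
#' @param parameters active parameters: data frame with columns `name`,
#'   `start`, `lo`, `hi` (or a named numeric of starts, with infinite
#'   default bounds for sign-free parameters and `(start/1e4, start*1e4)`
#'   for positive starts)
#' @param objective one of `"squares"`, `"modulus"`, `"relative_squares"`,
#'   `"relative_modulus"`
#' @param method `"zero_order"` (direct-search simplex) or `"first_order"`
#'   (quasi-Newton with finite-difference gradients)
#' @return object of class `fit_problem`
#' @export
fit_problem <- function(model, datasets, parameters,
                        objective = c("squares", "modulus",
                                      "relative_squares", "relative_modulus"),
                        method = c("zero_order", "first_order")) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  if (inherits(datasets, "fit_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, TRUE, "fit_dataset")))
  if (is.numeric(parameters)) {
    parameters <- tibble::tibble(
      name = names(parameters), start = unname(parameters),
      lo = ifelse(parameters > 0, unname(parameters) / 1e4, -Inf),
      hi = ifelse(parameters > 0, unname(parameters) * 1e4, Inf))
  }
  parameters <- tibble::as_tibble(parameters)
  stopifnot(all(c("name", "start", "lo", "hi") %in% names(parameters)))
  bad <- setdiff(parameters$name, names(model$parameters))
  if (length(bad)) stop("active parameters not in model: ",
                        paste(bad, collapse = ", "))
  if (any(parameters$lo >= parameters$hi))
    stop("parameter bounds must satisfy lo < hi")
  if (any(parameters$start < parameters$lo | parameters$start > parameters$hi))
    stop("parameter start values must lie within their bounds")
  structure(list(model = model, datasets = datasets,
                 parameters = parameters, objective = objective,
                 method = method),
            class = "fit_problem")
}

#' Objective (discrepancy) between theoretical and experimental values
#'
#' The four forms are `squares` \eqn{\sum (Y_t - Y_e)^2}; `modulus`
#' \eqn{\sum |Y_t - Y_e|}; `relative_squares`
#' \eqn{\sum (Y_t - Y_e)^2 / Y_e^2}; `relative_modulus`
#' \eqn{\sum |Y_t - Y_e| / |Y_e|}.
#'
#' @param y_t,y_e theoretical and experimental values (equal-shape vectors
#'   or matrices); `NA` in `y_e` is skipped
#' @param objective objective type
#' @param weight scalar dataset weight
#' @return F0, a nonnegative number
#' @export
objective_value <- function(y_t, y_e,
                            objective = c("squares", "modulus",
                                          "relative_squares",
                                          "relative_modulus"),
                            weight = 1) {
  objective <- match.arg(objective)
  stopifnot(length(y_t) == length(y_e))
  keep <- !is.na(y_e)
  y_t <- as.numeric(y_t)[keep]; y_e <- as.numeric(y_e)[keep]
  if (grepl("relative", objective) && any(y_e == 0)) {
    i <- which(y_e == 0)[[1L]]
    stop(sprintf("relative objective undefined: experimental value %d is zero", i))
  }
  r <- y_t - y_e
  weight * switch(objective,
                  squares = sum(r^2),
                  modulus = sum(abs(r)),
                  relative_squares = sum(r^2 / y_e^2),
                  relative_modulus = sum(abs(r) / abs(y_e)))
}

#' Simulate theoretical values for every dataset of a fit problem
#'
#' `ode` datasets are integrated at the dataset times (initial values at
#' time 0); `implicit` datasets are solved for the steady state at each
#' parameter value, warm-started along the sweep; `explicit` datasets are
#' explicit-function evaluations at the dataset points.  The three kinds may
#' be mixed in one problem.
#'
#' @param problem a `fit_problem`
#' @param parameter_values named numeric vector of active-parameter trial
#'   values
#' @return list of matrices (points x variables), one per dataset
#' @export
simulate_for_fit <- function(problem, parameter_values) {
  model <- set_parameters(problem$model, parameter_values)
  lapply(problem$datasets, function(d) simulate_dataset(model, d))
}

simulate_dataset <- function(model, d) {
  x <- d$data[[d$independent]]
  out <- matrix(NA_real_, nrow = length(x), ncol = length(d$variables),
                dimnames = list(NULL, d$variables))
  if (d$kind == "ode") {
    times <- sort(unique(c(0, x)))
    tc <- simulate_timecourse(model, times)
    idx <- match(x, tc$time)
    for (v in d$variables) out[, v] <- tc[[v]][idx]
  } else if (d$kind == "implicit") {
    guess <- NULL
    ord <- order(x)
    for (i in ord) {
      ss <- steady_state(
        set_parameters(model, stats::setNames(x[[i]], d$independent)),
        initial_guess = guess)
      guess <- ss$state
      vals <- c(ss$state, ss$fluxes)
      out[i, ] <- vals[d$variables]
    }
  } else {
    sc <- scan_points(model, d$variables, d$independent, x)
    out[, d$variables] <- as.matrix(sc[, d$variables])
  }
  out
}

# Explicit-function evaluation at arbitrary points (shared by fitting and
# scan_explicit's fixed grid).
scan_points <- function(model, function_names, variable, points) {
  env <- model_env(model)
  for (sp in model$species) assign(sp, model$initial[[sp]], env)
  assign(model$time_symbol, 0, env)
  all_names <- names(model$explicit_functions)
  missing_f <- setdiff(function_names, all_names)
  if (length(missing_f))
    stop("not an explicit function: ", paste(missing_f, collapse = ", "))
  vals <- matrix(NA_real_, length(points), length(function_names),
                 dimnames = list(NULL, function_names))
  for (i in seq_along(points)) {
    assign(variable, points[[i]], env)
    for (nm in all_names) {
      v <- tryCatch(suppressWarnings(eval(model$compiled$functions[[nm]],
                                           env)),
                    error = function(e) NA_real_)
      if (!is.finite(v)) v <- NA_real_
      assign(nm, v, env)
      if (nm %in% function_names) vals[i, nm] <- v
    }
  }
  out <- stats::setNames(data.frame(points), variable)
  tibble::as_tibble(cbind(out, vals))
}

# Total objective at active-parameter values; +Inf on simulation failure so
# the optimizer rejects the trial point.
problem_objective <- function(problem, parameter_values) {
  sims <- tryCatch(simulate_for_fit(problem, parameter_values),
                   error = function(e) NULL)
  if (is.null(sims)) return(Inf)
  total <- 0
  for (k in seq_along(problem$datasets)) {
    d <- problem$datasets[[k]]
    y_e <- as.matrix(d$data[, d$variables, drop = FALSE])
    f <- tryCatch(objective_value(sims[[k]], y_e, problem$objective, d$weight),
                  error = function(e) Inf)
    if (!is.finite(f)) return(Inf)
    total <- total + f
  }
  total
}

## ---- parameter transforms -----------------------------------------------------

# Positive-bounded parameters are optimized on log scale.
make_transform <- function(pars) {
  logscale <- pars$lo > 0
  list(
    to = function(p) ifelse(logscale, log(p), p),
    from = function(th) ifelse(logscale, exp(th), th),
    lo = ifelse(logscale, log(pars$lo), pars$lo),
    hi = ifelse(logscale, log(pars$hi), pars$hi))
}

#' Fit a model to experimental data
#'
#' `zero_order` is a bounded direct-search simplex (Nelder-Mead, restarted
#' once from its solution to guard against simplex collapse; Brent search
#' for a single parameter); `first_order` is bounded quasi-Newton (L-BFGS-B)
#' with finite-difference gradients.  Parameters with positive bounds are
#' transformed to log scale.  Termination: relative F0 change below 1e-9 or
#' `max_evaluations`.
#'
#' @param problem a `fit_problem`
#' @param max_evaluations objective-evaluation budget (default 1e4)
#' @param seed RNG seed for randomized restarts (default 0)
#' @return object of class `kin_fit`: estimates, `F0`, per-parameter
#'   statistics (for squares-type objectives), ANOVA table, convergence log
#' @export
fit_model <- function(problem, max_evaluations = 1e4, seed = 0) {
  stopifnot(inherits(problem, "fit_problem"))
  pars <- problem$parameters
  tr <- make_transform(pars)
  nev <- 0L
  obj_theta <- function(theta) {
    if (any(theta < tr$lo - 1e-12) || any(theta > tr$hi + 1e-12)) return(Inf)
    nev <<- nev + 1L
    problem_objective(problem, stats::setNames(tr$from(theta), pars$name))
  }
  theta0 <- tr$to(pars$start)
  f_start <- obj_theta(theta0)
  if (!is.finite(f_start))
    stop("objective is not finite at the starting parameter values")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  run_opt <- function(theta_init) {
    if (problem$method == "zero_order") {
      if (length(theta_init) == 1L) {
        lo <- max(tr$lo, theta_init - 50); hi <- min(tr$hi, theta_init + 50)
        o <- stats::optimize(function(th) obj_theta(th), c(lo, hi),
                             tol = 1e-12)
        list(par = o$minimum, value = o$objective)
      } else {
        o <- stats::optim(theta_init, obj_theta, method = "Nelder-Mead",
                          control = list(reltol = 1e-9,
                                         maxit = max_evaluations))
        # restart once from the solution against simplex collapse
        o2 <- stats::optim(o$par, obj_theta, method = "Nelder-Mead",
                           control = list(reltol = 1e-9,
                                          maxit = max_evaluations))
        if (o2$value < o$value) o <- o2
        list(par = o$par, value = o$value)
      }
    } else {
      safe_obj <- function(th) { v <- obj_theta(th); if (is.finite(v)) v else 1e30 }
      o <- stats::optim(theta_init, safe_obj, method = "L-BFGS-B",
                        lower = tr$lo, upper = tr$hi,
                        control = list(factr = 1e2, maxit = max_evaluations))
      list(par = o$par, value = o$value)
    }
  }
  sol <- run_opt(theta0)
  warn <- character()
  if (sol$value > f_start + 1e-15) {
    sol <- list(par = theta0, value = f_start)
    warn <- c(warn, "no improvement from the starting point")
  }
  estimates <- stats::setNames(tr$from(sol$par), pars$name)
  stats_res <- tryCatch(fit_statistics(problem, estimates),
                        error = function(e) NULL)
  structure(list(problem = problem, estimates = estimates,
                 F0 = sol$value, F0_start = f_start,
                 evaluations = nev, warnings = warn,
                 statistics = stats_res, seed = seed),
            class = "kin_fit")
}

#' Post-fit statistics: standard deviations, confidence intervals, ANOVA
#'
#' Linearized (Gauss-Newton) statistics: the residual sensitivity matrix `G`
#' is computed by finite differences at the estimates, the covariance is
#' \eqn{s^2 (G^T G)^{-1}} with \eqn{s^2 = F_0/(n-p)}, and 95% confidence
#' intervals use the t quantile with `n - p` degrees of freedom.  The ANOVA
#' table decomposes the weighted total sum of squares about the mean into
#' regression and residual parts.  For modulus-type objectives the same
#' linearization is applied to the squared residuals and the result is
#' flagged as a caveat.
#'
#' @param problem a `fit_problem`
#' @param estimates named numeric of converged estimates
#' @param level confidence level (default 0.95)
#' @return list: `parameters` tibble (`term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`), `anova` tibble, `s2`, `n`, `p`, `caveat`
#' @export
fit_statistics <- function(problem, estimates, level = 0.95) {
  pars <- problem$parameters
  stopifnot(setequal(names(estimates), pars$name))
  estimates <- estimates[pars$name]
  residvec <- function(pv) {
    sims <- simulate_for_fit(problem, pv)
    unlist(lapply(seq_along(problem$datasets), function(k) {
      d <- problem$datasets[[k]]
      y_e <- as.matrix(d$data[, d$variables, drop = FALSE])
      r <- (sims[[k]] - y_e)
      if (grepl("relative", problem$objective)) r <- r / y_e
      sqrt(d$weight) * r[!is.na(y_e)]
    }))
  }
  r0 <- residvec(estimates)
  n <- length(r0); p <- nrow(pars)
  if (n <= p) stop(sprintf("no residual degrees of freedom (n = %d, p = %d)",
                           n, p))
  G <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-6 * abs(estimates[[j]]), 1e-9)
    pv <- estimates; pv[[j]] <- pv[[j]] + h
    G[, j] <- (residvec(pv) - r0) / h
  }
  rss <- sum(r0^2)
  F0 <- if (problem$objective %in% c("squares", "relative_squares")) rss
        else problem_objective(problem, estimates)
  s2 <- rss / (n - p)
  gtg <- crossprod(G)
  cov <- tryCatch(s2 * solve(gtg), error = function(e) NULL)
  nonident <- is.null(cov)
  sd <- if (nonident) rep(Inf, p) else sqrt(pmax(diag(cov), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - p)
  params <- tibble::tibble(term = pars$name,
                           estimate = unname(estimates),
                           std.error = sd,
                           conf.low = unname(estimates) - tq * sd,
                           conf.high = unname(estimates) + tq * sd)
  # ANOVA on the weight-scaled raw residuals (relative scaling is a
  # property of the objective, not of the decomposition)
  sims0 <- simulate_for_fit(problem, estimates)
  raw <- lapply(seq_along(problem$datasets), function(k) {
    d <- problem$datasets[[k]]
    y_e <- as.matrix(d$data[, d$variables, drop = FALSE])
    keep <- !is.na(y_e)
    list(res = sqrt(d$weight) * (sims0[[k]] - y_e)[keep],
         obs = sqrt(d$weight) * y_e[keep])
  })
  obs <- unlist(lapply(raw, `[[`, "obs"))
  total <- sum((obs - mean(obs))^2)
  residual <- sum(unlist(lapply(raw, `[[`, "res"))^2)
  regression <- total - residual
  anova_tbl <- tibble::tibble(
    source = c("regression", "residual", "total"),
    sum_sq = c(regression, residual, total),
    df = c(p, n - p, n),
    mean_sq = c(regression / p, residual / (n - p), NA_real_))
  Fstat <- (regression / p) / (residual / (n - p))
  list(parameters = params, anova = anova_tbl, F_statistic = Fstat,
       s2 = s2, n = n, p = p, F0 = F0,
       caveat = if (problem$objective %in% c("modulus", "relative_modulus"))
         "linearized statistics computed on squared residuals" else NULL,
       nonidentifiable = nonident)
}

## ---- broom-style accessors ------------------------------------------------------

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("Model fit (%s objective, %s): F0 = %.6g (start %.6g), %d evaluations\n",
              x$problem$objective, x$problem$method, x$F0, x$F0_start,
              x$evaluations))
  if (length(x$warnings)) cat("warning:", x$warnings, "\n")
  if (!is.null(x$statistics)) print(x$statistics$parameters)
  else print(round(x$estimates, 6))
  invisible(x)
}

#' Tidy per-parameter fit results
#' @param x a `kin_fit`
#' @param ... unused
#' @return tibble with columns `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`
#' @export
tidy.kin_fit <- function(x, ...) {
  if (!is.null(x$statistics)) return(x$statistics$parameters)
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates),
                 std.error = NA_real_, conf.low = NA_real_,
                 conf.high = NA_real_)
}

#' One-row fit summary
#' @param x a `kin_fit`
#' @param ... unused
#' @return tibble with `F0`, `F0_start`, `n`, `p`, `s2`, `F_statistic`,
#'   `evaluations`
#' @export
glance.kin_fit <- function(x, ...) {
  s <- x$statistics
  tibble::tibble(F0 = x$F0, F0_start = x$F0_start,
                 n = if (is.null(s)) NA_integer_ else s$n,
                 p = if (is.null(s)) NA_integer_ else s$p,
                 s2 = if (is.null(s)) NA_real_ else s$s2,
                 F_statistic = if (is.null(s)) NA_real_ else s$F_statistic,
                 evaluations = x$evaluations)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
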