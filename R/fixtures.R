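#' @title Bundled toy models and synthetic datasets
#' @description Small kinetic models exercising every part of the package -
#'   linear decay, an open chain, a closed conserved four-species cycle
#'   driven by an external substrate (a miniature tricarboxylic-acid-like
#'   cycle), the fold normal form, the Brusselator, a damped oscillator with
#'   a focus-node transition, a reversible three-step chain, and a
#'   Michaelis-Menten explicit function - plus seeded synthetic datasets
#'   (independent Gaussian noise) for each fitting kind.
#' @name fixtures
NULL

#' Names of the bundled fixture models
#' @return character vector
#' @export
fixture_names <- function() c("decay", "open_chain", "mini_krebs", "fold",
                              "brusselator", "damped_oscillator",
                              "reversible_chain", "mm_explicit")

#' Build a bundled fixture model
#'
#' * `decay`: `A -> B`, mass action, `kf_v1 = 0.7`.
#' * `open_chain`: `-> A -> B ->`, all rate constants 1.
#' * `mini_krebs`: closed cycle `A -> B -> C -> D -> A` with the first step
#'   driven by the external substrate parameter `S_ext` (default 2
#'   concentration units, stepped to 10 in the demonstration sweep); one
#'   conservation law (total pool 4).
#' * `fold`: one-species fold normal form, `dX/dt = p - X^2`.
#' * `brusselator`: the four-reaction Brusselator scheme, `a = 1`,
#'   `b = 1.5`; a Hopf bifurcation sits at `b = 1 + a^2`.
#' * `damped_oscillator`: two-species linear system whose eigenvalues change
#'   from a complex pair to real (focus to node) as the damping parameter
#'   `d` crosses 2.
#' * `reversible_chain`: boundary-driven three-step chain with reversible
#'   steps, used by the metabolic control analysis examples.
#' * `mm_explicit`: explicit Michaelis-Menten rate `v = Vm*S/(Km + S)`,
#'   `Vm = 2`, `Km = 0.5`.
#'
#' @param name one of [fixture_names()]
#' @return a `kinetic_model`
#' @export
fixture_model <- function(name) {
  switch(match.arg(name, fixture_names()),
    decay = kinetic_model("v1: A => B", initial = c(A = 1),
                          parameters = c(kf_v1 = 0.7)),
    open_chain = kinetic_model("vin: => A\nv1: A => B\nvout: B =>",
                               initial = c(A = 1, B = 1)),
    mini_krebs = kinetic_model(
      "v1: A => B\nv2: B => C\nv3: C => D\nv4: D => A",
      initial = c(A = 2, B = 1, C = 0.5, D = 0.5),
      parameters = c(S_ext = 2, k1 = 0.5, k2 = 1, k3 = 2, k4 = 1),
      rates = c(v1 = "k1*S_ext*A", v2 = "k2*B", v3 = "k3*C", v4 = "k4*D")),
    fold = kinetic_model(
      list(reaction("vin", products = c(X = 1), rate = "p"),
           reaction("vout", substrates = c(X = 1), rate = "X^2")),
      initial = c(X = 1), parameters = c(p = 1)),
    brusselator = kinetic_model(
      list(reaction("r1", products = c(X = 1), rate = "a"),
           reaction("r2", substrates = c(X = 1), products = c(Y = 1),
                    rate = "b*X"),
           reaction("r3", substrates = c(X = 2, Y = 1), products = c(X = 3),
                    rate = "X^2*Y"),
           reaction("r4", substrates = c(X = 1), rate = "X")),
      initial = c(X = 1, Y = 1.5), parameters = c(a = 1, b = 1.5)),
    damped_oscillator = kinetic_model(
      list(reaction("r1", products = c(A = 1), rate = "p0 - B"),
           reaction("r2", products = c(B = 1), rate = "A - d*B")),
      initial = c(A = 2, B = 1), parameters = c(p0 = 1, d = 1)),
    reversible_chain = kinetic_model(
      list(reaction("v1", products = c(A = 1), rate = "k1*S0 - km1*A"),
           reaction("v2", substrates = c(A = 1), products = c(B = 1),
                    rate = "k2*A - km2*B"),
           reaction("v3", substrates = c(B = 1), rate = "k3*B")),
      initial = c(A = 0.5, B = 0.5),
      parameters = c(S0 = 2, k1 = 1, km1 = 0.5, k2 = 2, km2 = 1, k3 = 1.5)),
    mm_explicit = kinetic_model(
      "v1: A => B", initial = c(A = 1),
      parameters = c(kf_v1 = 1, Vm = 2, Km = 0.5, S = 1),
      functions = c(v = "Vm*S/(Km + S)")))
}

# model definition files for one fixture: reaction list, initial
# values/parameters program, and rate-override program where the rates are
# not plain mass action.
fixture_files <- function(name) {
  m <- fixture_model(name)
  iv <- c(
    vapply(m$species, function(s)
      sprintf("%s = %s;", s, fmt_num(m$initial[[s]])), ""),
    vapply(names(m$parameters), function(p)
      sprintf("%s = %s;", p, fmt_num(m$parameters[[p]])), ""))
  templates <- mass_action_rates(m$reactions)
  overrides <- character()
  for (rx in m$reactions)
    if (!identical(m$rate_text[[rx$id]], templates[[rx$id]]$rate))
      overrides <- c(overrides,
                     sprintf("%s = %s;", rx$id, m$rate_text[[rx$id]]))
  funs <- vapply(names(m$explicit_functions), function(fn)
    sprintf("%s = %s;", fn, format_expression(m$explicit_functions[[fn]])), "")
  list(rct = format_reaction_list(m$reactions),
       iv = paste(iv, collapse = "\n"),
       rhs = if (length(overrides)) paste(overrides, collapse = "\n"),
       fns = if (length(funs)) paste(funs, collapse = "\n"))
}

#' Generate fixture model files and seeded synthetic datasets
#'
#' Writes, for every fixture model, its reaction list (`.rct`), an
#' initial-value program (`.iv`) and, where rates are not mass action, a
#' rate program (`.rhs`) / explicit-function program (`.fns`); plus three
#' noisy datasets (independent Gaussian noise, standard deviation `sigma`):
#' a decay time course (`decay_timecourse.csv`, n = 200), a steady-state
#' sweep of the open chain (`open_chain_steady.csv`) and a Michaelis-Menten
#' explicit-function table (`mm_explicit_rate.csv`).  Generation is
#' deterministic given `seed`.
#'
#' @param outdir output directory (created if missing)
#' @param seed RNG seed
#' @param sigma noise standard deviation (default 0.02 concentration units)
#' @param n_timecourse points in the decay time course (default 200)
#' @return tibble listing the files written
#' @export
generate_fixtures <- function(outdir, seed = 0, sigma = 0.02,
                              n_timecourse = 200L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  files <- character()
  put <- function(name, text) {
    p <- file.path(outdir, name)
    writeLines(text, p)
    files <<- c(files, p)
    p
  }
  for (nm in fixture_names()) {
    fx <- fixture_files(nm)
    put(paste0(nm, ".rct"), fx$rct)
    put(paste0(nm, ".iv"), fx$iv)
    if (!is.null(fx$rhs)) put(paste0(nm, ".rhs"), fx$rhs)
    if (!is.null(fx$fns)) put(paste0(nm, ".fns"), fx$fns)
  }

  csv_text <- function(df) c(paste(names(df), collapse = ","),
                             apply(df, 1L, function(r)
                               paste(sprintf("%.17g", r), collapse = ",")))

  # decay time course: A(t) = exp(-0.7 t) + noise
  tt <- seq(0.05, 10, length.out = n_timecourse)
  dec <- data.frame(time = tt, A = exp(-0.7 * tt) + stats::rnorm(n_timecourse, 0, sigma))
  put("decay_timecourse.csv", csv_text(dec))

  # open chain steady state: A* = kf_vin / kf_v1 = p (all constants 1)
  pv <- seq(0.2, 2, by = 0.1)
  oc <- data.frame(kf_vin = pv, A = pv + stats::rnorm(length(pv), 0, sigma))
  put("open_chain_steady.csv", csv_text(oc))

  # Michaelis-Menten explicit rate: v = 2 S / (0.5 + S)
  sv <- seq(0.1, 4, by = 0.26)
  mmv <- data.frame(S = sv,
                    v = 2 * sv / (0.5 + sv) + stats::rnorm(length(sv), 0, sigma))
  put("mm_explicit_rate.csv", csv_text(mmv))

  tibble::tibble(file = files)
}
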