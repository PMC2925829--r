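# Independent oracles used across the suite.

# Random small reaction network with unit/small-integer coefficients,
# guaranteed non-degenerate (substrate and product sets disjoint).
random_network <- function(n_species = sample(2:6, 1),
                           n_reactions = sample(1:6, 1),
                           unit_coefficients = FALSE) {
  species <- paste0("S", seq_len(n_species))
  rxns <- lapply(seq_len(n_reactions), function(j) {
    ns <- sample(0:2, 1)
    np <- if (ns == 0L) sample(1:2, 1) else sample(0:2, 1)
    subs <- sample(species, ns)
    prods <- sample(setdiff(species, subs), min(np, n_species - ns))
    coeff <- function(k) if (unit_coefficients) rep(1, k) else sample(1:3, k,
                                                                replace = TRUE)
    reaction(paste0("r", j),
             stats::setNames(coeff(length(subs)), subs),
             stats::setNames(coeff(length(prods)), prods))
  })
  ok <- vapply(rxns, function(r)
    length(r$substrates) + length(r$products) > 0, TRUE)
  rxns[ok]
}

# Floating-point rank oracle (QR), independent of the package's exact
# integer elimination.
rank_qr <- function(M) if (length(M) == 0L) 0L else qr(M)$rank

# Random expression text drawn from the shared subset of the model DSL and
# base R (same operator precedence, same function names), so base R's own
# parser/evaluator serves as the independent reference evaluator.
random_expression <- function(depth = 3, vars = c("x", "y", "z")) {
  if (depth <= 0 || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.5) sprintf("%.6g", stats::runif(1, 0.1, 5))
    else sample(vars, 1)
  } else {
    a <- random_expression(depth - 1, vars)
    b <- random_expression(depth - 1, vars)
    pick <- sample(7, 1)
    switch(pick,
           sprintf("(%s + %s)", a, b),
           sprintf("(%s - %s)", a, b),
           sprintf("(%s * %s)", a, b),
           sprintf("(%s / %s)", a, b),
           sprintf("(%s^%.3g)", a, stats::runif(1, 0.2, 2)),
           sprintf("exp(-abs(%s))", a),
           sprintf("sqrt(abs(%s) + 1)", a))
  }
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- pmax(abs(expected), 1e-12)
  expect_lte(max(abs(actual - expected) / scale), tol)
}
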