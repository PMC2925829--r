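#' @title Reaction lists and stoichiometry
#' @description Parse line-oriented reaction-list text (one reaction per
#'   line, `id : 2*A + B => C`, `<=>` for reversible, an empty side for an
#'   exchange reaction), build the species-by-reactions stoichiometric
#'   matrix and generate mass-action rate templates.
#' @name reactions
NULL

#' Construct a reaction
#'
#' @param id short reaction name
#' @param substrates,products named integer vectors (species -> positive
#'   stoichiometric coefficient); one side may be empty for an exchange
#'   reaction
#' @param modifiers character vector of species appearing only in the rate
#'   law (stoichiometric coefficient 0)
#' @param reversible logical
#' @param rate optional rate-law text overriding the mass-action template
#' @return object of class `reaction`
#' @export
reaction <- function(id, substrates = numeric(), products = numeric(),
                     modifiers = character(), reversible = FALSE,
                     rate = NULL) {
  substrates <- norm_side(substrates, id, "substrate")
  products <- norm_side(products, id, "product")
  if (length(substrates) == 0L && length(products) == 0L)
    stop(sprintf("reaction '%s': both sides empty", id))
  both <- intersect(names(substrates), names(products))
  for (sp in both)
    if (substrates[[sp]] == products[[sp]] && !(sp %in% modifiers))
      stop(sprintf(
        "reaction '%s': species '%s' has identical coefficient on both sides; declare it a modifier",
        id, sp))
  structure(list(id = id, substrates = substrates, products = products,
                 modifiers = modifiers, reversible = isTRUE(reversible),
                 rate = rate),
            class = "reaction")
}

norm_side <- function(x, id, side) {
  if (length(x) == 0L) return(stats::setNames(numeric(), character()))
  if (is.null(names(x)) || any(names(x) == ""))
    stop(sprintf("reaction '%s': %s side must be a named vector", id, side))
  if (any(x <= 0) || any(x != floor(x)))
    stop(sprintf("reaction '%s': %s coefficients must be positive integers",
                 id, side))
  # merge duplicates (A + A == 2*A)
  tapply_res <- tapply(as.numeric(x), names(x), sum)
  stats::setNames(as.numeric(tapply_res), names(tapply_res))[unique(names(x))]
}

#' @export
format.reaction <- function(x, ...) {
  side <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(v == 1, names(v), paste0(format(v), "*", names(v))),
          collapse = " + ")
  }
  paste0(x$id, ": ", side(x$substrates),
         if (x$reversible) " <=> " else " => ", side(x$products))
}

#' @export
print.reaction <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Parse reaction-list text
#'
#' One reaction per line; blank lines and lines starting with `#` are
#' ignored.  Grammar: `line := ID ':' side ARROW side`,
#' `side := [term ('+' term)*]`, `term := [INT '*'] ID`,
#' `ARROW := '=>' | '<=>'`.  Omitted coefficients default to 1; an empty
#' side denotes an exchange (source/sink) reaction.
#'
#' @param text reaction-list text (single string, possibly multi-line)
#' @return list of `reaction` objects in file order
#' @examples
#' rxns <- parse_reaction_list("v1: A => B\nv2: B => C")
#' stoichiometric_matrix(rxns)
#' @export
parse_reaction_list <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  out <- list()
  ids <- character()
  for (i in seq_along(lines)) {
    raw <- trimws(lines[[i]])
    if (raw == "" || startsWith(raw, "#")) next
    rx <- parse_reaction_line(raw, i)
    if (rx$id %in% ids)
      stop(sprintf("line %d: duplicate reaction id '%s'", i, rx$id))
    ids <- c(ids, rx$id)
    out[[length(out) + 1L]] <- rx
  }
  out
}

parse_reaction_line <- function(line, lineno) {
  perr <- function(tok, why)
    stop(sprintf("line %d: malformed reaction near '%s' (%s)",
                 lineno, tok, why))
  m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:(.*)$", line))[[1]]
  if (length(m) == 0L) perr(line, "expected 'id : ...'")
  id <- m[[2]]; rest <- m[[3]]
  reversible <- grepl("<=>", rest, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "=>"
  if (!grepl(arrow, rest, fixed = TRUE)) perr(rest, "missing '=>' or '<=>'")
  sides <- strsplit(rest, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) perr(rest, "more than one arrow")
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "") return(stats::setNames(numeric(), character()))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    sp <- character(); co <- numeric()
    for (term in terms) {
      tm <- regmatches(term,
        regexec("^(?:(-?[0-9]+)\\s*\\*\\s*)?([A-Za-z_][A-Za-z0-9_]*)$", term))[[1]]
      if (length(tm) == 0L) perr(term, "expected '[coeff*]species'")
      coeff <- if (tm[[2]] == "") 1 else as.numeric(tm[[2]])
      if (coeff <= 0)
        stop(sprintf("line %d: coefficient %s of '%s' must be positive",
                     lineno, tm[[2]], tm[[3]]))
      sp <- c(sp, tm[[3]]); co <- c(co, coeff)
    }
    stats::setNames(co, sp)
  }
  reaction(id, parse_side(sides[[1]]), parse_side(sides[[2]]),
           reversible = reversible)
}

#' Serialize reactions to reaction-list text
#' @param reactions list of `reaction` objects
#' @return single string; `parse_reaction_list()` on it reproduces the input
#' @export
format_reaction_list <- function(reactions)
  paste(vapply(reactions, format, ""), collapse = "\n")

#' Species universe of a reaction list, ordered by first appearance
#' @param reactions list of `reaction` objects
#' @return character vector of species ids
#' @export
reaction_species <- function(reactions) {
  out <- character()
  for (rx in reactions)
    out <- union(out, c(names(rx$substrates), names(rx$products),
                        rx$modifiers))
  out
}

#' Build the stoichiometric matrix
#'
#' Entry (i, j) is the net coefficient of species i in reaction j
#' (products minus substrates); modifiers contribute 0.  Species rows are
#' ordered by first appearance in the reaction list.
#'
#' @param reactions list of `reaction` objects
#' @return integer matrix with species row names and reaction column names
#' @export
stoichiometric_matrix <- function(reactions) {
  species <- reaction_species(reactions)
  ids <- vapply(reactions, function(r) r$id, "")
  S <- matrix(0L, nrow = length(species), ncol = length(reactions),
              dimnames = list(species, ids))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    for (sp in names(rx$substrates))
      S[sp, j] <- S[sp, j] - as.integer(rx$substrates[[sp]])
    for (sp in names(rx$products))
      S[sp, j] <- S[sp, j] + as.integer(rx$products[[sp]])
    exchange <- length(rx$substrates) == 0L || length(rx$products) == 0L
    if (all(S[, j] == 0L) && !exchange)
      stop(sprintf(
        "reaction '%s' is degenerate: net stoichiometry is zero and it is not an exchange",
        rx$id))
  }
  S
}

#' Generate mass-action rate templates
#'
#' Irreversible: `v = kf_id * prod(substrate^coeff)`; reversible adds
#' `- kr_id * prod(product^coeff)`.  An exchange reaction with an empty
#' substrate side gets the constant influx `kf_id` (empty product over the
#' empty set is 1).
#'
#' @param reactions list of `reaction` objects
#' @param prefix_forward,prefix_backward prefixes for the auto-registered
#'   rate constants (default values 1)
#' @return named list: reaction id -> list(rate = expression text,
#'   parameters = named numeric of new rate constants)
#' @export
mass_action_rates <- function(reactions, prefix_forward = "kf_",
                              prefix_backward = "kr_") {
  out <- list()
  for (rx in reactions) {
    term <- function(side) {
      if (length(side) == 0L) return("1")
      paste(ifelse(side == 1, names(side),
                   paste0(names(side), "^", format(side))), collapse = "*")
    }
    kf <- paste0(prefix_forward, rx$id)
    pars <- stats::setNames(1, kf)
    fwd <- if (length(rx$substrates) == 0L) kf
           else paste0(kf, "*", term(rx$substrates))
    rate <- fwd
    if (rx$reversible) {
      kr <- paste0(prefix_backward, rx$id)
      pars[kr] <- 1
      bwd <- if (length(rx$products) == 0L) kr
             else paste0(kr, "*", term(rx$products))
      rate <- paste0(fwd, " - ", bwd)
    }
    out[[rx$id]] <- list(rate = rate, parameters = pars)
  }
  out
}
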