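#' @title SBML Level 2 Version 4 exchange
#' @description Import and export of the supported SBML subset: species
#'   (initial concentrations or amounts), compartments (imported as scaling
#'   constants), global and local parameters, reactions with mass-action or
#'   arbitrary kinetic laws, and assignment rules (conservation-law
#'   dependent species on export; parameter rules map to explicit
#'   functions).  Events, algebraic rules, rate rules, function definitions
#'   and delays are rejected with a named-feature error, never dropped
#'   silently.
#' @name sbml
NULL

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
SBML_TIME_URL <- "http://www.sbml.org/sbml/symbols/time"

## ---- expression tree <-> MathML -----------------------------------------------

ast_to_mathml <- function(node, parent, time_symbol = "t") {
  add <- function(name, ...) xml2::xml_add_child(parent, name, ...)
  apply_op <- function(opname, args) {
    ap <- add("apply")
    xml2::xml_add_child(ap, opname)
    for (a in args) ast_to_mathml(a, ap, time_symbol)
  }
  switch(node$type,
    num = {
      cn <- add("cn")
      xml2::xml_text(cn) <- fmt_num(node$value)
    },
    sym = {
      if (identical(node$name, time_symbol)) {
        ci <- add("csymbol", encoding = "text",
                  definitionURL = SBML_TIME_URL)
        xml2::xml_text(ci) <- node$name
      } else {
        ci <- add("ci")
        xml2::xml_text(ci) <- node$name
      }
    },
    neg = apply_op("minus", node$args),
    bin = apply_op(switch(node$op, "+" = "plus", "-" = "minus",
                          "*" = "times", "/" = "divide", "^" = "power"),
                   node$args),
    cmp = apply_op(switch(node$op, "<" = "lt", "<=" = "leq", ">" = "gt",
                          ">=" = "geq", "==" = "eq", "!=" = "neq"),
                   node$args),
    fun = {
      if (node$name == "pow") return(apply_op("power", node$args))
      if (node$name == "sqrt") {
        ap <- add("apply"); xml2::xml_add_child(ap, "root")
        ast_to_mathml(node$args[[1]], ap, time_symbol)
        return(invisible())
      }
      if (node$name == "log10") {
        ap <- add("apply"); xml2::xml_add_child(ap, "log")
        lb <- xml2::xml_add_child(ap, "logbase")
        cn <- xml2::xml_add_child(lb, "cn"); xml2::xml_text(cn) <- "10"
        ast_to_mathml(node$args[[1]], ap, time_symbol)
        return(invisible())
      }
      apply_op(switch(node$name, ln = "ln", exp = "exp", abs = "abs",
                      min = "min", max = "max",
                      stop("expression not representable in the SBML MathML subset: function '",
                           node$name, "'")),
               node$args)
    })
  invisible()
}

mathml_to_ast <- function(node, time_symbol = "t") {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "math") {
    if (length(kids) != 1L) stop("invalid MathML: expected one child of <math>")
    return(mathml_to_ast(kids[[1L]], time_symbol))
  }
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      mant <- as.numeric(xml2::xml_text(parts[[1L]]))
      expo <- as.numeric(xml2::xml_text(parts[[length(parts)]]))
      return(list(type = "num", value = mant * 10^expo))
    }
    return(list(type = "num", value = as.numeric(xml2::xml_text(node))))
  }
  if (nm == "ci") return(list(type = "sym",
                              name = trimws(xml2::xml_text(node))))
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (identical(url, SBML_TIME_URL))
      return(list(type = "sym", name = time_symbol))
    if (grepl("delay", url %||% ""))
      stop("unsupported SBML feature: delay csymbol")
    stop("unsupported SBML csymbol: ", url)
  }
  if (nm == "apply") {
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], mathml_to_ast, time_symbol = time_symbol)
    bin_chain <- function(rop) Reduce(function(a, b)
      list(type = "bin", op = rop, args = list(a, b)), args)
    return(switch(op,
      plus = if (length(args) == 0L) list(type = "num", value = 0)
             else bin_chain("+"),
      minus = if (length(args) == 1L) list(type = "neg", args = args)
              else bin_chain("-"),
      times = if (length(args) == 0L) list(type = "num", value = 1)
              else bin_chain("*"),
      divide = bin_chain("/"),
      power = list(type = "bin", op = "^", args = args),
      root = {
        degree <- which(vapply(kids[-1L], function(k)
          xml2::xml_name(k) == "degree", TRUE))
        if (length(degree)) stop("unsupported MathML: <root> with explicit degree")
        list(type = "fun", name = "sqrt", args = args)
      },
      log = {
        is_base <- vapply(kids[-1L], function(k)
          xml2::xml_name(k) == "logbase", TRUE)
        base_val <- if (any(is_base))
          as.numeric(xml2::xml_text(kids[-1L][is_base][[1L]])) else 10
        if (base_val != 10) stop("unsupported MathML: log base ", base_val)
        list(type = "fun", name = "log10", args = args[!is_base])
      },
      ln = list(type = "fun", name = "ln", args = args),
      exp = list(type = "fun", name = "exp", args = args),
      abs = list(type = "fun", name = "abs", args = args),
      min = list(type = "fun", name = "min", args = args),
      max = list(type = "fun", name = "max", args = args),
      lt = list(type = "cmp", op = "<", args = args),
      leq = list(type = "cmp", op = "<=", args = args),
      gt = list(type = "cmp", op = ">", args = args),
      geq = list(type = "cmp", op = ">=", args = args),
      eq = list(type = "cmp", op = "==", args = args),
      neq = list(type = "cmp", op = "!=", args = args),
      stop("unsupported MathML operator: ", op)))
  }
  stop("unsupported MathML element: ", nm)
}

## ---- export ---------------------------------------------------------------------

#' Export a kinetic model as SBML L2V4
#'
#' Conservation-law dependent species are exported as assignment rules (with
#' `boundaryCondition="true"`); explicit functions become assignment rules
#' on non-constant parameters.  Export is deterministic: the same model
#' always produces an identical document.
#'
#' @param model a `kinetic_model`
#' @param path output file
#' @param model_id SBML model id (default `"model"`)
#' @return `path`, invisibly
#' @export
export_sbml <- function(model, path, model_id = "model") {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "2",
                            version = "4")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id)

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", size = "1")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (sp in model$species) {
    dep <- sp %in% model$dependent
    xml2::xml_add_child(ls, "species", id = sp, compartment = "cell",
                        initialConcentration = fmt_num(model$initial[[sp]]),
                        boundaryCondition = if (dep) "true" else "false")
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (pn in names(model$parameters))
    xml2::xml_add_child(lp, "parameter", id = pn,
                        value = fmt_num(model$parameters[[pn]]),
                        constant = "true")
  for (tn in names(model$reduction$totals))
    xml2::xml_add_child(lp, "parameter", id = tn,
                        value = fmt_num(model$reduction$totals[[tn]]),
                        constant = "true")
  for (fn in names(model$explicit_functions))
    xml2::xml_add_child(lp, "parameter", id = fn, value = "0",
                        constant = "false")

  rules <- c(
    lapply(names(model$reduction$assignments), function(dep) list(
      variable = dep,
      ast = parse_expression(model$reduction$assignments[[dep]]))),
    lapply(names(model$explicit_functions), function(fn) list(
      variable = fn, ast = model$explicit_functions[[fn]])))
  if (length(rules)) {
    lr <- xml2::xml_add_child(mdl, "listOfRules")
    for (rl in rules) {
      rn <- xml2::xml_add_child(lr, "assignmentRule", variable = rl$variable)
      mn <- xml2::xml_add_child(rn, "math", xmlns = MATHML_NS)
      ast_to_mathml(rl$ast, mn, model$time_symbol)
    }
  }

  lrx <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rx in model$reactions) {
    rn <- xml2::xml_add_child(lrx, "reaction", id = rx$id,
                              reversible = if (rx$reversible) "true" else "false")
    if (length(rx$substrates)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (sp in names(rx$substrates))
        xml2::xml_add_child(lre, "speciesReference", species = sp,
                            stoichiometry = fmt_num(rx$substrates[[sp]]))
    }
    if (length(rx$products)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (sp in names(rx$products))
        xml2::xml_add_child(lpr, "speciesReference", species = sp,
                            stoichiometry = fmt_num(rx$products[[sp]]))
    }
    if (length(rx$modifiers)) {
      lmo <- xml2::xml_add_child(rn, "listOfModifiers")
      for (sp in rx$modifiers)
        xml2::xml_add_child(lmo, "modifierSpeciesReference", species = sp)
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    mn <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    ast_to_mathml(model$rate_ast[[rx$id]], mn, model$time_symbol)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- import ---------------------------------------------------------------------

sbml_unsupported <- function(feature)
  stop(sprintf("unsupported SBML feature: %s", feature))

#' Import an SBML Level 2 file as a kinetic model
#'
#' Supported subset: compartments (sizes registered as constants), species,
#' global and reaction-local parameters, reactions with kinetic laws,
#' assignment rules (species rules must correspond to conservation-law
#' dependent species; parameter rules become explicit functions).  Events,
#' algebraic rules, rate rules, function definitions, constraints and
#' delays raise an error naming the feature.
#'
#' @param path SBML file
#' @return a `kinetic_model`
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "sbml") stop("not an SBML document")
  level <- xml2::xml_attr(doc, "level")
  if (!identical(level, "2"))
    stop("unsupported SBML level: ", level %||% "missing")
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, "./model")
  if (inherits(mdl, "xml_missing")) stop("invalid SBML: no <model> element")

  rejected <- c(listOfEvents = "events",
                listOfFunctionDefinitions = "function definitions",
                listOfConstraints = "constraints",
                listOfInitialAssignments = "initial assignments")
  for (el in names(rejected))
    if (!inherits(xml2::xml_find_first(mdl, paste0("./", el)), "xml_missing"))
      sbml_unsupported(rejected[[el]])

  comp_sizes <- c()
  for (cn in xml2::xml_find_all(mdl, "./listOfCompartments/compartment")) {
    sz <- xml2::xml_attr(cn, "size")
    comp_sizes[[xml2::xml_attr(cn, "id")]] <-
      if (is.na(sz)) 1 else as.numeric(sz)
  }
  if (length(comp_sizes) == 0L) comp_sizes <- c(cell = 1)

  species_ids <- character(); initial <- numeric()
  boundary <- character()
  for (sn in xml2::xml_find_all(mdl, "./listOfSpecies/species")) {
    id <- xml2::xml_attr(sn, "id")
    comp <- xml2::xml_attr(sn, "compartment")
    size <- if (!is.na(comp) && comp %in% names(comp_sizes))
      comp_sizes[[comp]] else 1
    conc <- xml2::xml_attr(sn, "initialConcentration")
    amt <- xml2::xml_attr(sn, "initialAmount")
    value <- if (!is.na(conc)) as.numeric(conc)
             else if (!is.na(amt)) as.numeric(amt) / size
             else 0
    species_ids <- c(species_ids, id)
    initial[[id]] <- value
  }

  params <- numeric()
  for (pn in xml2::xml_find_all(mdl, "./listOfParameters/parameter")) {
    v <- xml2::xml_attr(pn, "value")
    params[[xml2::xml_attr(pn, "id")]] <- if (is.na(v)) 0 else as.numeric(v)
  }
  # compartment sizes available as symbols in kinetic laws
  for (cid in names(comp_sizes))
    if (!cid %in% names(params)) params[[cid]] <- comp_sizes[[cid]]

  species_rules <- list(); functions <- character()
  for (rn in xml2::xml_find_all(mdl, "./listOfRules/*")) {
    rnm <- xml2::xml_name(rn)
    if (rnm == "algebraicRule") sbml_unsupported("algebraic rules")
    if (rnm == "rateRule") sbml_unsupported("rate rules")
    if (rnm != "assignmentRule") sbml_unsupported(rnm)
    var <- xml2::xml_attr(rn, "variable")
    ast <- mathml_to_ast(xml2::xml_find_first(rn, "./math"))
    if (var %in% species_ids) species_rules[[var]] <- ast
    else {
      functions[[var]] <- format_expression(ast)
      params <- params[names(params) != var]
    }
  }

  reactions <- list()
  rates <- character()
  for (rn in xml2::xml_find_all(mdl, "./listOfReactions/reaction")) {
    id <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    side <- function(xp) {
      refs <- xml2::xml_find_all(rn, xp)
      if (length(refs) == 0L) return(stats::setNames(numeric(), character()))
      st <- vapply(refs, function(r) {
        s <- xml2::xml_attr(r, "stoichiometry")
        if (is.na(s)) 1 else as.numeric(s)
      }, 0)
      stats::setNames(st, vapply(refs, xml2::xml_attr, "", "species"))
    }
    mods <- vapply(xml2::xml_find_all(
      rn, "./listOfModifiers/modifierSpeciesReference"),
      xml2::xml_attr, "", "species")
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    rate <- NULL
    if (!inherits(kl, "xml_missing")) {
      for (lp in xml2::xml_find_all(
        kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")) {
        lid <- xml2::xml_attr(lp, "id")
        lval <- as.numeric(xml2::xml_attr(lp, "value"))
        if (lid %in% names(params) || lid %in% species_ids) {
          newid <- paste(id, lid, sep = "_")
          params[[newid]] <- lval
          # rename inside this law only
          attr(lp, "rename") <- newid
        } else params[[lid]] <- lval
      }
      ast <- mathml_to_ast(xml2::xml_find_first(kl, "./math"))
      for (lp in xml2::xml_find_all(
        kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")) {
        newid <- attr(lp, "rename")
        if (!is.null(newid))
          ast <- rename_symbol(ast, xml2::xml_attr(lp, "id"), newid)
      }
      rate <- format_expression(ast)
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(id, side("./listOfReactants/speciesReference"),
               side("./listOfProducts/speciesReference"),
               modifiers = mods, reversible = rev, rate = rate)
  }
  if (length(reactions) == 0L) stop("SBML model has no reactions")

  model <- kinetic_model(reactions,
                         initial = initial[reaction_species(reactions)],
                         parameters = params,
                         functions = if (length(functions)) functions,
                         time_symbol = "t")
  # species assignment rules must agree with the derived conservation laws
  extra <- setdiff(names(species_rules), model$dependent)
  if (length(extra))
    sbml_unsupported(sprintf(
      "assignment rule on species '%s' that is not conservation-dependent",
      extra[[1L]]))
  model
}

rename_symbol <- function(node, from, to) {
  if (node$type == "sym") {
    if (identical(node$name, from)) node$name <- to
    return(node)
  }
  if (!is.null(node$args))
    node$args <- lapply(node$args, rename_symbol, from = from, to = to)
  node
}
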