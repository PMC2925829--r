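#' @title Model-definition expression language
#' @description Parser, validator and evaluator for the small statement
#'   language used in right-hand-side (RHS) and initial-value (IV) programs,
#'   reaction rate laws and explicit functions.  A program is a sequence of
#'   `;`-terminated assignments `variable = expression;` plus conditional
#'   blocks `if (condition) {statements} else {statements}`.  Expressions
#'   support numeric literals, identifiers, `+ - * / ^`, unary minus,
#'   parentheses, comparisons (`< <= > >= == !=`) and the function set
#'   `exp, ln, log10, sqrt, abs, pow, min, max`.  `//` starts a line comment.
#' @name dsl
NULL

DSL_FUNCTIONS <- c(exp = 1L, ln = 1L, log10 = 1L, sqrt = 1L, abs = 1L,
                   pow = 2L, min = 2L, max = 2L)
DSL_COMPARISONS <- c("<", "<=", ">", ">=", "==", "!=")

dsl_error <- function(class, msg, line = NA_integer_, col = NA_integer_) {
  stop(structure(
    class = c(class, "dsl_error", "error", "condition"),
    list(message = if (is.na(line)) msg else
           sprintf("line %d, column %d: %s", line, col, msg),
         call = NULL, line = line, col = col)))
}

## ---- tokenizer ------------------------------------------------------------

dsl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  toks <- list()
  two_char <- c("<=", ">=", "==", "!=")
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L; n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
      if (ch == "/" && i < n && substr(s, i + 1L, i + 1L) == "/") break
      two <- if (i < n) substr(s, i, i + 1L) else ""
      if (two %in% two_char) {
        toks[[length(toks) + 1L]] <- list(type = "op", value = two,
                                          line = ln, col = i)
        i <- i + 2L; next
      }
      if (grepl("^[0-9.]", ch)) {
        m <- regmatches(substr(s, i, n),
                        regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                                substr(s, i, n)))
        if (length(m) == 0L || m == "")
          dsl_error("dsl_parse_error", sprintf("malformed number near '%s'",
                                               substr(s, i, i + 5L)), ln, i)
        toks[[length(toks) + 1L]] <- list(type = "num",
                                          value = as.numeric(m),
                                          line = ln, col = i)
        i <- i + nchar(m); next
      }
      if (grepl("^[A-Za-z_]", ch)) {
        m <- regmatches(substr(s, i, n),
                        regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(s, i, n)))
        toks[[length(toks) + 1L]] <- list(type = "id", value = m,
                                          line = ln, col = i)
        i <- i + nchar(m); next
      }
      if (ch %in% c("+", "-", "*", "/", "^", "(", ")", "{", "}", ";", "=",
                    "<", ">", ",")) {
        toks[[length(toks) + 1L]] <- list(type = "op", value = ch,
                                          line = ln, col = i)
        i <- i + 1L; next
      }
      dsl_error("dsl_parse_error", sprintf("unexpected character '%s'", ch),
                ln, i)
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", value = "",
                                    line = length(lines), col = 1L)
  toks
}

## ---- parser ---------------------------------------------------------------

# Token-stream cursor shared by the recursive-descent routines.
dsl_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env
}
p_peek <- function(p) p$tokens[[p$pos]]
p_next <- function(p) { t <- p$tokens[[p$pos]]; p$pos <- p$pos + 1L; t }
p_expect <- function(p, value) {
  t <- p_peek(p)
  if (t$type == "op" && t$value == value) return(p_next(p))
  dsl_error("dsl_parse_error",
            sprintf("expected '%s' but found '%s'", value,
                    if (t$type == "eof") "end of input" else t$value),
            t$line, t$col)
}
p_is <- function(p, value) {
  t <- p_peek(p)
  t$type == "op" && t$value == value
}

#' Parse a model-definition program
#'
#' @param text program source: `;`-terminated assignments and `if/else`
#'   blocks, `//` comments.
#' @return an object of class `dsl_program` with elements `statements`
#'   (list of assignment / conditional nodes) and `source_text`.
#' @examples
#' prog <- parse_program("v = Vm*S/(Km + S);")
#' evaluate_program(prog, list(Vm = 2, Km = 1, S = 1))$v
#' @export
parse_program <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  p <- dsl_parser(dsl_tokenize(text))
  stmts <- list()
  while (p_peek(p)$type != "eof")
    stmts[[length(stmts) + 1L]] <- parse_statement(p)
  structure(list(statements = stmts, source_text = text),
            class = "dsl_program")
}

parse_statement <- function(p) {
  t <- p_peek(p)
  if (t$type == "id" && t$value == "if") return(parse_if(p))
  if (t$type != "id")
    dsl_error("dsl_parse_error",
              sprintf("expected identifier or 'if' but found '%s'",
                      if (t$type == "eof") "end of input" else
                        as.character(t$value)), t$line, t$col)
  target <- p_next(p)
  p_expect(p, "=")
  expr <- parse_expr(p)
  p_expect(p, ";")
  list(type = "assign", target = target$value, expr = expr,
       line = target$line, col = target$col)
}

parse_if <- function(p) {
  kw <- p_next(p)                       # 'if'
  p_expect(p, "(")
  cond <- parse_expr(p)
  p_expect(p, ")")
  then_branch <- parse_block(p)
  else_branch <- list()
  t <- p_peek(p)
  if (t$type == "id" && t$value == "else") { p_next(p); else_branch <- parse_block(p) }
  list(type = "if", cond = cond, then = then_branch, else_branch = else_branch,
       line = kw$line, col = kw$col)
}

parse_block <- function(p) {
  p_expect(p, "{")
  stmts <- list()
  while (!p_is(p, "}")) {
    if (p_peek(p)$type == "eof") {
      t <- p_peek(p)
      dsl_error("dsl_parse_error", "unterminated block: expected '}'",
                t$line, t$col)
    }
    stmts[[length(stmts) + 1L]] <- parse_statement(p)
  }
  p_next(p)
  stmts
}

# precedence (low to high): comparison < additive < multiplicative <
# unary minus < power; power is right-associative and binds tighter than
# unary minus, so -a^b parses as -(a^b).
parse_expr <- function(p) parse_comparison(p)

parse_comparison <- function(p) {
  lhs <- parse_additive(p)
  t <- p_peek(p)
  if (t$type == "op" && t$value %in% DSL_COMPARISONS) {
    p_next(p)
    rhs <- parse_additive(p)
    return(list(type = "cmp", op = t$value, args = list(lhs, rhs)))
  }
  lhs
}

parse_additive <- function(p) {
  lhs <- parse_multiplicative(p)
  repeat {
    t <- p_peek(p)
    if (t$type == "op" && t$value %in% c("+", "-")) {
      p_next(p)
      rhs <- parse_multiplicative(p)
      lhs <- list(type = "bin", op = t$value, args = list(lhs, rhs))
    } else return(lhs)
  }
}

parse_multiplicative <- function(p) {
  lhs <- parse_unary(p)
  repeat {
    t <- p_peek(p)
    if (t$type == "op" && t$value %in% c("*", "/")) {
      p_next(p)
      rhs <- parse_unary(p)
      lhs <- list(type = "bin", op = t$value, args = list(lhs, rhs))
    } else return(lhs)
  }
}

parse_unary <- function(p) {
  if (p_is(p, "-")) {
    p_next(p)
    return(list(type = "neg", args = list(parse_unary(p))))
  }
  if (p_is(p, "+")) { p_next(p); return(parse_unary(p)) }
  parse_power(p)
}

parse_power <- function(p) {
  base <- parse_primary(p)
  if (p_is(p, "^")) {
    p_next(p)
    exponent <- parse_unary(p)          # right assoc, allows 2^-3
    return(list(type = "bin", op = "^", args = list(base, exponent)))
  }
  base
}

parse_primary <- function(p) {
  t <- p_peek(p)
  if (t$type == "num") { p_next(p); return(list(type = "num", value = t$value)) }
  if (t$type == "id") {
    p_next(p)
    if (p_is(p, "(")) {                 # function call
      if (!t$value %in% names(DSL_FUNCTIONS))
        dsl_error("dsl_unknown_function",
                  sprintf("unknown function '%s'", t$value), t$line, t$col)
      p_next(p)
      args <- list(parse_expr(p))
      while (p_is(p, ",")) { p_next(p); args[[length(args) + 1L]] <- parse_expr(p) }
      p_expect(p, ")")
      arity <- DSL_FUNCTIONS[[t$value]]
      if (length(args) != arity)
        dsl_error("dsl_parse_error",
                  sprintf("function '%s' expects %d argument(s), got %d",
                          t$value, arity, length(args)), t$line, t$col)
      return(list(type = "fun", name = t$value, args = args))
    }
    return(list(type = "sym", name = t$value))
  }
  if (p_is(p, "(")) {
    p_next(p)
    e <- parse_expr(p)
    p_expect(p, ")")
    return(e)
  }
  dsl_error("dsl_parse_error",
            sprintf("expected expression but found '%s'",
                    if (t$type == "eof") "end of input" else
                      as.character(t$value)), t$line, t$col)
}

#' Parse a single expression (no assignment)
#' @param text expression source text
#' @return expression tree (internal node list)
#' @export
parse_expression <- function(text) {
  p <- dsl_parser(dsl_tokenize(text))
  e <- parse_expr(p)
  t <- p_peek(p)
  if (t$type != "eof")
    dsl_error("dsl_parse_error",
              sprintf("trailing input after expression: '%s'", t$value),
              t$line, t$col)
  e
}

## ---- pretty printer -------------------------------------------------------

dsl_prec <- function(node) {
  switch(node$type,
         cmp = 1L, bin = switch(node$op, "+" = 2L, "-" = 2L,
                                "*" = 3L, "/" = 3L, "^" = 5L),
         neg = 4L, num = , sym = , fun = 6L)
}

#' Render an expression tree back to source text
#' @param node expression tree
#' @return single string; reparses to an identical tree
#' @export
format_expression <- function(node) {
  wrap <- function(child, parent_prec, strict = FALSE) {
    s <- format_expression(child)
    cp <- dsl_prec(child)
    if (cp < parent_prec || (strict && cp == parent_prec)) paste0("(", s, ")")
    else s
  }
  switch(node$type,
    num = {
      v <- node$value
      if (v == floor(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
      else format(v, digits = 17)
    },
    sym = node$name,
    neg = paste0("-", wrap(node$args[[1]], 4L, strict = FALSE)),
    cmp = paste0(wrap(node$args[[1]], 2L), " ", node$op, " ",
                 wrap(node$args[[2]], 2L)),
    bin = {
      pr <- dsl_prec(node)
      # parenthesize equal-precedence operands on the non-associative side
      # so that print -> parse reproduces the tree, not just the value
      left_strict <- node$op == "^"
      right_strict <- node$op != "^"
      paste0(wrap(node$args[[1]], pr, strict = left_strict),
             if (node$op == "^") "^" else paste0(" ", node$op, " "),
             wrap(node$args[[2]], pr, strict = right_strict))
    },
    fun = paste0(node$name, "(",
                 paste(vapply(node$args, format_expression, ""),
                       collapse = ", "), ")"))
}

#' @export
format.dsl_program <- function(x, ...) {
  fmt_stmt <- function(st, indent = "") {
    if (st$type == "assign")
      return(paste0(indent, st$target, " = ", format_expression(st$expr), ";"))
    body <- function(stmts) paste(
      vapply(stmts, fmt_stmt, "", indent = paste0(indent, "  ")),
      collapse = "\n")
    s <- paste0(indent, "if (", format_expression(st$cond), ") {\n",
                body(st$then), "\n", indent, "}")
    if (length(st$else_branch))
      s <- paste0(s, " else {\n", body(st$else_branch), "\n", indent, "}")
    s
  }
  paste(vapply(x$statements, fmt_stmt, ""), collapse = "\n")
}

#' @export
print.dsl_program <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

## ---- symbol analysis ------------------------------------------------------

expr_symbols <- function(node) {
  switch(node$type,
         num = character(),
         sym = node$name,
         unique(unlist(lapply(node$args, expr_symbols), use.names = FALSE)))
}

program_symbols_read <- function(prog) {
  read <- character(); assigned <- character()
  walk <- function(stmts) {
    for (st in stmts) {
      if (st$type == "assign") {
        syms <- expr_symbols(st$expr)
        read <<- union(read, setdiff(syms, assigned))
        assigned <<- union(assigned, st$target)
      } else {
        read <<- union(read, setdiff(expr_symbols(st$cond), assigned))
        walk(st$then); walk(st$else_branch)
      }
    }
  }
  walk(prog$statements)
  read
}

program_targets <- function(prog) {
  out <- character()
  walk <- function(stmts) for (st in stmts) {
    if (st$type == "assign") out <<- union(out, st$target)
    else { walk(st$then); walk(st$else_branch) }
  }
  walk(prog$statements)
  out
}

#' Validate a program against a set of known symbols
#'
#' Reports (as a data frame, not errors) identifiers read before assignment
#' that are not known, assignments to reserved symbols, and dead assignments
#' whose value is unconditionally overwritten before any use.
#'
#' @param program a `dsl_program`
#' @param known_symbols character vector: species, parameters, time symbol
#' @param reserved_symbols symbols that may be read but never assigned
#'   (default: the time symbol `"t"`)
#' @return tibble with columns `severity`, `message`, `line`, `col`;
#'   zero rows means the program is valid.
#' @export
validate_program <- function(program, known_symbols,
                             reserved_symbols = "t") {
  diags <- list()
  add <- function(severity, message, line, col)
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      severity = severity, message = message, line = line, col = col)
  assigned <- character()
  pending <- list()   # target -> statement of unread unconditional assignment
  walk <- function(stmts, conditional) {
    for (st in stmts) {
      if (st$type == "assign") {
        syms <- expr_symbols(st$expr)
        for (s in syms) {
          if (!is.null(pending[[s]])) pending[[s]] <<- NULL
          if (!(s %in% known_symbols) && !(s %in% assigned))
            add("error", sprintf("unresolved identifier '%s'", s),
                st$line, st$col)
        }
        if (st$target %in% reserved_symbols)
          add("error", sprintf("assignment to reserved symbol '%s'",
                               st$target), st$line, st$col)
        if (!conditional) {
          prev <- pending[[st$target]]
          if (!is.null(prev))
            add("warning",
                sprintf("value of '%s' assigned at line %d is never used",
                        st$target, prev$line), prev$line, prev$col)
          pending[[st$target]] <<- st
        }
        assigned <<- union(assigned, st$target)
      } else {
        for (s in expr_symbols(st$cond)) {
          if (!is.null(pending[[s]])) pending[[s]] <<- NULL
          if (!(s %in% known_symbols) && !(s %in% assigned))
            add("error", sprintf("unresolved identifier '%s'", s),
                st$line, st$col)
        }
        walk(st$then, TRUE); walk(st$else_branch, TRUE)
      }
    }
  }
  walk(program$statements, FALSE)
  if (length(diags) == 0L)
    return(tibble::tibble(severity = character(), message = character(),
                          line = integer(), col = integer()))
  do.call(rbind, diags)
}

## ---- compilation and evaluation -------------------------------------------

# Translate an expression tree into an R language object.  ln -> log,
# pow -> ^; comparisons yield logicals consumed only by `if` conditions.
compile_expression <- function(node) {
  switch(node$type,
    num = node$value,
    sym = as.name(node$name),
    neg = call("-", compile_expression(node$args[[1]])),
    cmp = call(node$op, compile_expression(node$args[[1]]),
               compile_expression(node$args[[2]])),
    bin = call(node$op, compile_expression(node$args[[1]]),
               compile_expression(node$args[[2]])),
    fun = {
      rname <- switch(node$name, ln = "log", pow = "^", node$name)
      as.call(c(as.name(rname), lapply(node$args, compile_expression)))
    })
}

#' Compile a program to an evaluator
#'
#' @param program a `dsl_program`
#' @return an object of class `dsl_evaluator`
#' @export
compile_program <- function(program) {
  compile_stmts <- function(stmts) lapply(stmts, function(st) {
    if (st$type == "assign")
      list(type = "assign", target = st$target,
           code = compile_expression(st$expr), line = st$line, col = st$col)
    else
      list(type = "if", cond = compile_expression(st$cond),
           then = compile_stmts(st$then),
           else_branch = compile_stmts(st$else_branch),
           line = st$line, col = st$col)
  })
  structure(list(compiled = compile_stmts(program$statements),
                 program = program),
            class = "dsl_evaluator")
}

eval_compiled <- function(stmts, env) {
  for (st in stmts) {
    if (st$type == "assign") {
      v <- suppressWarnings(eval(st$code, env))
      if (!is.finite(v))
        dsl_error("dsl_eval_error",
                  sprintf("evaluation of '%s' is not finite (%s)",
                          st$target, format(v)), st$line, st$col)
      assign(st$target, v, envir = env)
    } else {
      c_ <- eval(st$cond, env)
      if (is.na(c_))
        dsl_error("dsl_eval_error", "condition evaluated to NA",
                  st$line, st$col)
      if (isTRUE(c_)) eval_compiled(st$then, env)
      else eval_compiled(st$else_branch, env)
    }
  }
  invisible(env)
}

#' Evaluate a program in a symbol environment
#'
#' Statements execute in order; conditionals select a branch by strict
#' comparison.  Only statement targets are (re)bound; all other symbols are
#' left untouched.
#'
#' @param evaluator a `dsl_evaluator` (or a `dsl_program`, compiled on the
#'   fly)
#' @param environment named list or named numeric vector binding every free
#'   symbol
#' @return named list: the input bindings updated by the program
#' @export
evaluate_program <- function(evaluator, environment) {
  if (inherits(evaluator, "dsl_program"))
    evaluator <- compile_program(evaluator)
  stopifnot(inherits(evaluator, "dsl_evaluator"))
  env <- list2env(as.list(environment), parent = baseenv())
  eval_compiled(evaluator$compiled, env)
  as.list(env)
}

# Fast path used by solvers: evaluate into an existing R environment
# (mutated in place), skipping the list round-trip.
evaluate_into <- function(evaluator, env) {
  eval_compiled(evaluator$compiled, env)
  invisible(env)
}
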