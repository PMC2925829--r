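test_that("programs parse and evaluate assignments in order", {
  env <- evaluate_program(parse_program("x = 1 + 2;"), list())
  expect_equal(env$x, 3)

  env2 <- evaluate_program(parse_program("v = Vm*S/(Km + S);"),
                           list(Vm = 2, Km = 1, S = 1))
  expect_equal(env2$v, 1)   # Michaelis-Menten at S = Km gives Vm/2

  env3 <- evaluate_program(parse_program("x = 2*y;"), list(y = 3))
  expect_equal(env3$x, 6)
})

test_that("conditionals select branches by strict comparison", {
  prog <- parse_program("if (t > 5) {k = 2;} else {k = 1;}")
  expect_equal(evaluate_program(prog, list(t = 7))$k, 2)
  expect_equal(evaluate_program(prog, list(t = 5))$k, 1)
  expect_equal(evaluate_program(prog, list(t = 5.0000001))$k, 2)
})

test_that("operator precedence matches conventional mathematics", {
  cases <- list(
    list("x = 2 + 3 * 4;", 14),
    list("x = 2 * 3 ^ 2;", 18),
    list("x = -2 ^ 2;", -4),          # ^ binds tighter than unary minus
    list("x = 2 ^ -1;", 0.5),
    list("x = 2 ^ 3 ^ 2;", 512),      # right associative
    list("x = 8 / 4 / 2;", 1),        # left associative
    list("x = 10 - 4 - 3;", 3),
    list("x = (2 + 3) * 4;", 20),
    list("x = 6 / 2 + 1;", 4),
    list("if (1 + 1 > 1 * 2 - 1) {x = 1;} else {x = 0;}", 1))
  for (cs in cases)
    expect_equal(evaluate_program(parse_program(cs[[1]]), list())$x, cs[[2]],
                 info = cs[[1]])
})

test_that("pretty-printed programs reparse to identical trees", {
  texts <- c("x = 1 + 2*y - z/4;",
             "x = -(a + b)^2;",
             "r = kf*A^2 - kr*B;",
             "v = Vm*S/(Km + S);",
             "if (t > 5) {k = 2; q = k + 1;} else {k = 1;}",
             "y = min(a, max(b, 2)) + pow(a, 2) + ln(abs(b) + 1);")
  strip_loc <- function(x) {
    if (is.list(x)) {
      x$line <- NULL; x$col <- NULL
      x[] <- lapply(x, strip_loc)
    }
    x
  }
  for (tx in texts) {
    p1 <- parse_program(tx)
    p2 <- parse_program(format(p1))
    p1$source_text <- p2$source_text <- NULL
    expect_equal(strip_loc(p2), strip_loc(p1), info = tx)
  }
  set.seed(7)
  for (rep in 1:100) {
    e1 <- kinsolve:::parse_expression(random_expression(3))
    e2 <- kinsolve:::parse_expression(kinsolve:::format_expression(e1))
    expect_equal(e2, e1)
  }
})

test_that("syntax errors carry location and expected-token information", {
  expect_error(parse_program("x = 1 + ;"), "line 1")
  expect_error(parse_program("x = 1"), "expected ';'")
  expect_error(parse_program("x = foo(1);"), "unknown function 'foo'")
  expect_error(parse_program("if (x > 1) {y = 1;"), "unterminated block")
  expect_error(parse_program("x = min(1);"), "expects 2 argument")
})

test_that("validation reports unresolved, reserved and dead assignments", {
  d <- validate_program(parse_program("x = y;"), known_symbols = "t")
  expect_equal(nrow(d), 1)
  expect_match(d$message, "'y'")

  d2 <- validate_program(parse_program("t = 1;"), known_symbols = "t")
  expect_match(d2$message, "reserved")

  d3 <- validate_program(parse_program("x = 1; x = 2; y = x;"),
                         known_symbols = "t")
  expect_equal(d3$severity, "warning")
  expect_match(d3$message, "never used")

  # a valid fixture program is clean
  m <- fixture_model("mini_krebs")
  prog <- parse_program("vrate = k1*S_ext*A;")
  d4 <- validate_program(prog, c(m$species, names(m$parameters), "t"))
  expect_equal(nrow(d4), 0)
})

test_that("evaluation errors carry the statement location", {
  expect_error(evaluate_program(parse_program("x = 1/0;"), list()),
               "line 1")
  expect_error(evaluate_program(parse_program("y = 1;\nx = ln(0 - y);"),
                                list()), "line 2")
})

test_that("evaluation agrees with the base R evaluator on random trees", {
  set.seed(123)
  env <- list(x = 1.3, y = 0.7, z = 2.1)
  checked <- 0L
  for (rep in 1:10000) {
    ex <- random_expression(sample(1:3, 1))
    ours <- tryCatch(
      evaluate_program(parse_program(paste0("out = ", ex, ";")), env)$out,
      error = function(e) NULL)
    ref <- eval(parse(text = ex), env)
    if (is.null(ours) || !is.finite(ref)) next
    checked <- checked + 1L
    expect_lt(abs(ours - ref) / max(abs(ref), 1e-12), 1e-12)
  }
  expect_gt(checked, 9000)
})

test_that("evaluation is pure given the environment", {
  prog <- compile_program(parse_program("a = x + y; b = a * 2;"))
  env <- list(x = 0.25, y = 4)
  first <- evaluate_program(prog, env)
  for (rep in 1:100)
    expect_identical(evaluate_program(prog, env), first)
  expect_equal(env, list(x = 0.25, y = 4))   # input bindings untouched
})
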