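test_that("the four objective formulas reproduce hand-computed values", {
  for (obj in c("squares", "modulus", "relative_squares",
                "relative_modulus"))
    expect_equal(objective_value(c(1, 2), c(1, 2), obj), 0)

  expect_equal(objective_value(c(1, 2), c(0.0001, 0.0001), "squares"),
               (1 - 1e-4)^2 + (2 - 1e-4)^2)
  expect_equal(objective_value(c(1, 2), c(0, 0), "squares"), 5)
  expect_equal(objective_value(c(1, 2), c(0, 0), "modulus"), 3)
  expect_equal(objective_value(2, 4, "relative_squares"), 0.25)
  expect_equal(objective_value(2, 4, "relative_modulus"), 0.5)
  expect_equal(objective_value(c(1, 2), c(0, 0), "squares", weight = 2), 10)
  expect_error(objective_value(1, 0, "relative_squares"), "zero")
  # missing experimental values are skipped
  expect_equal(objective_value(c(1, 2, 3), c(0, NA, 0), "squares"), 10)
})

test_that("simulated values match closed forms for each dataset kind", {
  # ode: linear decay
  m <- fixture_model("decay")
  tt <- seq(0.5, 4, by = 0.5)
  d <- fit_dataset("ode", data.frame(time = tt, A = 0), "time")
  pr <- fit_problem(m, d, c(kf_v1 = 0.7))
  yt <- simulate_for_fit(pr, c(kf_v1 = 0.7))[[1]]
  expect_lt(max(abs(yt[, "A"] - exp(-0.7 * tt))), 1e-6)

  # implicit: open chain steady state A* = p / kf_v1 with kf_v1 = 1
  mo <- fixture_model("open_chain")
  pv <- seq(0.2, 2, by = 0.3)
  d2 <- fit_dataset("implicit", data.frame(kf_vin = pv, A = 0), "kf_vin")
  pr2 <- fit_problem(mo, d2, c(kf_v1 = 1))
  yt2 <- simulate_for_fit(pr2, c(kf_v1 = 1))[[1]]
  expect_lt(max(abs(yt2[, "A"] - pv)), 1e-8)

  # explicit: Michaelis-Menten values
  mm <- fixture_model("mm_explicit")
  sv <- c(0.25, 0.5, 1)
  d3 <- fit_dataset("explicit", data.frame(S = sv, v = 0), "S")
  pr3 <- fit_problem(mm, d3, c(Vm = 2))
  yt3 <- simulate_for_fit(pr3, c(Vm = 2))[[1]]
  expect_equal(unname(yt3[, "v"]), 2 * sv / (0.5 + sv))
})

test_that("a mixed problem's objective is the weighted sum of its parts", {
  m <- fixture_model("open_chain")
  tt <- seq(0.5, 3, by = 0.5)
  tc <- simulate_timecourse(m, c(0, tt))
  d1 <- fit_dataset("ode", data.frame(time = tt, A = tc$A[-1] + 0.1),
                    "time", weight = 2)
  pv <- seq(0.5, 1.5, by = 0.5)
  d2 <- fit_dataset("implicit", data.frame(kf_vin = pv, A = pv - 0.2),
                    "kf_vin", weight = 0.5)
  pr_mixed <- fit_problem(m, list(d1, d2), c(kf_v1 = 1))
  total <- kinsolve:::problem_objective(pr_mixed, c(kf_v1 = 1))
  parts <- vapply(list(d1, d2), function(d) {
    kinsolve:::problem_objective(fit_problem(m, d, c(kf_v1 = 1)),
                                 c(kf_v1 = 1))
  }, 0)
  expect_equal(total, sum(parts), tolerance = 1e-12)
})

test_that("noiseless data recover the generating parameters exactly", {
  # ode kind: k true 0.7, started from 2.0
  m <- fixture_model("decay")
  tt <- seq(0.25, 5, by = 0.25)
  tc <- simulate_timecourse(m, c(0, tt), rtol = 1e-10, atol = 1e-13)
  d <- fit_dataset("ode", data.frame(time = tt, A = tc$A[-1]), "time")
  pr <- fit_problem(m, d, tibble::tibble(name = "kf_v1", start = 2,
                                         lo = 1e-3, hi = 1e3))
  ft <- fit_model(pr)
  expect_lt(abs(ft$estimates[["kf_v1"]] - 0.7), 1e-5)
  expect_lte(ft$F0, 1e-10)
  expect_lte(ft$F0, ft$F0_start)

  # implicit kind
  mo <- fixture_model("open_chain")
  pv <- seq(0.2, 2, by = 0.2)
  d2 <- fit_dataset("implicit", data.frame(kf_vin = pv, A = pv / 1.6),
                    "kf_vin")
  pr2 <- fit_problem(mo, d2, tibble::tibble(name = "kf_v1", start = 0.4,
                                            lo = 1e-2, hi = 100))
  ft2 <- fit_model(pr2)
  expect_lt(abs(ft2$estimates[["kf_v1"]] - 1.6), 1e-4)

  # explicit kind, two parameters, both optimizers
  mm <- fixture_model("mm_explicit")
  sv <- seq(0.25, 2, by = 0.25)
  d3 <- fit_dataset("explicit",
                    data.frame(S = sv, v = 2 * sv / (0.5 + sv)), "S")
  for (method in c("zero_order", "first_order")) {
    pr3 <- fit_problem(mm, d3,
                       tibble::tibble(name = c("Vm", "Km"), start = c(1, 1),
                                      lo = c(1e-3, 1e-3), hi = c(50, 50)),
                       method = method)
    ft3 <- fit_model(pr3)
    expect_lt(abs(ft3$estimates[["Vm"]] - 2), 1e-4)
    expect_lt(abs(ft3$estimates[["Km"]] - 0.5), 1e-4)
  }

  # mixed problem: ode + implicit + explicit datasets jointly identify
  # the chain rate constant and the Michaelis constants
  tc_o <- simulate_timecourse(mo, c(0, tt), rtol = 1e-10, atol = 1e-13)
  dm1 <- fit_dataset("ode", data.frame(time = tt, B = tc_o$B[-1]), "time")
  mo_fns <- kinetic_model(
    "vin: => A\nv1: A => B\nvout: B =>",
    initial = c(A = 1, B = 1),
    parameters = c(kf_vin = 1, kf_v1 = 1, kf_vout = 1, Vm = 2, Km = 0.5),
    functions = c(vmm = "Vm*A/(Km + A)"))
  dm2 <- fit_dataset("implicit", data.frame(kf_vin = pv, A = pv), "kf_vin")
  dm3 <- fit_dataset("explicit",
                     data.frame(A = sv, vmm = 2 * sv / (0.5 + sv)), "A")
  prm <- fit_problem(mo_fns, list(dm1, dm2, dm3),
                     tibble::tibble(name = c("kf_v1", "Vm", "Km"),
                                    start = c(0.5, 1, 1),
                                    lo = c(1e-2, 1e-2, 1e-2),
                                    hi = c(10, 10, 10)))
  ftm <- fit_model(prm)
  expect_lt(abs(ftm$estimates[["kf_v1"]] - 1), 1e-4)
  expect_lt(abs(ftm$estimates[["Vm"]] - 2), 1e-4)
  expect_lt(abs(ftm$estimates[["Km"]] - 0.5), 1e-4)
})

test_that("fit statistics match the ordinary-least-squares closed form", {
  # y = a*x through an explicit function: SD(a) = s / sqrt(sum x^2)
  xv <- seq(0.5, 4, by = 0.5)
  set.seed(5)
  a_true <- 1.7
  yv <- a_true * xv + rnorm(length(xv), 0, 0.05)
  m <- kinetic_model("v1: A => B", initial = c(A = 1),
                     parameters = c(kf_v1 = 1, a = 1, x = 1),
                     functions = c(f = "a*x"))
  d <- fit_dataset("explicit", data.frame(x = xv, f = yv), "x")
  pr <- fit_problem(m, d, tibble::tibble(name = "a", start = 1,
                                         lo = 1e-3, hi = 100))
  ft <- fit_model(pr)
  a_hat <- sum(xv * yv) / sum(xv^2)      # OLS through the origin
  expect_equal(ft$estimates[["a"]], a_hat, tolerance = 1e-6)
  s2 <- sum((yv - a_hat * xv)^2) / (length(xv) - 1)
  sd_closed <- sqrt(s2 / sum(xv^2))
  expect_equal(ft$statistics$parameters$std.error, sd_closed,
               tolerance = 1e-5)
  tq <- qt(0.975, length(xv) - 1)
  expect_equal(ft$statistics$parameters$conf.high -
                 ft$statistics$parameters$estimate, tq * sd_closed,
               tolerance = 1e-5)

  # ANOVA decomposition identity
  an <- ft$statistics$anova
  expect_equal(an$sum_sq[an$source == "total"],
               sum(an$sum_sq[an$source != "total"]), tolerance = 1e-8)

  # noiseless fit: zero-residual limit
  d0 <- fit_dataset("explicit", data.frame(x = xv, f = a_true * xv), "x")
  pr0 <- fit_problem(m, d0, tibble::tibble(name = "a", start = 1,
                                           lo = 1e-3, hi = 100))
  ft0 <- fit_model(pr0)
  expect_lt(ft0$statistics$s2, 1e-12)
  expect_lt(ft0$statistics$parameters$conf.high -
              ft0$statistics$parameters$conf.low, 1e-5)
})

test_that("degenerate statistics requests fail informatively", {
  m <- fixture_model("mm_explicit")
  d <- fit_dataset("explicit", data.frame(S = 1, v = 1), "S")
  pr <- fit_problem(m, d, c(Vm = 2))
  expect_error(fit_statistics(pr, c(Vm = 2)), "degrees of freedom")
})

test_that("tidy and glance expose broom-style summaries", {
  m <- fixture_model("decay")
  tt <- seq(0.5, 3, by = 0.5)
  tc <- simulate_timecourse(m, c(0, tt))
  d <- fit_dataset("ode", data.frame(time = tt, A = tc$A[-1]), "time")
  ft <- fit_model(fit_problem(m, d, c(kf_v1 = 0.5)))
  td <- tidy(ft)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high"))
  gl <- glance(ft)
  expect_equal(gl$n, length(tt))
  expect_equal(gl$p, 1)
  expect_lte(gl$F0, 1e-8)
})
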