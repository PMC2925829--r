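test_that("linear decay matches the closed form at default tolerances", {
  m <- kinetic_model("v1: A => B", initial = c(A = 1),
                     parameters = c(kf_v1 = 1))
  tc <- simulate_timecourse(m, c(0, 0.5, 1, 2))
  expect_lt(max(abs(tc$A - exp(-tc$time))), 1e-6)
  expect_equal(tc$v1, tc$A)              # flux recomputed from state
})

test_that("reversible isomerization relaxes to its equilibrium", {
  m <- kinetic_model("v1: A <=> B", initial = c(A = 2),
                     parameters = c(kf_v1 = 1, kr_v1 = 1))
  tc <- simulate_timecourse(m, c(0, 50))
  expect_equal(tc$A[2], 1, tolerance = 1e-7)
  expect_equal(tc$B[2], 1, tolerance = 1e-7)
})

test_that("stiff two-timescale system self-converges", {
  m <- kinetic_model("v1: A <=> B\nv2: B => C",
                     initial = c(A = 1),
                     parameters = c(kf_v1 = 1e4, kr_v1 = 1e4, kf_v2 = 1))
  times <- c(0, 10^seq(-3, 1, length.out = 9))
  ref <- simulate_timecourse(m, times, rtol = 1e-10, atol = 1e-13)
  got <- simulate_timecourse(m, times)
  for (sp in c("A", "B", "C")) {
    scale <- pmax(abs(ref[[sp]]), 1e-8)
    expect_lt(max(abs(got[[sp]] - ref[[sp]]) / scale), 1e-5)
  }
})

test_that("tightening tolerances moves the trajectory toward the truth", {
  m <- kinetic_model("v1: A => B", initial = c(A = 1),
                     parameters = c(kf_v1 = 1))
  errs <- vapply(c(1e-3, 1e-6, 1e-9), function(tol) {
    tc <- simulate_timecourse(m, c(0, 1, 3), rtol = tol, atol = tol * 1e-3)
    max(abs(tc$A - exp(-tc$time)))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("conditional right-hand sides switch exactly at the event", {
  # influx switches on at t = 5; A(t) = 0 before, 2*(t-5) after
  m <- kinetic_model(
    list(reaction("vin", products = c(A = 1), rate = "u")),
    initial = c(A = 0), parameters = c(u = 0),
    rhs = "if (t > 5) {u = 2;} else {u = 0;}")
  tc <- simulate_timecourse(m, seq(0, 10, by = 0.5))
  expect_lt(max(abs(tc$A[tc$time <= 5])), 1e-7)
  after <- tc$time > 5
  expect_lt(max(abs(tc$A[after] - 2 * (tc$time[after] - 5))), 1e-5)
})

test_that("explicit scans evaluate on the fixed grid", {
  m <- fixture_model("mm_explicit")
  m <- set_parameters(m, c(Vm = 1, Km = 1))
  sc <- scan_explicit(m, "v", "S", 0, 10, 1)
  expect_equal(sc$S, 0:10)
  expect_equal(sc$v[sc$S == 1], 0.5)
  expect_equal(sc$v[sc$S == 9], 0.9)

  # constant function: all values equal
  mc <- kinetic_model("v1: A => B", initial = c(A = 1),
                      parameters = c(kf_v1 = 1, c0 = 3),
                      functions = c(f = "c0"))
  scc <- scan_explicit(mc, "f", "kf_v1", 0, 5, 0.5)
  expect_true(all(scc$f == 3))

  # scan equals a direct evaluation loop on a two-substrate rate law
  m2 <- kinetic_model("v1: A + B => C", initial = c(A = 1, B = 2),
                      parameters = c(kf_v1 = 1, k = 0.8),
                      functions = c(v2s = "k*A*B"))
  sc2 <- scan_explicit(m2, "v2s", "A", 0.1, 3, 0.1)
  direct <- vapply(sc2$A, function(a) 0.8 * a * 2, 0)
  expect_identical(sc2$v2s, direct)
})

test_that("scan records failed grid points as missing and continues", {
  m <- kinetic_model("v1: A => B", initial = c(A = 1),
                     parameters = c(kf_v1 = 1, q = 1),
                     functions = c(g = "ln(q)"))
  sc <- scan_explicit(m, "g", "q", -1, 1, 0.5)
  expect_true(anyNA(sc$g))
  expect_equal(sc$g[sc$q == 1], 0)
})

test_that("steady states solve by damped Newton with the contract residual", {
  # influx 1, efflux k*A with k = 2: A* = 0.5
  m <- kinetic_model("vin: => A\nvout: A =>",
                     parameters = c(kf_vin = 1, kf_vout = 2))
  ss <- steady_state(m)
  expect_equal(ss$state[["A"]], 0.5, tolerance = 1e-9)
  expect_lte(ss$residual, 1e-9)

  # detailed balance of a closed isomerization: A* = Total/(1 + kf/kr)
  m2 <- kinetic_model("v1: A <=> B", initial = c(A = 4),
                      parameters = c(kf_v1 = 3, kr_v1 = 1))
  ss2 <- steady_state(m2)
  expect_equal(ss2$state[["A"]], 1, tolerance = 1e-8)
  expect_equal(ss2$state[["B"]], 3, tolerance = 1e-8)

  # mini-cycle: Newton solution matches a long integration endpoint
  m3 <- fixture_model("mini_krebs")
  ss3 <- steady_state(m3)
  tc <- simulate_timecourse(m3, c(0, 1000), rtol = 1e-9, atol = 1e-12)
  for (sp in m3$species)
    expect_equal(ss3$state[[sp]], tc[[sp]][2], tolerance = 1e-6)
})

test_that("steady state failures are reported with the best residual", {
  # pure influx has no steady state
  m <- kinetic_model("vin: => A", parameters = c(kf_vin = 1))
  expect_error(steady_state(m), "residual|singular Jacobian")
})
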