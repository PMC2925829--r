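test_that("a linear branch is traced to closed-form accuracy", {
  m <- kinetic_model("vin: => A\nvout: A =>", initial = c(A = 0.05),
                     parameters = c(kf_vin = 0.1, kf_vout = 2))
  br <- continue_branch(m, "kf_vin", 0.1, 2)
  expect_gt(nrow(br), 10)
  expect_lt(max(abs(br$A - br$kf_vin / 2)), 1e-8)
  expect_equal(br$kf_vin[nrow(br)], 2)   # lands exactly on the boundary
  expect_true(all(br$stability == "stable node"))
})

test_that("every branch point independently re-converges under Newton", {
  m <- fixture_model("mini_krebs")
  br <- continue_branch(m, "S_ext", 2, 10)
  idx <- unique(round(seq(1, nrow(br), length.out = 25)))
  for (i in idx) {
    mi <- set_parameters(m, c(S_ext = br$S_ext[[i]]))
    guess <- br$independent_state[[i]] * 1.05   # nudge, then re-converge
    ss <- steady_state(mi, initial_guess = guess, tol = 1e-12)
    expect_lt(max(abs(ss$independent - br$independent_state[[i]])), 1e-7)
  }
})

test_that("stability labels follow the eigenvalue classification", {
  expect_equal(classify_stability(c(-1, -2)), "stable node")
  expect_equal(classify_stability(complex(real = c(-0.1, -0.1),
                                          imaginary = c(2, -2))),
               "stable focus")
  expect_equal(classify_stability(c(1, -1)), "saddle")
  expect_equal(classify_stability(c(2, 1)), "unstable node")
  expect_equal(classify_stability(complex(real = c(0.3, 0.3),
                                          imaginary = c(1, -1))),
               "unstable focus")
})

test_that("the fold of dX/dt = p - X^2 is located at p = 0", {
  m <- fixture_model("fold")
  br <- continue_branch(m, "p", -0.5, 1, initial_step = 0.02,
                        start = 1, direction = -1)
  # branch turns at the fold and continues onto the X < 0 branch
  expect_lt(min(br$X), -0.5)
  expect_gt(max(br$X), 0.9)
  bif <- detect_bifurcations(br)
  folds <- bif[bif$type == "fold", ]
  expect_equal(nrow(folds), 1)
  expect_lt(abs(folds$p), 1e-6)
  expect_true(folds$refined)
  # stability flips exactly at the fold: stable above, saddle/unstable below
  labs <- br$stability[order(br$X)]
  expect_true(all(grepl("unstable", labs[seq_len(sum(br$X < -1e-3))])))
})

test_that("the Brusselator Hopf point sits at b = 1 + a^2", {
  # analytic check first: at the equilibrium (a, b/a) the Jacobian trace is
  # b - 1 - a^2, so the complex pair crosses the axis at b = 1 + a^2 = 2
  m <- fixture_model("brusselator")
  br <- continue_branch(m, "b", 1.5, 2.5, initial_step = 0.01)
  bif <- detect_bifurcations(br)
  hopf <- bif[bif$type == "hopf", ]
  expect_equal(nrow(hopf), 1)
  expect_lt(abs(hopf$b - 2), 1e-4)
  expect_true(hopf$refined)
  # the critical pair is genuinely complex at the crossing
  vec <- hopf$eigenvector[[1]]
  expect_true(any(abs(Im(vec)) > 1e-8))
  # stability changes across the detected point and nowhere else
  split <- findInterval(br$b, hopf$b)
  labels_lo <- unique(br$stability[split == 0 & br$b < hopf$b])
  labels_hi <- unique(br$stability[split == 1 & br$b > hopf$b])
  expect_true(all(grepl("^stable", labels_lo)))
  expect_true(all(grepl("^unstable", labels_hi)))
})

test_that("a focus-node transition is detected where the discriminant vanishes", {
  # Jacobian [[0, -1], [1, -d]]: eigenvalue discriminant d^2 - 4 vanishes
  # at d = 2 (complex pair for d < 2, two real eigenvalues for d > 2)
  m <- fixture_model("damped_oscillator")
  br <- continue_branch(m, "d", 1, 3, initial_step = 0.05)
  expect_setequal(unique(br$stability), c("stable focus", "stable node"))
  bif <- detect_bifurcations(br)
  fn <- bif[bif$type == "focus_node", ]
  expect_equal(nrow(fn), 1)
  expect_lt(abs(fn$d - 2), 1e-4)
})

test_that("flux control coefficients sum to 1 and concentration ones to 0", {
  m <- fixture_model("reversible_chain")
  cc <- control_coefficients(m)
  fm <- as.matrix(cc$flux[, -1])
  cm <- as.matrix(cc$concentration[, -1])
  expect_true(all(abs(colSums(fm) - 1) < 1e-4))
  expect_true(all(abs(colSums(cm)) < 1e-4))
})

test_that("control coefficients match symbolic derivatives on a 2-step chain", {
  # v1 = e1*(k1*S0 - km1*A), v2 = e2*k2*A; steady flux
  # J(e1, e2) = e2*k2*e1*k1*S0 / (e2*k2 + e1*km1); C_i = dlnJ/dln e_i at e = 1
  k1 <- 1; km1 <- 0.5; k2 <- 2; S0 <- 2
  m <- kinetic_model(
    list(reaction("v1", products = c(A = 1), rate = "k1*S0 - km1*A"),
         reaction("v2", substrates = c(A = 1), rate = "k2*A")),
    initial = c(A = 0.5),
    parameters = c(k1 = k1, km1 = km1, k2 = k2, S0 = S0))
  cc <- control_coefficients(m)
  Jexpr <- quote(e2 * k2 * e1 * k1 * S0 / (e2 * k2 + e1 * km1))
  env <- list(e1 = 1, e2 = 1, k1 = k1, km1 = km1, k2 = k2, S0 = S0)
  J0 <- eval(Jexpr, env)
  for (i in 1:2) {
    dJ <- eval(stats::D(Jexpr, paste0("e", i)), env)
    analytic <- dJ / J0                  # e_i = 1: dlnJ/dln e_i = (dJ/de_i)/J
    got <- cc$flux[[ "v1" ]][[i]]        # flux identical through both steps
    expect_equal(got, analytic, tolerance = 1e-3)
  }
})
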