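test_that("conservation laws match hand-derived bases on small networks", {
  # closed chain: total mass conserved
  S <- stoichiometric_matrix(parse_reaction_list("v1: A => B\nv2: B => C"))
  laws <- conservation_laws(S)
  expect_length(laws, 1)
  expect_equal(laws[[1]]$coefficients, c(A = 1, B = 1, C = 1))

  # open chain: full row rank, no laws
  So <- stoichiometric_matrix(parse_reaction_list(
    "vin: => A\nv1: A => B\nvout: B =>"))
  expect_length(conservation_laws(So), 0)

  # A + B <=> C: two independent laws; compare spans against the
  # hand-solved null space of t(S) (c3 = c1 + c2)
  Sc <- stoichiometric_matrix(parse_reaction_list("v1: A + B <=> C"))
  laws2 <- conservation_laws(Sc)
  expect_length(laws2, 2)
  B <- do.call(cbind, lapply(laws2, function(l) l$coefficients))
  expect_true(all(t(B) %*% Sc == 0))
  ref <- cbind(c(1, 0, 1), c(0, 1, 1))       # A+C, B+C
  # same span: ref solvable in terms of returned basis
  expect_equal(qr(cbind(B, ref))$rank, 2)
})

test_that("laws are exact integer left-null vectors and complete the rank", {
  set.seed(42)
  for (rep in 1:50) {
    rxns <- random_network()
    S <- stoichiometric_matrix(rxns)
    laws <- conservation_laws(S)
    for (l in laws) {
      expect_true(all(l$coefficients == round(l$coefficients)))
      expect_true(all(as.numeric(t(l$coefficients) %*% S) == 0))
      nz <- l$coefficients[l$coefficients != 0]
      expect_gt(nz[[1]], 0)              # first nonzero positive
      g <- Reduce(function(a, b) kinsolve:::gcd2(a, b), abs(nz))
      expect_equal(g, 1)                 # smallest integers
    }
    expect_equal(rank_qr(S) + length(laws), nrow(S))
  }
})

test_that("system reduction rewrites one dependent species per law", {
  m <- kinetic_model("v1: A <=> B", initial = c(A = 2, B = 0),
                     parameters = c(kf_v1 = 1, kr_v1 = 1))
  expect_equal(m$dependent, "B")
  expect_equal(m$independent, "A")
  expect_equal(unname(m$reduction$totals), 2)
  st <- kinsolve:::eval_model_state(m, c(A = 0.7))
  expect_equal(st$species[["B"]], 1.3)

  # no laws: model unchanged
  mo <- kinetic_model("vin: => A\nvout: A =>")
  expect_length(mo$dependent, 0)
  expect_equal(mo$independent, "A")
})

test_that("conserved totals are preserved along simulated trajectories", {
  m <- fixture_model("mini_krebs")
  expect_length(m$conservation_laws, 1)
  tc <- simulate_timecourse(m, seq(0, 50, by = 0.5))
  co <- m$conservation_laws[[1]]$coefficients
  tot <- as.matrix(tc[, names(co)]) %*% co
  expect_lt(max(abs(tot - tot[[1]])) / abs(tot[[1]]), 1e-9)
})

test_that("reduced and unreduced systems produce the same trajectories", {
  args <- list("v1: A <=> B\nv2: B => C\nv3: C => A",
               initial = c(A = 3, B = 1, C = 0.5),
               parameters = c(kf_v1 = 2, kr_v1 = 1, kf_v2 = 0.7,
                              kf_v3 = 0.3))
  m_red <- do.call(kinetic_model, args)
  m_full <- do.call(kinetic_model, c(args, reduce = FALSE))
  expect_length(m_red$dependent, 1)
  expect_length(m_full$dependent, 0)
  times <- seq(0, 20, by = 0.5)
  t1 <- simulate_timecourse(m_red, times)
  t2 <- simulate_timecourse(m_full, times)
  for (sp in m_red$species)
    expect_lt(max(abs(t1[[sp]] - t2[[sp]])), 1e-6)
})
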