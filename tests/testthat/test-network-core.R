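test_that("rate laws evaluate to their defining forms", {
  m <- canonical
  state <- initial_state(m)
  ## first order: k * [A]
  dec <- reaction("d", reactants = c(A = 1),
                  rate = rate_law("mass_action_1", c(k = "k"),
                                  species = "A"))
  expect_equal(reaction_rate(dec, c(A = 2), c(k = 0.1)), 0.2)
  ## zero order source: k
  src <- reaction("s", products = c(A = 1),
                  rate = rate_law("mass_action_1", c(k = "k")))
  expect_equal(reaction_rate(src, c(A = 99), c(k = 0.007)), 0.007)
  ## second order: k * [A] * [B]
  bi <- reaction("b", reactants = c(A = 1, B = 1), products = c(C = 1),
                 rate = rate_law("mass_action_2", c(k = "k"),
                                 species = c("A", "B")))
  expect_equal(reaction_rate(bi, c(A = 2, B = 3, C = 0), c(k = 0.5)), 3)
  ## Michaelis-Menten half saturation: [S] = Km -> Vm / 2
  mm <- reaction("m", reactants = c(S = 1),
                 rate = rate_law("michaelis_menten",
                                 c(Vm = "Vm", Km = "Km"), species = "S"))
  expect_equal(reaction_rate(mm, c(S = 0.3), c(Vm = 4, Km = 0.3)), 2)
  ## Hill activation half max at [X] = K for any n
  for (n in c(1, 2, 4)) {
    hl <- reaction("h", products = c(Y = 1), modifiers = "X",
                   rate = rate_law("hill_activation",
                                   c(Vm = "Vm", K = "K", n = "n"),
                                   species = "X"))
    expect_equal(reaction_rate(hl, c(X = 0.05, Y = 0),
                               c(Vm = 6, K = 0.05, n = n)), 3)
  }
  ## Hill inhibition: Vm * K^n / (K^n + X^n)
  hi <- reaction("hi", products = c(Y = 1), modifiers = "X",
                 rate = rate_law("hill_inhibition",
                                 c(Vm = "Vm", K = "K", n = "n"),
                                 species = "X"))
  expect_equal(reaction_rate(hi, c(X = 1, Y = 0),
                             c(Vm = 2, K = 1, n = 3)), 1)
  ## reversible net flux can be negative
  rv <- reaction("r", reactants = c(A = 1), products = c(B = 1),
                 rate = rate_law("mass_action_rev",
                                 c(kf = "kf", kr = "kr"),
                                 species = "A", reverse_species = "B"))
  expect_equal(reaction_rate(rv, c(A = 0, B = 2), c(kf = 1, kr = 0.5)),
               -1)
})

test_that("rate evaluation rejects unknown species and bad states", {
  dec <- reaction("d", reactants = c(Z = 1),
                  rate = rate_law("mass_action_1", c(k = "k"),
                                  species = "Z"))
  expect_error(reaction_rate(dec, c(A = 1), c(k = 0.1)),
               "not in state")
  expect_error(reaction_rate(dec, c(Z = -1e-3), c(k = 0.1)),
               "negative concentration")
})

test_that("assembled RHS does stoichiometric bookkeeping", {
  ## single reaction A -> B
  m <- toy_chain(k1 = 0.1, k2 = 1e-30)
  f <- assemble_rhs(m)
  d <- f(0, c(A = 2, B = 0, C = 0))[[1]]
  expect_equal(d[1], -0.2)
  expect_equal(d[2], 0.2, tolerance = 1e-12)
  ## closed cycle A <-> B conserves mass at every state
  cyc <- toy_binding()
  fc <- assemble_rhs(cyc)
  for (s in list(c(1, 1, 0), c(0.2, 0.9, 0.4), c(0, 0, 1))) {
    d <- fc(0, stats::setNames(s, c("A", "B", "C")))[[1]]
    expect_equal(d[1] + d[3], 0, tolerance = 1e-15)
    expect_equal(d[2] + d[3], 0, tolerance = 1e-15)
  }
})

test_that("mass-action flux is linear in its rate constant", {
  f <- attr(assemble_rhs(canonical), "flux")
  y <- initial_state(canonical)
  p <- param_values(canonical)
  kinds <- vapply(canonical$reactions, function(r) r$rate$kind, "")
  ma <- which(kinds %in% c("mass_action_1", "mass_action_2"))
  base <- f(y, p)
  for (cfac in c(2, 7.5)) {
    p2 <- p
    for (j in ma) {
      kid <- canonical$reactions[[j]]$rate$params[["k"]]
      p2[kid] <- p[kid] * cfac
    }
    scaled <- f(y, p2)
    expect_equal(scaled[ma], cfac * base[ma], tolerance = 1e-12)
  }
})

test_that("integrated linear chain matches the matrix exponential", {
  skip_if_not_installed("Matrix")
  k1 <- 0.2; k2 <- 0.05; a0 <- 1.5
  m <- toy_chain(k1, k2, a0)
  f <- assemble_rhs(m)
  times <- seq(0, 120, by = 10)
  sol <- deSolve::lsoda(initial_state(m), times, f, param_values(m),
                        rtol = 1e-10, atol = 1e-14)
  A <- matrix(c(-k1, 0, 0,
                k1, -k2, 0,
                0, k2, 0), 3, 3, byrow = TRUE)
  for (i in seq_along(times)) {
    expected <- as.numeric(
      Matrix::expm(A * times[i]) %*% c(a0, 0, 0))
    expect_equal(unname(sol[i, -1]), expected, tolerance = 1e-6)
  }
})

test_that("binding sub-network conserves its pools along trajectories", {
  m <- toy_binding()
  f <- assemble_rhs(m)
  sol <- deSolve::lsoda(initial_state(m), seq(0, 200, by = 5), f,
                        param_values(m), rtol = 1e-10, atol = 1e-12)
  a_pool <- sol[, "A"] + sol[, "C"]
  b_pool <- sol[, "B"] + sol[, "C"]
  expect_lt(max(abs(a_pool - a_pool[1])), 1e-8)
  expect_lt(max(abs(b_pool - b_pool[1])), 1e-8)
})

test_that("validate_model reports counts and catches defects", {
  v <- validate_model(canonical)
  expect_equal(nrow(v), 0)
  expect_equal(unname(attr(v, "counts")),
               c(47, 57, 91))
  ## dangling species reference
  bad <- canonical
  bad$reactions <- c(bad$reactions, list(
    reaction("vx", reactants = c(GHOST = 1),
             rate = rate_law("mass_action_1", c(k = "kd_hif"),
                             species = "GHOST"))))
  vb <- validate_model(bad)
  expect_true(any(vb$check == "reference" &
                    grepl("GHOST", vb$message)))
  ## non-positive rate constant
  bad2 <- canonical
  bad2$parameters$value[bad2$parameters$id == "kd_hif"] <- -1
  v2 <- validate_model(bad2)
  expect_true(any(v2$check == "positivity" & grepl("kd_hif", v2$message)))
})
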