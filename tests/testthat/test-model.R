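test_that("right-hand side respects basal influx, symmetry and deletions", {
  p <- polarity_parameters()
  wt <- polarity_condition("wt")
  zero <- setNames(numeric(6), c("A1", "A2", "B1", "B2", "R1", "R2"))
  d0 <- model_rhs(zero, p, wt)
  expect_true(all(d0 > 0))  # basal binding drives influx everywhere

  sym <- setNames(rep(c(0.03, 0.03), 3), c("A1", "A2", "B1", "B2", "R1", "R2"))
  ds <- model_rhs(sym, p, wt)  # wild type: no bias
  expect_equal(ds[c("A1", "B1", "R1")], ds[c("A2", "B2", "R2")],
               ignore_attr = TRUE)

  dA <- polarity_condition("dA")
  dd <- model_rhs(sym * c(0, 0, 1, 1, 1, 1), p, dA)
  expect_equal(unname(dd[c("A1", "A2")]), c(0, 0))
  # with MglA absent the K-suppression factor is inactive
  pK <- p; pK$K <- Inf
  expect_equal(model_rhs(sym * c(0, 0, 1, 1, 1, 1), pK, dA), dd)

  expect_error(model_rhs(zero + c(0.9, 0.9, 0, 0, 0, 0), p, wt), "simplex")
})

test_that("compiled and reference implementations integrate identically", {
  # a mildly non-stiff parameter set exercises the Dormand-Prince path
  p <- polarity_parameters(a_A = 0.02, a_B = 0.02, a_R = 0.03, b_R = 1,
                           c_A = 1, c_B = 1, c_R = 1.5, d_AB = 30,
                           d_BA = 5, K = 0.02, beta = 0.8)
  wt <- polarity_condition("wt")
  init <- default_init(wt)
  r_rhs <- function(t, y, parms) {
    # clamp the integrator's trial-step overshoots into the simplex
    y <- pmax(y, 0)
    for (k in c(1, 3, 5)) {
      s <- y[k] + y[k + 1]
      if (s > 1) {
        y[k] <- y[k] / s
        y[k + 1] <- y[k + 1] / s
      }
    }
    list(unname(model_rhs(setNames(y, names(init)), p, wt)))
  }
  for (m in c("dopri", "lsoda")) {
    c_traj <- simulate_polarity(p, wt, init = init, t_end = 200,
                                t_step = 10, method = m)
    solver <- if (m == "dopri") deSolve::rkMethod("rk45dp7") else "lsoda"
    r_traj <- deSolve::ode(y = unname(init), times = seq(0, 200, 10),
                           func = r_rhs, parms = NULL, method = solver,
                           atol = 1e-10, rtol = 1e-8)
    expect_equal(unname(as.matrix(c_traj[, -1])),
                 unname(r_traj[, -1]), tolerance = 1e-6)
  }
})

test_that("wild type polarizes from a small seed; K -> Inf loses asymmetry", {
  p <- polarity_parameters()
  wt <- polarity_condition("wt")
  ss <- steady_state(p, wt)
  expect_equal(ss$classification, "polarized")
  s <- ss$state
  # MglB and RomR enriched together, MglA at the opposite pole
  expect_gt(s[["R1"]], s[["R2"]])
  expect_gt(s[["B1"]], s[["B2"]])
  expect_lt(s[["A1"]], s[["A2"]])

  pK <- p
  pK$K <- Inf  # direct-dissociation mode only
  ssK <- steady_state(pK, wt, init = ss$state)
  expect_equal(ssK$classification, "symmetric")

  # an exactly symmetric start stays symmetric under the flow
  traj <- simulate_polarity(p, wt, init = default_init(wt, 0.01, 0.01),
                            t_end = 300)
  last <- tail(traj, 1)
  expect_equal(last$A1, last$A2)
  expect_equal(last$R1, last$R2)
})

test_that("steady states satisfy the dynamics and classify correctly", {
  # pure decay: everything drains to zero
  p0 <- polarity_parameters(a_A = 0, a_B = 0, a_R = 0, b_R = 0, c_A = 0,
                            c_B = 0, c_R = 0, d_AB = 0, d_BA = 0,
                            K = 1, beta = 1)
  ss0 <- steady_state(p0, polarity_condition("wt"),
                      init = setNames(rep(0.1, 6),
                                      c("A1", "A2", "B1", "B2", "R1", "R2")))
  expect_equal(unname(ss0$state), rep(0, 6), tolerance = 1e-8)

  # RomR-only with old-pole bias: asymmetric with the larger pool at pole 1
  p <- polarity_parameters()
  ss <- steady_state(p, polarity_condition("dAdB"))
  expect_equal(ss$classification, "polarized")
  expect_gt(ss$state[["R1"]], ss$state[["R2"]])

  # the steady state satisfies the dynamics
  expect_lt(max(abs(model_rhs(ss$state, p, polarity_condition("dAdB")))),
            1e-8)
})

test_that("trajectories conserve pools and swap exactly under pole exchange", {
  p <- polarity_parameters()
  wt <- polarity_condition("wt")
  traj <- simulate_polarity(p, wt, t_end = 400)
  for (sp in c("A", "B", "R")) {
    tot <- traj[[paste0(sp, 1)]] + traj[[paste0(sp, 2)]]
    expect_true(all(tot <= 1 + 1e-9))
    expect_true(all(traj[[paste0(sp, 1)]] >= -1e-9))
  }
  init <- default_init(wt)
  swapped <- init[c("A2", "A1", "B2", "B1", "R2", "R1")]
  names(swapped) <- names(init)
  t1 <- simulate_polarity(p, wt, init = init, t_end = 100)
  t2 <- simulate_polarity(p, wt, init = swapped, t_end = 100)
  # equivariance holds to integrator precision
  expect_lt(max(abs(t1$A1 - t2$A2)), 1e-8)
  expect_lt(max(abs(t1$R1 - t2$R2)), 1e-8)
})

test_that("symmetric fixed points: stable in mutants, unstable in wild type", {
  p <- polarity_parameters()
  st_wt <- stability_of_symmetric_fixed_point(p, polarity_condition("wt"))
  expect_false(st_wt$stable)

  for (g in c("dA", "dB", "dR", "dAdB", "dAdR", "dBdR")) {
    st <- stability_of_symmetric_fixed_point(p, polarity_condition(g))
    expect_true(st$stable)
    expect_lt(st$residual, 1e-8)
  }
})

test_that("numerical Jacobian matches a directional-derivative oracle", {
  p <- polarity_parameters()
  wt <- polarity_condition("wt")
  st <- stability_of_symmetric_fixed_point(p, wt)
  J <- st$jacobian
  x0 <- st$state[st$pools]
  set.seed(4)
  for (i in 1:5) {
    v <- rnorm(length(x0))
    v <- v / sqrt(sum(v^2))
    h <- 1e-6
    f <- function(y) {
      s <- st$state
      s[st$pools] <- y
      unname(model_rhs(pmax(s, 0), p, wt)[st$pools])
    }
    dir_num <- (f(x0 + h * v) - f(x0 - h * v)) / (2 * h)
    expect_equal(unname(J %*% v)[, 1], dir_num, tolerance = 1e-5)
  }
})

test_that("polar differentiation needs intermediate regulatory strength", {
  p <- polarity_parameters()
  scan <- bifurcation_scan(p, K_grid = c(1e-6, p$K, 1e3))
  expect_equal(scan$classification, c("symmetric", "polarized", "symmetric"))
  expect_true(all(scan$omega_R[c(1, 3)] < 0.05))
  expect_gt(scan$omega_R[2], 0.05)
  # too-strong suppression extinguishes polar accumulation
  expect_lt(scan$R1[1] + scan$R2[1], scan$R1[2] + scan$R2[2])
  expect_error(bifurcation_scan(p, K_grid = c(-1, 1)), "positive")
})

test_that("no sustained oscillations at the fitted parameters", {
  p <- polarity_parameters()
  wt <- polarity_condition("wt")
  ss <- steady_state(p, wt)
  f <- function(y) {
    unname(model_rhs(setNames(pmax(y, 0),
                              c("A1", "A2", "B1", "B2", "R1", "R2")), p, wt))
  }
  J <- pracma::jacobian(f, unname(ss$state))
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
  # monotone convergence after the transient
  traj <- simulate_polarity(p, wt, t_end = 1000)
  dist <- sqrt(rowSums(sweep(as.matrix(traj[, -1]), 2,
                             unname(ss$state))^2))
  tail_dist <- dist[traj$time > 300]
  expect_true(all(diff(tail_dist) <= 1e-8))  # decay to integrator precision
  expect_lt(tail_dist[length(tail_dist)], 1e-6)
})

test_that("RomR dominance: a small seed wins over a larger MglB seed", {
  p <- polarity_parameters()
  dom <- dominance_threshold(p, b0 = 0.01)
  expect_lt(dom$threshold, 0.01)  # RomR needs less than the MglB seed

  # equal seeds: the RomR pole wins
  init <- setNames(numeric(6), c("A1", "A2", "B1", "B2", "R1", "R2"))
  init[["B1"]] <- 0.01
  init[["R2"]] <- 0.01
  ss <- steady_state(p, polarity_condition("wt"), init = init)
  expect_gt(ss$state[["R2"]], ss$state[["R1"]])

  # no RomR seed: the MglB pole nucleates RomR there
  init0 <- init
  init0[["R2"]] <- 0
  ss0 <- steady_state(p, polarity_condition("wt"), init = init0)
  expect_gt(ss0$state[["R1"]], ss0$state[["R2"]])
})

test_that("tidiers expose steady states and parameter constructors validate", {
  p <- polarity_parameters()
  td <- tidy(steady_state(p, polarity_condition("wt")))
  expect_equal(td$species, c("MglA", "MglB", "RomR"))
  expect_equal(td$total, td$pole1 + td$pole2)
  expect_error(polarity_parameters(beta = 1.2), "beta")
  expect_error(polarity_parameters(K = -1), "K")
  expect_error(polarity_condition("wtx"), "unknown")
  cond <- polarity_condition(present = c("RomR"))
  expect_equal(cond$genotype, "dAdB")
})
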