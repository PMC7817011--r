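test_that("shifted Hill function: anchors, midpoint, asymptote, monotonicity", {
  expect_equal(shifted_hill(0, 100, 3, 2), 1)
  expect_equal(shifted_hill(100, 100, 3, 2), 2)        # (1 + lam) / 2
  expect_equal(shifted_hill(100, 100, 0.1, 4), 0.55)
  expect_lt(abs(shifted_hill(1e6 * 100, 100, 3, 2) - 3), 1e-3)
  x <- seq(0, 500, by = 5)
  expect_true(all(diff(shifted_hill(x, 100, 3, 2)) > 0))       # activation
  expect_true(all(diff(shifted_hill(x, 100, 0.1, 2)) < 0))     # repression
})

test_that("reaction propensities: zero state, V = 0, negative-state guard", {
  p <- default_params()
  cnt <- c(N = 0L, D = 0L, I = 0L, R2 = 0L, R2s = 0L)
  pr <- reaction_propensities(cnt, 0, 0, 5, p)
  expect_true(all(pr[c("prod_N", "prod_D", "prod_R2")] > 0))
  expect_true(all(pr[setdiff(names(pr), c("prod_N", "prod_D", "prod_R2"))] == 0))
  cnt2 <- c(N = 10L, D = 10L, I = 5L, R2 = 20L, R2s = 0L)
  expect_equal(unname(reaction_propensities(cnt2, 0, 0, 0, p)["vegf_act"]), 0)
  expect_error(reaction_propensities(c(N = -1L, D = 0L, I = 0L, R2 = 0L,
                                       R2s = 0L), 0, 0, 5, p), "negative")
})

test_that("propensity-weighted stoichiometry reproduces the mean-field rhs", {
  p <- default_params()
  S <- angiosprout:::reaction_stoichiometry()
  set.seed(7)
  for (k in 1:20) {
    x <- c(N = runif(1, 0, 4000), D = runif(1, 0, 5000), I = runif(1, 0, 300),
           R2 = runif(1, 0, 1200), R2s = runif(1, 0, 250))
    Dext <- runif(1, 0, 3000); Next <- runif(1, 0, 3000); V <- runif(1, 0, 50)
    counts <- round(x * p$Omega)
    names(counts) <- names(x)
    pr <- reaction_propensities(counts, Dext, Next, V, p)
    drift <- as.numeric(S %*% pr) / p$Omega            # concentration scale
    rhs <- mean_field_rhs(counts / p$Omega, Dext, Next, V, p)
    expect_equal(drift, unname(rhs), tolerance = 1e-10)
  }
})

test_that("phenotype classification: inclusive threshold and monotonicity", {
  b_D <- default_params()$subcellular$b_D
  expect_identical(classify_phenotype(b_D), "tip")
  expect_identical(classify_phenotype(0), "stalk")
  D <- sort(runif(50, 0, 3000))
  cl <- classify_phenotype(D)
  expect_true(all(diff(cl == "tip") >= 0))   # once tip, higher D stays tip
})

test_that("external signals: isolated cell, single neighbour, uniform monolayer", {
  lat <- hex_lattice(10, 12, 10)
  D <- numeric(lat$n); N <- numeric(lat$n)
  sig <- external_signals(lat, D, N)
  expect_true(all(sig$Dbar == 0))
  # one neighbour only: weighted average has just one non-zero term
  i <- 5 * 10 + 5
  j <- neighbor(lat, i, "r")
  D[j] <- 1200
  sig <- external_signals(lat, D, N)
  st <- angiosprout:::build_stencil(lat, 15)
  k <- (st$ptr[i] + 1):st$ptr[i + 1]
  w_j <- st$w[k][st$idx[k] == j]
  expect_equal(sig$Dbar[i], 1200 * w_j / st$wsum[i], tolerance = 1e-12)
  # uniform field: the weighted average of a constant is that constant
  D <- rep(800, lat$n); N <- rep(1500, lat$n)
  sig <- external_signals(lat, D, N)
  expect_true(all(abs(sig$Dbar - 800) < 1e-9))
  expect_true(all(abs(sig$Nbar - 1500) < 1e-9))
})

test_that("mean-field fixed points satisfy the dynamics and a bistable window exists", {
  p <- default_params()
  ss <- angiosprout:::steady_states(p, V = 5, Dext = 700)
  for (r in seq_len(nrow(ss))) {
    x <- as.numeric(ss[r, c("N", "D", "I", "R2", "R2s")])
    expect_lt(max(abs(mean_field_rhs(x, 700, 700, 5, p))), 1e-6)
  }
  sc <- bifurcation_scan(p, seq(0, 3000, by = 100), V = 5)
  expect_false(is.null(sc$bistable_interval))
  # monostable tip at low Dext (high Delta), monostable stalk at high Dext
  lo <- sc$branches[sc$branches$Dext == 0 & sc$branches$stable == 1, ]
  hi <- sc$branches[sc$branches$Dext == 3000 & sc$branches$stable == 1, ]
  expect_identical(nrow(lo), 1L)
  expect_identical(nrow(hi), 1L)
  expect_gt(lo$D, p$subcellular$b_D)    # tip state
  expect_lt(hi$D, p$subcellular$b_D)    # stalk state
  expect_gt(lo$D, hi$D)
  expect_lt(hi$N * 0 + lo$N, hi$N)      # stalk has the higher Notch level
})

test_that("stochastic mean over replicate runs tracks the deterministic system", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  lat <- hex_lattice(2, 1, 10)
  # two isolated cells (R_s only reaches the direct neighbour; keep one cell)
  occupied <- 1L
  base <- angiosprout:::baseline_counts(p)
  n_rep <- 120
  Tend <- 1.5
  finals <- matrix(NA_real_, n_rep, 2)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    prot <- matrix(0L, lat$n, 5)
    prot[1, 1:2] <- c(base["N"], base["D"])
    prot[1, 4] <- base["R2"]
    st <- angio_setup(lat, occupied = occupied, lineages = list(WT = p),
                      V = 5, proteins = prot,
                      freeze = c("migration", "fields", "orientation", "influx"))
    sim <- simulate_angio(st, T_max = Tend, dt_sample = 0)
    finals[r, ] <- sim$prot[1, 1:2] / p$Omega
  }
  ode <- deSolve::ode(
    y = c(N = unname(base["N"]) / p$Omega, D = unname(base["D"]) / p$Omega,
          I = 0, R2 = unname(base["R2"]) / p$Omega, R2s = 0),
    times = c(0, Tend),
    func = function(t, y, parms) list(mean_field_rhs(y, 0, 0, 5, p)),
    parms = NULL)
  target <- ode[2, c("N", "D")]
  for (k in 1:2) {
    se <- stats::sd(finals[, k]) / sqrt(n_rep)
    expect_lt(abs(mean(finals[, k]) - target[k]), 3 * se + 1e-9)
  }
})
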