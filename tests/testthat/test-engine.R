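test_that("runs are reproducible for a fixed seed and T_max = 0 yields the initial state", {
  st <- make_monolayer(5, 5)
  a <- simulate_angio(st, T_max = 0.5, seed = 10, dt_sample = 0.1)
  b <- simulate_angio(st, T_max = 0.5, seed = 10, dt_sample = 0.1)
  expect_identical(a$prot, b$prot)
  expect_identical(a$traj, b$traj)
  expect_identical(a$n_events, b$n_events)
  z <- simulate_angio(st, T_max = 0, seed = 10, dt_sample = 0.1)
  expect_equal(z$n_events, 0)
  expect_identical(sort(unique(trajectory_log(z)$t)), 0)
  expect_equal(nrow(trajectory_log(z)), 25)
})

test_that("cell number is conserved up to influx, and plexus voxels refill", {
  p <- default_params()
  st <- make_setup("setup1_plexus", params = p, V = 5, nx = 12, ny = 12)
  sim <- simulate_angio(st, T_max = 1, seed = 5, dt_sample = 0.05)
  tr <- trajectory_log(sim)
  counts <- table(tr$t)
  expect_true(all(diff(as.integer(counts)) >= 0))      # no cell ever lost
  expect_equal(sum(sim$E), length(st$plexus) + sim$influx_count)
  # plexus voxels are always occupied at sample times (refill-on-vacancy)
  for (tt in unique(tr$t))
    expect_true(all(st$plexus %in% tr$voxel[tr$t == tt]))
  # labels are unique at every sample time
  expect_false(any(tapply(tr$label, tr$t, anyDuplicated) > 0))
})

test_that("incrementally maintained propensities equal a from-scratch recomputation", {
  p <- default_params()
  lat <- hex_lattice(8, 8, 10)
  set.seed(31)
  occ <- sample(lat$n, 30)
  st <- angio_setup(lat, occupied = occ, lineages = list(WT = p), V = 5,
                    c0 = 0.3, m0 = 0.2, l0 = list(s = "ur", value = 1),
                    freeze = "fields")
  sim <- simulate_angio(st, T_max = 1, seed = 32)
  expect_gt(sim$n_events, 1000)
  inc <- rowSums(sim$prop)
  scr <- angiosprout:::total_propensity_R(sim)
  expect_lt(max(abs(inc - scr) / pmax(1e-12, abs(scr))), 1e-9)
})

test_that("event engine agrees with a direct-method SSA reference", {
  p <- default_params()
  lat <- hex_lattice(2, 2, 10)
  base <- angiosprout:::baseline_counts(p)
  prot <- matrix(0L, 4, 5)
  prot[, 1] <- base["N"]; prot[, 2] <- base["D"]; prot[, 4] <- base["R2"]
  st <- angio_setup(lat, occupied = 1:4, lineages = list(WT = p), V = 5,
                    proteins = prot,
                    freeze = c("migration", "fields", "orientation", "influx"))
  stencil <- st$stencil_s
  n_rep <- 150
  first_nsv <- first_dir <- numeric(n_rep)
  finalN_nsv <- finalN_dir <- numeric(n_rep)
  set.seed(77)
  for (r in seq_len(n_rep)) {
    sim <- simulate_angio(st, T_max = 0.25, dt_sample = 0)
    first_nsv[r] <- sim$first_event_time
    finalN_nsv[r] <- sim$prot[1, 1]
    dd <- angiosprout:::ssa_direct(lat, prot, rep(1L, 4), 5, p, 0.25,
                                   stencil = stencil)
    first_dir[r] <- dd$first_event_time
    finalN_dir[r] <- dd$counts[1, 1]
  }
  ks <- suppressWarnings(stats::ks.test(first_nsv, first_dir))
  expect_gt(ks$p.value, 0.01)
  se <- sqrt(stats::var(finalN_nsv) / n_rep + stats::var(finalN_dir) / n_rep)
  expect_lt(abs(mean(finalN_nsv) - mean(finalN_dir)), 3 * se + 1e-9)
})

test_that("first-event channel frequencies match the propensity ratios", {
  p <- default_params()
  lat <- hex_lattice(2, 1, 10)
  prot <- matrix(0L, 2, 5)
  prot[1, ] <- c(40L, 120L, 5L, 60L, 10L)
  prot[2, ] <- c(150L, 10L, 30L, 20L, 2L)
  st <- angio_setup(lat, occupied = 1:2, lineages = list(WT = p), V = 5,
                    proteins = prot,
                    freeze = c("migration", "fields", "orientation", "influx"))
  # expected distribution over (voxel, channel) from the reaction propensities
  sig <- external_signals(lat, prot[, 2] / p$Omega, prot[, 1] / p$Omega,
                          stencil = st$stencil_s)
  pr <- rbind(
    reaction_propensities(structure(prot[1, ], names = c("N","D","I","R2","R2s")),
                          sig$Dbar[1], sig$Nbar[1], 5, p),
    reaction_propensities(structure(prot[2, ], names = c("N","D","I","R2","R2s")),
                          sig$Dbar[2], sig$Nbar[2], 5, p))
  probs <- as.vector(t(pr)) / sum(pr)       # (voxel 1 ch 1..12, voxel 2 ...)
  n_rep <- 800
  counts <- numeric(24)
  set.seed(55)
  for (r in seq_len(n_rep)) {
    sim <- simulate_angio(st, T_max = 10, dt_sample = 0, record_events = 1,
                          max_events = 1)
    k <- (sim$events$voxel[1] - 1) * 12 + sim$events$channel[1]
    counts[k] <- counts[k] + 1
  }
  for (k in which(probs > 0.02)) {
    se <- sqrt(n_rep * probs[k] * (1 - probs[k]))
    expect_lt(abs(counts[k] - n_rep * probs[k]), 3 * se + 3)
  }
})

test_that("realised migration directions follow the windowed von Mises masses", {
  p <- default_params()
  lat <- hex_lattice(5, 5, 10)
  ctr <- 2 * 5 + 3
  prot <- matrix(0L, lat$n, 5)
  prot[ctr, 2] <- as.integer(2000 * p$Omega)       # fixes kappa via Delta
  l0 <- matrix(0, lat$n, 6)
  l0[, 1] <- 1.2; l0[, 2] <- 0.5                   # anisotropic landscape
  st <- angio_setup(lat, occupied = ctr, lineages = list(WT = p), V = 5,
                    c0 = 0, m0 = 0.4, l0 = l0, proteins = prot,
                    freeze = c("reactions", "fields", "orientation", "influx"))
  # expected masses
  pol <- mean_polarisation(l0[ctr, ], p)
  kap <- exploratoriness(2000, 0.4, p)
  mass <- vapply(1:6, function(s) direction_mass(pol$mu, kap, s), numeric(1))
  n_rep <- 900
  counts <- numeric(6)
  set.seed(66)
  for (r in seq_len(n_rep)) {
    sim <- simulate_angio(st, T_max = 50, dt_sample = 0, record_events = 1,
                          max_events = 1)
    counts[sim$events$direction[1]] <- counts[sim$events$direction[1]] + 1
  }
  for (s in which(mass > 0.02)) {
    se <- sqrt(n_rep * mass[s] * (1 - mass[s]))
    expect_lt(abs(counts[s] - n_rep * mass[s]), 3 * se + 3)
  }
})

test_that("shuffling queue matches the exact Markov-chain distribution", {
  skip_if_not_installed("Matrix")
  p <- default_params()
  lat <- hex_lattice(4, 1, 10)
  Dlev <- c(3000, 400, 1800, 100)                   # distinct mobilities
  prot <- matrix(0L, 4, 5)
  prot[, 2] <- as.integer(Dlev * p$Omega)
  st <- angio_setup(lat, occupied = 1:4, lineages = list(WT = p), V = 5,
                    c0 = 0, m0 = 1, l0 = list(s = "r", value = 1),
                    proteins = prot,
                    freeze = c("reactions", "fields", "orientation", "influx"))
  # exact generator over the 24 permutations of the four labelled cells
  C <- angiosprout:::migration_rate_scale(p) *
    neighbourhood_function(1, p)                    # fully crowded strip
  kapp <- exploratoriness(Dlev, 1, p)
  mu <- 0                                           # landscape points right
  m_r <- vapply(kapp, function(k) direction_mass(mu, k, "r"), numeric(1))
  m_l <- vapply(kapp, function(k) direction_mass(mu, k, "l"), numeric(1))
  psw <- switching_probability(Dlev, p)
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 4), ]
  key <- apply(perms, 1, paste, collapse = "")
  Q <- matrix(0, 24, 24, dimnames = list(key, key))
  for (r in 1:24) {
    sig <- perms[r, ]
    for (pos in 1:3) {
      a <- sig[pos]; b <- sig[pos + 1]
      rate <- C * (psw[a] * m_r[a] + psw[b] * m_l[b])   # swap (pos, pos+1)
      tgt <- sig; tgt[pos] <- b; tgt[pos + 1] <- a
      Q[r, paste(tgt, collapse = "")] <- rate
    }
    diag(Q)[r] <- -sum(Q[r, ])
  }
  Tend <- 6
  P <- as.matrix(Matrix::expm(Matrix::Matrix(t(Q) * Tend)))
  p0 <- numeric(24); p0[match("1234", key)] <- 1
  pT <- as.numeric(P %*% p0)
  # exact marginal: probability that cell 1 occupies the leading position
  lead1 <- sum(pT[perms[, 4] == 1])
  n_rep <- 600
  hit <- 0
  set.seed(88)
  for (r in seq_len(n_rep)) {
    sim <- simulate_angio(st, T_max = Tend, dt_sample = 0)
    hit <- hit + (sim$label[4] == 1)
  }
  se <- sqrt(lead1 * (1 - lead1) / n_rep)
  expect_lt(abs(hit / n_rep - lead1), 3 * se + 0.01)
})
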