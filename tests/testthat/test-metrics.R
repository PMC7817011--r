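test_that("network distances: identity, straight path, BFS oracle", {
  lat <- hex_lattice(20, 20, 10)
  line <- c(41L, walk_arm(lat, 41L, "r", 4))     # 5-voxel straight sprout
  g <- network_graph(lat, line)
  expect_equal(network_distance(g, line[1], line[1]), 0)
  expect_equal(network_distance(g, line[1], line[5]), 4 * 10)
  expect_error(network_distance(g, 1L, line[1]), "node")
  # BFS oracle on random connected voxel sets
  bfs_dist <- function(nodes, nbr, from, to) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[as.character(from)] <- 0
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbr[v, ]) {
        if (!is.na(w) && w %in% nodes && dist[as.character(w)] > dist[as.character(v)] + 1) {
          dist[as.character(w)] <- dist[as.character(v)] + 1
          queue <- c(queue, w)
        }
      }
    }
    dist[as.character(to)] * 10
  }
  set.seed(14)
  for (k in 1:8) {
    rn <- make_random_network(n_nodes = 15, n_walkers = 1, n_steps = 1,
                              lattice = lat)
    pair <- sample(rn$nodes, 2)
    expect_equal(network_distance(rn$network, pair[1], pair[2]),
                 unname(bfs_dist(rn$nodes, lat$nbr, pair[1], pair[2])))
  }
})

test_that("displacement distribution: stationary cells, single hops, binomial oracle", {
  lat <- hex_lattice(30, 30, 10)
  # stationary cell
  log <- toy_log(lat, t = seq(0, 0.09, by = 0.03), label = 1L, voxel = 200L)
  expect_true(all(displacement_histogram(log) == 0))
  # one hop inside one window
  v2 <- neighbor(lat, 200L, "ur")
  log <- toy_log(lat, t = c(0, 0.03), label = 1L, voxel = c(200L, v2))
  expect_equal(displacement_histogram(log), 10)
  # incompatible window is rejected
  expect_error(displacement_histogram(log, window_min = 10), "multiple")
  # unbiased lattice walk: fraction of single-hop windows matches hop rate
  set.seed(15)
  q <- 0.3
  n_steps <- 4000
  v <- 435L
  vox <- integer(n_steps)
  for (k in seq_len(n_steps)) {
    vox[k] <- v
    if (stats::runif(1) < q) {
      nb <- lat$nbr[v, ]; nb <- nb[!is.na(nb)]
      v <- nb[sample.int(length(nb), 1)]
    }
  }
  log <- toy_log(lat, t = (seq_len(n_steps) - 1) * 0.03, label = 1L, voxel = vox)
  d <- displacement_histogram(log)     # one sampling step per window
  se <- sqrt(q * (1 - q) / length(d))
  expect_lt(abs(mean(d > 0) - q), 3 * se)
})

test_that("orientation statistic: straight paths, zigzags, bounded ratio", {
  lat <- hex_lattice(30, 30, 10)
  line <- c(156L, walk_arm(lat, 156L, "r", 8))
  log <- toy_log(lat, t = (0:8) * 0.01, label = 1L, voxel = line)
  expect_equal(unname(orientation_statistic(log)), 1, tolerance = 1e-9)
  # tight zigzag returning to the start is shortened by smoothing
  zig <- rep(c(400L, neighbor(lat, 400L, "r")), 6)
  log <- toy_log(lat, t = (0:11) * 0.01, label = 1L, voxel = zig)
  expect_lt(unname(orientation_statistic(log)), 1)
  # property: always within (0, 1] for random walks
  set.seed(16)
  for (k in 1:10) {
    v <- 500L; vox <- v
    for (q in 1:15) {
      nb <- lat$nbr[v, ]; nb <- nb[!is.na(nb)]
      v <- nb[sample.int(length(nb), 1)]
      vox <- c(vox, v)
    }
    r <- orientation_statistic(toy_log(lat, (0:15) * 0.01, 1L, vox))
    expect_gt(r, 0)
    expect_lte(r, 1)
  }
})

test_that("directionality: stationary logs, probability vector, swap symmetry", {
  lat <- hex_lattice(30, 30, 10)
  log <- toy_log(lat, t = rep(seq(0, 0.12, by = 0.04), each = 2),
                 label = rep(1:2, 4), voxel = rep(c(300L, 301L), 4))
  dd <- directionality(log, lat, base_voxels = 300L)
  expect_equal(unname(dd$proportions), c(0, 0, 1))
  # a pure swap: one cell forward, one backward relative to the base
  base <- 9L * 30L + 11L
  fwd <- walk_arm(lat, base, "r", 4)
  log <- toy_log(lat,
                 t = rep(c(0, 0.04), each = 2), label = rep(1:2, 2),
                 voxel = c(fwd[2], fwd[3], fwd[3], fwd[2]))
  dd <- directionality(log, lat, base_voxels = base)
  expect_equal(sum(dd$proportions), 1)
  expect_equal(unname(dd$proportions["anterograde"]),
               unname(dd$proportions["retrograde"]))
})

test_that("tip proportion: extremes and empty logs", {
  lat <- hex_lattice(10, 10, 10)
  log <- toy_log(lat, t = rep(0, 4), label = 1:4, voxel = 1:4)
  log$phenotype <- "tip"
  expect_equal(tip_proportion(log, 0), 1)
  log$phenotype <- c("tip", "stalk", "stalk", "stalk")
  expect_equal(tip_proportion(log, 0), 0.25)
  expect_true(is.na(tip_proportion(log[0, ], 1)))
})

test_that("mixing measure: frozen logs, brute-force oracle, relabelling invariance, bound", {
  lat <- hex_lattice(25, 25, 10)
  ctr <- 12L * 25L + 12L
  Y <- make_Y(lat, ctr, arm_len = 6)
  g <- network_graph(lat, Y)
  cluster <- intersect(c(ctr, lat$nbr[ctr, ]), Y)
  arms <- list(c(ctr, walk_arm(lat, ctr, "r", 6)),
               c(ctr, walk_arm(lat, ctr, "ul", 6)),
               c(ctr, walk_arm(lat, ctr, "dl", 6)))
  # three walkers moving out along distinct arms
  steps <- 6
  log <- do.call(rbind, lapply(1:3, function(w)
    toy_log(lat, t = (0:steps) * 0.1, label = w, voxel = arms[[w]])))
  M <- mixing_measure(log, g, cluster, t = 0, t_m = 0.6)
  # brute-force recomputation straight from the definition
  dm <- angiosprout:::network_distance_matrix(g)
  lab <- 1:3
  at0 <- vapply(lab, function(w) log$voxel[log$label == w & log$t == 0][1], numeric(1))
  tlast <- max(log$t)
  at1 <- vapply(lab, function(w) log$voxel[log$label == w & log$t == tlast][1], numeric(1))
  vf <- log$voxel[log$t == max(log$t)]
  d_max <- max(dm[as.character(vf), as.character(vf)])
  brute <- 0
  for (a in 1:2) for (b in (a + 1):3) {
    if (!(at0[a] %in% cluster) || !(at0[b] %in% cluster)) next
    brute <- brute + dm[as.character(at1[a]), as.character(at1[b])] -
                     dm[as.character(at0[a]), as.character(at0[b])]
  }
  brute <- brute / (length(cluster) * d_max)
  expect_equal(M, brute, tolerance = 1e-12)
  expect_gt(M, 0)
  # invariance under relabelling
  log2 <- log
  log2$label <- c(7, 9, 8)[log2$label]
  expect_equal(mixing_measure(log2, g, cluster, t = 0, t_m = 0.6), M)
  # algebraic bound: |M| <= n_pairs / |cluster| since |delta d| <= d_max
  n_cells <- sum(at0 %in% cluster)
  expect_lte(abs(M), choose(n_cells, 2) / length(cluster))
  # frozen log gives exactly zero (walkers parked on distinct cluster voxels)
  frozen <- log
  for (w in lab) frozen$voxel[frozen$label == w] <- arms[[w]][2]
  expect_equal(mixing_measure(frozen, g, cluster, t = 0, t_m = 0.6), 0)
  # fewer than two cluster cells: undefined
  expect_true(is.na(mixing_measure(log, g, cluster = Y[13], t = 0, t_m = 0.6)))
})

test_that("morphometrics: straight sprouts, Y junctions, enumeration oracle", {
  lat <- hex_lattice(25, 25, 10)
  line <- c(30L, walk_arm(lat, 30L, "r", 9))       # 10 voxels
  m <- network_morphometrics(network_graph(lat, line))
  expect_equal(m$n_branch_points, 0)
  expect_equal(m$n_segments, 1)
  expect_equal(m$segment_lengths, 90)
  expect_equal(m$network_area, 10 * sqrt(3) / 2 * 100)
  ctr <- 12L * 25L + 12L
  mY <- network_morphometrics(network_graph(lat, make_Y(lat, ctr, 5)))
  expect_equal(mY$n_branch_points, 1)
  expect_equal(mY$n_segments, 3)
  expect_true(all(mY$segment_lengths == 50))
  expect_equal(mY$branch_points_per_100um2, 1 / (16 * sqrt(3) / 2))
  # a one-voxel spur is pruned from the branching-point count
  spur <- c(ctr, walk_arm(lat, ctr, "r", 5), walk_arm(lat, ctr, "ul", 5),
            walk_arm(lat, ctr, "dl", 1))
  mb <- network_morphometrics(network_graph(lat, spur))
  expect_equal(mb$n_branch_points, 0)     # third segment is below 2 voxel widths
  expect_equal(mb$n_segments, 3)
  # double junction: a Y whose trunk ends in a second fork
  trunk <- walk_arm(lat, ctr, "r", 8)
  v8 <- trunk[8]
  dbl <- c(ctr, trunk, walk_arm(lat, ctr, "ul", 4), walk_arm(lat, ctr, "dl", 4),
           walk_arm(lat, v8, "ur", 4), walk_arm(lat, v8, "dr", 4))
  mc <- network_morphometrics(network_graph(lat, dbl))
  expect_equal(mc$n_branch_points, 2)
  expect_equal(mc$n_segments, 5)
})

test_that("metrics are pure: recomputation from the same log is identical", {
  set.seed(20)
  rn <- make_random_network(n_nodes = 25, n_walkers = 4, n_steps = 12)
  a1 <- displacement_histogram(rn$log)
  a2 <- displacement_histogram(rn$log)
  expect_identical(a1, a2)
  o1 <- orientation_statistic(rn$log)
  expect_identical(o1, orientation_statistic(rn$log))
  cl <- unique(rn$log$voxel[rn$log$t == 0])
  if (length(cl) >= 2) {
    m1 <- mixing_measure(rn$log, rn$network, cl, 0, 0.05)
    expect_identical(m1, mixing_measure(rn$log, rn$network, cl, 0, 0.05))
  }
})
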