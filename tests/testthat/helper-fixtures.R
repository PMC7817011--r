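# shared helpers for building small geometric fixtures

# follow `n` steps from `start` in direction `dir`, returning the visited voxels
walk_arm <- function(lattice, start, dir, n) {
  v <- start
  out <- integer(n)
  for (k in seq_len(n)) {
    v <- neighbor(lattice, v, dir)
    out[k] <- v
  }
  out
}

# a Y-shaped voxel set: three arms of `arm_len` voxels from a centre voxel
make_Y <- function(lattice, centre, arm_len = 5) {
  c(centre,
    walk_arm(lattice, centre, "r", arm_len),
    walk_arm(lattice, centre, "ul", arm_len),
    walk_arm(lattice, centre, "dl", arm_len))
}

# minimal trajectory-log data frame from (t, label, voxel) triples
toy_log <- function(lattice, t, label, voxel) {
  data.frame(t = t, label = label, voxel = voxel,
             x = unname(lattice$centers[voxel, 1]),
             y = unname(lattice$centers[voxel, 2]),
             D = 0, phenotype = "stalk", lineage = "WT",
             stringsAsFactors = FALSE)
}

# small fast parameter set for engine tests (fewer copies, faster run)
test_params <- function(...) default_params(...)
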