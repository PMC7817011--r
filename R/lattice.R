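#' Hexagonal lattice geometry
#'
#' Constructs a uniform lattice of flat-to-flat width `h` (micrometres) made of
#' regular hexagonal voxels with edge length `a = h / sqrt(3)`, arranged in
#' `ny` horizontal rows of `nx` voxels each; odd rows (0-based row parity 1)
#' are shifted right by `h/2` so that every interior voxel has exactly six
#' neighbours at centre-to-centre distance `h`.
#'
#' Voxel indices are 1-based and row-major: voxel `i` sits in column
#' `((i-1) %% nx) + 1` and row `((i-1) %/% nx) + 1`.
#'
#' @param nx number of voxel columns.
#' @param ny number of voxel rows.
#' @param h voxel width (flat-to-flat) in micrometres.
#' @return An object of class `hex_lattice`: a list with the lattice
#'   dimensions, voxel edge `a`, `centers` (n x 2 matrix, micrometres),
#'   `nbr` (n x 6 integer matrix of neighbour indices, `NA` off-lattice) and
#'   the direction table (see [hex_directions()]).
#' @export
hex_lattice <- function(nx, ny, h = 10) {
  stopifnot(nx >= 1, ny >= 1, h > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  n <- nx * ny
  col <- rep(seq_len(nx) - 1L, times = ny)
  row <- rep(seq_len(ny) - 1L, each = nx)
  shift <- ifelse(row %% 2L == 1L, h / 2, 0)
  centers <- cbind(x = col * h + shift, y = row * (sqrt(3) / 2) * h)
  dirs <- hex_directions()
  nbr <- matrix(NA_integer_, n, 6, dimnames = list(NULL, dirs$label))
  par <- row %% 2L
  # offset-coordinate neighbour table for row-shifted hexagons
  dc <- cbind(r  = 1L, ur = par, ul = par - 1L, l = -1L, dl = par - 1L, dr = par)
  dr <- cbind(r  = 0L, ur = 1L,  ul = 1L,       l = 0L,  dl = -1L,      dr = -1L)
  for (s in 1:6) {
    cc <- col + dc[, s]
    rr <- row + dr[, s]
    ok <- cc >= 0L & cc < nx & rr >= 0L & rr < ny
    idx <- rr * nx + cc + 1L
    nbr[ok, s] <- idx[ok]
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), h = h, a = h / sqrt(3),
         n = n, centers = centers, nbr = nbr, directions = dirs),
    class = "hex_lattice"
  )
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("hex_lattice: %d x %d voxels, h = %g um (a = %.4g um)\n",
              x$nx, x$ny, x$h, x$a))
  invisible(x)
}

#' Migration direction set of the hexagonal lattice
#'
#' The six migration directions r, ur, ul, l, dl, dr with their unit vectors
#' and half-open angle intervals `[phi_min, phi_max)` of width `pi/3`; the
#' right direction is associated with `[-pi/6, pi/6)` and the six intervals
#' partition the circle.
#'
#' @return data frame with columns `label`, `ux`, `uy`, `angle`, `phi_min`,
#'   `phi_max` (for `l` the interval `[5pi/6, 7pi/6)` wraps through `pi`).
#' @export
hex_directions <- function() {
  ang <- c(r = 0, ur = pi / 3, ul = 2 * pi / 3, l = pi,
           dl = -2 * pi / 3, dr = -pi / 3)
  data.frame(label = names(ang),
             ux = cos(ang), uy = sin(ang), angle = unname(ang),
             phi_min = unname(ang) - pi / 6, phi_max = unname(ang) + pi / 6,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Angle interval of a migration direction
#'
#' @param s direction label, one of `r, ur, ul, l, dl, dr`.
#' @return numeric `c(phi_min, phi_max)`, the half-open interval of width
#'   `pi/3` centred on the direction angle (`r` gives `[-pi/6, pi/6)`).
#' @export
angle_interval <- function(s) {
  d <- hex_directions()
  i <- match(s, d$label)
  if (is.na(i)) stop("unknown direction: ", s)
  c(d$phi_min[i], d$phi_max[i])
}

#' Map a polarity angle to a migration direction
#'
#' @param phi angle in radians (any real number; reduced mod 2*pi).
#' @return integer in 1..6 indexing the rows of [hex_directions()].
#' @export
direction_from_angle <- function(phi) {
  k <- floor((phi + pi / 6) / (pi / 3))
  as.integer(k %% 6) + 1L
}

#' Neighbour of a voxel in a given direction
#'
#' @param lattice a [hex_lattice()].
#' @param i voxel index.
#' @param s direction label or index in 1..6.
#' @return the neighbouring voxel index, or `NA` when the move leaves the
#'   lattice.
#' @export
neighbor <- function(lattice, i, s) {
  if (!is.numeric(i) || i < 1 || i > lattice$n) stop("invalid voxel index")
  if (is.character(s)) s <- match(s, lattice$directions$label)
  if (is.na(s) || s < 1 || s > 6) stop("invalid direction")
  unname(lattice$nbr[i, s])
}

# vertices of the hexagonal voxel centred at `center` (counter-clockwise)
hex_vertices <- function(center, h) {
  a <- h / sqrt(3)
  th <- pi / 6 + (0:5) * pi / 3
  cbind(center[1] + a * cos(th), center[2] + a * sin(th))
}

# Exact area of the intersection of a convex polygon (counter-clockwise
# vertex matrix) with the disc of radius R centred at `cc`.  Green's-theorem
# decomposition: chords contribute triangle areas, excursions outside the
# disc contribute circular-sector areas.
polygon_circle_area <- function(poly, cc, R) {
  px <- poly[, 1] - cc[1]
  py <- poly[, 2] - cc[2]
  nv <- nrow(poly)
  total <- 0
  for (e in seq_len(nv)) {
    x1 <- px[e]; y1 <- py[e]
    j <- if (e == nv) 1L else e + 1L
    x2 <- px[j]; y2 <- py[j]
    dx <- x2 - x1; dy <- y2 - y1
    # segment-circle intersection parameters
    aa <- dx * dx + dy * dy
    ts <- numeric(0)
    if (aa > 0) {
      bb <- 2 * (x1 * dx + y1 * dy)
      cc2 <- x1 * x1 + y1 * y1 - R * R
      disc <- bb * bb - 4 * aa * cc2
      if (disc > 0) {
        sq <- sqrt(disc)
        ts <- sort(c((-bb - sq) / (2 * aa), (-bb + sq) / (2 * aa)))
        ts <- ts[ts > 0 & ts < 1]
      }
    }
    knots <- c(0, ts, 1)
    for (k in seq_len(length(knots) - 1)) {
      t1 <- knots[k]; t2 <- knots[k + 1]
      mx <- x1 + dx * (t1 + t2) / 2
      my <- y1 + dy * (t1 + t2) / 2
      ax <- x1 + dx * t1; ay <- y1 + dy * t1
      bx <- x1 + dx * t2; by <- y1 + dy * t2
      if (mx * mx + my * my < R * R * (1 - 1e-12)) {
        total <- total + (ax * by - bx * ay) / 2
      } else {
        dth <- atan2(by, bx) - atan2(ay, ax)
        dth <- atan2(sin(dth), cos(dth))  # wrap to (-pi, pi]
        total <- total + R * R * dth / 2
      }
    }
  }
  total
}

#' Disc-overlap interaction weights
#'
#' For a disc of radius `R` centred on voxel `i`, returns the fractional
#' overlap `|v_j intersect B_R(i)| / |v_j|` for every voxel `j` with non-zero
#' overlap.  These weights define the non-local juxtacrine neighbourhood
#' (signalling radius) and the cell-cell adhesion neighbourhood (interaction
#' radius); the centre voxel can be excluded, as required for both uses.
#'
#' @param lattice a [hex_lattice()].
#' @param i centre voxel index.
#' @param R disc radius in micrometres.
#' @param include_self keep the `j = i` entry? Default `FALSE`.
#' @return data frame with columns `j` (voxel index) and `w` (weight in
#'   (0, 1]), ordered by `j`.
#' @export
overlap_weights <- function(lattice, i, R, include_self = FALSE) {
  stopifnot(R > 0, i >= 1, i <= lattice$n)
  ci <- lattice$centers[i, ]
  # candidates: centre distance below R + circumradius
  d <- sqrt((lattice$centers[, 1] - ci[1])^2 + (lattice$centers[, 2] - ci[2])^2)
  cand <- which(d < R + lattice$a + 1e-9)
  if (!include_self) cand <- setdiff(cand, i)
  varea <- sqrt(3) / 2 * lattice$h^2  # area of a regular hexagon of width h
  w <- vapply(cand, function(j) {
    polygon_circle_area(hex_vertices(lattice$centers[j, ], lattice$h), ci, R) / varea
  }, numeric(1))
  keep <- w > 1e-12
  out <- data.frame(j = cand[keep], w = pmin(w[keep], 1))
  out[order(out$j), , drop = FALSE]
}

# Precompute overlap stencils for all voxels at radius R, in compressed
# sparse-row form as consumed by the event engine.  Weights depend only on
# the centre-to-centre offset, so they are computed once per distinct offset.
# `denominator = "lattice"` normalises by the in-lattice weight sum (the
# lattice is the whole physical domain); "disc" normalises by the full-disc
# weight sum (the lattice is a sub-region, e.g. a sprout, embedded in a
# larger cell-free domain, whose empty surroundings dilute the averages).
build_stencil <- function(lattice, R, include_self = FALSE,
                          denominator = c("lattice", "disc")) {
  denominator <- match.arg(denominator)
  h <- lattice$h
  cx <- lattice$centers[, 1]; cy <- lattice$centers[, 2]
  # enumerate all integer offsets potentially overlapping the disc
  reach <- ceiling((R + lattice$a) / (sqrt(3) / 2 * h)) + 1L
  varea <- sqrt(3) / 2 * h^2
  cache <- new.env(parent = emptyenv())
  offset_w <- function(dx, dy) {
    key <- sprintf("%.6f_%.6f", dx, dy)
    if (!is.null(cache[[key]])) return(cache[[key]])
    w <- polygon_circle_area(hex_vertices(c(dx, dy), h), c(0, 0), R) / varea
    cache[[key]] <- w
    w
  }
  idx_list <- vector("list", lattice$n)
  w_list <- vector("list", lattice$n)
  for (i in seq_len(lattice$n)) {
    col <- (i - 1L) %% lattice$nx
    row <- (i - 1L) %/% lattice$nx
    cols <- max(0L, col - reach):min(lattice$nx - 1L, col + reach)
    rows <- max(0L, row - reach):min(lattice$ny - 1L, row + reach)
    js <- as.vector(outer(cols + 1L, rows * lattice$nx, `+`))
    if (!include_self) js <- js[js != i]
    dx <- cx[js] - cx[i]; dy <- cy[js] - cy[i]
    near <- sqrt(dx^2 + dy^2) < R + lattice$a + 1e-9
    js <- js[near]; dx <- dx[near]; dy <- dy[near]
    w <- vapply(seq_along(js), function(k) offset_w(dx[k], dy[k]), numeric(1))
    keep <- w > 1e-12
    idx_list[[i]] <- js[keep]
    w_list[[i]] <- pmin(w[keep], 1)
  }
  len <- lengths(idx_list)
  wsum <- vapply(w_list, sum, numeric(1))
  if (denominator == "disc") {
    self_w <- polygon_circle_area(hex_vertices(c(0, 0), h), c(0, 0), R) / varea
    wsum[] <- pi * R^2 / varea - if (include_self) 0 else self_w
  }
  list(ptr = c(0L, cumsum(len)),            # 0-based CSR row pointers
       idx = as.integer(unlist(idx_list)),  # 1-based voxel indices
       w = as.numeric(unlist(w_list)),
       wsum = wsum)
}
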