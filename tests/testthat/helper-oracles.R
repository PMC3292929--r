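# Independent oracles and fixture builders. The edge-weight formula and the
# shortest-path solver here are written from scratch (no calls into the
# package's accumulation engine) so they can certify it.

# Slope-speed curve, restated independently of toblerSpeed()
oracle_tobler <- function(slope_deg) {
  6 * exp(-3.5 * abs(tan(slope_deg * pi / 180) + 0.05))
}

# Minutes for one edge between adjacent cells: half the edge at each
# endpoint's effective speed; slope multiplier on human-powered modes only.
oracle_edge_minutes <- function(s1, m1, s2, m2, z1, z2, d_m) {
  mult <- if (is.null(z1)) 1 else {
    slope <- atan2(abs(z2 - z1), d_m) * 180 / pi
    oracle_tobler(slope) / oracle_tobler(0)
  }
  v1 <- if (m1 == 3) s1 else s1 * mult
  v2 <- if (m2 == 3) s2 else s2 * mult
  d_km <- d_m / 1000
  60 * (d_km / 2 / v1 + d_km / 2 / v2)
}

# Edge list of the 8-connected grid graph (directed, both ways)
oracle_edges <- function(speed, mode, dem, cellSize) {
  nr <- nrow(speed); nc <- ncol(speed)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (sh in shifts) {
    d_m <- cellSize * if (sh[1] != 0 && sh[2] != 0) sqrt(2) else 1
    for (r in seq_len(nr)) {
      r2 <- r + sh[1]
      if (r2 < 1 || r2 > nr) next
      for (c in seq_len(nc)) {
        c2 <- c + sh[2]
        if (c2 < 1 || c2 > nc) next
        if (speed[r, c] <= 0 || speed[r2, c2] <= 0) next
        from <- c(from, r + nr * (c - 1))
        to <- c(to, r2 + nr * (c2 - 1))
        w <- c(w, oracle_edge_minutes(
          speed[r, c], mode[r, c], speed[r2, c2], mode[r2, c2],
          if (is.null(dem)) NULL else dem[r, c],
          if (is.null(dem)) NULL else dem[r2, c2], d_m))
      }
    }
  }
  list(from = from, to = to, w = w)
}

# Bellman-Ford-style relaxation to a fixed point, single source set
oracle_shortest <- function(edges, n, sources) {
  dist <- rep(Inf, n)
  dist[sources] <- 0
  repeat {
    cand <- dist[edges$from] + edges$w
    m <- tapply(cand, edges$to, min)
    idx <- as.integer(names(m))
    newd <- dist
    newd[idx] <- pmin(dist[idx], as.numeric(m))
    if (identical(newd, dist)) break
    dist <- newd
  }
  dist
}

# Random friction instance for oracle comparisons
random_instance <- function(seed, nr = 15, nc = 15, nFac = NULL,
                            withDem = TRUE) {
  set.seed(seed)
  spec <- GridSpec(nr, nc)
  speed <- matrix(runif(nr * nc, 0.5, 80), nr, nc)
  mode <- matrix(sample(1:3, nr * nc, replace = TRUE), nr, nc)
  barrier <- matrix(runif(nr * nc) < 0.1, nr, nc)
  speed[barrier] <- 0
  mode[barrier] <- 0L
  if (is.null(nFac)) nFac <- sample(1:3, 1)
  open <- which(!barrier)
  facCells <- sample(open, nFac)
  row <- ((facCells - 1L) %% nr) + 1L
  col <- ((facCells - 1L) %/% nr) + 1L
  xy <- cellCenter(spec, row, col)
  dem <- if (withDem)
    matrix(cumsum(rnorm(nr * nc, sd = 20)), nr, nc) else NULL
  friction <- new("FrictionSurface", speed = speed,
                  mode = matrix(as.integer(mode), nr, nc),
                  barrier = barrier, spec = spec)
  list(spec = spec, friction = friction, dem = dem,
       facilities = data.frame(id = seq_len(nFac), x = xy[, 1], y = xy[, 2]),
       facCells = facCells)
}

# Uniform-shrub friction surface on an n x n grid (5 km/h walking)
uniform_shrub <- function(n = 5, cellSize = 1000) {
  g <- GridSpec(n, n, cellSize = cellSize)
  buildFrictionSurface(GridRaster(4L, g))
}

# Draw survey-like attendance records from a decay model
simulate_records <- function(model, n, xmax = 2.6, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, xmax)
  t <- 10^x
  p <- predictProbability(model, t)
  data.frame(travel_time = t, attended = rbinom(n, 1, p))
}
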