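# Shared fixtures, built in code at test time.

# Regular x-y grid mesh (spacing 1 mm) triangulated with diagonals.
grid_mesh <- function(nx = 5, ny = 5, spacing = 1) {
  v <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * spacing,
                             y = (seq_len(ny) - 1) * spacing))
  v <- cbind(v, 0)
  idx <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                 c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  cortical_mesh(v, f)
}

# Straight polyline between two points with constant FA.
straight_streamline <- function(from, to, fa = 0.5, npts = 3) {
  tt <- seq(0, 1, length.out = npts)
  list(points = outer(1 - tt, from) + outer(tt, to),
       fa = rep(fa, npts))
}

# 3-point polyline whose single turning angle is `angle` degrees.
bent_streamline <- function(angle, fa = 0.5) {
  th <- angle * pi / 180
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1 + cos(th), sin(th), 0))
  list(points = p, fa = rep(fa, 3))
}

# Four Gaussian clusters (SD 1) at non-antipodal square corners separated
# by `sep` SD; labels are the four diagnosis-by-sex cells.
four_cluster_data <- function(n_per = 10, sep = 10, seed = 7) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))
  x <- do.call(rbind, lapply(1:4, function(g) {
    sweep(matrix(stats::rnorm(2 * n_per), n_per, 2), 2, centers[g, ], "+")
  }))
  list(x = x,
       labels = factor(rep(c("ASD_M", "ASD_F", "TD_M", "TD_F"),
                           each = n_per),
                       levels = c("ASD_M", "ASD_F", "TD_M", "TD_F")),
       centers = centers)
}

# Independent single-source shortest paths (naive Dijkstra) on a mesh.
dijkstra_brute <- function(mesh, source) {
  n <- nrow(mesh$vertices)
  el <- igraph::as_edgelist(mesh$graph)
  w <- igraph::E(mesh$graph)$weight
  adj <- vector("list", n)
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, w[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[e]))
  }
  dist <- rep(Inf, n)
  dist[source] <- 0
  visited <- rep(FALSE, n)
  repeat {
    u <- which(!visited & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; duv <- adj[[u]][r, 2]
      if (dist[u] + duv < dist[v]) dist[v] <- dist[u] + duv
    }
  }
  dist
}

# Brute-force BH step-up: largest i with p_(i) <= i * alpha / m rejected.
bh_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Procrustes RMS after optimal rotation/translation (no scaling).
procrustes_rms <- function(a, b) {
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  s <- svd(t(bc) %*% ac)
  rot <- s$u %*% t(s$v)
  sqrt(mean((bc %*% rot - ac)^2))
}
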