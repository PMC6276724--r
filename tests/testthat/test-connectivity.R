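test_that("turning-angle filter retains straight and drops bent streamlines", {
  straight <- straight_streamline(c(0, 0, 0), c(10, 0, 0))
  right_angle <- bent_streamline(90)
  sl <- streamline_set(list(straight, right_angle))
  kept <- filter_streamlines(sl, max_angle = 60)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$points, straight$points)

  # angles {10, 59} retained; {10, 61} discarded
  mk <- function(a2) {
    p1 <- bent_streamline(10)$points
    th <- (10 + a2) * pi / 180  # cumulative direction after second turn
    p <- rbind(p1, p1[3, ] + c(cos(th), sin(th), 0))
    list(points = p, fa = rep(0.5, 4))
  }
  expect_length(filter_streamlines(streamline_set(list(mk(59)))), 1)
  expect_length(filter_streamlines(streamline_set(list(mk(61)))), 0)

  # empty input is not an error; 2-point polylines have no turns
  expect_length(filter_streamlines(streamline_set(list())), 0)
  two_pt <- list(points = rbind(c(0, 0, 0), c(1, 0, 0)), fa = c(0.1, 0.2))
  expect_length(filter_streamlines(streamline_set(list(two_pt))), 1)

  # literal discard-if-below rule drops the straight streamline instead
  expect_length(filter_streamlines(streamline_set(list(straight)),
                                   literal = TRUE), 0)
  expect_error(filter_streamlines(sl, max_angle = 0), "0, 180")
})

test_that("streamline mean FA is the arithmetic mean of samples", {
  expect_equal(streamline_mean_fa(straight_streamline(c(0, 0, 0), c(1, 0, 0),
                                                      fa = 0.5, npts = 10)),
               0.5)
  expect_equal(streamline_mean_fa(list(points = diag(3),
                                       fa = c(0.2, 0.4, 0.6))), 0.4)
  expect_equal(streamline_mean_fa(list(points = diag(3), fa = rep(0, 3))), 0)
  expect_error(streamline_mean_fa(list(points = diag(3))), "FA")
})

test_that("connectivity matrix maps endpoints, counts pairs, drops unmappable", {
  mesh <- grid_mesh(5, 5)
  a <- mesh$vertices[1, ]; b <- mesh$vertices[25, ]
  one <- streamline_set(list(straight_streamline(a, b)))
  conn <- build_connectivity_matrix(mesh, one, snap_radius = 0.4)
  expect_equal(conn$n_connections, 1)
  expect_equal(conn$matrix[1, 25], 1)
  expect_equal(conn$matrix[25, 1], 1)
  expect_equal(sum(conn$matrix), 2)  # symmetric single pair
  expect_true(all(Matrix::diag(conn$matrix) == 0))

  two <- streamline_set(list(straight_streamline(a, b),
                             straight_streamline(a, b)))
  conn2 <- build_connectivity_matrix(mesh, two, snap_radius = 0.4)
  expect_equal(conn2$matrix[1, 25], 2)

  # endpoint farther than snap_radius from every vertex: dropped
  far <- streamline_set(list(straight_streamline(c(90, 90, 90), b)))
  conn3 <- build_connectivity_matrix(mesh, far, snap_radius = 0.4)
  expect_equal(conn3$n_connections, 0)
  expect_equal(conn3$n_dropped, 1)
  expect_error(build_connectivity_matrix(mesh, one, snap_radius = 0), "> 0")
})

test_that("connectivity matrix is symmetric and non-negative on random fixtures", {
  tb <- generate_toy_brain(n_vertices = 42, n_streamlines = 30, radius = 20,
                           seed = 11)
  conn <- build_connectivity_matrix(tb$mesh, tb$streamlines, snap_radius = 2)
  m <- conn$matrix
  expect_equal(as.matrix(m), t(as.matrix(m)))
  expect_true(all(m >= 0))
  expect_true(all(Matrix::diag(m) == 0))
  expect_equal(sum(Matrix::triu(m, 1)), conn$n_connections)
})

test_that("geodesic neighborhoods agree with brute-force Dijkstra", {
  mesh <- grid_mesh(5, 5)  # 25 vertices, 1 mm spacing
  seed_v <- 13             # center vertex
  # radius below the shortest incident edge: just the seed
  expect_equal(geodesic_neighborhood(mesh, seed_v, radius = 0.5), seed_v)
  # radius >= mesh diameter: everything
  expect_equal(geodesic_neighborhood(mesh, seed_v, radius = 100),
               seq_len(25))
  # 2.05 mm on the unit grid: two axis steps or diagonal paths <= 2.05
  d <- dijkstra_brute(mesh, seed_v)
  expect_equal(sort(geodesic_neighborhood(mesh, seed_v, radius = 2.05)),
               sort(which(d <= 2.05)))
  # full agreement with the independent implementation on several seeds/radii
  for (v in c(1, 7, 25)) {
    db <- dijkstra_brute(mesh, v)
    for (r in c(1.2, 2.5, 3.7)) {
      expect_equal(sort(geodesic_neighborhood(mesh, v, radius = r)),
                   sort(which(db <= r)))
    }
  }
  expect_error(geodesic_neighborhood(mesh, 0, 1), "invalid")
})

test_that("connectivity density matches direct evaluation and is scale-invariant", {
  tb <- generate_toy_brain(n_vertices = 162, n_streamlines = 0, radius = 50,
                           seed = 1)
  mesh <- tb$mesh
  # single streamline between two far-apart vertices a, b
  a <- 1
  d_from_a <- igraph::distances(mesh$graph, v = a)[1, ]
  b <- which.max(d_from_a)
  sl <- streamline_set(list(straight_streamline(mesh$vertices[a, ],
                                                mesh$vertices[b, ],
                                                fa = 0.7)))
  conn <- build_connectivity_matrix(mesh, sl, snap_radius = 1)
  vm <- compute_vertex_metrics(mesh, conn, radius = 5)
  nb_a <- geodesic_neighborhood(mesh, a, 5)
  area_a <- sum(mesh$vertex_areas[nb_a])
  expect_equal(vm$cd[a], 1 / (area_a * 1), tolerance = 1e-12)
  expect_equal(vm$mean_fa[a], 0.7)
  # vertices whose neighborhood contains neither endpoint have CD 0
  far_v <- which(d_from_a > 5 & igraph::distances(mesh$graph, v = b)[1, ] > 5)
  expect_true(all(vm$cd[far_v] == 0))
  expect_true(all(vm$no_streamline[far_v]))

  # duplicating every streamline leaves CD unchanged (numerator and
  # denominator both double)
  tb2 <- generate_toy_brain(n_vertices = 162, n_streamlines = 25, radius = 50,
                            seed = 12)
  conn1 <- build_connectivity_matrix(mesh, tb2$streamlines, snap_radius = 1)
  dup <- streamline_set(c(unclass(tb2$streamlines), unclass(tb2$streamlines)))
  conn2 <- build_connectivity_matrix(mesh, dup, snap_radius = 1)
  cd1 <- compute_vertex_metrics(mesh, conn1, radius = 5)$cd
  cd2 <- compute_vertex_metrics(mesh, conn2, radius = 5)$cd
  expect_equal(cd2, cd1, tolerance = 1e-12)
})

test_that("geodesic Gaussian smoothing preserves constants and localizes spikes", {
  mesh <- grid_mesh(7, 7)
  n <- nrow(mesh$vertices)
  expect_equal(smooth_vertex_map(mesh, rep(3.5, n), fwhm = 5), rep(3.5, n))

  spike <- numeric(n); center <- 25  # middle of the 7x7 grid
  spike[center] <- 1
  sm <- smooth_vertex_map(mesh, spike, fwhm = 3)
  expect_equal(which.max(sm), center)
  expect_true(all(sm >= 0))
  # decreasing with geodesic distance ring by ring
  d <- igraph::distances(mesh$graph, v = center)[1, ]
  expect_true(sm[d == 1][1] < sm[center])
  expect_true(max(sm[d >= 3]) < min(sm[d <= 1]))

  # convex combination: output within [min, max] of input
  set.seed(3)
  vals <- rnorm(n)
  out <- smooth_vertex_map(mesh, vals, fwhm = 4)
  expect_true(all(out >= min(vals) - 1e-12 & out <= max(vals) + 1e-12))

  # fwhm far below the shortest edge: identity
  expect_equal(smooth_vertex_map(mesh, vals, fwhm = 0.1), vals)
  expect_error(smooth_vertex_map(mesh, vals[-1], fwhm = 5), "per vertex")
})

test_that("parcel aggregation is the area-weighted vertex mean", {
  mesh <- grid_mesh(4, 3)
  n <- nrow(mesh$vertices)
  parc <- rep(c(1L, 2L), each = n / 2)
  expect_equal(as.numeric(aggregate_to_parcels(mesh, rep(7, n), parc)),
               c(7, 7))
  vals <- ifelse(parc == 1, 0, 2)
  expect_equal(as.numeric(aggregate_to_parcels(mesh, vals, parc)), c(0, 2))
  # mixed parcel against a brute-force weighted sum
  set.seed(5)
  vals <- rnorm(n)
  parc2 <- rep_len(c(1L, 2L, 3L), n)
  got <- aggregate_to_parcels(mesh, vals, parc2)
  for (p in 1:3) {
    idx <- which(parc2 == p)
    expect_equal(as.numeric(got[as.character(p)]),
                 sum(vals[idx] * mesh$vertex_areas[idx]) /
                   sum(mesh$vertex_areas[idx]))
  }
  expect_error(aggregate_to_parcels(mesh, vals, c(parc2[-1], NA)),
               "unlabeled")
})

test_that("cortical_mesh rejects invalid triangulations", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(cortical_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(cortical_mesh(rbind(v, c(2, 0, 0)),
                             rbind(c(1, 2, 3), c(1, 2, 4), c(2, 4, 2))),
               "degenerate")
})
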