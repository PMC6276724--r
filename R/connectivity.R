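#' Filter streamlines by turning angle
#'
#' Computes, for each polyline, the turning angle between every pair of
#' consecutive segments (0 degrees = straight continuation) and retains
#' streamlines whose maximum turning angle does not exceed `max_angle`.
#' The literal rule discards streamlines whose minimum turning angle is
#' *below* the threshold instead; it is provided for completeness but
#' discards straight streamlines, so the retention rule is the default.
#'
#' @param streamlines a [streamline_set()].
#' @param max_angle threshold in degrees, in (0, 180).
#' @param literal if `TRUE`, apply the discard-if-below rule verbatim.
#' @return filtered `streamline_set`, order preserved.
#' @export
filter_streamlines <- function(streamlines, max_angle = 60, literal = FALSE) {
  if (max_angle <= 0 || max_angle >= 180) stop("`max_angle` must be in (0, 180)")
  keep <- vapply(streamlines, function(p) {
    ang <- turning_angles(p$points)
    if (length(ang) == 0) return(TRUE)   # 2-point polyline: no turns
    if (literal) all(ang >= max_angle) else max(ang) <= max_angle
  }, logical(1))
  structure(unclass(streamlines)[keep], class = "streamline_set")
}

#' Turning angles of a polyline
#' @param points k x 3 coordinate matrix.
#' @return numeric vector of k - 2 interior angles in degrees (0 = straight).
#' @export
turning_angles <- function(points) {
  k <- nrow(points)
  if (k < 3) return(numeric(0))
  seg <- points[-1, , drop = FALSE] - points[-k, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  u <- seg / pmax(len, .Machine$double.eps)
  cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Mean fractional anisotropy along one streamline
#' @param polyline list with `points` and `fa` as in [streamline_set()].
#' @return arithmetic mean of the FA samples, in \[0, 1\].
#' @export
streamline_mean_fa <- function(polyline) {
  if (is.null(polyline$fa) || length(polyline$fa) < 2) {
    stop("polyline must carry >= 2 FA samples")
  }
  mean(polyline$fa)
}

#' Build the vertex connectivity matrix
#'
#' Maps each streamline endpoint to its nearest mesh vertex within
#' `snap_radius`; streamlines with an unmapped endpoint, or whose endpoints
#' snap to the same vertex, are dropped (and counted). The retained
#' streamlines define a symmetric, zero-diagonal sparse count matrix over
#' vertices.
#'
#' @param mesh a [cortical_mesh()].
#' @param streamlines a (typically already filtered) [streamline_set()].
#' @param snap_radius maximum endpoint-to-vertex distance in mm (> 0).
#' @return A `connectivity` object: list with `matrix` (sparse symmetric
#'   counts), `endpoints` (data.frame of per-retained-streamline vertex
#'   indices `vertex_a`, `vertex_b` and `mean_fa`), `n_connections`,
#'   `n_dropped` and `n_vertices`.
#' @export
build_connectivity_matrix <- function(mesh, streamlines, snap_radius = 2) {
  if (snap_radius <= 0) stop("`snap_radius` must be > 0")
  n <- nrow(mesh$vertices)
  snap <- function(pt) {
    d2 <- rowSums(sweep(mesh$vertices, 2, pt)^2)
    i <- which.min(d2)
    if (sqrt(d2[i]) > snap_radius) NA_integer_ else i
  }
  va <- vb <- integer(0)
  fa <- numeric(0)
  dropped <- 0L
  for (p in streamlines) {
    a <- snap(p$points[1, ])
    b <- snap(p$points[nrow(p$points), ])
    if (is.na(a) || is.na(b) || a == b) {
      dropped <- dropped + 1L
      next
    }
    va <- c(va, a); vb <- c(vb, b)
    fa <- c(fa, streamline_mean_fa(p))
  }
  mat <- Matrix::sparseMatrix(i = c(va, vb), j = c(vb, va),
                              x = rep(1, 2 * length(va)),
                              dims = c(n, n))
  structure(list(matrix = mat,
                 endpoints = data.frame(vertex_a = va, vertex_b = vb,
                                        mean_fa = fa),
                 n_connections = length(va), n_dropped = dropped,
                 n_vertices = n),
            class = "connectivity")
}

#' Geodesic neighborhood of a vertex
#'
#' Vertices whose shortest-path distance along mesh edges (Euclidean edge
#' weights, Dijkstra) from the seed is at most `radius`; always contains the
#' seed.
#'
#' @param mesh a [cortical_mesh()].
#' @param vertex seed vertex index.
#' @param radius geodesic radius in mm (> 0; default 5).
#' @return integer vector of vertex indices.
#' @export
geodesic_neighborhood <- function(mesh, vertex, radius = 5) {
  n <- nrow(mesh$vertices)
  if (radius <= 0) stop("`radius` must be > 0")
  if (vertex < 1 || vertex > n) stop("invalid vertex index")
  d <- igraph::distances(mesh$graph, v = vertex)[1, ]
  which(d <= radius)
}

# All-source geodesic distance matrix (dense; fixtures are small).
geodesic_distances <- function(mesh) {
  igraph::distances(mesh$graph)
}

#' Vertex-wise connectivity density and mean FA
#'
#' For each vertex v, the connectivity density is the number of retained
#' streamlines linking the 5 mm geodesic neighborhood of v to the rest of
#' the brain (exactly one endpoint inside the neighborhood), divided by the
#' neighborhood area (sum of member vertex areas, mm^2) and by the total
#' connection count. The per-vertex mean FA averages the per-streamline mean
#' FA over streamlines with at least one endpoint in the neighborhood.
#'
#' @param mesh a [cortical_mesh()].
#' @param conn a `connectivity` object from [build_connectivity_matrix()].
#' @param radius geodesic neighborhood radius in mm.
#' @param denominator `"streamlines"` (total retained streamline count,
#'   default) or `"pairs"` (number of distinct connected vertex pairs).
#' @return A `vertex_metrics` list with `cd`, `mean_fa` (both length
#'   n-vertices), `no_streamline` (logical flag per vertex: neighborhood
#'   touched by no streamline) and `neighborhood_area`.
#' @export
compute_vertex_metrics <- function(mesh, conn, radius = 5,
                                   denominator = c("streamlines", "pairs")) {
  denominator <- match.arg(denominator)
  n <- nrow(mesh$vertices)
  D <- geodesic_distances(mesh)
  inside <- D <= radius                       # n x n: inside[v, u]
  nb_area <- as.numeric(inside %*% mesh$vertex_areas)

  total <- switch(denominator,
                  streamlines = conn$n_connections,
                  pairs = sum(Matrix::triu(conn$matrix, 1) > 0))
  cd <- numeric(n)
  mean_fa <- numeric(n)
  none <- rep(TRUE, n)
  if (conn$n_connections > 0) {
    A <- inside[, conn$endpoints$vertex_a, drop = FALSE]  # n x S
    B <- inside[, conn$endpoints$vertex_b, drop = FALSE]
    crossing <- A != B
    incident <- A | B
    cd <- rowSums(crossing) / nb_area / total
    ninc <- rowSums(incident)
    none <- ninc == 0
    mean_fa[!none] <- as.numeric(incident %*% conn$endpoints$mean_fa)[!none] /
      ninc[!none]
  } else {
    warning("no connections: connectivity density is identically zero")
  }
  structure(list(cd = cd, mean_fa = mean_fa, no_streamline = none,
                 neighborhood_area = nb_area),
            class = "vertex_metrics")
}

#' Smooth a vertex map with a geodesic Gaussian kernel
#'
#' Normalized Gaussian smoothing with sigma = fwhm / (2 sqrt(2 ln 2)) and
#' geodesic distances, truncated at 3 sigma. The output is a convex
#' combination of the input values, so constants are preserved.
#'
#' @param mesh a [cortical_mesh()].
#' @param values numeric vector, one value per vertex.
#' @param fwhm kernel full width at half maximum in mm (> 0; default 5).
#' @return smoothed numeric vector.
#' @export
smooth_vertex_map <- function(mesh, values, fwhm = 5) {
  n <- nrow(mesh$vertices)
  if (length(values) != n) stop("`values` must have one entry per vertex")
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  D <- geodesic_distances(mesh)
  W <- exp(-D^2 / (2 * sigma^2))
  W[D > 3 * sigma] <- 0
  as.numeric(W %*% values) / rowSums(W)
}

#' Aggregate a vertex map to parcels
#'
#' Area-weighted mean of the vertex values over each parcel.
#'
#' @param mesh a [cortical_mesh()].
#' @param values numeric vector, one value per vertex.
#' @param parcellation integer vector of parcel ids, one per vertex.
#' @return named numeric vector of per-parcel values.
#' @export
aggregate_to_parcels <- function(mesh, values, parcellation) {
  n <- nrow(mesh$vertices)
  if (length(values) != n) stop("`values` must have one entry per vertex")
  if (length(parcellation) != n || anyNA(parcellation)) {
    bad <- if (length(parcellation) != n) "(length mismatch)" else
      paste(which(is.na(parcellation)), collapse = ", ")
    stop("unlabeled vertices: ", bad)
  }
  w <- mesh$vertex_areas
  num <- tapply(values * w, parcellation, sum)
  den <- tapply(w, parcellation, sum)
  out <- num / den
  out[order(as.numeric(names(out)))]
}

#' Per-subject connectivity pipeline
#'
#' Convenience wrapper: filter by turning angle, build the connectivity
#' matrix, compute vertex metrics, optionally smooth, and aggregate to
#' parcels.
#'
#' @inheritParams compute_vertex_metrics
#' @inheritParams filter_streamlines
#' @inheritParams build_connectivity_matrix
#' @param parcellation parcel id per vertex (optional).
#' @param fwhm smoothing FWHM in mm; `NULL` disables smoothing.
#' @return list with `metrics`, `cd_smoothed` and (if a parcellation is
#'   given) `parcel_cd`.
#' @export
connectivity_pipeline <- function(mesh, streamlines, parcellation = NULL,
                                  max_angle = 60, snap_radius = 2,
                                  radius = 5, fwhm = 5, literal = FALSE) {
  kept <- filter_streamlines(streamlines, max_angle, literal = literal)
  conn <- build_connectivity_matrix(mesh, kept, snap_radius)
  metrics <- compute_vertex_metrics(mesh, conn, radius)
  cd_s <- if (is.null(fwhm)) metrics$cd else
    smooth_vertex_map(mesh, metrics$cd, fwhm)
  out <- list(connectivity = conn, metrics = metrics, cd_smoothed = cd_s)
  if (!is.null(parcellation)) {
    out$parcel_cd <- aggregate_to_parcels(mesh, cd_s, parcellation)
  }
  out
}
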