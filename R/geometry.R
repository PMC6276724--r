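#' Construct a triangulated cortical mesh
#'
#' Validates the triangulation and precomputes per-triangle areas, per-vertex
#' neighborhood areas (one third of the summed area of incident triangles)
#' and the edge graph used for geodesic distances.
#'
#' @param vertices n x 3 numeric matrix of coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `cortical_mesh` list with elements `vertices`, `faces`,
#'   `triangle_areas`, `vertex_areas`, `total_area` and `graph` (an igraph
#'   object whose edges are mesh edges weighted by Euclidean length).
#' @export
cortical_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3) stop("`faces` must be an m x 3 index matrix")
  n <- nrow(vertices)
  if (any(faces < 1) || any(faces > n) || any(faces != round(faces))) {
    stop("face indices out of range")
  }
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  if (any(tri_area <= 0)) stop("degenerate (zero-area) triangles present")

  vertex_areas <- numeric(n)
  for (k in 1:3) {
    s <- tapply(tri_area, faces[, k], sum)
    idx <- as.integer(names(s))
    vertex_areas[idx] <- vertex_areas[idx] + s / 3
  }

  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  elen <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                        vertices[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- elen

  structure(list(vertices = vertices, faces = faces,
                 triangle_areas = tri_area, vertex_areas = vertex_areas,
                 total_area = sum(tri_area), graph = g),
            class = "cortical_mesh")
}

#' Construct a streamline set
#'
#' A streamline set is a list of polylines; each polyline carries ordered 3-D
#' points (mm) and one fractional-anisotropy (FA) sample in \[0, 1\] per point.
#'
#' @param polylines list of lists with elements `points` (k x 3 matrix,
#'   k >= 2) and `fa` (numeric length k).
#' @return A `streamline_set`.
#' @export
streamline_set <- function(polylines) {
  for (i in seq_along(polylines)) {
    p <- polylines[[i]]
    if (is.null(p$points) || nrow(p$points) < 2) {
      stop("polyline ", i, " must have >= 2 points")
    }
    if (is.null(p$fa) || length(p$fa) != nrow(p$points)) {
      stop("polyline ", i, ": one FA sample per point required")
    }
    if (any(p$fa < 0 | p$fa > 1)) stop("polyline ", i, ": FA outside [0, 1]")
  }
  structure(polylines, class = "streamline_set")
}

# Unit icosahedron vertices/faces.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# One Loop-style subdivision step on the unit sphere.
subdivide_sphere <- function(vertices, faces) {
  key <- function(i, j) paste(min(i, j), max(i, j))
  midpoint <- new.env()
  verts <- vertices
  get_mid <- function(i, j) {
    k <- key(i, j)
    if (!is.null(midpoint[[k]])) return(midpoint[[k]])
    m <- (verts[i, ] + verts[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    midpoint[[k]] <- nrow(verts)
    nrow(verts)
  }
  newf <- matrix(0L, nrow(faces) * 4, 3)
  r <- 0L
  for (t in seq_len(nrow(faces))) {
    a <- faces[t, 1]; b <- faces[t, 2]; c <- faces[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    newf[r + 1L, ] <- c(a, ab, ca)
    newf[r + 2L, ] <- c(b, bc, ab)
    newf[r + 3L, ] <- c(c, ca, bc)
    newf[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = verts, faces = newf)
}

#' Generate toy brain geometry
#'
#' Produces a tessellated sphere (subdivided icosahedron, chosen as the
#' smallest subdivision with at least `n_vertices` vertices), a set of
#' streamlines whose endpoints coincide with mesh vertices and which carry
#' per-point FA samples, and an angular-sector parcellation of the vertices.
#' Streamlines are straight polylines between two distinct random vertices,
#' sampled at `points_per_streamline` evenly spaced points.
#'
#' @param n_vertices minimum vertex count (>= 4).
#' @param n_streamlines number of streamlines (>= 0).
#' @param radius sphere radius in mm.
#' @param n_parcels number of parcels (azimuthal sectors).
#' @param points_per_streamline polyline sampling density (>= 2).
#' @param seed integer seed.
#' @return list with elements `mesh` (a [cortical_mesh()]), `streamlines`
#'   (a [streamline_set()]) and `parcellation` (integer vector, one parcel id
#'   per vertex).
#' @export
generate_toy_brain <- function(n_vertices = 162, n_streamlines = 50,
                               radius = 50, n_parcels = 8,
                               points_per_streamline = 5, seed = 1) {
  if (n_vertices < 4) stop("`n_vertices` must be >= 4 (tetrahedron minimum)")
  if (n_streamlines < 0) stop("`n_streamlines` must be >= 0")
  if (points_per_streamline < 2) stop("`points_per_streamline` must be >= 2")
  ico <- icosahedron()
  while (nrow(ico$vertices) < n_vertices) {
    ico <- subdivide_sphere(ico$vertices, ico$faces)
  }
  mesh <- cortical_mesh(ico$vertices * radius, ico$faces)
  n <- nrow(mesh$vertices)

  az <- atan2(mesh$vertices[, 2], mesh$vertices[, 1])  # (-pi, pi]
  parcellation <- as.integer(cut(az, breaks = seq(-pi, pi, length.out = n_parcels + 1),
                                 include.lowest = TRUE))

  streamlines <- withr_seed(seed, {
    out <- vector("list", n_streamlines)
    for (s in seq_len(n_streamlines)) {
      ends <- sample.int(n, 2, replace = FALSE)
      tt <- seq(0, 1, length.out = points_per_streamline)
      pts <- outer(1 - tt, mesh$vertices[ends[1], ]) +
             outer(tt, mesh$vertices[ends[2], ])
      out[[s]] <- list(points = pts,
                       fa = stats::runif(points_per_streamline, 0.2, 0.8))
    }
    out
  })
  list(mesh = mesh, streamlines = streamline_set(streamlines),
       parcellation = parcellation)
}

#' @rdname mesh_io
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Mesh, streamline and parcellation IO
#'
#' Meshes are stored as Wavefront OBJ (`v`/`f` records); streamlines as a
#' delimited text format with columns `streamline_id`, `point_index`, `x`,
#' `y`, `z`, `fa`; parcellations as TSV with columns `vertex_id`,
#' `parcel_id`.
#'
#' @param mesh,streamlines,parcellation objects to write.
#' @param path file path.
#' @name mesh_io
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  vs <- lines[startsWith(lines, "v ")]
  fs <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  cortical_mesh(v, f)
}

#' @rdname mesh_io
#' @export
write_streamlines_tsv <- function(streamlines, path) {
  rows <- lapply(seq_along(streamlines), function(i) {
    p <- streamlines[[i]]
    data.frame(streamline_id = i, point_index = seq_len(nrow(p$points)),
               x = p$points[, 1], y = p$points[, 2], z = p$points[, 3],
               fa = p$fa)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(streamline_id = integer(), point_index = integer(),
                     x = numeric(), y = numeric(), z = numeric(),
                     fa = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_streamlines_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(df) == 0) return(streamline_set(list()))
  ids <- unique(df$streamline_id)
  streamline_set(lapply(ids, function(i) {
    d <- df[df$streamline_id == i, , drop = FALSE]
    d <- d[order(d$point_index), , drop = FALSE]
    list(points = as.matrix(d[, c("x", "y", "z")]), fa = d$fa)
  }))
}

#' @rdname mesh_io
#' @export
write_parcellation_tsv <- function(parcellation, path) {
  utils::write.table(
    data.frame(vertex_id = seq_along(parcellation), parcel_id = parcellation),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_parcellation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- integer(max(df$vertex_id))
  out[df$vertex_id] <- df$parcel_id
  out
}
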