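#' Triangulated surface meshes
#'
#' A `surface_mesh` holds vertex coordinates (mm) and triangles of a
#' 2-manifold surface, together with derived geometry (deduplicated
#' undirected edge list, per-triangle areas, per-vertex neighbor sets) used
#' throughout the covariance analysis and the random-field correction.
#' Vertex indices are 1-based inside R; every file interface (OBJ, GIFTI,
#' TSV) uses 0-based indices.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param validate reject invalid input (out-of-range indices, degenerate
#'   zero-area triangles, non-manifold edges shared by more than two
#'   triangles)? Non-manifold meshes are rejected, never repaired.
#' @return An object of class `surface_mesh`: list with `vertices`,
#'   `triangles`, `edges` (2-column matrix, each undirected edge once),
#'   `triangle_areas` (mm^2), and `neighbors` (list of integer vectors).
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns (x, y, z)")
  storage.mode(vertices) <- "double"
  nv <- nrow(vertices)
  if (validate) {
    if (any(triangles < 1L) || any(triangles > nv))
      stop("triangle indices out of range [1, ", nv, "]")
    if (any(triangles[, 1] == triangles[, 2] |
            triangles[, 2] == triangles[, 3] |
            triangles[, 1] == triangles[, 3]))
      stop("triangles with repeated vertices are degenerate")
  }
  areas <- triangle_areas(vertices, triangles)
  if (validate && any(areas <= .Machine$double.eps)) {
    bad <- which(areas <= .Machine$double.eps)[1L]
    stop("degenerate (zero-area) triangle at row ", bad)
  }
  edges <- undirected_edges(triangles)
  if (validate) {
    cnt <- edge_triangle_counts(triangles, edges)
    if (any(cnt > 2L))
      stop("non-manifold mesh: an edge is shared by more than 2 triangles")
  }
  nb <- vertex_neighbors(edges, nv)
  structure(list(vertices = vertices, triangles = triangles,
                 edges = edges, triangle_areas = areas, neighbors = nb),
            class = "surface_mesh")
}

# Unique undirected edges of a triangle soup, as a 2-column matrix with
# edge[,1] < edge[,2], sorted lexicographically (stable across platforms).
undirected_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# How many triangles contain each undirected edge (manifoldness check).
edge_triangle_counts <- function(triangles, edges) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  as.integer(tab[paste(edges[, 1], edges[, 2])])
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

vertex_neighbors <- function(edges, nv) {
  nb <- vector("list", nv)
  idx <- c(edges[, 1], edges[, 2])
  val <- c(edges[, 2], edges[, 1])
  sp <- split(val, idx)
  nb[as.integer(names(sp))] <- lapply(sp, function(x) sort(unique(x)))
  nb[vapply(nb, is.null, logical(1))] <- list(integer(0))
  nb
}

#' @export
print.surface_mesh <- function(x, ...) {
  m <- mesh_metrics(x)
  cat("surface_mesh: ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ", nrow(x$edges), " edges\n", sep = "")
  cat("  total area ", format(m$total_area, digits = 6), " mm^2,",
      " mean edge ", format(mean(m$edge_lengths), digits = 4), " mm,",
      " Euler characteristic ", euler_characteristic(x), "\n", sep = "")
  invisible(x)
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for closed sphere-topology surfaces; used both for mesh
#' validation and as the 0-dimensional resel count in random-field
#' inference.
#' @param mesh a [surface_mesh()].
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$triangles)
}

#' Build a triangulated sphere by recursive icosahedron subdivision
#'
#' Each subdivision level splits every triangle into 4 by edge midpoints,
#' projecting new vertices to the sphere. The level-6 mesh has 40962
#' vertices and 81920 triangles, the resolution at which one cortical
#' hemisphere is conventionally represented, so it serves as a synthetic
#' stand-in for a hemispheric template. V = 10 * 4^s + 2, F = 20 * 4^s.
#'
#' @param subdivisions non-negative integer number of subdivision levels
#'   (at most 8; the vertex count grows 4-fold per level).
#' @param radius sphere radius in mm (default 70, a hemisphere-like scale).
#' @return a [surface_mesh()], closed, Euler characteristic 2.
#' @examples
#' build_icosphere(0)        # regular icosahedron: 12 vertices, 20 triangles
#' build_icosphere(2, 70)
#' @export
build_icosphere <- function(subdivisions, radius = 70) {
  stopifnot_scalar(subdivisions, "subdivisions", integer = TRUE)
  if (subdivisions < 0) stop("'subdivisions' must be non-negative")
  if (subdivisions > 8) stop("'subdivisions' > 8 would exhaust memory")
  stopifnot_scalar(radius, "radius")
  if (radius <= 0) stop("'radius' must be positive")

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))

  for (s in seq_len(subdivisions)) {
    edges <- undirected_edges(f)
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mid_index <- stats::setNames(nrow(v) + seq_len(nrow(edges)),
                                 key(edges[, 1], edges[, 2]))
    mids <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_index[key(f[, 1], f[, 2])]
    m23 <- mid_index[key(f[, 2], f[, 3])]
    m31 <- mid_index[key(f[, 3], f[, 1])]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
    dimnames(f) <- NULL
  }
  surface_mesh(v * radius, f)
}

#' Geometric quantities of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return list with `edge_lengths` (mm, one per undirected edge, in the
#'   order of `mesh$edges`), `total_area` (mm^2), and `vertex_neighbors`.
#' @export
mesh_metrics <- function(mesh) {
  d <- mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
       mesh$vertices[mesh$edges[, 2], , drop = FALSE]
  list(edge_lengths = sqrt(rowSums(d^2)),
       total_area = sum(mesh$triangle_areas),
       vertex_neighbors = mesh$neighbors)
}

#' Seed regions on a mesh
#'
#' A `seed_region` is a named, non-empty set of vertex indices whose mean
#' adjusted thickness drives the covariance models (primary visual,
#' auditory and olfactory cortex in the motivating analysis, but any label
#' works).
#'
#' @param name label string, e.g. `"CAL_L"`.
#' @param vertex_indices integer vector of 1-based vertex indices, no
#'   duplicates.
#' @param mesh optional [surface_mesh()] to validate indices against.
#' @return object of class `seed_region`.
#' @export
seed_region <- function(name, vertex_indices, mesh = NULL) {
  vertex_indices <- as.integer(vertex_indices)
  if (length(vertex_indices) == 0L) stop("seed region '", name, "' is empty")
  if (anyDuplicated(vertex_indices))
    stop("duplicate vertex indices in seed region '", name, "'")
  if (any(vertex_indices < 1L)) stop("vertex indices must be >= 1")
  if (!is.null(mesh) && any(vertex_indices > nrow(mesh$vertices)))
    stop("seed region '", name, "' has indices beyond the mesh")
  structure(list(name = as.character(name), vertex_indices = vertex_indices),
            class = "seed_region")
}

#' @export
print.seed_region <- function(x, ...) {
  cat("seed_region '", x$name, "': ", length(x$vertex_indices),
      " vertices\n", sep = "")
  invisible(x)
}

#' Grow a seed patch by geodesic distance from a center vertex
#'
#' Geodesic distance is the edge-length-weighted graph shortest path on the
#' mesh (not an exact polyhedral geodesic), which is accurate enough for
#' compact synthetic patches. The center is always included, so a radius
#' smaller than every incident edge yields a singleton region.
#'
#' @param mesh a [surface_mesh()].
#' @param center 1-based vertex index of the patch center.
#' @param geodesic_radius radius in mm, > 0.
#' @param name label for the resulting region.
#' @return a [seed_region()] of all vertices within `geodesic_radius` of
#'   `center`.
#' @export
seed_patch <- function(mesh, center, geodesic_radius, name = "SEED") {
  stopifnot_scalar(center, "center", integer = TRUE)
  if (center < 1 || center > nrow(mesh$vertices))
    stop("'center' is not a valid vertex index")
  stopifnot_scalar(geodesic_radius, "geodesic_radius")
  if (geodesic_radius <= 0) stop("'geodesic_radius' must be > 0")
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = center, weights = igraph::E(g)$weight)[1, ]
  seed_region(name, which(d <= geodesic_radius), mesh)
}

# igraph view of the mesh edge graph, weighted by edge length.
mesh_graph <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- mesh_metrics(mesh)$edge_lengths
  g
}
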