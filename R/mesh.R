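#' Triangulated vessel-wall surface mesh
#'
#' Constructs a validated triangle surface mesh. Coordinates are in
#' millimetres throughout the package; stresses attached to meshes are in
#' pascal, so shear-stress gradients come out natively in Pa/mm.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, three vertex
#'   indices (1-based).
#' @param vertex_normals optional numeric matrix of outward unit normals;
#'   computed from the triangulation when `NULL`.
#' @param apex_vertex optional index of the bifurcation apex (flow divider)
#'   vertex.
#' @param branch_labels optional character vector, one of `"trunk"`,
#'   `"branch1"`, `"branch2"` per vertex.
#' @param drop_degenerate drop triangles with area below
#'   `degenerate_area` instead of failing.
#' @param degenerate_area area threshold (mm^2) below which a triangle is
#'   considered degenerate.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `vertex_normals`, `apex_vertex`,
#'   `branch_labels`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_normals = NULL,
                         apex_vertex = NULL, branch_labels = NULL,
                         drop_degenerate = TRUE, degenerate_area = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < 3L) stop("mesh is empty or too small")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("non-triangular cells: triangles must be m x 3")
  if (nrow(triangles) < 1L) stop("mesh has no triangles")
  nv <- nrow(vertices)
  if (any(is.na(triangles)) || any(triangles < 1L) || any(triangles > nv))
    stop("triangle references an invalid vertex index")
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("triangle with repeated vertex (zero edge length)")

  areas <- triangle_areas(vertices, triangles)
  bad <- areas < degenerate_area
  if (any(bad)) {
    if (!drop_degenerate)
      stop(sum(bad), " degenerate (near-zero-area) triangle(s) in mesh")
    triangles <- triangles[!bad, , drop = FALSE]
    if (nrow(triangles) == 0L) stop("all triangles degenerate")
  }

  if (!is.null(branch_labels)) {
    branch_labels <- as.character(branch_labels)
    if (length(branch_labels) != nv)
      stop("branch_labels must have one entry per vertex")
    ok <- branch_labels %in% c("trunk", "branch1", "branch2")
    if (!all(ok)) stop("branch_labels must be trunk/branch1/branch2")
  }
  if (!is.null(apex_vertex)) {
    apex_vertex <- as.integer(apex_vertex)
    if (length(apex_vertex) != 1L || is.na(apex_vertex) ||
        apex_vertex < 1L || apex_vertex > nv)
      stop("apex_vertex out of range")
  }

  if (is.null(vertex_normals)) {
    vertex_normals <- compute_vertex_normals(vertices, triangles)
  } else {
    vertex_normals <- as.matrix(vertex_normals)
    if (!all(dim(vertex_normals) == c(nv, 3L)))
      stop("vertex_normals must match vertices")
    nn <- sqrt(rowSums(vertex_normals^2))
    if (any(abs(nn - 1) > 1e-6))
      vertex_normals <- vertex_normals / nn
  }

  structure(list(vertices = vertices, triangles = triangles,
                 vertex_normals = vertex_normals,
                 apex_vertex = apex_vertex, branch_labels = branch_labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  cat("  surface area:", format(sum(triangle_areas(x$vertices, x$triangles))),
      "mm^2\n")
  if (!is.null(x$apex_vertex)) cat("  apex vertex:", x$apex_vertex, "\n")
  if (!is.null(x$branch_labels))
    cat("  labels:", paste(names(table(x$branch_labels)),
                           table(x$branch_labels), collapse = ", "), "\n")
  invisible(x)
}

# unsigned triangle areas (mm^2)
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# area-weighted vertex normals from triangle normals
compute_vertex_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  nv <- nrow(vertices)
  vn <- matrix(0, nv, 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], group = triangles[, j], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      vn[idx, k] <- vn[idx, k] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Per-vertex surface areas
#'
#' Each vertex receives one third of the total area of its incident
#' triangles, so the vertex areas sum exactly to the mesh surface area.
#' Used as quadrature weights for area-weighted region averages.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ta <- triangle_areas(mesh$vertices, mesh$triangles) / 3
  va <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    acc <- rowsum(ta, group = mesh$triangles[, j], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    va[idx] <- va[idx] + acc[, 1]
  }
  va
}

# undirected edge list (two columns, i < j) with lengths
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

# one-ring neighbour lists
vertex_neighbours <- function(mesh) {
  e <- mesh_edges(mesh)$edges
  nv <- nrow(mesh$vertices)
  nb <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
  lapply(nb, as.integer)
}

#' Geodesic (edge-graph) distances from a source vertex
#'
#' Shortest-path distances along mesh edges, computed with Dijkstra's
#' algorithm on the edge graph. This is the distance used by the default
#' (geodesic) apex-patch definition; it cannot jump across the gap between
#' the two daughter branches the way a straight-line distance can.
#'
#' @param mesh a [surface_mesh()].
#' @param from source vertex index.
#' @return numeric vector of distances (mm) from `from` to every vertex.
#' @export
geodesic_distances <- function(mesh, from) {
  stopifnot(inherits(mesh, "surface_mesh"))
  from <- as.integer(from)
  nv <- nrow(mesh$vertices)
  if (from < 1L || from > nv) stop("source vertex out of range")
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  as.numeric(igraph::distances(g, v = from, weights = ed$lengths))
}
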