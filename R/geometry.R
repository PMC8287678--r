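#' Extract the apex-centred analysis patch
#'
#' All haemodynamic region metrics are taken within a circular patch of
#' configurable radius (default 5 mm) centred on the bifurcation apex.
#' Membership is decided by distance from the apex: either edge-graph
#' shortest-path ("geodesic", the default, which cannot leak across the
#' gap between the daughter branches) or straight-line ("euclidean").
#'
#' @param mesh a [surface_mesh()].
#' @param apex apex vertex index; defaults to `mesh$apex_vertex`.
#' @param radius patch radius in mm (default 5).
#' @param metric `"geodesic"` or `"euclidean"`.
#' @return An object of class `apex_patch`: list with `vertex_indices`,
#'   `radius`, `center`, `metric` and the per-member `distances`.
#' @export
extract_apex_patch <- function(mesh, apex = mesh$apex_vertex, radius = 5,
                               metric = c("geodesic", "euclidean")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  metric <- match.arg(metric)
  if (is.null(apex)) stop("no apex vertex given and mesh has none")
  apex <- as.integer(apex)
  nv <- nrow(mesh$vertices)
  if (apex < 1L || apex > nv) stop("apex index out of range")
  if (!is.finite(radius) || radius < 0) stop("radius must be >= 0")
  d <- if (metric == "geodesic") {
    geodesic_distances(mesh, apex)
  } else {
    sqrt(rowSums((mesh$vertices -
                  matrix(mesh$vertices[apex, ], nv, 3, byrow = TRUE))^2))
  }
  inside <- which(d <= radius + 1e-12)
  structure(list(vertex_indices = inside, radius = radius, center = apex,
                 metric = metric, distances = d[inside]),
            class = "apex_patch")
}

#' @export
print.apex_patch <- function(x, ...) {
  cat("apex_patch:", length(x$vertex_indices), "vertices within",
      x$radius, "mm (", x$metric, ") of vertex", x$center, "\n")
  invisible(x)
}

#' Export a patch as plain text plus JSON metadata
#'
#' Writes `<prefix>_vertices.txt` (one vertex index per line) and
#' `<prefix>_patch.json` (radius, metric, apex).
#'
#' @param patch an [extract_apex_patch()] result.
#' @param prefix output path prefix.
#' @export
export_patch <- function(patch, prefix) {
  stopifnot(inherits(patch, "apex_patch"))
  writeLines(as.character(patch$vertex_indices),
             paste0(prefix, "_vertices.txt"))
  jsonlite::write_json(list(radius = patch$radius, metric = patch$metric,
                            apex = patch$center,
                            n_vertices = length(patch$vertex_indices)),
                       paste0(prefix, "_patch.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Tangent-plane gradient of a per-vertex scalar field
#'
#' At each vertex the field differences over the one-ring neighbourhood are
#' fitted by least squares in the local tangent plane (spanned by two
#' orthonormal vectors perpendicular to the vertex normal). The scheme is
#' exact for fields affine in the tangent coordinates of a planar mesh.
#' Vertices with fewer than two usable (non-collinear) neighbours are
#' marked undefined (`NA` rows) and are excluded from downstream averages.
#'
#' @param mesh a [surface_mesh()].
#' @param field numeric per-vertex scalar (field units; gradients come out
#'   in field-units/mm).
#' @param vertices vertex indices at which to evaluate (default: all).
#' @return n x 3 matrix of tangent gradient vectors with `NA` rows where
#'   undefined; the logical attribute `"defined"` flags usable rows.
#' @export
tangent_gradient <- function(mesh, field, vertices = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices)
  if (length(field) != nv) stop("field must have one value per vertex")
  if (is.null(vertices)) vertices <- seq_len(nv)
  nb <- vertex_neighbours(mesh)
  basis <- tangent_basis(mesh$vertex_normals)
  grad <- matrix(NA_real_, nv, 3)
  defined <- logical(nv)
  for (v in vertices) {
    ring <- nb[[v]]
    ring <- ring[is.finite(field[ring])]
    if (!is.finite(field[v]) || length(ring) < 2L) next
    d <- mesh$vertices[ring, , drop = FALSE] -
      matrix(mesh$vertices[v, ], length(ring), 3, byrow = TRUE)
    A <- cbind(d %*% basis$e1[v, ], d %*% basis$e2[v, ])
    b <- field[ring] - field[v]
    sv <- svd(A)
    if (sv$d[2] < 1e-8 * sv$d[1]) next  # collinear ring
    g2 <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
    grad[v, ] <- g2[1] * basis$e1[v, ] + g2[2] * basis$e2[v, ]
    defined[v] <- TRUE
  }
  attr(grad, "defined") <- defined
  grad
}

# orthonormal tangent basis (e1, e2) per vertex from unit normals
tangent_basis <- function(normals) {
  nv <- nrow(normals)
  # pick the global axis least aligned with each normal
  ref <- diag(3)[max.col(-abs(normals)), , drop = FALSE]
  e1 <- ref - normals * rowSums(ref * normals)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(normals[, 2] * e1[, 3] - normals[, 3] * e1[, 2],
              normals[, 3] * e1[, 1] - normals[, 1] * e1[, 3],
              normals[, 1] * e1[, 2] - normals[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}
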