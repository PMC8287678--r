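#' Time-resolved wall-shear field on a surface mesh
#'
#' Bundles a mesh with per-vertex, per-time wall-shear vectors sampled over
#' one cardiac cycle. Times need not be uniformly spaced; all cycle
#' integrals use trapezoidal quadrature on the samples as given.
#'
#' @param mesh a [surface_mesh()].
#' @param times sample times in seconds, strictly increasing, spanning one
#'   cardiac cycle `[0, T]`.
#' @param vectors numeric array `n_vertices x n_times x 3` of wall-shear
#'   vectors (Pa).
#' @param check_tangency warn if vectors deviate from the local tangent
#'   plane by more than `tangency_tol` radians (checked on the strongest
#'   sample per vertex).
#' @param tangency_tol angular tolerance in radians.
#' @return object of class `wall_field`.
#' @export
wall_field <- function(mesh, times, vectors, check_tangency = FALSE,
                       tangency_tol = 0.1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least 2 time samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  period <- diff(range(times))
  if (period <= 0) stop("cycle duration must be positive")
  if (length(times) < 8L)
    warning("fewer than 8 samples over the cycle; integrals will be coarse")
  nv <- nrow(mesh$vertices)
  if (!is.array(vectors) || length(dim(vectors)) != 3L ||
      dim(vectors)[1] != nv || dim(vectors)[2] != length(times) ||
      dim(vectors)[3] != 3L)
    stop("vectors must be an n_vertices x n_times x 3 array")
  if (check_tangency) {
    mag <- sqrt(vectors[, , 1]^2 + vectors[, , 2]^2 + vectors[, , 3]^2)
    k <- max.col(mag, ties.method = "first")
    pick <- cbind(seq_len(nv), k)
    w <- cbind(vectors[, , 1][pick], vectors[, , 2][pick], vectors[, , 3][pick])
    wm <- sqrt(rowSums(w^2))
    use <- wm > 0
    ang <- asin(pmin(1, abs(rowSums(w[use, , drop = FALSE] *
                                    mesh$vertex_normals[use, , drop = FALSE])) /
                       wm[use]))
    if (any(ang > tangency_tol))
      warning(sum(ang > tangency_tol),
              " vertices with wall-shear vectors off the tangent plane")
  }
  structure(list(mesh = mesh, times = times, vectors = vectors,
                 period = period), class = "wall_field")
}

#' @export
print.wall_field <- function(x, ...) {
  cat("wall_field:", dim(x$vectors)[1], "vertices,", length(x$times),
      "time samples over", format(x$period), "s\n")
  invisible(x)
}

# trapezoid quadrature weights for possibly non-uniform times
trapezoid_weights <- function(times) {
  n <- length(times)
  dt <- diff(times)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

#' Time-averaged wall shear stress magnitude (TAWSS)
#'
#' Computes `(1/T) * integral |wss(t)| dt` per vertex by trapezoidal
#' quadrature over the provided samples.
#'
#' @param field a [wall_field()].
#' @return numeric per-vertex TAWSS (Pa).
#' @export
time_averaged_wss <- function(field) {
  stopifnot(inherits(field, "wall_field"))
  w <- trapezoid_weights(field$times)
  mag <- sqrt(field$vectors[, , 1]^2 + field$vectors[, , 2]^2 +
              field$vectors[, , 3]^2)
  as.numeric(mag %*% w) / field$period
}

#' Time-averaged wall shear stress vector
#'
#' Component-wise trapezoidal average `(1/T) * integral wss(t) dt`. Its
#' magnitude is the numerator of the OSI and its direction defines the
#' p-axis of the gradient decomposition.
#'
#' @param field a [wall_field()].
#' @return n x 3 matrix (Pa).
#' @export
time_averaged_wss_vector <- function(field) {
  stopifnot(inherits(field, "wall_field"))
  w <- trapezoid_weights(field$times)
  sapply(1:3, function(k) as.numeric(field$vectors[, , k] %*% w)) /
    field$period
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |integral wss dt| / integral |wss| dt)`, ranging from
#' 0 for unidirectional flow to 0.5 for complete reversal. Vertices whose
#' shear trajectory is identically zero are undefined (`NA`).
#'
#' @param field a [wall_field()].
#' @param tol relative tolerance below which the denominator is treated as
#'   zero.
#' @return numeric per-vertex OSI in `[0, 0.5]` with `NA` where undefined.
#' @export
osi <- function(field, tol = 1e-12) {
  stopifnot(inherits(field, "wall_field"))
  num <- sqrt(rowSums(time_averaged_wss_vector(field)^2))
  den <- time_averaged_wss(field)
  out <- 0.5 * (1 - num / den)
  out[den <= tol * max(den, 0) | den == 0] <- NA_real_
  pmin(pmax(out, 0), 0.5)  # clamp roundoff
}

#' Local (p, q) frame of the time-averaged WSS
#'
#' The p-direction is the time-averaged WSS direction projected into the
#' tangent plane; q is perpendicular to p within the tangent plane
#' (`q = n x p`). Vertices whose mean shear vector is (numerically) zero —
#' e.g. perfect reversal — are flagged undefined.
#'
#' @param field a [wall_field()].
#' @param min_mag magnitude (Pa) below which the mean vector is treated as
#'   zero.
#' @return object of class `wss_frame` with `p_dir`, `q_dir` (n x 3) and
#'   logical `defined`.
#' @export
wss_frame <- function(field, min_mag = 1e-9) {
  stopifnot(inherits(field, "wall_field"))
  m <- time_averaged_wss_vector(field)
  n <- field$mesh$vertex_normals
  # project out the normal component
  p <- m - n * rowSums(m * n)
  mag <- sqrt(rowSums(p^2))
  defined <- mag > min_mag
  p <- p / ifelse(mag > 0, mag, 1)
  q <- cbind(n[, 2] * p[, 3] - n[, 3] * p[, 2],
             n[, 3] * p[, 1] - n[, 1] * p[, 3],
             n[, 1] * p[, 2] - n[, 2] * p[, 1])
  p[!defined, ] <- NA_real_
  q[!defined, ] <- NA_real_
  structure(list(p_dir = p, q_dir = q, defined = defined),
            class = "wss_frame")
}

#' Directional wall shear stress gradient field
#'
#' Decomposes the tangent-plane gradient of TAWSS onto the local (p, q)
#' frame. The magnitude is `sqrt((dtau/dp)^2 + (dtau/dq)^2)` (Pa/mm) and
#' the sign is that of the p-component: positive where the TAWSS gradient
#' points along the WSS direction (flow-acceleration zone), negative where
#' it opposes it (recovery zone).
#'
#' @param tawss per-vertex TAWSS (Pa), e.g. from [time_averaged_wss()].
#' @param frame a [wss_frame()].
#' @param mesh the [surface_mesh()] the fields live on.
#' @return object of class `wssg_field` with per-vertex `d_tau_dp`,
#'   `d_tau_dq`, `magnitude`, `sign` and logical `defined`.
#' @export
wssg_field <- function(tawss, frame, mesh) {
  stopifnot(inherits(frame, "wss_frame"), inherits(mesh, "surface_mesh"))
  if (length(tawss) != nrow(mesh$vertices))
    stop("tawss must have one value per vertex")
  g <- tangent_gradient(mesh, tawss)
  gdef <- attr(g, "defined")
  defined <- gdef & frame$defined
  dp <- rowSums(g * frame$p_dir)
  dq <- rowSums(g * frame$q_dir)
  dp[!defined] <- NA_real_
  dq[!defined] <- NA_real_
  structure(list(d_tau_dp = dp, d_tau_dq = dq,
                 magnitude = sqrt(dp^2 + dq^2),
                 sign = ifelse(dp >= 0, 1, -1),
                 defined = defined),
            class = "wssg_field")
}

#' High-WSS region within a patch
#'
#' Vertices of the patch whose TAWSS is at or above the given percentile
#' (default 98th) of TAWSS over the patch. The percentile uses linear
#' interpolation between order statistics.
#'
#' @param tawss per-vertex TAWSS over the whole mesh.
#' @param patch an [extract_apex_patch()] result.
#' @param percentile percentile in `[0, 100]` (default 98).
#' @param restrict optional vertex subset (e.g. one branch) intersected
#'   with the patch before thresholding.
#' @return integer vertex indices of the high-WSS region.
#' @export
high_wss_region <- function(tawss, patch, percentile = 98, restrict = NULL) {
  stopifnot(inherits(patch, "apex_patch"))
  idx <- patch$vertex_indices
  if (!is.null(restrict)) idx <- intersect(idx, restrict)
  idx <- idx[is.finite(tawss[idx])]
  if (length(idx) == 0L) stop("empty patch (or no defined TAWSS in patch)")
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  thr <- stats::quantile(tawss[idx], probs = percentile / 100, names = FALSE,
                         type = 7)
  idx[tawss[idx] >= thr]
}

#' Region-averaged haemodynamic metrics
#'
#' Area-weighted averages of TAWSS, signed WSSG, absolute WSSG and OSI over
#' a vertex region (typically the high-WSS region of the apex patch), plus
#' the categorical gradient direction `dir_wssg` (positive iff the signed
#' average is > 0). Vertices with undefined gradient frame or OSI are
#' excluded from the respective averages.
#'
#' @param region integer vertex indices.
#' @param tawss per-vertex TAWSS (Pa).
#' @param wssg a [wssg_field()].
#' @param osi_field per-vertex OSI.
#' @param areas per-vertex areas from [vertex_areas()]; required when
#'   `area_weighted`.
#' @param area_weighted use one-third-area vertex weights (default) or
#'   plain vertex means.
#' @return object of class `region_metrics`: list with `wss`,
#'   `wssg_signed`, `abs_wssg`, `osi`, `dir_wssg` (`"positive"` /
#'   `"negative"`), `region_size`, `region_area`.
#' @export
region_metrics <- function(region, tawss, wssg, osi_field, areas = NULL,
                           area_weighted = TRUE) {
  stopifnot(inherits(wssg, "wssg_field"))
  region <- as.integer(region)
  if (length(region) == 0L) stop("empty region")
  if (area_weighted && is.null(areas))
    stop("areas required for area-weighted averages")
  w <- if (area_weighted) areas[region] else rep(1, length(region))
  wavg <- function(x, wt) {
    ok <- is.finite(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * wt[ok]) / sum(wt[ok])
  }
  tw <- tawss[region]
  sg <- (wssg$sign * wssg$magnitude)[region]
  mg <- wssg$magnitude[region]
  os <- osi_field[region]
  if (!any(is.finite(sg))) stop("region has no defined WSSG vertices")
  m <- list(wss = wavg(tw, w),
            wssg_signed = wavg(sg, w),
            abs_wssg = wavg(mg, w),
            osi = wavg(os, w),
            region_size = length(region),
            region_area = if (is.null(areas)) NA_real_ else sum(areas[region]))
  m$dir_wssg <- if (m$wssg_signed > 0) "positive" else "negative"
  structure(m, class = "region_metrics")
}

#' @export
print.region_metrics <- function(x, ...) {
  cat(sprintf("region_metrics (%d vertices, %.3f mm^2)\n",
              x$region_size, x$region_area))
  cat(sprintf("  WSS %.3f Pa | WSSG %+.3f Pa/mm | absWSSG %.3f Pa/mm | OSI %.4f | dirWSSG %s\n",
              x$wss, x$wssg_signed, x$abs_wssg, x$osi, x$dir_wssg))
  invisible(x)
}

#' Select the branch carrying the higher WSS
#'
#' Gradient measurements are taken from the daughter branch whose patch
#' vertices attain the higher maximum TAWSS. Ties break deterministically
#' to `branch1` with a warning.
#'
#' @param mesh labelled [surface_mesh()] (needs `branch_labels`).
#' @param tawss per-vertex TAWSS.
#' @param patch an [extract_apex_patch()] result.
#' @return `"branch1"` or `"branch2"`.
#' @export
select_branch <- function(mesh, tawss, patch) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(patch, "apex_patch"))
  if (is.null(mesh$branch_labels)) stop("mesh has no branch labels")
  idx <- patch$vertex_indices
  mx <- function(lbl) {
    v <- idx[mesh$branch_labels[idx] == lbl & is.finite(tawss[idx])]
    if (length(v) == 0L) -Inf else max(tawss[v])
  }
  m1 <- mx("branch1"); m2 <- mx("branch2")
  if (!is.finite(m1) && !is.finite(m2))
    stop("patch contains no labelled branch vertices")
  if (m1 == m2) {
    warning("branch WSS maxima tie; selecting branch1")
    return("branch1")
  }
  if (m1 > m2) "branch1" else "branch2"
}

#' Per-subject wall metrics from a time-resolved field
#'
#' Composes the whole per-subject post-processing chain: TAWSS, OSI and the
#' directional WSSG field; apex patch extraction; branch selection (when
#' the mesh is labelled); 98th-percentile high-WSS region; and the
#' area-weighted region averages.
#'
#' @param field a [wall_field()] whose mesh has an apex vertex.
#' @param radius patch radius (mm).
#' @param percentile high-WSS percentile.
#' @param metric patch distance metric.
#' @param area_weighted area-weighted region averages.
#' @param restrict_branch restrict the region to the higher-WSS branch when
#'   labels are available.
#' @return a `region_metrics` object; per-vertex fields are attached as the
#'   `"fields"` attribute (list with tawss, osi, wssg, region, patch,
#'   branch).
#' @export
subject_metrics <- function(field, radius = 5, percentile = 98,
                            metric = "geodesic", area_weighted = TRUE,
                            restrict_branch = TRUE) {
  stopifnot(inherits(field, "wall_field"))
  mesh <- field$mesh
  if (is.null(mesh$apex_vertex)) stop("geometry stage: mesh has no apex vertex")
  tawss <- time_averaged_wss(field)
  osiv <- osi(field)
  frame <- wss_frame(field)
  wssg <- wssg_field(tawss, frame, mesh)
  patch <- extract_apex_patch(mesh, radius = radius, metric = metric)
  branch <- NULL
  restrict <- NULL
  if (restrict_branch && !is.null(mesh$branch_labels)) {
    branch <- select_branch(mesh, tawss, patch)
    restrict <- which(mesh$branch_labels == branch)
  }
  region <- high_wss_region(tawss, patch, percentile, restrict = restrict)
  areas <- vertex_areas(mesh)
  rm <- region_metrics(region, tawss, wssg, osiv, areas,
                       area_weighted = area_weighted)
  attr(rm, "fields") <- list(tawss = tawss, osi = osiv, wssg = wssg,
                             region = region, patch = patch, branch = branch)
  rm
}
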