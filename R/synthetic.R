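#' Blood material properties
#'
#' Newtonian blood model used throughout: density 1056 kg/m^3 and constant
#' dynamic viscosity 0.0035 Pa s.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @export
blood_properties <- function(density = 1056, viscosity = 0.0035) {
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (!is.finite(viscosity) || viscosity <= 0) stop("viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

# Bessel J_nu of complex argument by power series (nu = 0 or 1).
# Adequate for the moderate |z| of arterial Womersley numbers.
bessel_j_complex <- function(z, nu = 0) {
  stopifnot(nu %in% c(0, 1))
  half <- z / 2
  term <- if (nu == 0) 1 + 0i else half
  s <- term
  for (k in 1:200) {
    term <- -term * half * half / (k * (k + nu))
    s <- s + term
    if (Mod(term) < 1e-17 * Mod(s) && k > 5) break
  }
  s
}

#' Analytic Womersley wall shear in a rigid tube
#'
#' Closed-form oscillatory pipe-flow oracle used to validate the cycle
#' integrals: for a pressure-gradient amplitude G (Pa/m) the steady term
#' contributes the Poiseuille wall shear G R / 2, and each harmonic n
#' contributes the classical Womersley wall-shear term built from Bessel
#' functions of complex argument, evaluated at Womersley number
#' `alpha_n = R * sqrt(n * omega * rho / mu)`. The superposition is
#' returned at the requested times (signed along the tube axis, Pa).
#'
#' @param radius tube radius in metres.
#' @param props a [blood_properties()].
#' @param pressure_harmonics matrix (or coercible) with columns
#'   `amplitude` (Pa/m) and `phase` (rad); row 1 is the steady term
#'   (harmonic 0, phase ignored), row k+1 is harmonic k.
#' @param period cardiac period (s).
#' @param times evaluation times (s).
#' @return numeric wall-shear time series (Pa) at `times`.
#' @export
womersley_wall_shear <- function(radius, props, pressure_harmonics, period,
                                 times) {
  stopifnot(inherits(props, "blood_properties"))
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (!is.finite(period) || period <= 0) stop("period must be positive")
  h <- as.matrix(pressure_harmonics)
  if (ncol(h) == 1L) h <- cbind(h, 0)
  omega <- 2 * pi / period
  mu <- props$viscosity; rho <- props$density
  tau <- rep(h[1, 1] * radius / 2, length(times))
  if (nrow(h) > 1L) {
    for (n in seq_len(nrow(h) - 1L)) {
      G <- h[n + 1L, 1]; phi <- h[n + 1L, 2]
      if (G == 0) next
      alpha <- radius * sqrt(n * omega * rho / mu)
      lam <- alpha * exp(3i * pi / 4)  # i^(3/2) * alpha
      coefc <- -mu * (G / (1i * rho * n * omega)) * (lam / radius) *
        bessel_j_complex(lam, 1) / bessel_j_complex(lam, 0)
      tau <- tau + Re(coefc * exp(1i * (n * omega * times + phi)))
    }
  }
  tau
}

# ---- parametric bifurcation surface -------------------------------------

#' Synthetic Y-shaped bifurcation surface mesh
#'
#' Builds an idealised trunk-plus-two-branches surface: a cylindrical
#' trunk, a junction collar closed by an explicit flow-divider ridge, and
#' two cylindrical daughter branches. The apex vertex sits at the middle
#' of the divider ridge; every vertex carries a trunk/branch1/branch2
#' label (divider and trunk-collar vertices are labelled `trunk`).
#' Triangle orientation is made globally consistent and outward.
#'
#' @param trunk_radius mm (default 2.5).
#' @param branch_radii length-2 mm (default `c(2.0, 1.8)`).
#' @param bifurcation_angle total angle between the daughter axes, degrees.
#' @param edge_length target edge length, mm.
#' @param trunk_length,branch_length axial lengths, mm.
#' @return a labelled [surface_mesh()] with `apex_vertex` set.
#' @export
make_bifurcation_mesh <- function(trunk_radius = 2.5,
                                  branch_radii = c(2.0, 1.8),
                                  bifurcation_angle = 90,
                                  edge_length = 0.4,
                                  trunk_length = 8,
                                  branch_length = 12) {
  if (trunk_radius <= 0 || any(branch_radii <= 0) || edge_length <= 0 ||
      trunk_length <= 0 || branch_length <= 0)
    stop("geometric parameters must be positive")
  if (bifurcation_angle <= 10 || bifurcation_angle >= 175)
    stop("bifurcation angle geometrically impossible")
  n <- 4L * max(4L, round(pi * trunk_radius / (2 * edge_length)))
  half <- (bifurcation_angle / 2) * pi / 180
  ax <- list(c(sin(half), 0, cos(half)), c(-sin(half), 0, cos(half)))
  h <- 0.7 * trunk_radius  # divider ridge height above trunk outlet plane

  verts <- list(); labels <- character(0); nvert <- 0L
  add <- function(m, lab) {
    verts[[length(verts) + 1L]] <<- m
    labels <<- c(labels, rep(lab, nrow(m)))
    out <- nvert + seq_len(nrow(m))
    nvert <<- nvert + nrow(m)
    out
  }
  tris <- list()
  strip <- function(a, b) {
    k <- length(a); kn <- c(2:k, 1)
    tris[[length(tris) + 1L]] <<- rbind(cbind(a, a[kn], b),
                                        cbind(b, a[kn], b[kn]))
  }

  # trunk rings along +z, outlet plane at z = 0
  phi <- 2 * pi * (0:(n - 1)) / n
  nz <- max(2L, round(trunk_length / edge_length))
  zs <- seq(-trunk_length, 0, length.out = nz + 1L)
  trunk_rings <- lapply(zs, function(z)
    add(cbind(trunk_radius * cos(phi), trunk_radius * sin(phi), z), "trunk"))
  for (i in seq_len(nz)) strip(trunk_rings[[i]], trunk_rings[[i + 1L]])
  Tring <- trunk_rings[[nz + 1L]]

  # divider ridge in the x = 0 plane from (0, r, 0) over (0, 0, h) to (0, -r, 0)
  jd <- seq_len(n / 2L - 1L)
  td <- jd * pi / (n / 2L)
  Dpts <- add(cbind(0, trunk_radius * cos(td), h * sin(td)), "trunk")
  apex <- Dpts[n / 4L]

  Pp <- Tring[n / 4L + 1L]   # (0, +r, 0)
  Pm <- Tring[3L * n / 4L + 1L]
  # base loops: outer half of the trunk outlet ring + divider path
  outer1 <- Tring[c((n / 4L + 1L):1L, n:(3L * n / 4L + 1L))]   # +x side
  loop1 <- c(outer1, rev(Dpts))
  outer2 <- Tring[(3L * n / 4L + 1L):(n / 4L + 1L)]            # -x side
  loop2 <- c(outer2, Dpts)

  all_v <- function() do.call(rbind, verts)
  for (b in 1:2) {
    a <- ax[[b]]; rb <- branch_radii[b]
    er <- c(a[3], 0, -a[1])  # in-plane radial unit vector, perpendicular to axis
    psis <- 2 * pi * (0:(n - 1)) / n
    circ <- function(center)
      t(sapply(psis, function(p) center + rb * (cos(p) * er + sin(p) * c(0, 1, 0))))
    s0 <- 1.5 * trunk_radius
    nzb <- max(2L, round(branch_length / edge_length))
    ss <- seq(s0, s0 + branch_length, length.out = nzb + 1L)
    ring1_xyz <- circ(ss[1] * a)
    # align ring ordering with the base loop (cyclic offset and direction)
    base <- loop1; if (b == 2L) base <- loop2
    V <- all_v()
    bxyz <- V[base, , drop = FALSE]
    best <- NULL; bestcost <- Inf
    for (dir in c(1L, -1L)) {
      ord0 <- if (dir == 1L) 1:n else c(1L, n:2L)
      for (off in 0:(n - 1L)) {
        ord <- ord0[((0:(n - 1L) + off) %% n) + 1L]
        cost <- sum((ring1_xyz[ord, ] - bxyz)^2)
        if (cost < bestcost) { bestcost <- cost; best <- ord }
      }
    }
    lab <- paste0("branch", b)
    ring1 <- ring1_xyz[best, , drop = FALSE]
    # refine the junction collar so edge lengths stay near the target;
    # collar vertices belong to the flow-divider region, labelled trunk
    gap <- mean(sqrt(rowSums((ring1 - bxyz)^2)))
    ncol_rings <- max(0L, round(gap / edge_length) - 1L)
    prev <- base
    if (ncol_rings > 0L) for (j in seq_len(ncol_rings)) {
      w <- j / (ncol_rings + 1L)
      mid <- add((1 - w) * bxyz + w * ring1, "trunk")
      strip(prev, mid)
      prev <- mid
    }
    rings <- lapply(ss, function(s) add(circ(s * a)[best, , drop = FALSE], lab))
    strip(prev, rings[[1L]])
    for (i in seq_len(nzb)) strip(rings[[i]], rings[[i + 1L]])
  }

  V <- all_v()
  TR <- do.call(rbind, tris)
  TR <- orient_consistent(TR)
  # flip globally if normals point inward (test on trunk mid-section)
  m <- surface_mesh(V, TR, apex_vertex = apex, branch_labels = labels)
  tv <- which(labels == "trunk" & abs(V[, 3] + trunk_length / 2) < trunk_length / 4)
  if (length(tv) && mean(rowSums(m$vertex_normals[tv, , drop = FALSE] *
                                 cbind(V[tv, 1], V[tv, 2], 0))) < 0) {
    TR <- TR[, c(1, 3, 2)]
    m <- surface_mesh(V, TR, apex_vertex = apex, branch_labels = labels)
  }
  m
}

# make triangle winding consistent across shared edges (BFS flood fill)
orient_consistent <- function(tr) {
  nt <- nrow(tr)
  ekey <- function(u, v) paste(pmin(u, v), pmax(u, v))
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  keys <- ekey(e[, 1], e[, 2])
  tri_of <- rep(seq_len(nt), 3L)
  emap <- split(tri_of, keys)
  visited <- logical(nt)
  queue <- 1L; visited[1L] <- TRUE
  dir_edges <- function(i) rbind(tr[i, 1:2], tr[i, 2:3], tr[i, c(3, 1)])
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    de <- dir_edges(i)
    for (r in 1:3) {
      nbrs <- setdiff(emap[[ekey(de[r, 1], de[r, 2])]], i)
      for (j in nbrs) {
        if (visited[j]) next
        dj <- dir_edges(j)
        same <- any(dj[, 1] == de[r, 1] & dj[, 2] == de[r, 2])
        if (same) tr[j, ] <- tr[j, c(1, 3, 2)]
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  tr
}

# ---- zonal wall-shear field ---------------------------------------------

#' Parameters of the zonal bifurcation wall-shear profile
#'
#' Describes the canonical impingement / acceleration / recovery pattern
#' along a daughter branch: TAWSS rises linearly from `tau_impingement`
#' at the apex to `tau_peak` at `peak_distance` (acceleration zone), then
#' decays exponentially with scale `decay_length` (recovery zone).
#' `pulsatility` modulates the magnitude over the cycle and
#' `reversal_fraction` flips the direction for the stated fraction of the
#' cycle, giving OSI approximately equal to that fraction.
#'
#' @param tau_impingement Pa at the apex (>= 0).
#' @param tau_peak Pa at the peak (> tau_impingement).
#' @param peak_distance mm from the apex (> 0).
#' @param decay_length mm (> 0).
#' @param pulsatility fraction in `[0, 1)`.
#' @param reversal_fraction fraction of the cycle in `[0, 0.5]`.
#' @export
zonal_field_params <- function(tau_impingement = 20, tau_peak = 95,
                               peak_distance = 7, decay_length = 3,
                               pulsatility = 0.4, reversal_fraction = 0.1) {
  if (tau_impingement < 0 || tau_peak <= tau_impingement)
    stop("need tau_peak > tau_impingement >= 0")
  if (peak_distance <= 0 || decay_length <= 0)
    stop("peak_distance and decay_length must be positive")
  if (pulsatility < 0 || pulsatility >= 1) stop("pulsatility must be in [0, 1)")
  if (reversal_fraction < 0 || reversal_fraction > 0.5)
    stop("reversal_fraction must be in [0, 0.5]")
  structure(list(tau_impingement = tau_impingement, tau_peak = tau_peak,
                 peak_distance = peak_distance, decay_length = decay_length,
                 pulsatility = pulsatility,
                 reversal_fraction = reversal_fraction),
            class = "zonal_field_params")
}

#' Named zonal presets
#'
#' `"case_like"` places the TAWSS peak beyond the 5-mm analysis patch so
#' the high-WSS region falls in the acceleration zone (positive dirWSSG);
#' `"control_like"` places a steep peak just past the apex so the region
#' falls in the recovery zone (negative dirWSSG).
#'
#' @param name `"case_like"` or `"control_like"`.
#' @return a [zonal_field_params()].
#' @export
zonal_preset <- function(name = c("case_like", "control_like")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".yaml"), package = "wallshear")
  do.call(zonal_field_params, yaml::read_yaml(f))
}

#' Synthetic time-resolved wall-shear field with zonal structure
#'
#' TAWSS follows the zonal profile as a function of geodesic distance from
#' the apex; the shear direction is the surface-tangent direction of
#' increasing distance (i.e. down-branch flow); the magnitude is modulated
#' over the cycle by `1 + pulsatility * sin(2 pi t / T)` and the direction
#' is reversed during the final `reversal_fraction` of the cycle.
#' Optional multiplicative per-vertex noise is seeded and deterministic.
#'
#' @param mesh a labelled [surface_mesh()] with an apex vertex.
#' @param params a [zonal_field_params()] or preset name.
#' @param period cardiac period (s).
#' @param n_times number of samples over `[0, T]`.
#' @param noise per-vertex multiplicative noise sd (0 disables).
#' @param seed integer seed for the noise.
#' @return a [wall_field()].
#' @export
make_zonal_wss_field <- function(mesh, params = zonal_preset("case_like"),
                                 period = 0.9, n_times = 32L, noise = 0,
                                 seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.character(params)) params <- zonal_preset(params)
  stopifnot(inherits(params, "zonal_field_params"))
  if (is.null(mesh$apex_vertex)) stop("mesh has no apex vertex")
  if (period <= 0 || n_times < 8L) stop("invalid period or n_times")
  s <- geodesic_distances(mesh, mesh$apex_vertex)
  p <- params
  tau <- ifelse(s <= p$peak_distance,
                p$tau_impingement +
                  (p$tau_peak - p$tau_impingement) * s / p$peak_distance,
                p$tau_peak * exp(-(s - p$peak_distance) / p$decay_length))
  if (noise > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    tau <- tau * exp(stats::rnorm(length(tau), 0, noise))
  }
  g <- tangent_gradient(mesh, s)
  gm <- sqrt(rowSums(g^2))
  dirv <- g / ifelse(is.finite(gm) & gm > 1e-9, gm, 1)
  bad <- !is.finite(gm) | gm <= 1e-9
  if (any(bad)) {  # apex and degenerate vertices: any tangent direction
    tb <- tangent_basis(mesh$vertex_normals)
    dirv[bad, ] <- tb$e1[bad, , drop = FALSE]
  }
  times <- seq(0, period, length.out = n_times)
  gmod <- 1 + p$pulsatility * sin(2 * pi * times / period)
  sgn <- ifelse(times >= (1 - p$reversal_fraction) * period & times < period,
                -1, 1)
  nv <- nrow(mesh$vertices)
  vec <- array(0, c(nv, n_times, 3L))
  for (k in 1:3)
    vec[, , k] <- outer(tau * dirv[, k], gmod * sgn)
  wall_field(mesh, times, vec)
}

# ---- cohort generator ---------------------------------------------------

#' Printed group calibration targets for the cohort generator
#'
#' Median and quartiles (q25, median, q75) of each haemodynamic metric in
#' the two groups of the 77-subject study the generator emulates.
#'
#' @return nested list `targets$<group>$<metric> = c(q25, median, q75)`.
#' @export
cohort_targets <- function() {
  list(case = list(WSS = c(59.27, 69.36, 89.96),
                   WSSG = c(-14.88, 11.05, 28.06),
                   absWSSG = c(12.29, 23.63, 56.13),
                   OSI = c(0.069, 0.175, 0.319)),
       control = list(WSS = c(61.92, 76.59, 125.27),
                      WSSG = c(-64.49, -14.76, 18.14),
                      absWSSG = c(15.29, 35.07, 74.86),
                      OSI = c(0, 0.185, 0.353)))
}

#' Cohort generator parameters
#'
#' @param n_case,n_control group sizes (defaults 38 and 39).
#' @param p_dir_pos_case,p_dir_pos_control probabilities of a positive
#'   gradient direction (defaults 23/38 and 14/39).
#' @param targets per-group metric quantile targets, see
#'   [cohort_targets()].
#' @param seed integer seed.
#' @export
cohort_params <- function(n_case = 38L, n_control = 39L,
                          p_dir_pos_case = 23 / 38,
                          p_dir_pos_control = 14 / 39,
                          targets = cohort_targets(), seed = 1L) {
  if (n_case < 1L || n_control < 1L) stop("group sizes must be >= 1")
  if (p_dir_pos_case < 0 || p_dir_pos_case > 1 ||
      p_dir_pos_control < 0 || p_dir_pos_control > 1)
    stop("direction probabilities must be in [0, 1]")
  for (g in names(targets)) for (m in names(targets[[g]])) {
    q <- targets[[g]][[m]]
    if (length(q) != 3L || q[3] <= q[1]) stop("infeasible targets (IQR <= 0)")
  }
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 p_dir_pos_case = p_dir_pos_case,
                 p_dir_pos_control = p_dir_pos_control,
                 targets = targets, seed = as.integer(seed)),
            class = "cohort_params")
}

# lognormal (mu, sigma) matching median exactly and the IQR width
lognormal_from_median_iqr <- function(q) {
  q25 <- q[1]; m <- q[2]; q75 <- q[3]
  if (m <= 0) stop("lognormal calibration needs a positive median")
  width <- q75 - q25
  if (width <= 0) stop("infeasible targets (IQR <= 0)")
  sigma <- asinh(width / (2 * m)) / stats::qnorm(0.75)
  c(mu = log(m), sigma = sigma)
}

# two-component signed lognormal mixture hitting q25/median/q75 exactly;
# the majority sign carries two quantile conditions, the minority one and
# the majority's sigma
signed_mixture_calib <- function(p_pos, q) {
  q25 <- q[1]; m <- q[2]; q75 <- q[3]
  if (p_pos >= 0.5) {
    if (m <= 0 || q75 <= 0)
      stop("infeasible targets: majority-positive mixture needs m, q75 > 0")
    za <- stats::qnorm((p_pos - 0.5) / p_pos)
    zb <- stats::qnorm(1 - 0.25 / p_pos)
    s_pos <- (log(q75) - log(m)) / (zb - za)
    mu_pos <- log(m) - s_pos * za
    if (p_pos < 1) {
      if (q25 >= 0) stop("infeasible targets: q25 must be negative")
      u <- 1 - 0.25 / (1 - p_pos)
      s_neg <- s_pos
      mu_neg <- log(-q25) - s_neg * stats::qnorm(u)
    } else { mu_neg <- NA_real_; s_neg <- NA_real_ }
  } else {
    if (m >= 0 || q25 >= 0)
      stop("infeasible targets: majority-negative mixture needs m, q25 < 0")
    pn <- 1 - p_pos
    za <- stats::qnorm((pn - 0.5) / pn)
    zb <- stats::qnorm(1 - 0.25 / pn)
    s_neg <- (log(-q25) - log(-m)) / (zb - za)
    mu_neg <- log(-m) - s_neg * za
    if (p_pos > 0) {
      if (q75 <= 0) stop("infeasible targets: q75 must be positive")
      u <- 1 - 0.25 / p_pos
      s_pos <- s_neg
      mu_pos <- log(q75) - s_pos * stats::qnorm(u)
    } else { mu_pos <- NA_real_; s_pos <- NA_real_ }
  }
  list(mu_pos = mu_pos, s_pos = s_pos, mu_neg = mu_neg, s_neg = s_neg)
}

# scaled beta on [0, upper] with exact median and least-squares quartiles
beta_from_quantiles <- function(q, upper = 0.5) {
  tm <- q[2] / upper; t25 <- q[1] / upper; t75 <- q[3] / upper
  if (tm <= 0 || tm >= 1) stop("infeasible OSI median")
  b_for <- function(a) stats::uniroot(
    function(b) suppressWarnings(stats::qbeta(0.5, a, b)) - tm,
    c(1e-3, 1e3), tol = 1e-12)$root
  obj <- function(la) {
    a <- exp(la); b <- b_for(a)
    (stats::qbeta(0.25, a, b) - t25)^2 + (stats::qbeta(0.75, a, b) - t75)^2
  }
  o <- suppressWarnings(stats::optimize(obj, c(log(1e-2), log(50)), tol = 1e-10))
  a <- exp(o$minimum)
  c(alpha = a, beta = b_for(a))
}

# randomized stratified uniforms: one draw per 1/n stratum, shuffled
stratified_uniforms <- function(n) {
  (sample.int(n) - stats::runif(n)) / n
}

#' Generate a synthetic case-control cohort table
#'
#' Seeded draws whose group-wise marginals are calibrated to the printed
#' quantile targets: WSS and absWSSG from lognormals matching the median
#' and IQR, signed WSSG from a sign-mixture of lognormal magnitudes whose
#' mixture quartiles match the targets exactly, OSI from a scaled beta on
#' `[0, 0.5]`. The positive-direction count is `round(p * n)` assigned by
#' random permutation, and all continuous draws use randomized stratified
#' uniforms through the component quantile functions, so empirical
#' quantiles converge at O(1/n) rather than O(1/sqrt(n)).
#'
#' @param params a [cohort_params()].
#' @return a `cohort_table` data frame with columns `subject_id`, `group`,
#'   `WSS`, `WSSG`, `absWSSG`, `OSI`, `dirWSSG`.
#' @export
make_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  gen_group <- function(group, n, p_pos) {
    tg <- params$targets[[group]]
    n_pos <- round(p_pos * n)
    dir <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    lw <- lognormal_from_median_iqr(tg$WSS)
    wss <- stats::qlnorm(stratified_uniforms(n), lw["mu"], lw["sigma"])
    la <- lognormal_from_median_iqr(tg$absWSSG)
    abswssg <- stats::qlnorm(stratified_uniforms(n), la["mu"], la["sigma"])
    mx <- signed_mixture_calib(p_pos, tg$WSSG)
    wssg <- numeric(n)
    if (n_pos > 0)
      wssg[dir == 1L] <- stats::qlnorm(stratified_uniforms(n_pos),
                                       mx$mu_pos, mx$s_pos)
    if (n - n_pos > 0)
      wssg[dir == 0L] <- -stats::qlnorm(stratified_uniforms(n - n_pos),
                                        mx$mu_neg, mx$s_neg)
    bo <- beta_from_quantiles(tg$OSI, upper = 0.5)
    osiv <- 0.5 * stats::qbeta(stratified_uniforms(n), bo["alpha"], bo["beta"])
    data.frame(subject_id = sprintf("%s_%04d", group, seq_len(n)),
               group = group, WSS = wss, WSSG = wssg, absWSSG = abswssg,
               OSI = osiv, dirWSSG = dir, stringsAsFactors = FALSE)
  }
  tab <- rbind(gen_group("case", params$n_case, params$p_dir_pos_case),
               gen_group("control", params$n_control, params$p_dir_pos_control))
  rownames(tab) <- NULL
  # marginals are calibrated independently, so the row-wise
  # absWSSG >= |WSSG| consistency check is not informative here
  cohort_table(tab, check_consistency = FALSE)
}

#' Validate a cohort table
#'
#' Checks the per-subject metric table schema: required columns, OSI in
#' `[0, 0.5]`, dirWSSG in {0, 1}, both groups non-empty. Rows where
#' `absWSSG < |WSSG|` — possible for independently calibrated marginals —
#' are flagged with a warning rather than rejected.
#'
#' @param tab data frame with columns `subject_id`, `group`, `WSS`,
#'   `WSSG`, `absWSSG`, `OSI`, `dirWSSG`.
#' @param check_consistency warn on rows violating `absWSSG >= |WSSG|`
#'   (disabled by [make_cohort()], whose marginals are calibrated
#'   independently).
#' @return the validated table, classed `cohort_table`.
#' @export
cohort_table <- function(tab, check_consistency = TRUE) {
  req <- c("subject_id", "group", "WSS", "WSSG", "absWSSG", "OSI", "dirWSSG")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(tab$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  if (!all(c("case", "control") %in% tab$group))
    stop("both groups must be non-empty")
  if (any(!is.finite(tab$OSI)) || any(tab$OSI < 0 | tab$OSI > 0.5))
    stop("OSI out of [0, 0.5]")
  if (!all(tab$dirWSSG %in% c(0L, 1L))) stop("dirWSSG must be 0/1")
  if (check_consistency) {
    nviol <- sum(tab$absWSSG < abs(tab$WSSG))
    if (nviol > 0)
      warning(nviol, " row(s) with absWSSG < |WSSG|")
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
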