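#' Elastic-foundation contact parameters
#'
#' Material and geometry constants of the penalty contact law. The default
#' contact pressure module is \eqn{P_V = 2.74\times 10^{11}} N/m^3, the
#' value used for a conventional polyethylene glenoid insert; it can be
#' recomputed from the nonlinear polyethylene material law with
#' [pressure_module()].
#'
#' @param P_V contact pressure module, N/m^3.
#' @param eps_o dimensionless strain constant of the nonlinear
#'   polyethylene law.
#' @param p_o pressure constant of the nonlinear law, MPa.
#' @param n exponent of the nonlinear law.
#' @param v Poisson's ratio of the insert (must lie in (0, 0.5)).
#' @param h insert thickness, m.
#' @return an object of class `contact_params`.
#' @export
contact_params <- function(P_V = 2.74e11, eps_o = 0.0597, p_o = 18.4,
                           n = 3, v = 0.46, h = 5e-3) {
  if (P_V <= 0) stop("P_V must be positive")
  if (v <= 0 || v >= 0.5) stop("Poisson's ratio must lie in (0, 0.5)")
  if (h <= 0) stop("insert thickness must be positive")
  structure(list(P_V = P_V, eps_o = eps_o, p_o = p_o, n = n, v = v, h = h),
            class = "contact_params")
}

#' Contact pressure module from elastic-foundation theory
#'
#' Evaluates the elastic-foundation expression for the pressure module of
#' a confined polyethylene layer with the nonlinear material law
#' \eqn{\varepsilon = \varepsilon_o \,[\exp(p/p_o)-1]}-type constants:
#' \deqn{P_V = \frac{(1-v)}{(1+v)(1-2v)}\,\frac{1}{h}\,
#'   \frac{2 p_o}{\varepsilon_o}\,
#'   \left[1 + n\,(p_i/p_o)^{\,n-1}\right]}
#' with \eqn{v} Poisson's ratio, \eqn{h} the insert thickness and
#' \eqn{p_i} the reference contact pressure at which the tangent of the
#' nonlinear law is taken. Units: \eqn{p_o} and `reference_pressure` in
#' MPa, `h` in m; the result is in N/m^3.
#'
#' This is a pure function of its arguments; the shipped default in
#' [contact_params()] is the constant 2.74e11 N/m^3 and is not recomputed
#' from this expression, so sweep results never depend on the reading of
#' the material-law constants.
#'
#' @param params a [contact_params()].
#' @param reference_pressure reference contact pressure \eqn{p_i}, MPa.
#' @return pressure module, N/m^3.
#' @export
pressure_module <- function(params, reference_pressure) {
  if (reference_pressure <= 0) stop("reference pressure must be positive")
  v <- params$v; h <- params$h
  if (v >= 0.5) stop("Poisson's ratio >= 0.5: incompressible singularity")
  if (h <= 0) stop("insert thickness must be positive")
  confinement <- (1 - v) / ((1 + v) * (1 - 2 * v))
  p_o <- params$p_o * 1e6                       # MPa -> Pa
  p_i <- reference_pressure * 1e6
  bracket <- 1 + params$n * (p_i / p_o)^(params$n - 1)
  confinement / h * (2 * p_o / params$eps_o) * bracket
}

assert_rigid <- function(pose) {
  R <- pose$rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("pose is not a rigid transform (rotation not proper orthonormal)")
}

#' Rigid pose of the master body relative to the slave frame
#'
#' @param translation 3-vector (m).
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @return a list with class `rigid_pose`.
#' @export
rigid_pose <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  p <- structure(list(translation = as.numeric(translation),
                      rotation = rotation), class = "rigid_pose")
  assert_rigid(p)
  p
}

#' Per-vertex penetration depth of a slave mesh into a master body
#'
#' For every vertex of `slave`, the depth \eqn{d_i \ge 0} by which it lies
#' inside the material of `master` after applying `pose` to the master.
#' When the master is a generated spherical primitive the signed distance
#' to its analytic surface is used (exact); otherwise depth is measured by
#' projection onto the nearest master vertex along its outward normal.
#'
#' @param slave,master [trimesh()] surfaces.
#' @param pose a [rigid_pose()] applied to the master (its translation
#'   moves the master body; the slave stays fixed).
#' @return numeric vector of depths (m), zero outside contact.
#' @export
vertex_penetration <- function(slave, master, pose = rigid_pose()) {
  assert_rigid(pose)
  x <- slave$vertices
  if (!is.null(master$sphere)) {
    ctr <- drop(pose$rotation %*% master$sphere$center) + pose$translation
    r <- sqrt(rowSums(sweep(x, 2, ctr)^2))
    if (isTRUE(master$sphere$concave)) {
      # material lies outside the spherical surface (a cup)
      d <- r - master$sphere$radius
    } else {
      d <- master$sphere$radius - r
    }
    d <- pmax(d, 0)
    d[d < 1e-12] <- 0   # sub-picometre depths are rounding noise
    d
  } else {
    mv <- sweep(master$vertices %*% t(pose$rotation), 2, pose$translation, "+")
    mn <- master$vertex_normal %*% t(pose$rotation)
    d <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      dx <- sweep(mv, 2, x[i, ])
      j <- which.min(rowSums(dx^2))
      # positive when the slave vertex is behind the master surface
      d[i] <- sum((mv[j, ] - x[i, ]) * mn[j, ])
    }
    pmax(d, 0)
  }
}

#' Elastic-foundation contact force between two implant surfaces
#'
#' Implements the linear force/penetration-volume law on the slave mesh:
#' each slave vertex carries a volume \eqn{V_i = d_i A_i} and a force
#' \eqn{F_i = P_V V_i} directed along the slave vertex inward normal
#' (i.e. the contact pushes the slave into its own material). The
#' resultant force/moment are exact sums of the per-vertex contributions.
#'
#' @inheritParams vertex_penetration
#' @param params a [contact_params()].
#' @param gh_center point about which the resultant moment is taken (m).
#' @return an object of class `contact_result`: list with per-vertex
#'   `depth`, `volume`, `force` (signed magnitudes, N), the 3-vector
#'   `resultant_force` on the slave, `force_on_master` (= minus that),
#'   `resultant_moment` about `gh_center` on the slave, `contact_area`,
#'   `center_of_pressure`, and scalar `total_force` \eqn{= \sum F_i}.
#' @export
contact_force <- function(slave, master, pose = rigid_pose(),
                          params = contact_params(),
                          gh_center = c(0, 0, 0)) {
  d <- vertex_penetration(slave, master, pose)
  A <- slave$vertex_area
  V <- d * A
  Fi <- params$P_V * V
  dir <- -slave$vertex_normal                      # inward normal of the slave
  fvec <- dir * Fi
  resultant <- colSums(fvec)
  r <- sweep(slave$vertices, 2, gh_center)
  mom <- colSums(cbind(r[, 2] * fvec[, 3] - r[, 3] * fvec[, 2],
                       r[, 3] * fvec[, 1] - r[, 1] * fvec[, 3],
                       r[, 1] * fvec[, 2] - r[, 2] * fvec[, 1]))
  act <- d > 0
  cop <- if (any(act)) colSums(slave$vertices[act, , drop = FALSE] * Fi[act]) /
    sum(Fi[act]) else rep(NA_real_, 3)
  structure(list(
    depth = d, area = A, volume = V, force = Fi,
    resultant_force = resultant,
    force_on_master = -resultant,
    resultant_moment = mom,
    contact_area = sum(A[act]),
    center_of_pressure = cop,
    total_force = sum(Fi)), class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf(
    "contact_result: |F| = %.2f N, active area %.2f mm^2, max depth %.1f um\n",
    sqrt(sum(x$resultant_force^2)), x$contact_area * 1e6, max(x$depth) * 1e6))
  invisible(x)
}

#' Dump per-vertex contact diagnostics to CSV
#'
#' @param result a `contact_result`.
#' @param path output CSV path.
#' @return `path`, invisibly. Columns: vertex_id, d_i, A_i, V_i, F_i.
#' @export
write_contact_diagnostics <- function(result, path) {
  n <- length(result$depth)
  df <- data.frame(vertex_id = seq_len(n), d_i = result$depth,
                   A_i = result$area, V_i = result$volume, F_i = result$force)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
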