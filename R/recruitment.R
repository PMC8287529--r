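#' Moment-balance system for muscle recruitment
#'
#' Only the three rotational equations about the GH center enter the
#' recruitment problem; the force balance is handled by the FDK
#' translations. A muscle force vector f must satisfy
#' \eqn{R f = -M_{ext}} within bounds \eqn{0 \le f_i \le N_i}, with the
#' upper bound forced to zero for deficient muscles.
#'
#' @param moment_arms matrix R (n_constraints x n_muscles, m): moment per
#'   unit muscle force about the GH center.
#' @param external_moment external moment vector (N*m): gravity plus
#'   contact plus spring contributions.
#' @param strengths isometric strengths N_i (N).
#' @param deficient logical vector; deficient muscles get upper bound 0.
#' @return object of class `equilibrium_system`.
#' @export
equilibrium_system <- function(moment_arms, external_moment, strengths,
                               deficient = rep(FALSE, length(strengths))) {
  R <- as.matrix(moment_arms)
  if (!all(is.finite(R))) stop("moment arm matrix has non-finite entries")
  if (ncol(R) != length(strengths))
    stop("dimension mismatch between moment arms and strengths")
  if (length(external_moment) != nrow(R))
    stop("dimension mismatch between moment arms and external moment")
  if (any(strengths < 0)) stop("strengths must be nonnegative")
  structure(list(R = R, M_ext = as.numeric(external_moment),
                 strengths = as.numeric(strengths),
                 upper = ifelse(deficient, 0, as.numeric(strengths)),
                 deficient = deficient),
            class = "equilibrium_system")
}

#' Muscle moment-arm matrix at a glenohumeral state
#'
#' Column i is \eqn{r \times \hat u} for muscle i, where r runs from the
#' GH center to the effective humeral attachment (the humeral path point
#' adjacent to the joint-crossing segment, translated by the released GH
#' translation) and \eqn{\hat u} is the unit line of action from that
#' attachment toward the fixed-side anchor.
#'
#' @param model a [shoulder_model()].
#' @param state a [gh_state()].
#' @return 3 x n_muscles matrix (m), columns named by muscle.
#' @export
moment_arms <- function(model, state) {
  n <- length(model$muscles)
  R <- matrix(0, 3, n, dimnames = list(c("AP", "SI", "ML"),
                                       names(model$muscles)))
  for (i in seq_len(n)) {
    g <- muscle_line_of_action(model$muscles[[i]], state)
    R[, i] <- cross3(g$attachment, g$direction)
  }
  R
}

# Effective joint-crossing segment of a muscle path at a state: the first
# humeral point and the adjacent fixed-side point.
muscle_line_of_action <- function(m, state) {
  ih <- which(m$segment == "humerus")[1L]
  ifix <- if (ih > 1L) ih - 1L else which(m$segment != "humerus")[1L]
  p_h <- anchor_position(m$path[ih, ], "humerus", state)
  p_f <- anchor_position(m$path[ifix, ], m$segment[ifix], state)
  d <- p_f - p_h
  len <- sqrt(sum(d^2))
  if (len < 1e-9)
    stop(sprintf("muscle '%s': zero-length joint-crossing segment", m$name))
  list(attachment = p_h, direction = d / len)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed elevation (abduction) moment arm of one muscle
#'
#' Positive values abduct the arm (raise it in the frontal plane). In the
#' model's right-shoulder frame the abduction rotation is about the -AP
#' axis, so the elevation moment arm is minus the AP component of the
#' muscle's moment column.
#'
#' @inheritParams moment_arms
#' @param muscle muscle name.
#' @return moment arm, m (force-normalized moment about the abduction
#'   axis).
#' @export
elevation_moment_arm <- function(model, muscle, state = gh_state()) {
  R <- moment_arms(model, state)
  -R["AP", muscle]
}

#' Axial-rotation moment arm of one muscle
#'
#' Projection of the muscle's moment column onto the humeral long axis at
#' the given state; internal and external rotators have opposite signs.
#'
#' @inheritParams elevation_moment_arm
#' @return signed moment arm, m.
#' @export
axial_moment_arm <- function(model, muscle, state = gh_state()) {
  R <- moment_arms(model, state)
  axis <- drop(abduction_rotation(state$abduction_angle) %*% c(0, -1, 0))
  sum(R[, muscle] * axis)
}

#' Solve the polynomial muscle-recruitment problem
#'
#' Minimizes the polynomial criterion \eqn{\sum_i (f_i/N_i)^p} subject to
#' the moment balance \eqn{R f = -M_{ext}} and the bounds
#' \eqn{0 \le f_i \le N_i} (deficient muscles: \eqn{f_i = 0}). The
#' default order p = 2 is the quadratic polynomial criterion and is
#' solved as a strictly convex quadratic program (Goldfarb-Idnani active
#' set); higher even orders, used by the sensitivity sweep, are solved by
#' an augmented-Lagrangian bound-constrained minimization warm-started
#' from the quadratic solution.
#'
#' Infeasibility (no f within bounds balances the moment) is reported via
#' `status = "infeasible"`, not raised, so sweeps can record failed
#' steps.
#'
#' @param system an [equilibrium_system()].
#' @param criterion_order integer p >= 2.
#' @return object of class `recruitment_solution`: list with `forces`
#'   (N, named), `activations` f_i/N_i, `objective`, `status`
#'   ("optimal"/"infeasible"), and `residual` (moment-balance residual
#'   norm, N*m).
#' @export
solve_recruitment <- function(system, criterion_order = 2L) {
  p <- as.integer(criterion_order)
  if (p < 2L) stop("criterion order must be >= 2")
  R <- system$R
  m <- nrow(R); n <- ncol(R)
  b <- -system$M_ext
  N <- system$strengths
  ub <- system$upper

  free <- ub > 0
  Rf <- R[, free, drop = FALSE]
  nf <- sum(free)
  forces <- setNames(numeric(n), colnames(R))

  target_norm <- max(1, sqrt(sum(b^2)))
  if (nf == 0L) {
    res <- sqrt(sum(b^2))
    status <- if (res <= 1e-6 * target_norm) "optimal" else "infeasible"
    return(new_recruitment_solution(forces, N, status, res, p))
  }

  sol <- try_qp(Rf, b, N[free], ub[free])
  if (is.null(sol)) {
    # QP failed: decide between genuine infeasibility and numerics by
    # box-constrained least squares on the moment residual.
    proj <- stats::optim(rep(0, nf), fn = function(f) sum((Rf %*% f - b)^2),
                         gr = function(f) drop(2 * t(Rf) %*% (Rf %*% f - b)),
                         method = "L-BFGS-B", lower = rep(0, nf),
                         upper = ub[free],
                         control = list(maxit = 500, factr = 1e4))
    res <- sqrt(proj$value)
    if (res > 1e-6 * target_norm)
      return(new_recruitment_solution(forces, N, "infeasible", res, p))
    f <- proj$par
  } else {
    f <- sol
  }

  if (p > 2L) f <- polish_higher_order(Rf, b, N[free], ub[free], p, f)

  forces[free] <- pmax(f, 0)
  res <- sqrt(sum((R %*% forces - b)^2))
  new_recruitment_solution(forces, N, "optimal", res, p)
}

new_recruitment_solution <- function(forces, strengths, status, residual, p) {
  a <- ifelse(strengths > 0, forces / strengths, 0)
  structure(list(forces = forces, activations = a,
                 objective = sum(a^p), status = status,
                 residual = residual, criterion_order = p),
            class = "recruitment_solution")
}

#' @export
print.recruitment_solution <- function(x, ...) {
  cat(sprintf("recruitment_solution (p = %d): %s, objective %.4g\n",
              x$criterion_order, x$status, x$objective))
  if (length(x$forces)) {
    df <- data.frame(force_N = round(x$forces, 2),
                     activation = round(x$activations, 4))
    print(df)
  }
  invisible(x)
}

# Strictly convex QP: min sum (f_i/N_i)^2 s.t. Rf f = b, 0 <= f <= ub.
try_qp <- function(Rf, b, N, ub) {
  nf <- ncol(Rf)
  D <- diag(2 / N^2, nf)
  Amat <- cbind(t(Rf), diag(nf), -diag(nf))
  bvec <- c(b, rep(0, nf), -ub)
  out <- tryCatch(
    quadprog::solve.QP(D, rep(0, nf), Amat, bvec, meq = nrow(Rf)),
    error = function(e) NULL)
  if (is.null(out)) NULL else out$solution
}

# Augmented-Lagrangian refinement for p > 2, warm-started from the
# quadratic solution.
polish_higher_order <- function(Rf, b, N, ub, p, f0) {
  lambda <- rep(0, nrow(Rf))
  mu <- 1e4
  f <- pmin(pmax(f0, 0), ub)
  for (outer in 1:30) {
    obj <- function(f) {
      cvec <- drop(Rf %*% f - b)
      sum((f / N)^p) + sum(lambda * cvec) + 0.5 * mu * sum(cvec^2)
    }
    grad <- function(f) {
      cvec <- drop(Rf %*% f - b)
      p * f^(p - 1) / N^p + drop(t(Rf) %*% (lambda + mu * cvec))
    }
    opt <- stats::optim(f, obj, grad, method = "L-BFGS-B",
                        lower = rep(0, length(f)), upper = ub,
                        control = list(maxit = 400, factr = 1e2))
    f <- opt$par
    cvec <- drop(Rf %*% f - b)
    if (sqrt(sum(cvec^2)) < 1e-9 * max(1, sqrt(sum(b^2)))) break
    lambda <- lambda + mu * cvec
    if (outer %% 5 == 0) mu <- mu * 10
  }
  f
}
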