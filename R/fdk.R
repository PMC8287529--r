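#' Settings of the force-dependent-kinematics solver
#'
#' @param tolerance residual-force tolerance, N. The default 20 N is the
#'   convergence criterion adopted for the reference ATSA simulations.
#' @param max_iterations Newton iteration cap per step.
#' @param fd_step finite-difference step for the residual Jacobian, m.
#' @param warm_start start each sweep step from the previous converged
#'   translation.
#' @return object of class `fdk_settings`.
#' @export
fdk_settings <- function(tolerance = 20, max_iterations = 50,
                         fd_step = 1e-5, warm_start = TRUE) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 fd_step = fd_step, warm_start = isTRUE(warm_start)),
            class = "fdk_settings")
}

#' Net quasi-static residual force on the humerus
#'
#' Sum of all force elements acting on the humeral segment at the given
#' state, expressed in the GH frame: recruited muscle forces (the
#' recruitment problem is solved at this state), arm gravity, the
#' contact resultant transmitted by the insert, and the capsule-spring
#' force. A pure function of (model, state); FDK drives this residual to
#' zero in the three released translations.
#'
#' If recruitment is infeasible at the state the residual is undefined:
#' a vector of `NA` is returned with attribute `diagnostic`.
#'
#' @param model a [shoulder_model()] or a toy model from [toy_models()].
#' @param state a [gh_state()].
#' @return residual force 3-vector (N) with attribute `details` (the
#'   full force breakdown).
#' @export
fdk_residual <- function(model, state) UseMethod("fdk_residual")

#' @export
fdk_residual.shoulder_model <- function(model, state) {
  ev <- fdk_eval(model, state)
  if (is.null(ev$residual)) {
    out <- rep(NA_real_, 3)
    attr(out, "diagnostic") <- ev$diagnostic
    return(out)
  }
  out <- ev$residual
  attr(out, "details") <- ev
  out
}

#' @export
fdk_residual.toy_model <- function(model, state) {
  u <- state$translation
  f <- model$external_force + spring_force(u, model$spring)
  if (!is.null(model$insert_mesh)) {
    pose <- rigid_pose(translation = u,
                       rotation = abduction_rotation(state$abduction_angle))
    cr <- contact_force(model$insert_mesh, model$head_mesh, pose,
                        model$contact)
    f <- f + cr$force_on_master
  }
  f
}

# Full force/moment bookkeeping at one state (internal workhorse).
fdk_eval <- function(model, state) {
  u <- state$translation
  rot <- abduction_rotation(state$abduction_angle)

  pose <- rigid_pose(translation = u, rotation = rot)
  cr <- contact_force(model$insert_mesh, model$head_mesh, pose,
                      model$contact)
  f_contact <- cr$force_on_master
  m_contact <- -cr$resultant_moment

  f_grav <- model$arm$mass * model$gravity
  r_com <- drop(rot %*% model$arm$com) + u
  m_grav <- cross3(r_com, f_grav)

  f_spring <- spring_force(u, model$spring)
  m_spring <- cross3(u, f_spring)

  R <- moment_arms(model, state)
  deficient <- vapply(model$muscles, `[[`, FALSE, "deficient")
  strengths <- vapply(model$muscles, `[[`, 0, "strength")
  M_ext <- m_grav + m_contact + m_spring
  sys <- equilibrium_system(R, M_ext, strengths, deficient)
  rec <- solve_recruitment(sys, model$recruitment$criterion_order)

  if (rec$status != "optimal") {
    return(list(residual = NULL, recruitment = rec, contact = cr,
                diagnostic = sprintf(
                  "recruitment infeasible at %.1f deg (moment residual %.3g N*m)",
                  state$abduction_angle, rec$residual)))
  }

  f_muscle <- c(0, 0, 0)
  for (i in seq_along(model$muscles)) {
    fi <- rec$forces[i]
    if (fi > 0) {
      g <- muscle_line_of_action(model$muscles[[i]], state)
      f_muscle <- f_muscle + fi * g$direction
    }
  }

  residual <- f_muscle + f_grav + f_contact + f_spring
  list(residual = residual, recruitment = rec, contact = cr,
       forces = list(muscle = f_muscle, gravity = f_grav,
                     contact = f_contact, spring = f_spring))
}

#' Solve one FDK step: translations at quasi-static equilibrium
#'
#' Damped-Newton root search on the three-component residual force with a
#' forward finite-difference Jacobian; after three stagnant iterations it
#' falls back to a derivative-free simplex minimization of the residual
#' norm (the contact quadrature makes the residual only piecewise
#' smooth). Deterministic given its arguments. If the iteration cap is
#' reached the best state found is returned with `converged = FALSE` —
#' never silently.
#'
#' @param model a [shoulder_model()] or toy model.
#' @param angle driven abduction angle, degrees (0 to 90).
#' @param u0 initial translation guess (m).
#' @param settings an [fdk_settings()].
#' @return object of class `fdk_result`: `state`, `residual_norm` (N),
#'   `iterations`, `recruitment`, `contact`, `converged`.
#' @export
fdk_solve_step <- function(model, angle, u0 = c(0, 0, 0),
                           settings = fdk_settings()) {
  if (angle < 0 || angle > 90) stop("angle must lie in [0, 90] degrees")
  resid_fn <- function(u) fdk_residual(model, gh_state(angle, u))
  norm_fn <- function(u) {
    g <- resid_fn(u)
    if (anyNA(g)) Inf else sqrt(sum(g^2))
  }

  u <- as.numeric(u0)
  g <- resid_fn(u)
  infeasible_start <- anyNA(g)
  if (infeasible_start) {
    # try the centered state before declaring the step failed
    u <- c(0, 0, 0)
    g <- resid_fn(u)
  }
  if (anyNA(g)) {
    return(new_fdk_result(model, angle, u, Inf, 0L, FALSE,
                          attr(g, "diagnostic")))
  }
  gn <- sqrt(sum(g^2))
  best_u <- u; best_gn <- gn
  iterations <- 0L
  stagnant <- 0L
  h <- settings$fd_step
  # refine well below the convergence tolerance while iterations are
  # cheap, so converged states do not depend on where inside the
  # tolerance band the search happened to stop
  tol_inner <- 0.01 * settings$tolerance

  while (gn > tol_inner && iterations < settings$max_iterations) {
    iterations <- iterations + 1L
    J <- matrix(0, 3, 3)
    ok <- TRUE
    for (k in 1:3) {
      up <- u; up[k] <- up[k] + h
      gk <- resid_fn(up)
      if (anyNA(gk)) { ok <- FALSE; break }
      J[, k] <- (gk - g) / h
    }
    step <- if (ok) tryCatch(-solve(J, g), error = function(e) NULL) else NULL
    improved <- FALSE
    if (!is.null(step)) {
      # clamp to 1 mm: the contact penalty makes the residual far stiffer
      # inside contact than the spring-only Jacobian suggests outside it
      sl <- sqrt(sum(step^2))
      if (sl > 1e-3) step <- step * (1e-3 / sl)
      alpha <- 1
      for (ls in 1:14) {
        un <- u + alpha * step
        gnew <- resid_fn(un)
        if (!anyNA(gnew)) {
          gnn <- sqrt(sum(gnew^2))
          if (gnn < gn) {
            u <- un; g <- gnew; gn <- gnn; improved <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
    }
    if (!improved) stagnant <- stagnant + 1L else stagnant <- 0L
    if (gn < best_gn) { best_u <- u; best_gn <- gn }

    if (stagnant >= 2L) {
      nm <- stats::optim(u, norm_fn, method = "Nelder-Mead",
                         control = list(maxit = 300,
                                        reltol = 1e-12,
                                        parscale = rep(1e-4, 3)))
      improved_nm <- is.finite(nm$value) && nm$value < gn
      if (improved_nm) {
        u <- nm$par
        g <- resid_fn(u)
        gn <- if (anyNA(g)) Inf else sqrt(sum(g^2))
        if (gn < best_gn) { best_u <- u; best_gn <- gn }
      }
      stagnant <- 0L
      if (!improved_nm) break  # both searches exhausted
    }
  }

  if (best_gn < gn) { u <- best_u; gn <- best_gn }
  new_fdk_result(model, angle, u, gn, iterations,
                 gn <= settings$tolerance, NULL)
}

new_fdk_result <- function(model, angle, u, gn, iterations, converged,
                           diagnostic) {
  st <- gh_state(angle, u)
  rec <- NULL; cr <- NULL
  if (inherits(model, "shoulder_model")) {
    ev <- fdk_eval(model, st)
    rec <- ev$recruitment; cr <- ev$contact
  } else if (!is.null(model$insert_mesh)) {
    cr <- contact_force(model$insert_mesh, model$head_mesh,
                        rigid_pose(translation = u,
                                   rotation = abduction_rotation(angle)),
                        model$contact)
  }
  structure(list(state = st, residual_norm = gn,
                 iterations = iterations, recruitment = rec, contact = cr,
                 converged = isTRUE(converged), diagnostic = diagnostic),
            class = "fdk_result")
}

#' @export
print.fdk_result <- function(x, ...) {
  cat(sprintf(
    "fdk_result: %.1f deg, u = (%.3f, %.3f, %.3f) mm, |residual| = %.3g N, %s (%d it)\n",
    x$state$abduction_angle, x$state$translation[1] * 1e3,
    x$state$translation[2] * 1e3, x$state$translation[3] * 1e3,
    x$residual_norm, if (x$converged) "converged" else "NOT converged",
    x$iterations))
  invisible(x)
}
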