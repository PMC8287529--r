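#' Run an abduction sweep under a cuff scenario
#'
#' The central simulation: the driven abduction angle is swept over the
#' driver grid (default 0-90 degrees in 91 steps over 90 s) and at each
#' step the three released glenohumeral translations are solved by
#' force-dependent kinematics with muscle recruitment in the loop. The
#' previous converged translation warm-starts the next step.
#'
#' @param model a [shoulder_model()].
#' @param scenario a scenario id (`"INTACT"`, `"Q1"`..`"Q5"`) or
#'   [scenario_spec()].
#' @param driver a [driver_spec()].
#' @param settings an [fdk_settings()].
#' @param max_failed_fraction abort (with a diagnostic summary) when more
#'   than this fraction of steps fails to converge.
#' @return object of class `abduction_trace`: a per-step data.frame in
#'   `$steps` (time, angle, translations in mm, per-muscle forces in N,
#'   contact force components/magnitude in N, residual, converged) plus
#'   the scenario id and run metadata. Failed steps carry `NA` forces.
#' @seealso [summary.abduction_trace()], [plot.abduction_trace()],
#'   [residuals.abduction_trace()]
#' @export
run_abduction_sweep <- function(model, scenario = "INTACT",
                                driver = driver_spec(),
                                settings = fdk_settings(),
                                max_failed_fraction = 0.5) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  m <- apply_scenario(model, scenario)
  grid <- time_grid(driver)
  mus <- names(m$muscles)
  n <- nrow(grid)

  steps <- data.frame(t = grid$t, angle = grid$angle,
                      u_AP = NA_real_, u_SI = NA_real_, u_ML = NA_real_)
  for (nm in mus) steps[[paste0("F_", nm)]] <- NA_real_
  steps$F_contact_AP <- NA_real_
  steps$F_contact_SI <- NA_real_
  steps$F_contact_ML <- NA_real_
  steps$F_contact <- NA_real_
  steps$residual <- NA_real_
  steps$converged <- FALSE

  u_prev <- c(0, 0, 0)
  for (i in seq_len(n)) {
    u0 <- if (settings$warm_start) u_prev else c(0, 0, 0)
    res <- fdk_solve_step(m, grid$angle[i], u0 = u0, settings = settings)
    steps$residual[i] <- res$residual_norm
    steps$converged[i] <- res$converged
    if (res$converged) {
      u <- res$state$translation
      u_prev <- u
      steps[i, c("u_AP", "u_SI", "u_ML")] <- u * 1e3
      fr <- res$recruitment$forces
      for (nm in mus) steps[[paste0("F_", nm)]][i] <- fr[[nm]]
      fc <- res$contact$force_on_master
      steps$F_contact_AP[i] <- fc[1]
      steps$F_contact_SI[i] <- fc[2]
      steps$F_contact_ML[i] <- fc[3]
      steps$F_contact[i] <- sqrt(sum(fc^2))
    }
  }

  failed <- sum(!steps$converged)
  if (failed > max_failed_fraction * n) {
    stop(sprintf(
      "abduction sweep aborted: %d of %d steps failed to converge (worst residual %.3g N)",
      failed, n, max(steps$residual, na.rm = TRUE)))
  }

  structure(list(steps = steps, scenario = scenario$id, muscles = mus,
                 settings = settings, driver = driver),
            class = "abduction_trace")
}

#' @export
print.abduction_trace <- function(x, ...) {
  s <- x$steps
  cat(sprintf("abduction_trace [%s]: %d steps, %d converged\n",
              x$scenario, nrow(s), sum(s$converged)))
  ok <- s$converged
  if (any(ok)) {
    cat(sprintf("  angle range  : %.1f to %.1f deg\n",
                min(s$angle), max(s$angle)))
    cat(sprintf("  peak contact : %.1f N at %.1f deg\n",
                max(s$F_contact[ok]), s$angle[ok][which.max(s$F_contact[ok])]))
    cat(sprintf("  max residual : %.3g N (tolerance %g N)\n",
                max(s$residual[ok]), x$settings$tolerance))
  }
  invisible(x)
}

#' @export
as.data.frame.abduction_trace <- function(x, ...) x$steps

#' FDK residual norms of a sweep
#'
#' @param object an `abduction_trace`.
#' @param ... unused.
#' @return numeric vector of per-step residual-force norms (N).
#' @export
residuals.abduction_trace <- function(object, ...) object$steps$residual

#' Summary of one abduction sweep
#'
#' Per-muscle peak force with the angle at which it occurs, plus the
#' contact-force peak.
#'
#' @param object an `abduction_trace`.
#' @param ... unused.
#' @return object of class `summary.abduction_trace`.
#' @export
summary.abduction_trace <- function(object, ...) {
  s <- object$steps[object$steps$converged, , drop = FALSE]
  pk <- function(col) {
    i <- which.max(s[[col]])
    c(peak = s[[col]][i], angle = s$angle[i])
  }
  mus <- do.call(rbind, lapply(object$muscles, function(nm)
    pk(paste0("F_", nm))))
  rownames(mus) <- object$muscles
  out <- list(scenario = object$scenario,
              muscle_peaks = as.data.frame(mus),
              contact_peak = pk("F_contact"),
              n_steps = nrow(object$steps),
              n_converged = sum(object$steps$converged))
  class(out) <- "summary.abduction_trace"
  out
}

#' @export
print.summary.abduction_trace <- function(x, ...) {
  cat(sprintf("Sweep summary [%s]: %d/%d steps converged\n",
              x$scenario, x$n_converged, x$n_steps))
  cat("Peak muscle forces (N):\n")
  print(round(x$muscle_peaks, 1))
  cat(sprintf("Peak GH contact force: %.1f N at %.1f deg\n",
              x$contact_peak["peak"], x$contact_peak["angle"]))
  invisible(x)
}

#' Quick-look plot of a sweep
#'
#' Base-graphics panels of muscle forces and GH contact force against
#' abduction angle.
#'
#' @param x an `abduction_trace`.
#' @param muscles muscle names to draw (default: all non-zero).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.abduction_trace <- function(x, muscles = NULL, ...) {
  s <- x$steps
  if (is.null(muscles)) {
    peak <- vapply(x$muscles, function(nm)
      max(s[[paste0("F_", nm)]], na.rm = TRUE), 0)
    muscles <- x$muscles[peak > 1]
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(max(length(muscles), 2L), "Dark 3")
  graphics::matplot(s$angle, as.matrix(s[paste0("F_", muscles)]),
                    type = "l", lty = 1, col = cols,
                    xlab = "abduction (deg)", ylab = "muscle force (N)",
                    main = x$scenario, ...)
  graphics::legend("topleft", legend = muscles, col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  graphics::plot(s$angle, s$F_contact, type = "l",
                 xlab = "abduction (deg)", ylab = "GH contact force (N)",
                 main = "contact")
  invisible(x)
}

#' Percent change of a quantity relative to a reference
#'
#' @param reference reference (intact) value.
#' @param value scenario value.
#' @return 100 * (value - reference) / reference.
#' @export
percent_change <- function(reference, value) {
  100 * (value - reference) / reference
}

#' Cross-scenario summary statistics
#'
#' Peak forces per muscle and scenario, GH contact force interpolated at
#' query angles (default 78 degrees, the standard reporting angle for
#' these simulations), and percent changes relative to the intact cuff —
#' both at peak and at the query angles, since both conventions appear in
#' the literature.
#'
#' @param traces named list of `abduction_trace` objects; must contain
#'   `INTACT`. All traces must share the same angle grid.
#' @param query_angles angles (degrees) at which contact force is
#'   reported by linear interpolation.
#' @return object of class `sweep_summary` with data.frames
#'   `muscle_peaks` (scenario x muscle), `contact_at_angle`,
#'   `contact_peaks`, `pct_change_peaks`, `pct_change_at_angle`.
#' @export
summarize_sweeps <- function(traces, query_angles = 78) {
  if (!"INTACT" %in% names(traces))
    stop("summaries require an INTACT trace as reference")
  grids <- lapply(traces, function(tr) tr$steps$angle)
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), TRUE)))
    stop("all traces must share the same angle grid")

  mus <- traces[[1]]$muscles
  peak_of <- function(tr, col) {
    s <- tr$steps[tr$steps$converged, , drop = FALSE]
    max(s[[col]])
  }
  at_angle <- function(tr, col, a) {
    s <- tr$steps[tr$steps$converged, , drop = FALSE]
    stats::approx(s$angle, s[[col]], xout = a, rule = 1)$y
  }

  muscle_peaks <- matrix(0, length(traces), length(mus),
                         dimnames = list(names(traces), mus))
  for (i in seq_along(traces))
    for (j in seq_along(mus))
      muscle_peaks[i, j] <- peak_of(traces[[i]], paste0("F_", mus[j]))
  contact_peaks <- vapply(traces, peak_of, 0, col = "F_contact")
  contact_at_angle <- do.call(rbind, lapply(traces, function(tr)
    vapply(query_angles, function(a) at_angle(tr, "F_contact", a), 0)))
  dimnames(contact_at_angle) <- list(names(traces),
                                     paste0("deg_", query_angles))

  pct_peaks <- sweep_pct(contact_peaks, contact_peaks["INTACT"])
  pct_at <- apply(contact_at_angle, 2, function(col)
    sweep_pct(col, col["INTACT"]))
  muscle_pct <- muscle_peaks
  for (j in seq_len(ncol(muscle_peaks))) {
    r <- muscle_peaks["INTACT", j]
    muscle_pct[, j] <- if (r > 0) 100 * (muscle_peaks[, j] - r) / r else
      NA_real_
  }

  structure(list(
    muscle_peaks = as.data.frame(muscle_peaks),
    muscle_pct_change = as.data.frame(muscle_pct),
    contact_peaks = contact_peaks,
    contact_at_angle = as.data.frame(contact_at_angle),
    pct_change_peaks = pct_peaks,
    pct_change_at_angle = as.data.frame(pct_at),
    query_angles = query_angles), class = "sweep_summary")
}

sweep_pct <- function(v, ref) 100 * (v - ref) / ref

#' @export
print.sweep_summary <- function(x, ...) {
  cat("Cross-scenario summary\n\nPeak muscle forces (N):\n")
  print(round(x$muscle_peaks, 1))
  cat("\nGH contact force at query angle(s) (N):\n")
  print(round(x$contact_at_angle, 1))
  cat("\nPercent change of GH contact force vs INTACT (at query angles):\n")
  print(round(x$pct_change_at_angle, 1))
  invisible(x)
}

#' Root-mean-square error between two force-vs-angle curves
#'
#' Curve `b` is linearly resampled onto the angle grid of `a` restricted
#' to the overlap of the two ranges.
#'
#' @param a,b data.frames with columns `angle` (degrees) and `force` (N).
#' @return RMSE in N.
#' @export
rmse_curves <- function(a, b) {
  lo <- max(min(a$angle), min(b$angle))
  hi <- min(max(a$angle), max(b$angle))
  if (hi <= lo) stop("angle ranges of the two curves do not overlap")
  keep <- a$angle >= lo & a$angle <= hi
  if (!any(keep)) stop("no grid points of the first curve in the overlap")
  bi <- stats::approx(b$angle, b$force, xout = a$angle[keep])$y
  sqrt(mean((a$force[keep] - bi)^2))
}

#' Compare a simulated contact-force curve with a reference CSV
#'
#' The reference file must have columns `angle` (degrees) and `force`
#' (N); no third-party in-vivo data ships with the package.
#'
#' @param trace an `abduction_trace`.
#' @param ref_path path to the reference CSV.
#' @param column trace column to compare (default the contact-force
#'   magnitude).
#' @return RMSE in N.
#' @export
compare_with_reference <- function(trace, ref_path, column = "F_contact") {
  ref <- utils::read.csv(ref_path)
  if (!all(c("angle", "force") %in% names(ref)))
    stop("reference CSV needs columns 'angle' and 'force'")
  s <- trace$steps[trace$steps$converged, , drop = FALSE]
  rmse_curves(data.frame(angle = s$angle, force = s[[column]]), ref)
}

#' Sensitivity sweep over key modelling parameters
#'
#' Re-runs reduced INTACT abduction sweeps while varying one parameter at
#' a time — the contact pressure module `P_V`, the recruitment criterion
#' order, and the number of analysis steps — and reports the percent
#' change of the peak GH contact force relative to the base
#' configuration. Cells whose sub-run aborts are reported as failed
#' rather than stopping the sweep.
#'
#' @param config base configuration list (see [default_config()]).
#' @param grid named list of parameter values, e.g.
#'   `list(P_V = c(1.37e11, 5.48e11), criterion_order = 3, n_steps = 46)`.
#' @param n_steps step count for the reduced sweeps (default 31).
#' @param settings an [fdk_settings()].
#' @return data.frame with columns `parameter`, `value`,
#'   `peak_contact_N`, `pct_change`, `failed`.
#' @export
sensitivity_sweep <- function(config = default_config(),
                              grid = list(P_V = c(1.37e11, 5.48e11),
                                          criterion_order = 3,
                                          n_steps = c(46, 181)),
                              n_steps = 31,
                              settings = fdk_settings()) {
  run_peak <- function(cfg, steps) {
    model <- shoulder_model(cfg)
    tr <- run_abduction_sweep(model, "INTACT",
                              driver = driver_spec(n_steps = steps),
                              settings = settings)
    max(tr$steps$F_contact[tr$steps$converged])
  }
  base_peak <- run_peak(config, n_steps)
  rows <- list(data.frame(parameter = "base", value = NA_real_,
                          peak_contact_N = base_peak, pct_change = 0,
                          failed = FALSE))
  for (par in names(grid)) {
    for (val in grid[[par]]) {
      cfg <- config
      steps <- n_steps
      if (par == "P_V") cfg$contact$P_V <- val
      else if (par == "criterion_order") cfg$recruitment$criterion_order <- val
      else if (par == "n_steps") steps <- val
      else stop("unknown sensitivity parameter: ", par)
      pk <- tryCatch(run_peak(cfg, steps), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, value = val, peak_contact_N = pk,
        pct_change = if (is.na(pk)) NA_real_ else
          percent_change(base_peak, pk),
        failed = is.na(pk))
    }
  }
  do.call(rbind, rows)
}

#' Write one trace per scenario plus a summary to a directory
#'
#' @param traces named list of `abduction_trace` objects.
#' @param dir output directory (created if needed).
#' @param query_angles passed to [summarize_sweeps()].
#' @return the directory path, invisibly.
#' @export
write_sweep_outputs <- function(traces, dir, query_angles = 78) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(traces))
    utils::write.csv(traces[[nm]]$steps,
                     file.path(dir, paste0("trace_", nm, ".csv")),
                     row.names = FALSE)
  sm <- summarize_sweeps(traces, query_angles)
  utils::write.csv(cbind(scenario = rownames(sm$muscle_peaks),
                         sm$muscle_peaks),
                   file.path(dir, "summary_muscle_peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(scenario = names(sm$contact_peaks),
                              peak_contact_N = sm$contact_peaks,
                              sm$contact_at_angle,
                              pct_change_peak = sm$pct_change_peaks,
                              sm$pct_change_at_angle,
                              check.names = FALSE),
                   file.path(dir, "summary_contact.csv"), row.names = FALSE)
  invisible(dir)
}
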