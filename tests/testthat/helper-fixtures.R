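# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default model (meshes are the expensive part; build once).
default_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- shoulder_model()
  .fixture_env$model
}

# Full-resolution sweep over all six scenarios, shared between the FDK
# convergence checks and the qualitative trend suite.
default_traces <- function() {
  if (is.null(.fixture_env$traces)) {
    model <- default_model()
    ids <- c("INTACT", "Q1", "Q2", "Q3", "Q4", "Q5")
    .fixture_env$traces <- setNames(
      lapply(ids, function(id) run_abduction_sweep(model, id)), ids)
  }
  .fixture_env$traces
}

# Coarse sweep for cheap pipeline checks.
coarse_trace <- function(scenario = "INTACT", n_steps = 11) {
  key <- paste0("coarse_", scenario, "_", n_steps)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_abduction_sweep(
      default_model(), scenario, driver = driver_spec(n_steps = n_steps))
  .fixture_env[[key]]
}

# Hand-built trace objects with prescribed curves, for summary/RMSE
# arithmetic tests that need no simulation.
synthetic_trace <- function(scenario, angles, contact, muscle_forces = NULL) {
  steps <- data.frame(t = angles, angle = angles)
  if (!is.null(muscle_forces))
    for (nm in names(muscle_forces)) steps[[paste0("F_", nm)]] <-
      muscle_forces[[nm]]
  steps$F_contact <- contact
  steps$residual <- 0
  steps$converged <- TRUE
  structure(list(steps = steps, scenario = scenario,
                 muscles = if (is.null(muscle_forces)) character(0) else
                   names(muscle_forces),
                 settings = fdk_settings(), driver = NULL),
            class = "abduction_trace")
}
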