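SCENARIO_TABLE <- list(
  INTACT = character(0),
  Q1 = "infraspinatus",
  Q2 = "supraspinatus",
  Q3 = c("supraspinatus", "infraspinatus"),
  Q4 = "subscapularis",
  Q5 = c("supraspinatus", "infraspinatus", "subscapularis", "teres_minor")
)

#' Rotator-cuff deficiency scenarios
#'
#' The intact cuff plus the five deficiency situations studied for ATSA:
#' Q1 infraspinatus; Q2 supraspinatus; Q3 supraspinatus + infraspinatus;
#' Q4 subscapularis; Q5 supraspinatus + infraspinatus + subscapularis +
#' teres minor. In a deficient muscle the activation is lost: its force
#' upper bound is zero while the muscle stays in the model, so traces
#' report an explicit 0 N.
#'
#' @param id one of `"INTACT"`, `"Q1"` ... `"Q5"`.
#' @return object of class `scenario_spec` with elements `id` and
#'   `deficient_muscles`.
#' @export
scenario_spec <- function(id = c("INTACT", "Q1", "Q2", "Q3", "Q4", "Q5")) {
  id <- match.arg(id)
  structure(list(id = id, deficient_muscles = SCENARIO_TABLE[[id]]),
            class = "scenario_spec")
}

#' Apply a deficiency scenario to a shoulder model
#'
#' Returns a copy of the model in which the scenario's muscles are marked
#' deficient (force capacity zero); everything else is unchanged and the
#' input model is not modified. Application is idempotent and composes:
#' applying Q2 after Q1 yields the Q3 deficiency set.
#'
#' @param model a [shoulder_model()].
#' @param scenario a [scenario_spec()] or a scenario id string.
#' @return modified copy of `model`.
#' @export
apply_scenario <- function(model, scenario) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  unknown <- setdiff(scenario$deficient_muscles, names(model$muscles))
  if (length(unknown))
    stop("scenario names unknown muscle(s): ", paste(unknown, collapse = ", "))
  for (nm in scenario$deficient_muscles)
    model$muscles[[nm]]$deficient <- TRUE
  model
}
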