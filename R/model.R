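#' @keywords internal
"_PACKAGE"

# Units: SI throughout (m, kg, N, N*m, s); angles in degrees at every
# user-facing boundary, converted once on entry.
#
# Coordinate convention (right shoulder, origin at the GH joint center):
#   x = AP, anterior positive
#   y = SI, superior positive
#   z = ML, lateral positive
# The triad is right handed (AP x SI = ML). Abduction elevates the arm in
# the frontal (SI-ML) plane: the humeral long axis moves from -SI at 0
# degrees to +ML at 90 degrees.

SPECIFIC_TENSION <- 27      # N/cm^2, isometric strength per unit PCSA
GRAVITY <- c(0, -9.81, 0)   # m/s^2 in the GH frame

REQUIRED_MUSCLES <- c("deltoideus_clavicular", "deltoideus_scapular",
                      "supraspinatus", "infraspinatus", "subscapularis",
                      "teres_minor")

#' Local reference frame at the glenohumeral joint center
#'
#' @param origin position of the GH joint center (m).
#' @param axes 3 x 3 matrix whose columns are the AP, SI and ML axes;
#'   must be right-handed orthonormal.
#' @return object of class `gh_frame`.
#' @export
gh_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  if (max(abs(crossprod(axes) - diag(3))) > 1e-12)
    stop("frame axes are not orthonormal")
  if (det(axes) < 0) stop("frame is not right-handed")
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "gh_frame")
}

#' Isometric muscle strength from physiological cross-sectional area
#'
#' Strength is PCSA times the specific tension of 27 N/cm^2, applied
#' uniformly to all muscles.
#'
#' @param pcsa physiological cross-sectional area, cm^2 (positive).
#' @return isometric strength, N.
#' @export
muscle_strength <- function(pcsa) {
  if (any(pcsa <= 0)) stop("pcsa must be positive")
  SPECIFIC_TENSION * pcsa
}

#' Linear capsule-spring restraint force
#'
#' The passive restriction of the joint capsule and ligaments is lumped
#' into one linear spring acting on the humeral head center:
#' \eqn{F = -k (u - u_{rest})}.
#'
#' @param u glenohumeral translation 3-vector (m).
#' @param spring list with `stiffness` (N/m) and `rest_point` (m), as
#'   stored in a [shoulder_model()].
#' @return restoring force 3-vector, N.
#' @export
spring_force <- function(u, spring) {
  -spring$stiffness * (as.numeric(u) - spring$rest_point)
}

#' Glenohumeral state: driven angle plus released translations
#'
#' @param abduction_angle degrees (0 to 90 within a sweep).
#' @param translation released GH translation u = (u_AP, u_SI, u_ML), m.
#' @return object of class `gh_state`.
#' @export
gh_state <- function(abduction_angle = 0, translation = c(0, 0, 0)) {
  structure(list(abduction_angle = abduction_angle,
                 translation = as.numeric(translation)),
            class = "gh_state")
}

# Rotation carrying humerus-local coordinates (arm hanging, long axis -SI)
# to the GH frame at `angle_deg` of frontal-plane abduction.
abduction_rotation <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3)
}

# World position of a muscle path point given the state.
anchor_position <- function(point, segment, state) {
  if (segment == "humerus") {
    drop(abduction_rotation(state$abduction_angle) %*% point) +
      state$translation
  } else {
    point       # scapula/clavicle/thorax anchors are fixed in the GH frame
  }
}

validate_muscle <- function(m) {
  if (is.null(m$name) || !nzchar(m$name)) stop("muscle without a name")
  if (is.null(m$pcsa) || m$pcsa <= 0)
    stop(sprintf("muscle '%s': pcsa must be positive", m$name))
  if (nrow(m$path) < 2L)
    stop(sprintf("muscle '%s': path needs at least 2 points", m$name))
  if (length(m$segment) != nrow(m$path))
    stop(sprintf("muscle '%s': one segment label per path point", m$name))
  if (!any(m$segment == "humerus"))
    stop(sprintf("muscle '%s': no humeral attachment", m$name))
  if (!any(m$segment != "humerus"))
    stop(sprintf("muscle '%s': no non-humeral attachment", m$name))
  m$strength <- muscle_strength(m$pcsa)
  if (is.null(m$deficient)) m$deficient <- FALSE
  if (is.null(m$group)) m$group <- "other"
  m
}

#' Assemble and validate a shoulder model
#'
#' Builds the full quasi-static model description from a configuration
#' list (see [default_config()]): implant meshes, muscle set with
#' strengths recomputed from PCSA, capsule spring, lumped arm segment and
#' contact parameters. All six principal abduction-relevant muscles
#' (`deltoideus_clavicular`, `deltoideus_scapular`, `supraspinatus`,
#' `infraspinatus`, `subscapularis`, `teres_minor`) must be present.
#'
#' @param config configuration list; defaults to [default_config()].
#' @return object of class `shoulder_model`.
#' @export
shoulder_model <- function(config = default_config()) {
  cfg <- config
  spec <- implant_spec(head_diameter = cfg$implant$head_diameter,
                       mismatch = cfg$implant$mismatch,
                       insert_thickness = cfg$implant$insert_thickness,
                       coverage_angle = cfg$implant$coverage_angle,
                       mesh_resolution = cfg$implant$mesh_resolution)
  meshes <- build_implant_meshes(spec)

  muscle_tab <- if (is.null(cfg$muscles)) default_muscle_fixture() else
    cfg$muscles
  muscles <- muscle_table_to_list(muscle_tab)
  muscles <- lapply(muscles, validate_muscle)
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  if (anyDuplicated(names(muscles))) stop("muscle names must be unique")
  missing <- setdiff(REQUIRED_MUSCLES, names(muscles))
  if (length(missing))
    stop("required muscle(s) missing from configuration: ",
         paste(missing, collapse = ", "))

  arm <- list(name = "arm", mass = cfg$arm$mass,
              com = as.numeric(cfg$arm$com))
  if (arm$mass <= 0) stop("arm mass must be positive")

  spring <- list(stiffness = cfg$spring$stiffness,
                 rest_point = as.numeric(cfg$spring$rest_point))
  if (spring$stiffness <= 0) stop("spring stiffness must be positive")

  contact <- contact_params(P_V = cfg$contact$P_V, eps_o = cfg$contact$eps_o,
                            p_o = cfg$contact$p_o, n = cfg$contact$n,
                            v = cfg$contact$v,
                            h = spec$insert_thickness * 1e-3)

  structure(list(
    gh_frame = gh_frame(),
    arm = arm,
    muscles = muscles,
    head_mesh = meshes$head,
    insert_mesh = meshes$insert,
    implant = spec,
    contact = contact,
    spring = spring,
    gravity = GRAVITY,
    rhythm = if (is.null(cfg$rhythm)) 1.0 else cfg$rhythm,
    recruitment = list(
      criterion_order = if (is.null(cfg$recruitment$criterion_order)) 2L
                        else as.integer(cfg$recruitment$criterion_order))
  ), class = "shoulder_model")
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat("ATSA shoulder model (quasi-static, FDK-released GH translations)\n")
  cat(sprintf("  implant : head %g mm / insert %g mm (mismatch %g mm)\n",
              x$implant$head_diameter,
              x$implant$head_diameter + x$implant$mismatch,
              x$implant$mismatch))
  defc <- sum(vapply(x$muscles, `[[`, FALSE, "deficient"))
  cat(sprintf("  muscles : %d (%d deficient)\n", length(x$muscles), defc))
  cat(sprintf("  spring  : k = %.3g N/m\n", x$spring$stiffness))
  cat(sprintf("  contact : P_V = %.3g N/m^3\n", x$contact$P_V))
  cat(sprintf("  arm     : %.1f kg at %.2f m\n", x$arm$mass,
              sqrt(sum(x$arm$com^2))))
  invisible(x)
}

muscle_table_to_list <- function(tab) {
  tab <- as.data.frame(tab)
  need <- c("muscle", "point_index", "segment", "x", "y", "z", "pcsa")
  if (!all(need %in% names(tab)))
    stop("muscle table must have columns ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$muscle), function(d) {
    d <- d[order(d$point_index), ]
    list(name = as.character(d$muscle[1]),
         path = as.matrix(d[, c("x", "y", "z")]),
         segment = as.character(d$segment),
         pcsa = d$pcsa[1],
         group = if ("group" %in% names(d)) as.character(d$group[1]) else
           "other",
         deficient = FALSE)
  })
}

#' Default model configuration
#'
#' All defaults correspond to the reference ATSA setup: 48 mm head, 8 mm
#' diametral mismatch, capsule spring of 1.74e4 N/m, contact pressure
#' module 2.74e11 N/m^3, quadratic recruitment criterion, and a 4 kg
#' lumped arm segment with its center of mass 0.30 m down the humeral
#' axis.
#'
#' @return nested configuration list understood by [shoulder_model()].
#' @export
default_config <- function() {
  list(
    implant = list(head_diameter = 48, mismatch = 8, insert_thickness = 5,
                   coverage_angle = 60, mesh_resolution = 2000),
    arm = list(mass = 4.0, com = c(0, -0.30, 0)),
    spring = list(stiffness = 1.74e4, rest_point = c(0, 0, 0)),
    contact = list(P_V = 2.74e11, eps_o = 0.0597, p_o = 18.4, n = 3,
                   v = 0.46),
    recruitment = list(criterion_order = 2),
    rhythm = 1.0,
    muscles = NULL    # NULL -> default_muscle_fixture()
  )
}

#' Read / write a model configuration as YAML
#'
#' The configuration file mirrors [default_config()]; missing keys fall
#' back to the defaults. The muscle table may be given inline (list of
#' rows) or as a path to a fixture CSV relative to the config file.
#'
#' @param path file path.
#' @param config configuration list.
#' @return `read_config` returns a configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_defaults(default_config(), user)
  if (is.character(cfg$muscles)) {
    mp <- cfg$muscles
    if (!file.exists(mp))
      mp <- file.path(dirname(path), cfg$muscles)
    cfg$muscles <- read_muscle_fixture(mp)
  } else if (is.list(cfg$muscles)) {
    cfg$muscles <- do.call(rbind, lapply(cfg$muscles, as.data.frame))
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- config
  if (is.data.frame(cfg$muscles)) {
    rows <- split(cfg$muscles, seq_len(nrow(cfg$muscles)))
    cfg$muscles <- lapply(rows, as.list)
    names(cfg$muscles) <- NULL
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

modify_defaults <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])) && k != "muscles") {
      base[[k]] <- modify_defaults(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}
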