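#' Implant geometry specification
#'
#' Articular geometry of the anatomic prosthesis: a spherical humeral
#' head against a concave polyethylene insert whose radius of curvature
#' exceeds the head radius by half the *diametral* mismatch (the standard
#' convention for this implant family; the convention is isolated here).
#' With the default 48 mm head and 8 mm mismatch the insert articular
#' radius is 28 mm.
#'
#' @param head_diameter humeral head diameter, mm.
#' @param mismatch diametral curvature mismatch, mm (>= 0).
#' @param insert_thickness polyethylene insert thickness, mm.
#' @param coverage_angle half-opening angle of the insert's spherical cap,
#'   degrees.
#' @param mesh_resolution target triangle count per generated surface.
#' @return object of class `implant_spec`.
#' @export
implant_spec <- function(head_diameter = 48, mismatch = 8,
                         insert_thickness = 5, coverage_angle = 60,
                         mesh_resolution = 2000) {
  if (head_diameter <= 0) stop("head_diameter must be positive")
  if (mismatch < 0) stop("mismatch must be nonnegative")
  if (insert_thickness <= 0) stop("insert_thickness must be positive")
  structure(list(head_diameter = head_diameter, mismatch = mismatch,
                 insert_thickness = insert_thickness,
                 coverage_angle = coverage_angle,
                 mesh_resolution = mesh_resolution,
                 head_radius = head_diameter / 2,
                 insert_radius = (head_diameter + mismatch) / 2),
            class = "implant_spec")
}

#' Generate head and insert meshes for an implant specification
#'
#' The head is a spherical cap of 120 degrees half-angle about the medial
#' (-ML) axis centred on the (translated) GH joint center. The insert cup
#' is fixed on the glenoid side with its center of curvature displaced
#' laterally by (insert radius - head radius) so that at zero translation
#' the two surfaces are exactly tangent at the medial pole, the gap
#' opening with the mismatch away from the pole.
#'
#' Mesh generation is deterministic: the same spec always yields the same
#' mesh.
#'
#' @param spec an [implant_spec()].
#' @return list with [trimesh()] elements `head` and `insert`, plus
#'   `cup_center` (m).
#' @export
build_implant_meshes <- function(spec) {
  R_h <- spec$head_radius * 1e-3
  R_c <- spec$insert_radius * 1e-3
  cup_center <- c(0, 0, R_c - R_h)
  head <- sphere_cap_mesh(R_h, center = c(0, 0, 0), axis = c(0, 0, -1),
                          cap_angle = 120,
                          target_faces = spec$mesh_resolution,
                          concave = FALSE)
  insert <- sphere_cap_mesh(R_c, center = cup_center, axis = c(0, 0, -1),
                            cap_angle = spec$coverage_angle,
                            target_faces = spec$mesh_resolution,
                            concave = TRUE)
  list(head = head, insert = insert, cup_center = cup_center)
}

#' Default muscle-attachment fixture
#'
#' Synthetic straight-line attachment geometry for the six principal
#' muscles of the reduced shoulder model plus two antagonists
#' (pectoralis_major, latissimus_dorsi) that keep the three-component
#' moment balance solvable when the whole cuff is deficient. Coordinates
#' are in the GH frame (m): scapula/clavicle anchors fixed, humeral
#' anchors in humerus-local coordinates with the arm hanging (long axis
#' -SI). PCSA values (cm^2) follow literature-style magnitudes with the
#' scapular deltoid largest; signed moment arms over 0-90 degrees of
#' abduction are anatomically plausible by construction: the scapular
#' deltoid is the prime abductor, supraspinatus a weak abductor with
#' strong compression, infraspinatus/teres minor external rotators and
#' subscapularis an internal rotator (opposite axial moment signs).
#'
#' @return data.frame with columns `muscle`, `point_index`, `segment`,
#'   `x`, `y`, `z`, `pcsa`, `group`.
#' @export
default_muscle_fixture <- function() {
  row <- function(muscle, idx, segment, x, y, z, pcsa, group)
    data.frame(muscle = muscle, point_index = idx, segment = segment,
               x = x, y = y, z = z, pcsa = pcsa, group = group)
  rbind(
    # origin (fixed), insertion (humerus-local)
    row("deltoideus_clavicular", 1, "clavicle", 0.025, 0.042, 0.018, 8, "deltoid"),
    row("deltoideus_clavicular", 2, "humerus", 0.006, -0.120, 0.010, 8, "deltoid"),
    row("deltoideus_scapular", 1, "scapula", -0.005, 0.045, 0.030, 20, "deltoid"),
    row("deltoideus_scapular", 2, "humerus", 0.000, -0.130, 0.012, 20, "deltoid"),
    row("supraspinatus", 1, "scapula", 0.000, 0.022, -0.045, 6, "rotator_cuff"),
    row("supraspinatus", 2, "humerus", 0.000, 0.012, 0.021, 6, "rotator_cuff"),
    row("infraspinatus", 1, "scapula", -0.030, -0.005, -0.048, 9, "rotator_cuff"),
    row("infraspinatus", 2, "humerus", -0.014, 0.004, 0.018, 9, "rotator_cuff"),
    row("subscapularis", 1, "scapula", 0.030, -0.008, -0.018, 16, "rotator_cuff"),
    row("subscapularis", 2, "humerus", 0.019, 0.012, 0.012, 16, "rotator_cuff"),
    row("teres_minor", 1, "scapula", -0.026, -0.038, -0.042, 3, "rotator_cuff"),
    row("teres_minor", 2, "humerus", -0.012, -0.010, 0.016, 3, "rotator_cuff"),
    row("pectoralis_major", 1, "thorax", 0.050, -0.030, -0.060, 12, "other"),
    row("pectoralis_major", 2, "humerus", 0.008, -0.050, 0.008, 12, "other"),
    row("latissimus_dorsi", 1, "thorax", -0.040, -0.090, -0.060, 10, "other"),
    row("latissimus_dorsi", 2, "humerus", 0.004, -0.045, 0.006, 10, "other")
  )
}

#' Read / write a muscle-attachment fixture CSV
#'
#' Columns: `muscle`, `point_index`, `segment`, `x`, `y`, `z`, `pcsa`,
#' and optionally `group`.
#'
#' @param table fixture data.frame (see [default_muscle_fixture()]).
#' @param path CSV path.
#' @return `read_muscle_fixture` returns the fixture data.frame;
#'   `write_muscle_fixture` returns `path` invisibly.
#' @export
write_muscle_fixture <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_muscle_fixture
#' @export
read_muscle_fixture <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Library of degenerate toy models for solver verification
#'
#' Closed-form-solvable reductions of the full model used by the FDK and
#' recruitment test batteries:
#' \describe{
#' \item{spring_only}{no muscles, no contact; a constant external force
#'   against the capsule spring, equilibrium at u = F/k.}
#' \item{single_muscle}{one muscle, one moment equation; recruitment has
#'   a unique feasible point.}
#' \item{two_muscle_symmetric}{two identical muscles sharing one moment
#'   equation; the polynomial criterion must split the load equally.}
#' \item{zero_gravity_contact}{head and insert tangent at the pole,
#'   capsule spring, no muscles, no gravity; the FDK fixed point is
#'   u = 0 by symmetry.}
#' }
#'
#' @param external_force constant external force (N) applied to the
#'   humerus in the `spring_only` toy.
#' @return named list of toy models / systems.
#' @export
toy_models <- function(external_force = c(10, 0, 0)) {
  spring <- list(stiffness = 1.74e4, rest_point = c(0, 0, 0))
  spring_only <- structure(
    list(kind = "spring_only", spring = spring,
         external_force = as.numeric(external_force)),
    class = c("toy_model", "shoulder_toy"))

  single_muscle <- list(
    kind = "single_muscle",
    system = equilibrium_system(
      moment_arms = matrix(0.02, 1, 1),
      external_moment = -10,
      strengths = 1000))

  two_muscle_symmetric <- list(
    kind = "two_muscle_symmetric",
    system = equilibrium_system(
      moment_arms = matrix(c(0.02, 0.02), 1, 2),
      external_moment = -10,
      strengths = c(1000, 1000)))

  spec <- implant_spec(mesh_resolution = 1500)
  meshes <- build_implant_meshes(spec)
  zero_gravity_contact <- structure(
    list(kind = "zero_gravity_contact", spring = spring,
         head_mesh = meshes$head, insert_mesh = meshes$insert,
         contact = contact_params(), external_force = c(0, 0, 0)),
    class = c("toy_model", "shoulder_toy"))

  list(spring_only = spring_only,
       single_muscle = single_muscle,
       two_muscle_symmetric = two_muscle_symmetric,
       zero_gravity_contact = zero_gravity_contact)
}
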