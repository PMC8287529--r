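test_that("spherical-cap mesh area matches the analytic cap area", {
  R <- 0.024
  for (theta in c(60, 120)) {
    m <- sphere_cap_mesh(R, cap_angle = theta, target_faces = 10000)
    analytic <- 2 * pi * R^2 * (1 - cos(theta * pi / 180))
    expect_gt(nrow(m$faces), 10000)
    expect_lt(abs(mesh_area(m) - analytic) / analytic, 0.01)
  }
})

test_that("vertex areas and normals satisfy the quadrature invariants", {
  m <- sphere_cap_mesh(0.028, center = c(0, 0, 0.004), cap_angle = 60,
                       target_faces = 1500, concave = TRUE)
  # per-vertex areas sum exactly to the total surface area
  fa_total <- sum(atsasim:::face_areas(m$vertices, m$faces))
  expect_lt(abs(sum(m$vertex_area) - fa_total) / fa_total, 1e-9)
  # unit normals, pointing toward the center of a concave cup
  expect_lt(max(abs(sqrt(rowSums(m$vertex_normal^2)) - 1)), 1e-9)
  to_center <- sweep(-m$vertices, 2, c(0, 0, 0.004), "+")
  to_center <- to_center / sqrt(rowSums(to_center^2))
  expect_lt(max(abs(m$vertex_normal - to_center)), 1e-9)
})

test_that("mesh generation is deterministic and validates resolution", {
  a <- sphere_cap_mesh(0.024, target_faces = 500)
  b <- sphere_cap_mesh(0.024, target_faces = 500)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_error(sphere_cap_mesh(0.024, target_faces = 50), "resolution")
  expect_error(sphere_cap_mesh(-1), "radius")
})

test_that("implant spec applies the diametral mismatch convention", {
  spec <- implant_spec()
  expect_equal(spec$head_radius, 24)
  expect_equal(spec$insert_radius, 28)
  conforming <- implant_spec(mismatch = 0)
  expect_equal(conforming$insert_radius, conforming$head_radius)
  expect_error(implant_spec(mismatch = -1), "mismatch")
})

test_that("generated implant surfaces are tangent at the pole when u = 0", {
  for (mm in c(0, 8)) {
    meshes <- build_implant_meshes(implant_spec(mismatch = mm))
    d <- vertex_penetration(meshes$insert, meshes$head)
    expect_true(all(d == 0))
    # tangency: the gap closes quadratically at the pole, so the nearest
    # vertex sits within the curvature sag of one mesh edge
    gaps <- abs(sqrt(rowSums(meshes$insert$vertices^2)) - 0.024)
    expect_lt(min(gaps), 2e-6)
    if (mm == 0) expect_lt(max(gaps), 1e-12)  # conforming limit: zero gap
  }
})

test_that("STL files round-trip through both flavours", {
  m <- sphere_cap_mesh(0.024, cap_angle = 60, target_faces = 300)
  for (bin in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(m, path, binary = bin)
    r <- read_stl(path)
    expect_equal(nrow(r$faces), nrow(m$faces))
    expect_equal(nrow(r$vertices), nrow(m$vertices))
    tol <- if (bin) 1e-6 else 1e-8    # float32 binary / %.9e ASCII
    expect_lt(abs(mesh_area(r) - mesh_area(m)) / mesh_area(m), tol)
  }
})

test_that("default muscle fixture has the required actuators and signs", {
  tab <- default_muscle_fixture()
  required <- c("deltoideus_clavicular", "deltoideus_scapular",
                "supraspinatus", "infraspinatus", "subscapularis",
                "teres_minor")
  expect_true(all(required %in% tab$muscle))
  # deltoid carries the largest PCSA
  pcsa <- tapply(tab$pcsa, tab$muscle, unique)
  expect_equal(names(which.max(pcsa)), "deltoideus_scapular")

  model <- default_model()
  st <- gh_state(30)
  # the scapular deltoid abducts
  expect_gt(elevation_moment_arm(model, "deltoideus_scapular", st), 0)
  # internal vs external rotators have opposite axial moment arms
  expect_lt(axial_moment_arm(model, "subscapularis", st) *
              axial_moment_arm(model, "infraspinatus", st), 0)
  # cuff elevation moment arms are small next to the deltoid's
  for (nm in c("supraspinatus", "infraspinatus", "subscapularis"))
    expect_lt(abs(elevation_moment_arm(model, nm, st)),
              elevation_moment_arm(model, "deltoideus_scapular", st))
})

test_that("muscle fixture CSV round-trips", {
  tab <- default_muscle_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_muscle_fixture(tab, path)
  back <- read_muscle_fixture(path)
  expect_equal(back$muscle, tab$muscle)
  expect_equal(back$x, tab$x, tolerance = 1e-12)
  expect_equal(back$pcsa, tab$pcsa)
})
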