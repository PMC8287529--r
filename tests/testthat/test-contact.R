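test_that("uniform-depth contact reproduces the analytic overlap volume", {
  # conforming cup (R = 24 mm) against a head inflated by d = 0.5 mm with
  # the same center: every cup vertex penetrates by exactly d
  d <- 0.5e-3
  cup <- sphere_cap_mesh(0.024, cap_angle = 60, target_faces = 10000,
                         concave = TRUE)
  head <- sphere_cap_mesh(0.024 + d, cap_angle = 120, target_faces = 500)
  cr <- contact_force(cup, head)
  expect_equal(unname(range(cr$depth)), c(d, d), tolerance = 1e-12)

  params <- contact_params()
  V_analytic <- d * 2 * pi * 0.024^2 * (1 - cos(pi / 3))
  expect_lt(abs(cr$total_force - params$P_V * V_analytic) /
              (params$P_V * V_analytic), 0.02)
  # the vector resultant carries the cosine projection of the cap
  F_analytic <- params$P_V * d * pi * 0.024^2 * sin(pi / 3)^2
  expect_lt(abs(sqrt(sum(cr$resultant_force^2)) - F_analytic) / F_analytic,
            0.02)
  # force law identities hold exactly on the quadrature
  expect_equal(cr$force, params$P_V * cr$volume, tolerance = 1e-12)
  expect_equal(cr$resultant_force,
               colSums(-cup$vertex_normal * cr$force), tolerance = 1e-12)
})

test_that("sphere-in-cup penetration matches the closed form", {
  # concentric 24 mm head in a 28 mm cup, pushed 4.5 mm toward the pole:
  # 0.5 mm max depth at the pole, zero at the rim side
  cup <- sphere_cap_mesh(0.028, cap_angle = 60, target_faces = 4000,
                         concave = TRUE)
  head <- sphere_cap_mesh(0.024, cap_angle = 120, target_faces = 500)
  pose <- rigid_pose(translation = c(0, 0, -4.5e-3))
  d <- vertex_penetration(cup, head, pose)
  expect_equal(max(d), 0.5e-3, tolerance = 1e-6)
  i <- which.max(d)
  expect_lt(sqrt(sum(cup$vertices[i, 1:2]^2)), 2e-3)  # at the pole
  # per-vertex closed form: d = max(0, R_h - |x - c|)
  r <- sqrt(rowSums(sweep(cup$vertices, 2, c(0, 0, -4.5e-3))^2))
  expect_equal(d, pmax(0.024 - r, 0), tolerance = 1e-15)
})

test_that("separated or tangent surfaces carry no contact force", {
  meshes <- build_implant_meshes(implant_spec(mesh_resolution = 1000))
  expect_true(all(vertex_penetration(meshes$insert, meshes$head) == 0))
  away <- rigid_pose(translation = c(0, 0, 1e-4))
  cr <- contact_force(meshes$insert, meshes$head, away)
  expect_equal(cr$resultant_force, c(0, 0, 0))
  expect_equal(cr$contact_area, 0)
})

test_that("contact force is linear in the pressure module", {
  meshes <- build_implant_meshes(implant_spec(mesh_resolution = 1000))
  pose <- rigid_pose(translation = c(0, 0, -2e-4))
  a <- contact_force(meshes$insert, meshes$head, pose, contact_params())
  b <- contact_force(meshes$insert, meshes$head, pose,
                     contact_params(P_V = 2 * 2.74e11))
  expect_equal(b$resultant_force, 2 * a$resultant_force, tolerance = 1e-12)
})

test_that("resultant converges to the analytic value under refinement", {
  d <- 0.5e-3
  params <- contact_params()
  V_analytic <- d * 2 * pi * 0.024^2 * (1 - cos(pi / 3))
  errs <- vapply(c(500, 2000, 8000), function(res) {
    cup <- sphere_cap_mesh(0.024, cap_angle = 60, target_faces = res,
                           concave = TRUE)
    head <- sphere_cap_mesh(0.024 + d, cap_angle = 120, target_faces = 500)
    cr <- contact_force(cup, head, params = params)
    abs(cr$total_force - params$P_V * V_analytic) / (params$P_V * V_analytic)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("force vanishes continuously as penetration shrinks", {
  cup <- sphere_cap_mesh(0.028, cap_angle = 60, target_faces = 2000,
                         concave = TRUE)
  head <- sphere_cap_mesh(0.024, cap_angle = 120, target_faces = 500)
  # from concentric tangency-to-penetration: |u| = 4 mm is first touch
  depths <- c(4.2e-3, 4.05e-3, 4.01e-3, 4.001e-3)
  mags <- vapply(depths, function(dz) {
    cr <- contact_force(cup, head, rigid_pose(translation = c(0, 0, -dz)))
    sqrt(sum(cr$resultant_force^2))
  }, 0)
  expect_true(all(diff(mags) < 0))
  expect_lt(mags[length(mags)] / mags[1], 0.01)
})

test_that("swapping slave and master respects Newton's third law", {
  cup <- sphere_cap_mesh(0.028, cap_angle = 60, target_faces = 2000,
                         concave = TRUE)
  head <- sphere_cap_mesh(0.024, cap_angle = 120, target_faces = 2000)
  pose <- rigid_pose(translation = c(0, 0, -4.3e-3))
  a <- contact_force(cup, head, pose)$resultant_force
  # swapped roles: pose the cup relative to a fixed head instead
  head0 <- sphere_cap_mesh(0.024, cap_angle = 120, target_faces = 2000)
  cup_moved <- sphere_cap_mesh(0.028, center = c(0, 0, 4.3e-3),
                               cap_angle = 60, target_faces = 2000,
                               concave = TRUE)
  b <- contact_force(head0, cup_moved, rigid_pose())$resultant_force
  expect_lt(sqrt(sum((a + b)^2)) / sqrt(sum(a^2)), 0.05)
})

test_that("pressure module matches an independent high-precision oracle", {
  # frozen 40-digit evaluations of the elastic-foundation expression
  oracle <- rbind(
    c(0.3, 0.003, 9.2, 484044152385.86087),
    c(0.3, 0.005, 18.4, 663831980414.89488),
    c(0.3, 0.008, 36.8, 1348408710217.7552),
    c(0.4, 0.003, 18.4, 1761186886815.0276),
    c(0.4, 0.005, 36.8, 3434314429289.3037),
    c(0.4, 0.008, 9.2, 288944723618.09048),
    c(0.46, 0.005, 18.4, 2279892613753.7007),
    c(0.46, 0.003, 36.8, 12349418324499.212),
    c(0.46, 0.008, 18.4, 1424932883596.0629))
  for (i in seq_len(nrow(oracle))) {
    p <- contact_params(v = oracle[i, 1], h = oracle[i, 2])
    got <- pressure_module(p, reference_pressure = oracle[i, 3])
    expect_lt(abs(got - oracle[i, 4]) / oracle[i, 4], 1e-10)
  }
})

test_that("pressure module degenerate cases behave as specified", {
  # n = 1: the nonlinearity bracket collapses to 2 for any pressure
  p1 <- contact_params(n = 1, v = 0.46, h = 5e-3)
  conf <- (1 - 0.46) / ((1 + 0.46) * (1 - 2 * 0.46))
  base <- conf / 5e-3 * (2 * 18.4e6 / 0.0597)
  for (pi_ref in c(1, 18.4, 50))
    expect_equal(pressure_module(p1, pi_ref), 2 * base, tolerance = 1e-12)
  expect_error(contact_params(v = 0.5), "Poisson")
  expect_error(contact_params(h = 0), "thickness")
  expect_error(pressure_module(contact_params(), -1), "positive")
  # the shipped default is the precomputed constant, not an Eq-derived one
  expect_equal(contact_params()$P_V, 2.74e11)
})

test_that("contact diagnostics dump has the documented schema", {
  meshes <- build_implant_meshes(implant_spec(mesh_resolution = 1000))
  cr <- contact_force(meshes$insert, meshes$head,
                      rigid_pose(translation = c(0, 0, -2e-4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contact_diagnostics(cr, path)
  df <- read.csv(path)
  expect_named(df, c("vertex_id", "d_i", "A_i", "V_i", "F_i"))
  expect_equal(nrow(df), nrow(meshes$insert$vertices))
  expect_equal(df$V_i, df$d_i * df$A_i, tolerance = 1e-12)
})
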