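test_that("moment arms follow the cross-product definition", {
  model <- default_model()
  # hand-computed check at 0 and 35 degrees for every muscle
  for (ang in c(0, 35)) {
    st <- gh_state(ang, translation = c(0, 0, 0))
    R <- moment_arms(model, st)
    for (nm in names(model$muscles)) {
      m <- model$muscles[[nm]]
      rot <- atsasim:::abduction_rotation(ang)
      ins <- drop(rot %*% m$path[2, ])
      dir <- m$path[1, ] - ins
      dir <- dir / sqrt(sum(dir^2))
      expect_equal(unname(R[, nm]), unname(atsasim:::cross3(ins, dir)),
                   tolerance = 1e-12)
    }
  }
})

test_that("a muscle acting through the joint center has no moment", {
  tab <- default_muscle_fixture()
  extra <- data.frame(
    muscle = "central", point_index = 1:2,
    segment = c("scapula", "humerus"),
    x = c(0, 0), y = c(0.05, 0.025), z = c(0, 0),
    pcsa = 5, group = "other")
  cfg <- default_config()
  cfg$implant$mesh_resolution <- 500
  cfg$muscles <- rbind(tab, extra)
  model <- shoulder_model(cfg)
  R <- moment_arms(model, gh_state(0))
  expect_equal(unname(R[, "central"]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("translating the state shifts moment arms consistently", {
  model <- default_model()
  u <- c(1e-3, -2e-3, 0.5e-3)
  st <- gh_state(20, translation = u)
  R <- moment_arms(model, st)
  for (nm in c("deltoideus_scapular", "subscapularis")) {
    m <- model$muscles[[nm]]
    rot <- atsasim:::abduction_rotation(20)
    ins <- drop(rot %*% m$path[2, ]) + u
    dir <- m$path[1, ] - ins
    dir <- dir / sqrt(sum(dir^2))
    expect_equal(unname(R[, nm]), unname(atsasim:::cross3(ins, dir)),
                   tolerance = 1e-12)
  }
})

test_that("zero-length joint-crossing segments are reported by name", {
  tab <- default_muscle_fixture()
  bad <- data.frame(
    muscle = "degenerate", point_index = 1:2,
    segment = c("scapula", "humerus"),
    x = c(0.01, 0.01), y = c(0.02, 0.02), z = c(0.005, 0.005),
    pcsa = 5, group = "other")
  cfg <- default_config()
  cfg$implant$mesh_resolution <- 500
  cfg$muscles <- rbind(tab, bad)
  model <- shoulder_model(cfg)
  expect_error(moment_arms(model, gh_state(0)), "degenerate")
})

test_that("recruitment reproduces closed-form solutions", {
  toys <- toy_models()
  # one muscle, one equation: unique feasible point f = M / r
  s1 <- solve_recruitment(toys$single_muscle$system)
  expect_equal(unname(s1$forces), 500, tolerance = 1e-6)
  expect_equal(s1$status, "optimal")
  # two identical muscles split the load equally
  s2 <- solve_recruitment(toys$two_muscle_symmetric$system)
  expect_equal(unname(s2$forces), c(250, 250), tolerance = 1e-6)
  # Lagrange closed form f_i = M r_i N_i^2 / sum r_j^2 N_j^2
  s3 <- solve_recruitment(
    equilibrium_system(matrix(c(0.02, 0.01), 1, 2), -10, c(1000, 1000)))
  expect_equal(unname(s3$forces), c(400, 200), tolerance = 1e-6)
  expect_lt(s3$residual, 1e-9)
})

test_that("recruitment matches the brute-force oracle on random instances", {
  set.seed(7)
  for (k in 1:40) {
    n <- sample(2:3, 1)
    m <- sample(1:min(2, n - 1), 1)
    inst <- random_recruitment_instance(n, m)
    sol <- solve_recruitment(inst$system)
    expect_equal(sol$status, "optimal")
    oracle <- recruitment_oracle(inst$R, inst$system$M_ext, inst$N)
    expect_lt(abs(sol$objective - oracle) / max(oracle, 1e-8), 1e-4)
  }
})

test_that("zeroing any muscle's bound never decreases the objective", {
  set.seed(11)
  for (k in 1:30) {
    inst <- random_recruitment_instance(3, sample(1:2, 1))
    base <- solve_recruitment(inst$system)
    for (j in 1:3) {
      sys_d <- equilibrium_system(inst$R, inst$system$M_ext, inst$N,
                                  deficient = seq_len(3) == j)
      sol_d <- solve_recruitment(sys_d)
      if (sol_d$status == "optimal")
        expect_gte(sol_d$objective, base$objective - 1e-8)
    }
  }
})

test_that("activations scale inversely with a uniform strength factor", {
  # interior-solution regime: bounds inactive before and after scaling
  R <- matrix(c(0.02, 0.015, -0.01,
                0.005, -0.01, 0.02), 2, 3, byrow = TRUE)
  N <- c(800, 900, 700)
  sys1 <- equilibrium_system(R, c(-6, -4), N)
  sys2 <- equilibrium_system(R, c(-6, -4), 3 * N)
  a1 <- solve_recruitment(sys1)$activations
  a2 <- solve_recruitment(sys2)$activations
  expect_equal(a2, a1 / 3, tolerance = 1e-4)
})

test_that("infeasibility is reported, not raised", {
  # positive moment demanded from muscles that can only pull negative
  sys <- equilibrium_system(matrix(c(0.02, 0.01), 1, 2), 10, c(100, 100))
  sol <- solve_recruitment(sys)
  expect_equal(sol$status, "infeasible")
  expect_true(all(sol$forces == 0))
  # a deficient-only system balances nothing but a zero moment
  sys0 <- equilibrium_system(matrix(0.02, 1, 1), 0, 500, deficient = TRUE)
  expect_equal(solve_recruitment(sys0)$status, "optimal")
})

test_that("malformed systems are rejected", {
  expect_error(equilibrium_system(matrix(1, 3, 2), c(0, 0, 0), c(1, 2, 3)),
               "dimension")
  expect_error(equilibrium_system(matrix(1, 2, 2), c(0, 0, 0), c(1, 2)),
               "dimension")
  expect_error(equilibrium_system(matrix(NaN, 1, 1), 0, 1), "finite")
  expect_error(solve_recruitment(
    equilibrium_system(matrix(0.02, 1, 1), -10, 500), criterion_order = 1),
    "order")
})

test_that("higher criterion orders concentrate load less", {
  # with unequal moment arms, raising p pushes the split toward equal
  # activations; the constraint is still satisfied
  sys <- equilibrium_system(matrix(c(0.02, 0.01), 1, 2), -10, c(1000, 1000))
  s2 <- solve_recruitment(sys, 2)
  s4 <- solve_recruitment(sys, 4)
  expect_lt(sqrt(sum((sys$R %*% s4$forces + sys$M_ext)^2)), 1e-5)
  gap2 <- abs(diff(s2$activations))
  gap4 <- abs(diff(s4$activations))
  expect_lt(gap4, gap2)
})
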