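test_that("the eight cube corners are the pure equilibria and rest points", {
  eq <- pure_equilibria()
  expect_equal(dim(eq), c(8L, 3L))
  expect_identical(rownames(eq), paste0("E", 1:8))
  expect_equal(unname(eq["E3", ]), c(0, 1, 0))
  expect_equal(unname(eq["E8", ]), c(1, 1, 1))
  expect_identical(pure_equilibria(), pure_equilibria())
  for (p in random_scenarios(10, seed = 31)) {
    for (i in 1:8) {
      expect_equal(unname(replicator_field(p, eq[i, ])), c(0, 0, 0))
    }
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  params <- random_scenarios(20, seed = 32)
  states <- random_states(20, seed = 33, lo = 0.1, hi = 0.9)
  for (i in seq_along(params)) {
    Ja <- replicator_jacobian(params[[i]], states[i, ])
    Jn <- fd_jacobian(params[[i]], states[i, ])
    expect_equal(unname(Ja), Jn, tolerance = 1e-5)
  }
  # off-diagonal entries vanish on the x-faces
  p <- baseline_params()
  expect_equal(replicator_jacobian(p, c(0, 0.4, 0.6))[1, 2:3],
               c(y = 0, z = 0))
  expect_equal(replicator_jacobian(p, c(1, 0.4, 0.6))[1, 2:3],
               c(y = 0, z = 0))
})

test_that("baseline Jacobian diagonal at the accept/loose corner", {
  J <- replicator_jacobian(baseline_params(), c(0, 1, 0))
  expect_equal(unname(diag(J)), c(-25, -6, -10))
  expect_equal(unname(J[upper.tri(J) | lower.tri(J)]), rep(0, 6))
})

test_that("closed-form corner eigenvalues equal the numeric eigendecomposition", {
  params <- random_scenarios(30, seed = 34)
  corners <- pure_equilibria()
  for (p in params) {
    for (lbl in rownames(corners)) {
      ev_closed <- sort(unname(corner_eigenvalues(p, lbl)))
      ev_num <- sort(Re(eigen(replicator_jacobian(p, corners[lbl, ]),
                              only.values = TRUE)$values))
      expect_equal(ev_closed, ev_num, tolerance = 1e-8)
    }
  }
  # homogeneity: all-zero parameters give zero eigenvalues
  p0 <- game_params(.values = stats::setNames(rep(0, 21), param_names()))
  expect_equal(unname(corner_eigenvalues(p0, "E5")), c(0, 0, 0))
  expect_error(corner_eigenvalues(baseline_params(), c(0.5, 1, 0)), "corner")
})

test_that("baseline is bistable: exactly E3 and E8 are ESS", {
  rep <- classify_equilibria(baseline_params())
  ess <- rep$point[rep$class == "ESS"]
  expect_identical(sort(ess), c("E3", "E8"))
  expect_identical(rep$class[!rep$point %in% c("E3", "E8")],
                   rep("unstable", 6))
  e3 <- rep[rep$point == "E3", ]
  expect_equal(c(e3$lambda_x, e3$lambda_y, e3$lambda_z), c(-25, -6, -10))
  e8 <- rep[rep$point == "E8", ]
  expect_equal(sort(c(e8$lambda_x, e8$lambda_y, e8$lambda_z)),
               sort(c(-35, -10, -114)))
})

test_that("raising the opportunistic gain above the penalty destabilizes E8", {
  rep <- classify_equilibria(game_params(A = 70))
  e8 <- rep[rep$point == "E8", ]
  expect_identical(e8$class, "unstable")
  expect_equal(e8$lambda_x, 10)  # A - K2 = 70 - 60
})

test_that("classes are exclusive and critical cases are reported, not guessed", {
  for (p in random_scenarios(15, seed = 35)) {
    rep <- classify_equilibria(p)
    expect_true(all(rep$class %in% c("ESS", "unstable", "critical")))
  }
  # H5 = 40 makes H4 - H5 - R2 = 0: E8 is non-hyperbolic
  rep <- classify_equilibria(game_params(H5 = 40))
  expect_identical(rep$class[rep$point == "E8"], "critical")
})

test_that("condition checks carry the baseline values and flip termwise", {
  cc <- check_ess_conditions(baseline_params())
  expect_equal(cc$value, c(-6, -10, -35, -10, -114))
  expect_true(all(cc$satisfied))

  cc2 <- check_ess_conditions(game_params(H4 = 120))
  bad <- cc2[!cc2$satisfied, ]
  expect_identical(bad$inequality, "H4 - H5 - R2 < 0")
  expect_equal(bad$value, 10)
})

test_that("condition sets and the classification agree on random scenarios", {
  for (p in random_scenarios(25, seed = 36)) {
    cc <- check_ess_conditions(p)
    rep <- classify_equilibria(p)
    ess <- rep$point[rep$class == "ESS"]
    if (attr(cc, "condition1")) expect_true("E3" %in% ess)
    if (attr(cc, "condition2")) expect_true("E8" %in% ess)
    if ("E3" %in% ess) expect_true(attr(cc, "condition1"))
    if ("E8" %in% ess) expect_true(attr(cc, "condition2"))
  }
  for (p in random_scenarios(15, seed = 37, enforce = "both")) {
    ess <- with(classify_equilibria(p), point[class == "ESS"])
    expect_true(all(c("E3", "E8") %in% ess))
  }
})

test_that("trajectories return to an ESS and leave unstable corners", {
  p <- baseline_params()
  rep <- classify_equilibria(p)
  corners <- pure_equilibria()
  for (lbl in c("E3", "E8")) {
    s0 <- corners[lbl, ] * (1 - 2e-3) + 1e-3  # radius ~1e-3, interior
    tr <- integrate_game(p, s0 = s0)
    expect_identical(tr$terminal_corner, lbl)
  }
  # unstable corner: kick E1 along its (all-positive) unstable directions
  tr <- integrate_game(p, s0 = c(1e-3, 1e-3, 1e-3), horizon = 100)
  expect_gt(max(abs(tr$terminal - corners["E1", ])), 0.1)
})

test_that("interior rest points are absent at baseline and never ESS", {
  inter <- interior_equilibria(baseline_params())
  expect_equal(nrow(inter), 0L)
  rep <- classify_equilibria(baseline_params(), interior = TRUE)
  expect_true(!is.null(attr(rep, "interior")))
})

test_that("stability JSON report carries corners, eigenvalues and conditions", {
  rep <- classify_equilibria(baseline_params())
  path <- tempfile(fileext = ".json")
  write_stability_json(rep, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(got$equilibria), 8L)
  expect_true(got$conditions$condition1)
  expect_true(got$conditions$condition2)
})
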