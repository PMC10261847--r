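test_that("replicator field matches hand-computed baseline values", {
  p <- baseline_params()
  f <- replicator_field(p, c(0.5, 0.5, 0.5))
  # brackets (20, 68, 171) scaled by 0.25
  expect_equal(unname(f), c(5, 17, 42.75))
  expect_equal(unname(replicator_field_payoff(p, c(0.5, 0.5, 0.5))),
               c(5, 17, 42.75), tolerance = 1e-12)
})

test_that("faces and corners of the cube are invariant", {
  p <- baseline_params()
  expect_equal(replicator_field(p, c(0, 0.3, 0.8))[["dx"]], 0)
  expect_equal(replicator_field(p, c(1, 0.3, 0.8))[["dx"]], 0)
  expect_equal(unname(replicator_field(p, c(0, 1, 0))), c(0, 0, 0))
  expect_error(replicator_field(p, c(-0.1, 0.5, 0.5)), "unit cube")
})

test_that("closed-form field equals the payoff-table field on random inputs", {
  params <- random_scenarios(40, seed = 21)
  states <- random_states(25, seed = 22, lo = 0, hi = 1)
  worst <- 0
  for (p in params) {
    for (i in seq_len(nrow(states))) {
      f1 <- replicator_field(p, states[i, ])
      f2 <- replicator_field_payoff(p, states[i, ])
      scale <- max(1, max(abs(f1)))
      worst <- max(worst, max(abs(f1 - f2)) / scale)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("field does not depend on the parameters that cancel out", {
  # D, E, R1, H1, H3 appear in the payoff table but cancel in the
  # replicator equations
  p <- baseline_params()
  q <- game_params(D = 1234, E = 7, R1 = 0, H1 = 999, H3 = 55.5)
  states <- random_states(20, seed = 23, lo = 0, hi = 1)
  for (i in seq_len(nrow(states))) {
    expect_identical(replicator_field(p, states[i, ]),
                     replicator_field(q, states[i, ]))
  }
})

test_that("threshold surfaces vanish on the matching brackets and report poles", {
  p <- baseline_params()
  th <- thresholds(p)
  expect_equal(th$z_tangent, 25 / 60)
  expect_equal(th$y_star(25 / 60), 1)            # tangent to the top face
  expect_equal(th$y_star(0.5), 7 / 6)            # may exceed 1; callers clip
  expect_equal(th$y_double_star(0.5), 1)

  # the hospital threshold has a pole at z = 12/32 at the baseline
  v <- th$x_star(c(0.2, 0.375, 0.9))
  expect_true(is.nan(v[2]))
  expect_identical(attr(v, "singular_at"), 2L)
  expect_false(anyNA(v[c(1, 3)]))

  # defining property G(y*) = 0, J(x*) = 0, M(y**) = 0
  params <- random_scenarios(20, seed = 24)
  set.seed(240)
  for (q in params) {
    tq <- thresholds(q)
    z <- runif(1)
    x <- runif(1)
    ys <- tq$y_star(z)
    xs <- tq$x_star(z)
    yds <- tq$y_double_star(x)
    a <- q[["alpha"]]
    if (!is.nan(ys)) {
      G <- ys * (a * q[["V2"]] - a * q[["V1"]]) + a * q[["V1"]] -
        a * q[["V2"]] - z * q[["K2"]] + q[["A"]]
      expect_equal(G, 0, tolerance = 1e-9)
    }
    if (!is.nan(xs)) {
      J <- z * (xs * a * q[["P2"]] - xs * a * q[["P1"]] + xs * q[["B"]] -
                  q[["B"]] - a * q[["P2"]]) +
        xs * (a * q[["W1"]] - a * q[["W2"]]) + a * q[["W2"]] - a * q[["H2"]]
      expect_equal(J, 0, tolerance = 1e-8)
    }
    if (!is.nan(yds)) {
      M <- q[["H4"]] - q[["R2"]] - q[["K1"]] - q[["K2"]] - q[["H5"]] -
        q[["T"]] - a * q[["P2"]] -
        x * (a * q[["P1"]] - a * q[["P2"]] - q[["K2"]]) -
        yds * (x * (q[["B"]] + a * q[["P2"]] - a * q[["P1"]]) -
                 q[["B"]] - a * q[["P2"]] - q[["K1"]] - q[["T"]])
      expect_equal(M, 0, tolerance = 1e-8)
    }
  }
})

test_that("monotonicity of the stability functions holds by differencing", {
  # G increasing in y, J decreasing in x, M increasing in y
  params <- random_scenarios(15, seed = 25)
  for (p in params) {
    a <- p[["alpha"]]
    G <- function(y, z) y * (a * p[["V2"]] - a * p[["V1"]]) +
      a * p[["V1"]] - a * p[["V2"]] - z * p[["K2"]] + p[["A"]]
    J <- function(x, z) z * (x * a * p[["P2"]] - x * a * p[["P1"]] +
                               x * p[["B"]] - p[["B"]] - a * p[["P2"]]) +
      x * (a * p[["W1"]] - a * p[["W2"]]) + a * p[["W2"]] - a * p[["H2"]]
    expect_gte(G(0.8, 0.3) - G(0.2, 0.3), 0)
    # J is affine in x; its slope is -(z(aP1 - aP2 - B) + a(W2 - W1)) and
    # is negative only where that coefficient is positive (at the baseline,
    # for z below the pole 12/32)
    z <- 0.3
    c_x <- z * (a * p[["P1"]] - a * p[["P2"]] - p[["B"]]) +
      a * (p[["W2"]] - p[["W1"]])
    expect_equal(sign(J(0.8, z) - J(0.2, z)), -sign(c_x))
    # government: bracket gz is decreasing in y, so M = -gz is increasing
    gz <- function(y) replicator_field(p, c(0.4, y, 0.5))[["dz"]] / 0.25
    expect_lte(gz(0.9) - gz(0.1), 0)
  }
})

test_that("sign law: the allocator drifts up below the acceptance threshold", {
  params <- random_scenarios(15, seed = 26)
  set.seed(260)
  for (p in params) {
    th <- thresholds(p)
    z <- runif(1)
    ys <- th$y_star(z)
    if (is.nan(ys)) next
    for (dy in c(-0.1, 0.1)) {
      y <- min(max(ys + dy, 0.01), 0.99)
      f <- replicator_field(p, c(0.5, y, z))
      if (y < ys) expect_gt(f[["dx"]], 0) else if (y > ys) {
        expect_lt(f[["dx"]], 0)
      }
    }
    # hospital: crossing x* flips the drift of y; the orientation follows
    # the sign of the bracket's x-coefficient (the hospital bracket is not
    # globally decreasing in x for every z)
    xs <- th$x_star(z)
    a <- p[["alpha"]]
    c_x <- z * (a * p[["P1"]] - a * p[["P2"]] - p[["B"]]) +
      a * (p[["W2"]] - p[["W1"]])
    if (!is.nan(xs) && abs(c_x) > 1e-9) {
      for (dx in c(-0.1, 0.1)) {
        x <- min(max(xs + dx, 0.01), 0.99)
        f <- replicator_field(p, c(x, 0.5, z))
        if (x != xs) expect_equal(sign(f[["dy"]]), sign(c_x * (x - xs)))
      }
    }
    # government: below y** the government drifts toward strict supervision
    x <- runif(1)
    yds <- th$y_double_star(x)
    if (!is.nan(yds)) {
      for (dy in c(-0.1, 0.1)) {
        y <- min(max(yds + dy, 0.01), 0.99)
        f <- replicator_field(p, c(x, y, 0.5))
        if (y < yds) expect_gt(f[["dz"]], 0) else if (y > yds) {
          expect_lt(f[["dz"]], 0)
        }
      }
    }
  }
})

test_that("baseline trajectory converges to one of the two stable corners", {
  tr <- integrate_game(baseline_params())
  expect_true(tr$converged)
  expect_true(tr$terminal_corner %in% c("E3", "E8"))
  expect_true(all(tr$states$x >= 0 & tr$states$x <= 1))
  expect_true(all(tr$states$y >= 0 & tr$states$y <= 1))
  expect_true(all(tr$states$z >= 0 & tr$states$z <= 1))
  expect_lt(tr$clamp_excess, 1e-9)
  expect_true(!is.unsorted(tr$states$t, strictly = TRUE))
})

test_that("corner starts are stationary and tolerances do not move the result", {
  p <- baseline_params()
  tr <- integrate_game(p, s0 = c(0, 1, 0))
  expect_equal(unname(tr$terminal), c(0, 1, 0))
  expect_equal(max(abs(tr$states$x)), 0)

  t1 <- integrate_game(p)
  t2 <- integrate_game(p, rtol = 5e-9, atol = 5e-11)
  expect_equal(unname(t1$terminal), unname(t2$terminal), tolerance = 1e-6)
})

test_that("trajectory CSV export round-trips with a metadata sidecar", {
  tr <- integrate_game(baseline_params(), horizon = 5)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  got <- utils::read.csv(path)
  expect_equal(got$x, tr$states$x)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$params$K1, 80)
  expect_equal(meta$terminal_corner, tr$terminal_corner)
})
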