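test_that("the three-factor BBD has the canonical run structure", {
  d <- bbd_design(n_center = 5)
  expect_identical(nrow(d), 17L)
  X <- as.matrix(d[, c("x1", "x2", "x3")])
  non_center <- X[rowSums(X != 0) > 0, ]
  expect_identical(nrow(non_center), 12L)
  expect_true(all(rowSums(non_center == 0) == 1))
  expect_true(all(abs(non_center[non_center != 0]) == 1))
  expect_equal(unname(colSums(X)), c(0, 0, 0))
  expect_identical(sum(rowSums(X != 0) == 0), 5L)
  # actual-unit columns follow the factor specs
  expect_equal(range(d$first_liquid_solid_ratio), c(7, 9))
  expect_equal(range(d$first_extraction_time), c(30, 60))
  expect_error(bbd_design(n_center = 0), "n_center")
  expect_error(bbd_design(list(factor_spec("a", 0, 1))), "exactly 3")
})

test_that("linear desirability maps bounds to 0/1 and clips supplied bounds", {
  y <- c(2, 5, 8)
  d <- desirability(y)
  expect_equal(d, c(0, 0.5, 1))
  ds <- desirability(c(-1, 5, 20), ymin = 0, ymax = 10)
  expect_equal(ds, c(0, 0.5, 1))
  expect_error(desirability(y, ymin = 5, ymax = 5), "degenerate")
  expect_error(desirability(y, ymin = 5), "both")
})

test_that("overall desirability is the geometric mean with zero propagation", {
  expect_equal(overall_desirability(cbind(1, 1, 1)), 1)
  expect_equal(overall_desirability(cbind(0, 0.9, 0.8)), 0)
  expect_equal(overall_desirability(cbind(0.25, 1, 1)), 0.25^(1 / 3),
               tolerance = 1e-12)
  set.seed(5)
  d <- matrix(runif(30), nrow = 10)
  od <- overall_desirability(d)
  expect_true(all(od <= apply(d, 1, max) + 1e-12))
  expect_true(all(od >= apply(d, 1, min) - 1e-12))
  expect_equal(overall_desirability(d[, 3:1]), od)
  expect_error(overall_desirability(cbind(-0.1, 1)), "non-negative")
})

test_that("run 6 scores zero desirability under observed bounds", {
  t2 <- table2()
  d <- sapply(c("CAGC", "CAC", "TSR"), function(cl) desirability(t2[[cl]]))
  expect_equal(unname(d[6, "CAGC"]), 0)  # observed minimum
  expect_equal(overall_desirability(d)[6], 0)
  expect_equal(overall_desirability(d)[17], 0)
})

test_that("quadratic fit recovers a noiseless surface exactly", {
  surf <- true_surface(0.8612, c(0.3228, 0.1158, 0.1248),
                       c(-0.1440, -0.1435, -0.0205),
                       c(-0.2179, -0.0159, -0.0058), noise_sd = 0)
  des <- bbd_design()
  y <- make_bbd_responses(surf, des)
  m <- fit_quadratic(des, y)
  expect_equal(unname(m$coefficients), unname(surf$beta),
               tolerance = 1e-10)
  # saturated-fit ANOVA is flagged rather than reporting nonsense
  expect_true(attr(m$anova, "saturated"))
  expect_identical(m$anova$F[m$anova$source == "model"], Inf)
})

test_that("BBD orthogonality identities hold against the OLS solution", {
  t2 <- table2()
  des <- table2_design()
  m <- fit_quadratic(des, t2$OD)
  ctr <- t2$x1 == 0 & t2$x2 == 0 & t2$x3 == 0
  expect_equal(m$coefficients[["b0"]], mean(t2$OD[ctr]), tolerance = 1e-10)
  for (j in 1:3) {
    xj <- t2[[paste0("x", j)]]
    contrast <- (sum(t2$OD[xj == 1]) - sum(t2$OD[xj == -1])) / 8
    expect_equal(m$coefficients[[paste0("b", j)]], contrast,
                 tolerance = 1e-10)
  }
  # interaction contrast: the 4 runs where both factors are active
  b12 <- sum(t2$OD * t2$x1 * t2$x2) / 4
  expect_equal(m$coefficients[["b12"]], b12, tolerance = 1e-10)
})

test_that("ANOVA partitions pure error from the center replicates", {
  t2 <- table2()
  m <- fit_quadratic(table2_design(), t2$OD)
  a <- m$anova
  ctr <- t2$OD[t2$x1 == 0 & t2$x2 == 0 & t2$x3 == 0]
  expect_equal(a$SS[a$source == "pure_error"],
               sum((ctr - mean(ctr))^2), tolerance = 1e-12)
  expect_identical(a$df[a$source == "pure_error"], 4)
  expect_identical(a$df[a$source == "lack_of_fit"], 3)
  expect_equal(a$SS[a$source == "residual"],
               a$SS[a$source == "pure_error"] +
                 a$SS[a$source == "lack_of_fit"], tolerance = 1e-12)
  expect_equal(a$SS[a$source == "total"],
               a$SS[a$source == "model"] + a$SS[a$source == "residual"],
               tolerance = 1e-12)
})

test_that("constrained maximization is exact for a concave separable model", {
  surf <- true_surface(2, c(0, 0, 0), c(0, 0, 0), c(-1, -1, -1))
  des <- bbd_design()
  m <- fit_quadratic(des, make_bbd_responses(surf, des))
  opt <- optimize_quadratic(m)
  expect_equal(opt$coded, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(opt$predicted, 2, tolerance = 1e-9)
  # and lands on the boundary when the stationary point lies outside
  surf2 <- true_surface(1, c(1, 0, 0), c(0, 0, 0), c(-0.1, -0.1, -0.1))
  m2 <- fit_quadratic(des, make_bbd_responses(surf2, des))
  opt2 <- optimize_quadratic(m2)
  expect_equal(opt2$coded[1], 1, tolerance = 1e-9)
})

test_that("the optimum dominates a dense grid over the cube", {
  m <- fit_quadratic(table2_design(), table2()$OD)
  opt <- optimize_quadratic(m)
  gr <- seq(-1, 1, length.out = 101)
  grid <- as.matrix(expand.grid(gr, gr, gr))
  vals <- herbqc:::eval_quadratic(m$coefficients, grid)
  expect_gte(opt$predicted, max(vals) - 1e-9)
})

test_that("prediction codes actual units and warns on extrapolation", {
  m <- fit_quadratic(table2_design(), table2()$OD)
  expect_equal(predict(m, c(8, 45, 30)), m$coefficients[["b0"]],
               tolerance = 1e-12)
  # coded (1,-1,0) equals direct polynomial arithmetic
  beta <- m$coefficients
  direct <- beta[["b0"]] + beta[["b1"]] - beta[["b2"]] - beta[["b12"]] +
    beta[["b11"]] + beta[["b22"]]
  expect_equal(predict(m, c(9, 30, 30)), direct, tolerance = 1e-12)
  expect_equal(predict(m, c(1, -1, 0), coded = TRUE), direct,
               tolerance = 1e-12)
  expect_warning(predict(m, c(12, 45, 30)), "outside")
  # a purely linear model predicts linearly
  surf <- true_surface(1, c(0.5, 0, 0), c(0, 0, 0), c(0, 0, 0))
  des <- bbd_design()
  ml <- fit_quadratic(des, make_bbd_responses(surf, des))
  ys <- predict(ml, cbind(c(-1, 0, 1), 0, 0), coded = TRUE)
  expect_equal(diff(ys), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("surface grids are bounded by the optimum and deterministic", {
  m <- fit_quadratic(table2_design(), table2()$OD)
  opt <- optimize_quadratic(m)
  g1 <- surface_grid(m, c(1, 2), fixed_level = 1)
  expect_lte(max(g1$predicted), opt$predicted + 1e-9)
  expect_identical(g1, surface_grid(m, c(1, 2), fixed_level = 1))
  # no-interaction symmetric model gives a symmetric grid
  surf <- true_surface(1, c(0, 0, 0), c(0, 0, 0), c(-1, -1, 0))
  des <- bbd_design()
  ms <- fit_quadratic(des, make_bbd_responses(surf, des))
  gs <- surface_grid(ms, c(1, 2), n = 21)
  expect_equal(gs$predicted, rev(gs$predicted), tolerance = 1e-9)
})
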