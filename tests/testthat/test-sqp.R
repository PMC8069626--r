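test_that("QP solver handles unconstrained and projected gradients", {
  # H = I, no constraints: d = -g
  r <- solve_qp(diag(2), c(1, -2))
  expect_equal(r$d, c(-1, 2))
  # H = I, g = (-1,-1), equality d1 + d2 = 0: projection kills the gradient
  r <- solve_qp(diag(2), c(-1, -1), Aeq = matrix(1, 1, 2), beq = 0)
  expect_equal(r$d, c(0, 0), tolerance = 1e-12)
})

test_that("QP solver agrees with a dense KKT linear solve", {
  set.seed(11)
  for (rep in 1:5) {
    H <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    g <- rnorm(4)
    A <- matrix(rnorm(4), 1)
    b <- rnorm(1)
    r <- solve_qp(H, g, Aeq = A, beq = b)
    # oracle: one equality, solve the KKT block system directly
    K <- rbind(cbind(H, t(A)), cbind(A, 0))
    sol <- solve(K, c(-g, b))
    expect_equal(r$d, sol[1:4], tolerance = 1e-9)
    expect_equal(r$lambda_eq, sol[5], tolerance = 1e-9)
  }
})

test_that("QP solver activates the right inequalities", {
  # min 0.5||d||^2 - d1 subject to d1 <= 0.3: constraint binds
  r <- solve_qp(diag(2), c(-1, 0), Aineq = matrix(c(1, 0), 1), bineq = 0.3)
  expect_equal(r$d, c(0.3, 0), tolerance = 1e-10)
  expect_equal(r$mu_ineq, 0.7, tolerance = 1e-10)
  # slack constraint leaves the unconstrained optimum untouched
  r <- solve_qp(diag(2), c(-1, 0), Aineq = matrix(c(1, 0), 1), bineq = 5)
  expect_equal(r$d, c(1, 0), tolerance = 1e-10)
  expect_equal(r$mu_ineq, 0)
  expect_error(solve_qp(diag(2), c(0, 0),
                        Aeq = rbind(c(1, 0), c(1, 0)), beq = c(0, 1)),
               "infeasible")
})

test_that("damped BFGS preserves positive definiteness", {
  H <- diag(3)
  expect_identical(bfgs_update(H, c(0, 0, 0), c(1, 1, 1)), H)
  set.seed(23)
  for (rep in 1:50) {
    s <- rnorm(3)
    y <- rnorm(3)   # arbitrary, often s'y < 0: damping must rescue PD
    H <- bfgs_update(H, s, y)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("BFGS converges to the true Hessian of a quadratic model", {
  set.seed(42)
  Q <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  H <- diag(4)
  for (i in 1:50) {
    s <- rnorm(4)
    H <- bfgs_update(H, s, drop(Q %*% s))  # exact curvature pairs
  }
  expect_lt(norm(H - Q, "F") / norm(Q, "F"), 1e-6)
})

test_that("KKT residual vanishes exactly at an analytic KKT point", {
  pr <- optimization_problem(function(x) sum(x^2), x0 = c(3, -1),
                             gradient = function(x) 2 * x,
                             eq = function(x) sum(x) - 1,
                             eq_jacobian = function(x) matrix(1, 1, 2))
  expect_lt(kkt_residual(pr, c(0.5, 0.5), lambda_eq = -1), 1e-12)
  # wrong multiplier or infeasible point gives a positive residual
  expect_gt(kkt_residual(pr, c(0.5, 0.5), lambda_eq = 0), 0.1)
  expect_gt(kkt_residual(pr, c(2, 1), lambda_eq = -1), 0.1)
})

test_that("KKT residual matches a hand-assembled residual", {
  # min (x-1)^2 + y^2 with x <= 0.25 (bound), at x = (0.25, 0.1), mu = 1.5
  pr <- optimization_problem(function(x) (x[1] - 1)^2 + x[2]^2,
                             x0 = c(0, 0),
                             gradient = function(x) c(2 * (x[1] - 1),
                                                      2 * x[2]),
                             upper = c(0.25, Inf))
  x <- c(0.25, 0.1)
  mu <- 1.5
  # by hand: stationarity (2(x1-1) + mu, 2 x2), feasibility 0, dual 0,
  # complementarity |mu * (x1 - 0.25)| = 0
  hand <- max(abs(c(2 * (0.25 - 1) + mu, 2 * 0.1)))
  expect_equal(kkt_residual(pr, x, mu_ineq = mu), hand)
})

test_that("SQP reproduces analytic solutions on the constrained test suite", {
  probs <- analytic_problems()
  expect_gte(length(probs), 5)
  for (p in probs) {
    sol <- solve_sqp(p$problem, sqp_control(tol = 1e-10, max_iter = 400))
    expect_true(sol$converged, info = p$name)
    expect_equal(sol$x, p$solution, tolerance = 1e-6,
                 ignore_attr = TRUE, info = p$name)
    if (!is.null(p$lambda)) {
      expect_equal(sol$lambda_eq, p$lambda, tolerance = 1e-6, info = p$name)
    }
  }
})

test_that("SQP converges with finite-difference gradients at the classic tolerance", {
  pr <- optimization_problem(function(x) sum(x^2), x0 = c(3, -1),
                             eq = function(x) sum(x) - 1)
  sol <- solve_sqp(pr, sqp_control(tol = 1e-4, max_iter = 100))
  expect_true(sol$converged)
  expect_equal(sol$x, c(0.5, 0.5), tolerance = 1e-4)
  expect_lte(sol$iterations, 10)  # strictly convex QP: a few outer steps
  expect_lt(sol$kkt_residual, 1e-4)
})

test_that("SQP flags non-convergence instead of raising", {
  pr <- optimization_problem(
    function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2, x0 = c(-1.2, 1))
  sol <- solve_sqp(pr, sqp_control(tol = 1e-12, max_iter = 3))
  expect_s3_class(sol, "sqp_solution")
  expect_false(sol$converged)
  expect_error(optimization_problem(function(x) NaN, x0 = 1), "finite")
})
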