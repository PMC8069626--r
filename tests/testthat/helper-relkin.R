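# Shared oracles and fixtures, kept independent of the package internals.

# Brute-force plane-sheet series: fixed number of odd-index terms, no
# truncation logic. Reference for the adaptive series in the package.
reference_diffusion_series <- function(D_e, h, t, n_terms = 10000L) {
  m <- 2 * (0:(n_terms - 1L)) + 1
  vapply(t, function(ti) {
    1 - (8 / pi^2) * sum(exp(-m^2 * pi^2 * D_e * ti / h^2) / m^2)
  }, numeric(1))
}

# Closed-form simple linear regression (hand least squares), used as the
# independent oracle for the correlation fits.
hand_lm <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(a = a, b = b)
}

# Smooth constrained test problems with known analytic KKT solutions.
# Solutions derived by hand from the stationarity conditions.
analytic_problems <- function() {
  list(
    list(name = "1d quadratic",
         problem = optimization_problem(function(x) x^2, x0 = 3,
                                        gradient = function(x) 2 * x),
         solution = 0),
    list(name = "symmetric QP with equality",
         problem = optimization_problem(function(x) sum(x^2), x0 = c(3, -1),
                                        gradient = function(x) 2 * x,
                                        eq = function(x) sum(x) - 1,
                                        eq_jacobian = function(x)
                                          matrix(1, 1, 2)),
         solution = c(0.5, 0.5), lambda = -1),
    list(name = "bounded Rosenbrock",
         problem = optimization_problem(
           function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2,
           x0 = c(-1.2, 1),
           gradient = function(x)
             c(-2 * (1 - x[1]) - 400 * x[1] * (x[2] - x[1]^2),
               200 * (x[2] - x[1]^2)),
           lower = c(-2, -1), upper = c(2, 3)),
         solution = c(1, 1)),
    list(name = "projection onto unit disc",
         # min (x-2)^2 + (y-1)^2 s.t. x^2+y^2 <= 1: optimum at (2,1)/sqrt(5)
         problem = optimization_problem(
           function(x) (x[1] - 2)^2 + (x[2] - 1)^2, x0 = c(0, 0),
           gradient = function(x) c(2 * (x[1] - 2), 2 * (x[2] - 1)),
           ineq = function(x) sum(x^2) - 1,
           ineq_jacobian = function(x) matrix(2 * x, 1)),
         solution = c(2, 1) / sqrt(5)),
    list(name = "parabolic equality",
         # min (1-x)^2 s.t. 10(y - x^2) = 0: optimum (1, 1)
         problem = optimization_problem(
           function(x) (1 - x[1])^2, x0 = c(-1.2, 1),
           gradient = function(x) c(-2 * (1 - x[1]), 0),
           eq = function(x) 10 * (x[2] - x[1]^2),
           eq_jacobian = function(x) matrix(c(-20 * x[1], 10), 1)),
         solution = c(1, 1)),
    list(name = "maximum entropy on the simplex",
         problem = optimization_problem(
           function(x) sum(x * log(x)), x0 = c(0.2, 0.3, 0.5),
           gradient = function(x) log(x) + 1,
           eq = function(x) sum(x) - 1,
           eq_jacobian = function(x) matrix(1, 1, 3),
           lower = rep(1e-4, 3), upper = rep(1, 3)),
         solution = rep(1, 3) / 3),
    list(name = "active linear inequality",
         # min (x+1)^2 + (y+1)^2 s.t. x + y >= 1: optimum (0.5, 0.5)
         problem = optimization_problem(
           function(x) (x[1] + 1)^2 + (x[2] + 1)^2, x0 = c(2, 2),
           gradient = function(x) 2 * (x + 1),
           ineq = function(x) 1 - x[1] - x[2],
           ineq_jacobian = function(x) matrix(c(-1, -1), 1)),
         solution = c(0.5, 0.5))
  )
}

# Run the packaged CLI in a child Rscript that sees the same library paths.
run_cli <- function(args) {
  out <- tempfile()
  err <- tempfile()
  status <- system2("Rscript", c(relkin_cli_path(), args),
                    stdout = out, stderr = err,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}

table1_conditions <- function() builtin_conditions()$condition
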