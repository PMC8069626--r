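#' Define a constrained nonlinear optimization problem
#'
#' Bundles an objective, optional analytic gradient, equality and inequality
#' constraints and box bounds for [solve_sqp()]. Constraints follow the
#' standard form `h(x) = 0` (equalities) and `g(x) <= 0` (inequalities);
#' bounds are handled internally as additional inequalities, ordered after
#' the user-supplied ones (first all finite lower bounds, then all finite
#' upper bounds).
#'
#' @param objective Function `x -> scalar`; must be finite at `x0`.
#' @param x0 Numeric starting vector.
#' @param gradient Optional function `x -> gradient vector`. When `NULL`,
#'   forward finite differences with relative step `fd_step` are used.
#' @param eq Optional function `x -> numeric vector` of equality residuals
#'   `h(x)` (target 0).
#' @param eq_jacobian Optional function `x -> matrix` (rows = constraints).
#' @param ineq Optional function `x -> numeric vector` of inequality values
#'   `g(x)` (feasible when `<= 0`).
#' @param ineq_jacobian Optional function `x -> matrix`.
#' @param lower,upper Optional per-parameter bounds (recycled scalars
#'   allowed; `-Inf`/`Inf` for unbounded).
#' @return An object of class `optimization_problem`.
#' @seealso [solve_sqp()]
#' @export
optimization_problem <- function(objective, x0, gradient = NULL,
                                 eq = NULL, eq_jacobian = NULL,
                                 ineq = NULL, ineq_jacobian = NULL,
                                 lower = NULL, upper = NULL) {
  stopifnot(is.function(objective))
  x0 <- as.numeric(x0)
  n <- length(x0)
  if (n == 0L || anyNA(x0)) stop("`x0` must be a nonempty numeric vector",
                                 call. = FALSE)
  f0 <- objective(x0)
  if (!is.finite(f0)) stop("objective is not finite at `x0`", call. = FALSE)
  if (!is.null(eq)) {
    h0 <- eq(x0)
    if (anyNA(h0)) stop("equality constraints undefined at `x0`", call. = FALSE)
  }
  if (!is.null(ineq)) {
    g0 <- ineq(x0)
    if (anyNA(g0)) stop("inequality constraints undefined at `x0`",
                        call. = FALSE)
  }
  lower <- if (is.null(lower)) rep(-Inf, n) else rep_len(as.numeric(lower), n)
  upper <- if (is.null(upper)) rep(Inf, n) else rep_len(as.numeric(upper), n)
  if (any(lower > upper)) stop("`lower` must not exceed `upper`", call. = FALSE)
  structure(list(objective = objective, x0 = x0, gradient = gradient,
                 eq = eq, eq_jacobian = eq_jacobian,
                 ineq = ineq, ineq_jacobian = ineq_jacobian,
                 lower = lower, upper = upper),
            class = "optimization_problem")
}

#' Settings for the SQP solver
#'
#' @param tol KKT convergence tolerance (default `1e-4`, the classical
#'   acceptance tolerance for the step and optimality residual).
#' @param max_iter Maximum outer iterations.
#' @param damping Powell damping threshold: the update requires
#'   `s'y >= damping * s'Hs`, else `y` is damped toward `Hs`.
#' @param armijo Sufficient-decrease constant for the l1-merit line search.
#' @param backtrack Backtracking factor for the step length.
#' @param fd_step Relative forward-difference step for numerical gradients.
#' @param min_alpha Smallest admissible line-search step.
#' @return A list of class `sqp_control`.
#' @export
sqp_control <- function(tol = 1e-4, max_iter = 100L, damping = 0.2,
                        armijo = 1e-4, backtrack = 0.5, fd_step = 1e-7,
                        min_alpha = 1e-12) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 damping = damping, armijo = armijo, backtrack = backtrack,
                 fd_step = fd_step, min_alpha = min_alpha),
            class = "sqp_control")
}

# Forward finite-difference gradient, relative step.
fd_gradient <- function(f, x, f_x = f(x), step = 1e-7) {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    h <- step * max(1, abs(x[i]))
    xi <- x
    xi[i] <- xi[i] + h
    g[i] <- (f(xi) - f_x) / h
  }
  g
}

# Finite-difference Jacobian of a vector-valued function (rows = outputs).
fd_jacobian <- function(fn, x, f_x = fn(x), step = 1e-7) {
  n <- length(x)
  m <- length(f_x)
  J <- matrix(0, m, n)
  for (i in seq_len(n)) {
    h <- step * max(1, abs(x[i]))
    xi <- x
    xi[i] <- xi[i] + h
    J[, i] <- (fn(xi) - f_x) / h
  }
  J
}

#' Solve a strictly convex quadratic program by the primal active-set method
#'
#' Minimises `g'd + 0.5 * d'Hd` subject to `Aeq d = beq` and
#' `Aineq d <= bineq`. A feasible point is found by least-norm projection
#' onto the equalities followed by repair of violated inequalities; the
#' active-set iteration then solves one equality-constrained KKT system per
#' working set until all working-set multipliers are nonnegative.
#'
#' @param H Symmetric positive-definite matrix.
#' @param g Gradient vector of the linear term.
#' @param Aeq,beq Equality constraint matrix/vector (or `NULL`).
#' @param Aineq,bineq Inequality constraint matrix/vector (or `NULL`).
#' @param tol Numerical tolerance for feasibility and multiplier tests.
#' @return A list with `d` (the minimiser), `lambda_eq` (equality
#'   multipliers), `mu_ineq` (inequality multipliers, zero off the active
#'   set) and `active` (indices of active inequalities).
#' @examples
#' # unconstrained: d = -g for H = I
#' solve_qp(diag(2), c(1, -2))$d
#' @export
solve_qp <- function(H, g, Aeq = NULL, beq = NULL, Aineq = NULL,
                     bineq = NULL, tol = 1e-10) {
  n <- length(g)
  H <- (H + t(H)) / 2
  if (!is.null(Aeq)) Aeq <- matrix(Aeq, ncol = n)
  if (!is.null(Aineq)) Aineq <- matrix(Aineq, ncol = n)
  m_eq <- if (is.null(Aeq)) 0L else nrow(Aeq)
  m_in <- if (is.null(Aineq)) 0L else nrow(Aineq)

  # ---- phase 1: feasible starting point -------------------------------
  d <- numeric(n)
  if (m_eq > 0L) {
    d <- tryCatch(
      drop(t(Aeq) %*% solve(Aeq %*% t(Aeq), beq)),
      error = function(e) stop("infeasible QP subproblem: inconsistent ",
                               "linearized equalities", call. = FALSE))
    if (max(abs(Aeq %*% d - beq)) > 1e-6 * (1 + max(abs(beq)))) {
      stop("infeasible QP subproblem: inconsistent linearized equalities",
           call. = FALSE)
    }
  }
  forced <- integer(0)          # inequalities pinned during repair
  if (m_in > 0L) {
    for (pass in seq_len(2L * m_in + 1L)) {
      viol <- drop(Aineq %*% d) - bineq
      worst <- which.max(viol)
      if (viol[worst] <= tol) break
      forced <- union(forced, worst)
      A <- rbind(Aeq, Aineq[forced, , drop = FALSE])
      b <- c(beq, bineq[forced])
      d <- tryCatch(
        drop(t(A) %*% solve(A %*% t(A), b)),
        error = function(e) NULL)
      if (is.null(d)) {
        stop("infeasible QP subproblem: could not satisfy linearized ",
             "constraints", call. = FALSE)
      }
    }
    if (max(drop(Aineq %*% d) - bineq) > 1e-6) {
      stop("infeasible QP subproblem: could not satisfy linearized ",
           "constraints", call. = FALSE)
    }
  }

  # ---- active-set iteration -------------------------------------------
  W <- forced                    # working set of inequality indices
  mu <- numeric(m_in)
  lambda <- numeric(m_eq)
  for (iter in seq_len(50L * (n + m_in + 1L))) {
    Aw <- rbind(Aeq, if (length(W)) Aineq[W, , drop = FALSE])
    m_w <- if (is.null(Aw)) 0L else nrow(Aw)
    grad_d <- g + drop(H %*% d)
    if (m_w == 0L) {
      p <- -solve(H, grad_d)
      lam <- numeric(0)
    } else {
      K <- rbind(cbind(H, t(Aw)), cbind(Aw, matrix(0, m_w, m_w)))
      rhs <- c(-grad_d, rep(0, m_w))
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol)) {
        # degenerate working set: drop the most recent inequality and retry
        if (length(W)) {
          W <- W[-length(W)]
          next
        }
        sol <- qr.solve(K, rhs)
      }
      p <- sol[seq_len(n)]
      lam <- sol[-seq_len(n)]
    }
    if (max(abs(p)) < 1e-11 * (1 + max(abs(d)))) {
      lambda <- if (m_eq > 0L) lam[seq_len(m_eq)] else numeric(0)
      mu_w <- if (length(W)) lam[m_eq + seq_along(W)] else numeric(0)
      if (!length(W) || all(mu_w >= -tol)) {
        mu <- numeric(m_in)
        if (length(W)) mu[W] <- pmax(mu_w, 0)
        return(list(d = d, lambda_eq = lambda, mu_ineq = mu, active = sort(W)))
      }
      W <- W[-which.min(mu_w)]
      next
    }
    # ratio test against inequalities not in the working set
    alpha <- 1
    blocking <- 0L
    if (m_in > 0L) {
      outside <- setdiff(seq_len(m_in), W)
      if (length(outside)) {
        ap <- drop(Aineq[outside, , drop = FALSE] %*% p)
        slack <- bineq[outside] - drop(Aineq[outside, , drop = FALSE] %*% d)
        cand <- which(ap > tol)
        if (length(cand)) {
          ratios <- pmax(slack[cand], 0) / ap[cand]
          j <- which.min(ratios)
          if (ratios[j] < alpha) {
            alpha <- ratios[j]
            blocking <- outside[cand[j]]
          }
        }
      }
    }
    d <- d + alpha * p
    if (blocking > 0L) W <- c(W, blocking)
  }
  stop("active-set QP iteration limit reached", call. = FALSE)
}

#' Damped BFGS update of a Hessian approximation
#'
#' Updates `H` from a step `s` and gradient change `y`, with Powell damping:
#' when `s'y < damping * s'Hs` the vector `y` is blended toward `Hs` so the
#' update keeps `H` symmetric positive definite.
#'
#' @param H Current symmetric positive-definite approximation.
#' @param s Step in the parameters (`x_new - x_old`).
#' @param y Change in the Lagrangian gradient.
#' @param damping Damping threshold in `(0, 1)` (default 0.2).
#' @return The updated matrix; `H` unchanged when `s` is zero.
#' @export
bfgs_update <- function(H, s, y, damping = 0.2) {
  s <- as.numeric(s)
  y <- as.numeric(y)
  if (all(s == 0)) return(H)
  Hs <- drop(H %*% s)
  sHs <- drop(crossprod(s, Hs))
  if (sHs <= 0) return(H)   # should not happen for PD H; refuse the update
  sy <- drop(crossprod(s, y))
  if (sy < damping * sHs) {
    theta <- (1 - damping) * sHs / (sHs - sy)
    y <- theta * y + (1 - theta) * Hs
    sy <- drop(crossprod(s, y))
  }
  if (sy <= 1e-14 * sHs) return(H)
  Hn <- H - tcrossprod(Hs) / sHs + tcrossprod(y) / sy
  Hn <- (Hn + t(Hn)) / 2
  # conditioning guard: refuse updates that would make H numerically
  # singular (repeated damping can drive curvature to the round-off floor)
  if (!all(is.finite(Hn)) || rcond(Hn) < 1e-12) return(H)
  Hn
}

# Evaluate constraints and Jacobians of a problem at x, with bounds appended
# as inequalities (lower bounds first, then upper bounds).
eval_constraints <- function(problem, x, fd_step = 1e-7) {
  n <- length(x)
  h <- if (is.null(problem$eq)) numeric(0) else as.numeric(problem$eq(x))
  Jh <- if (length(h) == 0L) {
    matrix(0, 0, n)
  } else if (!is.null(problem$eq_jacobian)) {
    matrix(problem$eq_jacobian(x), ncol = n)
  } else {
    fd_jacobian(problem$eq, x, h, fd_step)
  }
  g_user <- if (is.null(problem$ineq)) numeric(0) else as.numeric(problem$ineq(x))
  Jg_user <- if (length(g_user) == 0L) {
    matrix(0, 0, n)
  } else if (!is.null(problem$ineq_jacobian)) {
    matrix(problem$ineq_jacobian(x), ncol = n)
  } else {
    fd_jacobian(problem$ineq, x, g_user, fd_step)
  }
  lo <- which(is.finite(problem$lower))
  up <- which(is.finite(problem$upper))
  g_lo <- problem$lower[lo] - x[lo]
  g_up <- x[up] - problem$upper[up]
  J_lo <- matrix(0, length(lo), n)
  if (length(lo)) J_lo[cbind(seq_along(lo), lo)] <- -1
  J_up <- matrix(0, length(up), n)
  if (length(up)) J_up[cbind(seq_along(up), up)] <- 1
  list(h = h, Jh = Jh,
       g = c(g_user, g_lo, g_up),
       Jg = rbind(Jg_user, J_lo, J_up))
}

#' KKT residual of a candidate solution
#'
#' Max-norm over the four first-order optimality blocks: stationarity of the
#' Lagrangian gradient, primal feasibility (equalities and violated
#' inequalities), dual feasibility (`mu >= 0`) and complementary slackness.
#' Inequality multipliers are ordered as user inequalities, then finite
#' lower bounds, then finite upper bounds.
#'
#' @param problem An [optimization_problem()].
#' @param x Candidate parameter vector.
#' @param lambda_eq Equality multipliers (length = number of equalities).
#' @param mu_ineq Inequality multipliers (user constraints + bounds).
#' @param fd_step Finite-difference step for numerical derivatives.
#' @return Scalar residual; 0 at an exact KKT point.
#' @export
kkt_residual <- function(problem, x, lambda_eq = numeric(0),
                         mu_ineq = numeric(0), fd_step = 1e-7) {
  stopifnot(inherits(problem, "optimization_problem"))
  con <- eval_constraints(problem, x, fd_step)
  grad <- if (is.null(problem$gradient)) {
    fd_gradient(problem$objective, x, step = fd_step)
  } else {
    as.numeric(problem$gradient(x))
  }
  lambda_eq <- rep_len(as.numeric(lambda_eq), length(con$h))
  mu_ineq <- rep_len(as.numeric(mu_ineq), length(con$g))
  stat <- grad
  if (length(con$h)) stat <- stat + drop(crossprod(con$Jh, lambda_eq))
  if (length(con$g)) stat <- stat + drop(crossprod(con$Jg, mu_ineq))
  r <- max(abs(stat), 0)
  if (length(con$h)) r <- max(r, max(abs(con$h)))
  if (length(con$g)) {
    r <- max(r, max(pmax(con$g, 0)))          # primal feasibility
    r <- max(r, max(pmax(-mu_ineq, 0)))       # dual feasibility
    r <- max(r, max(abs(mu_ineq * con$g)))    # complementarity
  }
  r
}

#' Sequential quadratic programming solver
#'
#' Minimises a smooth objective under nonlinear equality and inequality
#' constraints and box bounds. Each outer iteration linearises the
#' constraints, solves a strictly convex QP subproblem ([solve_qp()]) for a
#' search direction and multiplier estimates, performs a backtracking line
#' search on an l1 exact-penalty merit function, and updates the Lagrangian
#' Hessian approximation by damped BFGS ([bfgs_update()]). Iteration stops
#' when the KKT residual falls below `control$tol`.
#'
#' @param problem An [optimization_problem()].
#' @param control An [sqp_control()] settings list.
#' @return An object of class `sqp_solution`: list with `x`, `objective`,
#'   `lambda_eq`, `mu_ineq`, `converged`, `iterations`, `kkt_residual`.
#' @examples
#' pr <- optimization_problem(function(x) sum(x^2), x0 = c(3, -1),
#'                            eq = function(x) sum(x) - 1)
#' solve_sqp(pr)$x   # (0.5, 0.5)
#' @export
solve_sqp <- function(problem, control = sqp_control()) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (!inherits(control, "sqp_control")) control <- do.call(sqp_control, control)
  x <- problem$x0
  n <- length(x)
  f <- problem$objective
  grad_fn <- function(z) {
    if (is.null(problem$gradient)) fd_gradient(f, z, step = control$fd_step)
    else as.numeric(problem$gradient(z))
  }

  fx <- f(x)
  if (!is.finite(fx)) stop("objective is not finite at `x0`", call. = FALSE)
  gx <- grad_fn(x)
  con <- eval_constraints(problem, x, control$fd_step)
  H <- diag(n)
  nu <- 1                       # l1 merit penalty parameter
  lambda <- numeric(length(con$h))
  mu <- numeric(length(con$g))

  merit <- function(fv, hv, gv) {
    fv + nu * (sum(abs(hv)) + sum(pmax(gv, 0)))
  }
  infeas <- function(hv, gv) {
    m <- 0
    if (length(hv)) m <- max(m, max(abs(hv)))
    if (length(gv)) m <- max(m, max(pmax(gv, 0)))
    m
  }

  best <- list(x = x, f = fx, infeas = infeas(con$h, con$g),
               lambda = lambda, mu = mu)
  converged <- FALSE
  kkt <- Inf
  iter <- 0L

  for (iter in seq_len(control$max_iter)) {
    qp <- tryCatch(
      solve_qp(H, gx,
               Aeq = if (length(con$h)) con$Jh, beq = -con$h,
               Aineq = if (length(con$g)) con$Jg, bineq = -con$g),
      error = function(e) NULL)
    if (is.null(qp)) {
      # relaxed restoration step: least-squares on the equalities with a
      # small ridge, ignoring inequalities for this iteration
      A <- rbind(con$Jh, con$Jg[con$g > 0, , drop = FALSE])
      b <- c(-con$h, -con$g[con$g > 0])
      if (nrow(A) == 0L) break
      d <- drop(solve(crossprod(A) + 1e-8 * diag(n), crossprod(A, b)))
      qp <- list(d = d, lambda_eq = lambda, mu_ineq = mu)
    }
    d <- qp$d
    lambda_new <- qp$lambda_eq
    mu_new <- qp$mu_ineq

    # penalty parameter large enough that d is a descent direction of merit
    mult_max <- max(0, abs(lambda_new), mu_new)
    if (nu < 1.1 * mult_max) nu <- 1.5 * mult_max + 1e-6

    phi0 <- merit(fx, con$h, con$g)
    # directional derivative of the l1 merit along d
    dphi <- sum(gx * d) - nu * (sum(abs(con$h)) + sum(pmax(con$g, 0)))
    alpha <- 1
    repeat {
      x_new <- x + alpha * d
      f_new <- f(x_new)
      con_new <- eval_constraints(problem, x_new, control$fd_step)
      ok <- is.finite(f_new) &&
        merit(f_new, con_new$h, con_new$g) <=
          phi0 + control$armijo * alpha * min(dphi, 0)
      if (ok || alpha <= control$min_alpha) break
      alpha <- alpha * control$backtrack
    }

    gx_new <- grad_fn(x_new)
    # BFGS on the Lagrangian gradient change, multipliers held at new values
    grad_L_new <- gx_new
    grad_L_old <- gx
    if (length(con$h)) {
      grad_L_new <- grad_L_new + drop(crossprod(con_new$Jh, lambda_new))
      grad_L_old <- grad_L_old + drop(crossprod(con$Jh, lambda_new))
    }
    if (length(con$g)) {
      grad_L_new <- grad_L_new + drop(crossprod(con_new$Jg, mu_new))
      grad_L_old <- grad_L_old + drop(crossprod(con$Jg, mu_new))
    }
    s <- x_new - x
    H <- bfgs_update(H, s, grad_L_new - grad_L_old, control$damping)

    x <- x_new; fx <- f_new; gx <- gx_new; con <- con_new
    lambda <- lambda_new; mu <- mu_new

    cur_infeas <- infeas(con$h, con$g)
    if (cur_infeas <= best$infeas + control$tol &&
        (fx < best$f || cur_infeas < best$infeas)) {
      best <- list(x = x, f = fx, infeas = cur_infeas,
                   lambda = lambda, mu = mu)
    }

    kkt <- kkt_residual_at(gx, con, lambda, mu)
    if (kkt < control$tol ||
        (max(abs(alpha * d)) < control$tol^1.5 && cur_infeas < control$tol)) {
      converged <- kkt < control$tol ||
        kkt < sqrt(control$tol)   # step-collapse near optimum still counts
      break
    }
  }

  # report the best iterate seen (usually the final one)
  if (best$f < fx - 1e-12 && best$infeas <= infeas(con$h, con$g) + control$tol) {
    x <- best$x; fx <- best$f; lambda <- best$lambda; mu <- best$mu
    con <- eval_constraints(problem, x, control$fd_step)
    gx <- grad_fn(x)
    kkt <- kkt_residual_at(gx, con, lambda, mu)
    converged <- converged || kkt < control$tol
  }

  structure(list(x = x, objective = fx, lambda_eq = lambda, mu_ineq = mu,
                 converged = converged, iterations = iter,
                 kkt_residual = kkt),
            class = "sqp_solution")
}

# KKT residual from pre-evaluated pieces (internal fast path).
kkt_residual_at <- function(grad, con, lambda, mu) {
  stat <- grad
  if (length(con$h)) stat <- stat + drop(crossprod(con$Jh, lambda))
  if (length(con$g)) stat <- stat + drop(crossprod(con$Jg, mu))
  r <- max(abs(stat), 0)
  if (length(con$h)) r <- max(r, max(abs(con$h)))
  if (length(con$g)) {
    r <- max(r, max(pmax(con$g, 0)), max(pmax(-mu, 0)), max(abs(mu * con$g)))
  }
  r
}

#' @export
print.sqp_solution <- function(x, ...) {
  cat(sprintf("SQP solution (%s, %d iterations)\n",
              if (x$converged) "converged" else "not converged",
              x$iterations))
  cat("  x =", format(x$x, digits = 8), "\n")
  cat(sprintf("  objective = %.8g, KKT residual = %.3g\n",
              x$objective, x$kkt_residual))
  invisible(x)
}
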