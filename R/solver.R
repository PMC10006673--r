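# Dual solver for linearly constrained separable convex programs
#
#   minimize    sum_i f_i(v_i)
#   subject to  A v = b,   lb <= v <= ub
#
# with each f_i strictly convex and smooth on (lb_i, ub_i).  The Lagrange
# dual q(y) = min_{lb<=v<=ub} sum_i f_i(v_i) + y'(Av - b) is concave and
# differentiable (the inner minimizer v(y) is unique), with gradient
# grad q = A v(y) - b.  We maximize q with L-BFGS-B and polish with damped
# Newton steps on the dual (Hessian -A D A', D_ii = 1/f_i''(v_i) on interior
# coordinates), then read off the unique primal solution v(y).
#
# An objective "family" is a list of vectorized functions:
#   value(v)      -> sum_i f_i(v_i) contributions (vector)
#   inner_min(c)  -> argmin_{lb<=v<=ub} f(v) + c*v, elementwise
#   hess(v)       -> f_i''(v_i)

# Entropy family: f_i(v) = v * log((v + eps) / (g_i + eps)).
# f'(v) = log((v+eps)/(g+eps)) + v/(v+eps); safeguarded Newton inversion.
obj_family_entropy <- function(g, eps, lb, ub) {
  ge <- g + eps
  fp <- function(v) log((v + eps) / ge) + v / (v + eps)
  list(
    value = function(v) v * log((v + eps) / ge),
    hess = function(v) 1 / (v + eps) + eps / (v + eps)^2,
    inner_min = function(cc) {
      v <- numeric(length(cc))
      at_lb <- fp(lb) + cc >= 0
      at_ub <- fp(ub) + cc <= 0
      v[at_lb] <- lb[at_lb]
      v[at_ub] <- ub[at_ub]
      act <- which(!at_lb & !at_ub)
      if (length(act)) {
        gea <- ge[act]
        ca <- cc[act]
        lo <- lb[act]
        hi <- ub[act]
        # start from the eps-free solution g*exp(-1-c), clipped into the box
        x <- gea * exp(pmin(-1 - ca, log(hi + 1) - log(gea))) - eps
        x <- pmin(pmax(x, lo), hi)
        for (it in 1:80) {
          r <- log((x + eps) / gea) + x / (x + eps) + ca
          if (max(abs(r)) < 1e-12) break
          live <- abs(r) >= 1e-14   # freeze converged coordinates
          lo[live & r < 0] <- x[live & r < 0]
          hi[live & r > 0] <- x[live & r > 0]
          h <- 1 / (x + eps) + eps / (x + eps)^2
          xn <- x - r / h
          bad <- live & (xn <= lo | xn >= hi)
          xn[bad] <- (lo[bad] + hi[bad]) / 2
          xn[!live] <- x[!live]
          x <- xn
        }
        v[act] <- x
      }
      v
    }
  )
}

# KL family: f_i(v) = v * log(v / g_i); closed-form inner minimizer
# v = g * exp(-1 - c), clipped to the box (computed in log space).
obj_family_kl <- function(g, lb, ub) {
  lg <- log(g)
  lub <- log(pmax(ub, .Machine$double.xmin))
  list(
    value = function(v) ifelse(v > 0, v * log(v / g), 0),
    hess = function(v) 1 / pmax(v, .Machine$double.xmin),
    inner_min = function(cc) {
      lv <- lg - 1 - cc
      v <- exp(pmin(lv, lub))
      pmin(pmax(v, lb), ub)
    }
  )
}

# Quadratic family: f_i(v) = (v_i - ref_i)^2 / 2; closed-form inner
# minimizer clip(ref - c).  Used for least-distance / feasibility problems
# and as the l2 stage of the FBA baseline.
obj_family_quadratic <- function(ref, lb, ub) {
  list(
    value = function(v) 0.5 * (v - ref)^2,
    hess = function(v) rep(1, length(v)),
    inner_min = function(cc) pmin(pmax(ref - cc, lb), ub)
  )
}

# Log-barrier family: f_i(v) = -log(v_i - lb_i) - log(ub_i - v_i).  Its
# constrained minimizer is the analytic center of {Av = b} with the box,
# strictly interior whenever a relative interior exists.  The inner problem
# f'(v) + c = 0 reduces to a quadratic in a = v - lb with the stable root
# a = 2w / ((2 + cw) + sqrt(4 + c^2 w^2)), w = ub - lb.
obj_family_logbarrier <- function(lb, ub) {
  w <- ub - lb
  fixed <- w <= 0
  list(
    value = function(v) {
      a <- pmax(v - lb, .Machine$double.xmin)
      bgap <- pmax(ub - v, .Machine$double.xmin)
      out <- -log(a) - log(bgap)
      out[fixed] <- 0
      out
    },
    hess = function(v) {
      h <- 1 / pmax(v - lb, 1e-300)^2 + 1 / pmax(ub - v, 1e-300)^2
      h[fixed] <- 1
      h
    },
    inner_min = function(cc) {
      a <- 2 * w / ((2 + cc * w) + sqrt(4 + (cc * w)^2))
      v <- lb + a
      v[fixed] <- lb[fixed]
      v
    }
  )
}

# Reduce an equality system to linearly independent rows (QR on the
# transpose); keeps quadprog happy and the dual Hessian well scaled.
independent_rows <- function(A, b, tol = 1e-10) {
  Ad <- as.matrix(A)
  qrA <- qr(t(Ad), tol = tol)
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  dropped <- setdiff(seq_len(nrow(Ad)), keep)
  if (length(dropped)) {
    # a dropped row must be consistent with the kept ones; verified later
    # through the primal residual check
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
  }
  list(A = A, b = b, kept = keep)
}

# Feasibility check / feasible point: min ||v - ref||^2 s.t. Av = b, box.
# Tries quadprog first; if it balks (its active-set method can misreport
# feasible degenerate systems as inconsistent), falls back to the dual
# solver with the quadratic family.  Returns NULL when no point satisfies
# the constraints to tolerance.
find_feasible_point <- function(A, b, lb, ub, ref = NULL) {
  n <- ncol(A)
  red <- independent_rows(A, b)
  Ad <- as.matrix(red$A)
  ref <- ref %||% ((lb + ub) / 2)
  if (length(ref) != n) ref <- rep(ref[1], n)
  tol <- 1e-6 * max(1, max(abs(b)))
  out <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = ref,
                       Amat = cbind(t(Ad), diag(n), -diag(n)),
                       bvec = c(red$b, lb, -ub), meq = nrow(Ad)),
    error = function(e) NULL
  )
  if (!is.null(out)) {
    v <- pmin(pmax(out$solution, lb), ub)
    if (max(abs(as.numeric(A %*% v - b))) <= tol) return(v)
  }
  fam <- obj_family_quadratic(ref, lb, ub)
  dual <- solve_separable_dual(fam, A, b, lb, ub, feas_check = FALSE)
  v <- dual$v
  if (max(abs(as.numeric(A %*% v - b))) <= tol) return(v)
  NULL
}

# A point in the relative interior of {Av = b, lb <= v <= ub}: the analytic
# center (log-barrier minimizer) via the dual engine.  Falls back to a
# (possibly boundary) feasible point when the barrier solve does not
# converge (e.g. no relative interior).
interior_point <- function(A, lb, ub, b = numeric(nrow(A))) {
  fam <- obj_family_logbarrier(lb, ub)
  center <- solve_separable_dual(fam, A, b, lb, ub, tol_res = 1e-8,
                                 feas_check = FALSE)
  if (center$status == "optimal") return(center$v)
  find_feasible_point(A, b, lb, ub)
}

# Maximize the dual; returns list(v, y, status, iterations, residual).
solve_separable_dual <- function(fam, A, b, lb, ub,
                                 y0 = NULL,
                                 tol_res = 1e-9,
                                 max_iter = 3000,
                                 feas_check = TRUE) {
  m <- nrow(A)
  n <- ncol(A)
  scale_b <- max(1, max(abs(b)))
  y <- y0 %||% numeric(m)
  At <- Matrix::t(A)

  v_of <- function(y) fam$inner_min(as.numeric(At %*% y))
  resid <- function(v) as.numeric(A %*% v - b)

  neg_q <- function(y) {
    v <- v_of(y)
    -(sum(fam$value(v)) + sum(y * resid(v)))
  }
  neg_grad <- function(y) -resid(v_of(y))

  opt <- stats::optim(
    par = y, fn = neg_q, gr = neg_grad, method = "L-BFGS-B",
    control = list(maxit = max_iter, factr = 10)
  )
  y <- opt$par
  iters <- opt$counts[["function"]]

  # damped Newton polish on the dual
  v <- v_of(y)
  r <- resid(v)
  newton_it <- 0
  while (max(abs(r)) > tol_res * scale_b && newton_it < 60) {
    newton_it <- newton_it + 1
    interior <- v > lb + 1e-12 & v < ub - 1e-12
    d <- numeric(n)
    d[interior] <- 1 / fam$hess(v)[interior]
    H <- as.matrix(A %*% (d * At))
    ridge <- max(1e-12, 1e-10 * max(abs(diag(H))))
    step <- tryCatch(
      solve(H + ridge * diag(m), r),
      error = function(e) r / max(1, max(abs(diag(H))))
    )
    t_step <- 1
    r_norm <- max(abs(r))
    improved <- FALSE
    for (ls in 1:30) {
      y_try <- y + t_step * step
      v_try <- v_of(y_try)
      r_try <- resid(v_try)
      if (max(abs(r_try)) < r_norm) {
        y <- y_try
        v <- v_try
        r <- r_try
        improved <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    if (!improved) break
  }

  converged <- max(abs(r)) <= max(tol_res * scale_b, 1e-12)
  status <- if (converged) {
    "optimal"
  } else if (!feas_check) {
    "numerical_failure"
  } else if (is.null(find_feasible_point(A, b, lb, ub))) {
    "infeasible"
  } else if (iters >= max_iter) {
    "iteration_limit"
  } else {
    "numerical_failure"
  }
  list(
    v = v, y = y, status = status,
    iterations = iters + newton_it,
    residual = max(abs(r))
  )
}
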