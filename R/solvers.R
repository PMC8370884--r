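# Conjugate gradients on the damped normal equations
#   (A'A + lambda I) x = A'b - shift
# matrix-free: only forward/adjoint applications of the operator are used.
# Returns the solution together with the per-iteration normal-equation
# residual norms (monotone for CG) and convergence diagnostics.
normal_cg <- function(op, b_vec, lambda = 0, shift = NULL, x0 = NULL,
                      max_iters = 200, tol = 1e-8) {
  np <- op_ncol(op)
  rhs <- op_adjoint(op, b_vec)
  if (!is.null(shift)) rhs <- rhs - shift
  rhs_norm <- sqrt(sum(rhs^2))
  if (rhs_norm == 0) {
    return(list(x = numeric(np), iterations = 0L, relres = 0,
                residual_trace = numeric(0), converged = TRUE))
  }
  matvec <- function(v) op_adjoint(op, op_forward(op, v)) + lambda * v
  x <- if (is.null(x0)) numeric(np) else x0
  r <- rhs - matvec(x)
  p <- r
  rs <- sum(r^2)
  trace <- sqrt(rs)
  it <- 0L
  while (it < max_iters && sqrt(rs) / rhs_norm > tol) {
    Ap <- matvec(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
    trace <- c(trace, sqrt(rs))
  }
  list(x = x, iterations = it, relres = sqrt(rs) / rhs_norm,
       residual_trace = trace, converged = sqrt(rs) / rhs_norm <= tol)
}

# scalar soft-threshold with asymmetric dead zone [-a, b]; the proximal
# operator of z -> a*max(-z,0) + b*max(z,0)
sthresh_asym <- function(t, a, b) {
  ifelse(t >= b, t - b, ifelse(t <= -a, t + a, 0))
}

# smallest eigenvalue of A'A by inverse power iteration (CG solves);
# deterministic start, for well-conditioned operators only
min_eig_normal <- function(op, n_iter = 10, cg_iters = 200) {
  np <- op_ncol(op)
  v <- cos(seq_len(np))
  v <- v / sqrt(sum(v^2))
  lam_inv <- 1
  for (i in seq_len(n_iter)) {
    matvec <- function(u) op_adjoint(op, op_forward(op, u))
    # CG solve (A'A) w = v
    w <- numeric(np); r <- v; p <- r; rs <- sum(r^2)
    for (k in seq_len(cg_iters)) {
      Ap <- matvec(p)
      alpha <- rs / sum(p * Ap)
      if (!is.finite(alpha)) break
      w <- w + alpha * p; r <- r - alpha * Ap
      rs2 <- sum(r^2)
      if (sqrt(rs2) < 1e-12 * sqrt(sum(v^2))) break
      p <- r + (rs2 / rs) * p; rs <- rs2
    }
    lam_inv <- sqrt(sum(w^2))
    if (lam_inv == 0) break
    v <- w / lam_inv
  }
  if (lam_inv <= 0) stop("could not estimate smallest eigenvalue", call. = FALSE)
  1 / lam_inv
}
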