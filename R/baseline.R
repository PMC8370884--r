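#' Reconstruction parameters
#'
#' @param method One of `"bp"` (backprojection), `"tikhonov"`, `"l1"`.
#' @param lambda Regularization weight (>= 0; must be > 0 for `tikhonov`
#'   and `l1`).
#' @param max_iters Iteration cap for iterative solvers.
#' @param tol Relative-change stopping threshold.
#' @return A `pat_recon_params`.
#' @export
recon_params <- function(method = c("tikhonov", "bp", "l1"), lambda = 0,
                         max_iters = 200, tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(is.finite(lambda), lambda >= 0, max_iters >= 1, tol > 0)
  structure(list(method = method, lambda = lambda,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "pat_recon_params")
}

new_recon_result <- function(image, params, objective_trace, residual_norm,
                             iterations, converged) {
  structure(list(image = image, params = params,
                 objective_trace = objective_trace,
                 residual_norm = residual_norm,
                 iterations = iterations, converged = converged),
            class = "pat_recon")
}

#' @export
print.pat_recon <- function(x, ...) {
  cat(sprintf("<pat_recon> method = %s, lambda = %g, %d iterations, ||Ax-b|| = %.4g\n",
              x$params$method, x$params$lambda, x$iterations, x$residual_norm))
  invisible(x)
}

# resolve b to the operator's NM vector and check sizes
check_data <- function(A, b) {
  y <- sino_vec(b)
  if (length(y) != op_nrow(A))
    stop("data size does not match the system matrix", call. = FALSE)
  y
}

result_image <- function(A, xvec) {
  if (inherits(A, "pat_sysmat")) vec_img(xvec, A$grid) else xvec
}

#' Backprojection reconstruction
#'
#' The adjoint image `x = A' b`: a single non-iterative pass, the simplest
#' comparator. Quality is limited, especially with few detectors, but it is
#' fast and linear in the data.
#'
#' @param A A `pat_sysmat` (or plain matrix for small studies).
#' @param b A `pat_sinogram` or data vector.
#' @return A `pat_recon`.
#' @export
backproject <- function(A, b) {
  y <- check_data(A, b)
  x <- op_adjoint(A, y)
  res <- sqrt(sum((op_forward(A, x) - y)^2))
  new_recon_result(result_image(A, x), recon_params("bp"),
                   objective_trace = numeric(0), residual_norm = res,
                   iterations = 0L, converged = TRUE)
}

#' Tikhonov (L2) regularized reconstruction
#'
#' Minimises `||Ax - b||^2 + lambda ||x||^2`, i.e. solves the damped normal
#' equations `(A'A + lambda I) x = A'b`, matrix-free by conjugate gradients
#' so that `A'A` is never formed. Larger `lambda` gives smoother images.
#'
#' @param A A `pat_sysmat` or plain matrix.
#' @param b A `pat_sinogram` or data vector.
#' @param params `recon_params("tikhonov", lambda = ...)`; `lambda > 0`.
#' @return A `pat_recon`; `objective_trace` holds the (monotone) normal-
#'   equation residual norms.
#' @export
tikhonov_solve <- function(A, b, params = recon_params("tikhonov", lambda = 1)) {
  stopifnot(inherits(params, "pat_recon_params"))
  if (params$lambda <= 0)
    stop("Tikhonov regularization requires lambda > 0", call. = FALSE)
  y <- check_data(A, b)
  sol <- normal_cg(A, y, lambda = params$lambda,
                   max_iters = params$max_iters, tol = params$tol)
  if (!sol$converged)
    warning(sprintf(
      "Tikhonov CG stopped at %d iterations with relative residual %.3g",
      sol$iterations, sol$relres), call. = FALSE)
  res <- sqrt(sum((op_forward(A, sol$x) - y)^2))
  new_recon_result(result_image(A, sol$x), params,
                   objective_trace = sol$residual_trace,
                   residual_norm = res, iterations = sol$iterations,
                   converged = sol$converged)
}

#' L1-regularized reconstruction by majorization-minimization
#'
#' Minimises `||Ax - b||^2 + lambda ||x||_1` with the iterative shrinkage
#' scheme obtained from a quadratic majorizer of the data term:
#' `x <- soft(x + (1/c) A'(b - Ax), lambda / (2 c))` with `c` at least the
#' largest eigenvalue of `A'A` (estimated by power iteration with a 5%
#' safety factor). The objective is non-increasing across iterations;
#' negative values are retained in the output (clipping, if any, is an
#' evaluation-stage choice).
#'
#' @param A A `pat_sysmat` or plain matrix.
#' @param b A `pat_sinogram` or data vector.
#' @param params `recon_params("l1", lambda = ...)`; `lambda > 0`.
#' @param step_c Majorizer constant; default `1.05 *` the power-iteration
#'   estimate of `||A||^2`.
#' @return A `pat_recon`; `objective_trace` holds the L1 objective values.
#' @export
l1_mm_solve <- function(A, b, params = recon_params("l1", lambda = 1),
                        step_c = NULL) {
  stopifnot(inherits(params, "pat_recon_params"))
  if (params$lambda <= 0)
    stop("L1 regularization requires lambda > 0", call. = FALSE)
  y <- check_data(A, b)
  if (is.null(step_c)) step_c <- 1.05 * operator_norm_sq(A)
  if (step_c <= 0) step_c <- 1
  lam <- params$lambda
  x <- numeric(op_ncol(A))
  r <- y                                   # b - A x
  obj <- sum(r^2) + lam * sum(abs(x))
  trace <- obj
  it <- 0L
  while (it < params$max_iters) {
    it <- it + 1L
    x_new <- sthresh_asym(x + op_adjoint(A, r) / step_c,
                          lam / (2 * step_c), lam / (2 * step_c))
    r_new <- y - op_forward(A, x_new)
    obj_new <- sum(r_new^2) + lam * sum(abs(x_new))
    if (obj_new > obj * (1 + 1e-10) + 1e-12)
      stop("L1 objective increased: step constant too small; ",
           "increase step_c above ||A||^2", call. = FALSE)
    delta <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x_new^2)), 1e-30)
    x <- x_new; r <- r_new; obj <- obj_new
    trace <- c(trace, obj)
    if (delta < params$tol) break
  }
  new_recon_result(result_image(A, x), params, objective_trace = trace,
                   residual_norm = sqrt(sum(r^2)), iterations = it,
                   converged = it < params$max_iters)
}

#' Sweep the regularization parameter against ground truth
#'
#' Runs a reconstruction method over a grid of `lambda` values, segments
#' each result (clip negatives, threshold at the image mean by default) and
#' scores Dice against the ground-truth mask. This mirrors heuristic
#' parameter selection against the figure of merit, and is only meaningful
#' in simulation where the truth is known.
#'
#' @param A A `pat_sysmat`.
#' @param b A `pat_sinogram`.
#' @param method `"tikhonov"` or `"l1"`.
#' @param lambda_grid Positive lambda values to try (non-empty).
#' @param truth A ground-truth `pat_pressure_image` or `pat_binary_mask`.
#' @param segment Segmentation function applied to each reconstruction
#'   (default [segment_threshold_mean()]).
#' @param ... Passed to the solver (e.g. `max_iters`).
#' @return List with `best_params` (a `pat_recon_params` at the Dice-argmax
#'   lambda), `best_dice`, and `table`, a tibble with one row per lambda.
#' @export
sweep_lambda <- function(A, b, method = c("tikhonov", "l1"), lambda_grid,
                         truth, segment = segment_threshold_mean, ...) {
  method <- match.arg(method)
  if (length(lambda_grid) == 0)
    stop("lambda_grid must be non-empty", call. = FALSE)
  stopifnot(all(lambda_grid > 0))
  truth_mask <- as_binary_mask(truth)
  solver <- switch(method, tikhonov = tikhonov_solve, l1 = l1_mm_solve)
  rows <- lapply(lambda_grid, function(lam) {
    rec <- solver(A, b, recon_params(method, lambda = lam, ...))
    mask <- segment(rec$image)
    tibble::tibble(lambda = lam,
                   dice = dice(truth_mask, mask),
                   residual_norm = rec$residual_norm,
                   iterations = rec$iterations)
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab$dice)
  list(best_params = recon_params(method, lambda = tab$lambda[best], ...),
       best_dice = tab$dice[best],
       table = tab)
}
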