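#' Non-negative least squares from normal equations
#'
#' Active-set solver for `min ||Ax - b||^2 s.t. x >= 0`, working directly on
#' the Gram matrix `G = t(A) %*% A` and the vector `h = t(A) %*% b`
#' (Lawson-Hanson iteration in the normal-equation form of Bro & de Jong's
#' fast NNLS). The Gram interface is what makes the global spectrum fit
#' cheap inside the resampling loop: the Gram matrices of the per-condition
#' design blocks are formed once per bleach-number evaluation and recombined
#' across the amplitude alternation at negligible cost.
#'
#' @param G symmetric positive semi-definite matrix `t(A) %*% A`.
#' @param h vector `t(A) %*% b`.
#' @param tol non-negativity / optimality tolerance; default scales with
#'   `max(diag(G))`.
#' @param max_iter safety cap on inner iterations.
#' @param x0 optional feasible (non-negative) warm start, e.g. the solution
#'   of a nearby problem; the active set is taken from its support.
#' @return the non-negative solution vector.
#' @examples
#' A <- matrix(runif(50), 10, 5); b <- runif(10)
#' x <- nnls_gram(crossprod(A), crossprod(A, b))
#' all(x >= 0)
#' @export
nnls_gram <- function(G, h, tol = NULL, max_iter = NULL, x0 = NULL) {
  n <- length(h)
  if (is.null(tol)) tol <- 10 * n * .Machine$double.eps * max(diag(G), 1e-30)
  if (is.null(max_iter)) max_iter <- 50L * n
  if (!is.null(x0) && length(x0) == n && all(x0 >= 0) && any(x0 > 0)) {
    x <- x0
    passive <- x0 > 0
    # re-solve on the warm-start support; fall back to a cold start if the
    # restricted solution leaves the feasible cone
    s <- numeric(n)
    s[passive] <- .solve_spd(G[passive, passive, drop = FALSE], h[passive])
    if (min(s[passive]) > 0) x <- s else { x <- numeric(n); passive[] <- FALSE }
  } else {
    x <- numeric(n)
    passive <- logical(n)
  }
  iter <- 0L
  repeat {
    grad <- h - as.numeric(G %*% x)
    cand <- which(!passive)
    if (!length(cand) || max(grad[cand]) <= tol) break
    passive[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(x)
      s <- numeric(n)
      s[passive] <- .solve_spd(G[passive, passive, drop = FALSE], h[passive])
      if (min(s[passive]) > 0) { x <- s; break }
      neg <- passive & (s <= 0)
      step <- x[neg] / (x[neg] - s[neg])
      alpha <- min(step[is.finite(step)], 1)
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

# Cholesky solve with a tiny ridge fallback for the near-collinear
# exponential design blocks.
.solve_spd <- function(A, b) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-10 * mean(diag(A))
    for (i in 1:6) {
      ch <- tryCatch(chol(A + diag(ridge, nrow(A))), error = function(e) NULL)
      if (!is.null(ch)) break
      ridge <- ridge * 100
    }
    if (is.null(ch)) return(qr.solve(A, b))
  }
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}
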