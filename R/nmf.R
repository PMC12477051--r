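#' Non-negative matrix factorisation by multiplicative updates
#'
#' Frobenius-loss NMF (Lee-Seung multiplicative updates) with several random
#' restarts; the factorisation with the lowest reconstruction error wins.
#' Written for the modest signature-submatrix sizes used in subtype
#' classification, where a compact dense implementation is adequate.
#'
#' @param x Non-negative numeric matrix (features x samples).
#' @param k Factorisation rank (>= 2).
#' @param n_restarts Number of random restarts (default 20).
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative change in reconstruction error below which a restart
#'   stops early.
#' @param seed Integer seed; restart r uses the derived seed `seed + r`.
#' @return List with `W` (features x k), `H` (k x samples), `error`
#'   (Frobenius norm of the residual) and `restart` (index of the winning
#'   restart).
#' @export
nmf_fit <- function(x, k, n_restarts = 20, max_iter = 300, tol = 1e-6,
                    seed = 1L) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("x must be non-negative")
  if (k < 2) stop("k must be >= 2")
  if (k > min(dim(x))) stop("k exceeds matrix dimensions")
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(as.integer(seed) + r, {
      W <- matrix(runif(nrow(x) * k, 0, max(x)), nrow(x), k)
      H <- matrix(runif(k * ncol(x), 0, 1), k, ncol(x))
      err_prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, x) / (crossprod(W) %*% H + eps))
        W <- W * (tcrossprod(x, H) / (W %*% tcrossprod(H) + eps))
        if (it %% 10 == 0) {
          err <- sqrt(sum((x - W %*% H)^2))
          if (is.finite(err_prev) &&
              abs(err_prev - err) <= tol * max(err_prev, eps)) break
          err_prev <- err
        }
      }
      list(W = W, H = H, error = sqrt(sum((x - W %*% H)^2)))
    })
    if (is.null(best) || fit$error < best$error) {
      best <- fit
      best$restart <- r
    }
  }
  best
}
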