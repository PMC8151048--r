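# Firth-type penalized logistic regression (Jeffreys-prior score
# correction), used as fallback when ML fits separate. Newton iterations on
# the modified score U*(b) = X'(y - p + h (1/2 - p)) with h the hat-matrix
# diagonal. Returns Wald-type SEs from the observed information.
firth_logistic <- function(x, y, maxit = 100, tol = 1e-8) {
  x <- as.matrix(x)
  b <- rep(0, ncol(x))
  converged <- FALSE
  # invert the information, ridging ill-conditioned (collinear) fits
  inv_info <- function(info) {
    tryCatch(solve(info), error = function(e) {
      solve(info + diag(1e-6 * max(diag(info)), ncol(info)))
    })
  }
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% b)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    inv <- inv_info(info)
    h <- rowSums((xw %*% inv) * xw)
    u <- drop(crossprod(x, y - p + h * (0.5 - p)))
    step <- drop(inv %*% u)
    # dampen huge steps far from the optimum
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% b)
  w <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-12)
  info <- crossprod(x * sqrt(w))
  se <- sqrt(pmax(diag(inv_info(info)), 0))
  list(coefficients = setNames(b, colnames(x)),
       se = setNames(se, colnames(x)), converged = converged)
}
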