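# closed-form weighted least squares with linear-theory uncertainties;
# X is the design matrix, w the weights (1/sigma^2)
.wls <- function(X, y, w) {
  W <- w
  A <- crossprod(X * W, X)
  b <- crossprod(X * W, y)
  beta <- solve(A, b)
  fitted <- drop(X %*% beta)
  r <- y - fitted
  n <- length(y); k <- ncol(X)
  s2 <- sum(W * r^2) / max(n - k, 1)
  covm <- solve(A) * s2
  list(coef = unname(drop(beta)), se = unname(sqrt(pmax(diag(covm), 0))),
       cov = covm,
       fitted = fitted, rss_w = sum(W * r^2),
       rsq = 1 - sum(W * r^2) / sum(W * (y - sum(W * y) / sum(W))^2))
}
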