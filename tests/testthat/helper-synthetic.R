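# Shared helpers for the test suite: thin wrappers that build small payload
# objects and apply Poisson counting noise to a noiseless reference.

make_eisf_curve <- function(q, a0, sigma = rep(1e-3, length(q))) {
  out <- data.frame(q = q, a0 = a0, sigma = sigma, a0_raw = a0)
  class(out) <- c("eisf_curve", "data.frame")
  out
}

# Poisson noise at `counts` total counts per q row of a noiseless
# qens_dataset; returns a new qens_dataset with sqrt-count sigmas
poissonize_qens <- function(ref, counts = 1e4) {
  q <- ref$q; omega <- ref$omega
  S <- ref$s_qw[1, , ]; E <- S * 0
  for (j in seq_along(q)) {
    sc <- counts / sum(ref$s_qw[1, j, ])
    cts <- stats::rpois(length(omega), ref$s_qw[1, j, ] * sc)
    S[j, ] <- cts / sc
    E[j, ] <- sqrt(pmax(cts, 1)) / sc
  }
  qens_dataset(q, omega, array(S, c(1, length(q), length(omega))),
               array(E, c(1, length(q), length(omega))),
               ref$resolution, NULL, ref$conditions)
}

max_rel_err <- function(a, b) {
  ok <- abs(b) > 1e-12
  max(abs(a[ok] - b[ok]) / abs(b[ok]))
}
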