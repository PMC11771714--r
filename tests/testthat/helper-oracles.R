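# Independent brute-force oracle for the relaxation fit: coarse grid over
# the two time constants with ordinary linear least squares for the three
# amplitudes at each grid point. Deliberately separate from the package's
# solver (and from its grid fallback, which uses non-negative amplitudes
# and a different grid).
grid_oracle <- function(t, y, n_grid = 40) {
  taus_e <- exp(seq(log(0.1), log(4.99), length.out = n_grid))
  taus_m <- exp(seq(log(5.01), log(60), length.out = n_grid))
  best <- list(rss = Inf)
  for (te in taus_e) for (tm in taus_m) {
    X <- cbind(1, exp(-t / te), exp(-t / tm))
    a <- qr.solve(X, y)
    rss <- sum((y - X %*% a)^2)
    if (rss < best$rss) {
      best <- list(rss = rss, a_qi = a[1], a_qe = a[2], a_qm = a[3],
                   tau_qe = te, tau_qm = tm)
    }
  }
  best
}

# eigen-decomposition oracle for canonical correlations:
# eigenvalues of Sxx^-1 Sxy Syy^-1 Syx are the squared correlations
cca_eigen_oracle <- function(x, y) {
  xs <- scale(x); ys <- scale(y)
  Sxx <- cov(xs); Syy <- cov(ys); Sxy <- cov(xs, ys)
  ev <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy))$values
  sqrt(sort(pmax(Re(ev), 0), decreasing = TRUE))[seq_len(min(ncol(x), ncol(y)))]
}

# small standard fixtures
toy_truth <- function() kinetics_truth(2.0, 1.6, 0.5, 1.0, 23, 1.5)

noisy_relax_series <- function(seed, noise_cv = 0.02, truth = toy_truth()) {
  compute_npq(simulate_trace(truth, noise_cv = noise_cv, seed = seed))
}
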