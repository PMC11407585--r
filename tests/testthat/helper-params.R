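## shared fixtures built in code

## the reference mean-Fano parameter set: p1 = 0.95, tau_P = 0.165 min,
## exponential composite silent cycle of mean 100 min, tau_m = 5 min
ref_params <- function() burstParams(tau_P = 0.165, p1 = 0.95, tau_S = 100,
                                     tau_m = 5)

## random direct-tau_S parameter sets with moderate burst sizes, used for
## simulation-vs-formula checks
random_direct_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    burstParams(tau_P = exp(runif(1, log(0.05), log(5))),
                p1 = runif(1, 0.2, 0.95),
                tau_S = exp(runif(1, log(2), log(200))),
                tau_m = exp(runif(1, log(2), log(10)))))
}

## random component-mode parameter sets
random_component_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    burstParams(tau_P = exp(runif(1, log(0.1), log(2))),
                p1 = runif(1, 0.3, 0.95),
                tau_S1 = exp(runif(1, log(1), log(30))),
                tau_S2 = exp(runif(1, log(1), log(30))),
                tau_S3 = exp(runif(1, log(1), log(30))),
                p2 = runif(1, 0.1, 0.8),
                tau_m = 5))
}

## steady-state grid late enough for burn-in
steady_grid <- function(params, n_pts = 2) {
  dq <- deriveQuantities(params)
  t0 <- 6 * max(dq@period, params@tau_m)
  seq(t0, t0 + (n_pts - 1) * max(dq@period, params@tau_m), length.out = n_pts)
}

## truncated master-equation steady state for the telegraph model:
## states (gene on/off) x (mRNA count 0..N)
telegraph_master_moments <- function(k_on, k_off, k_syn, tau_m, N = 300) {
  nst <- 2 * (N + 1)
  idx <- function(on, m) 2 * m + on + 1  # on in 0/1
  A <- matrix(0, nst, nst)
  for (m in 0:N) {
    for (on in 0:1) {
      i <- idx(on, m)
      out <- 0
      if (on == 0) { A[idx(1, m), i] <- A[idx(1, m), i] + k_on; out <- out + k_on }
      if (on == 1) { A[idx(0, m), i] <- A[idx(0, m), i] + k_off; out <- out + k_off }
      if (on == 1 && m < N) { A[i + 2, i] <- A[i + 2, i] + k_syn; out <- out + k_syn }
      if (m > 0) { A[i - 2, i] <- A[i - 2, i] + m / tau_m; out <- out + m / tau_m }
      A[i, i] <- A[i, i] - out
    }
  }
  A[nst, ] <- 1  # replace one balance row by normalisation
  b <- c(rep(0, nst - 1), 1)
  p <- solve(A, b)
  mvals <- rep(0:N, each = 2)
  mu <- sum(p * mvals)
  v <- sum(p * mvals^2) - mu^2
  c(mean = mu, variance = v, fano = v / mu)
}

## master-equation steady state for instantaneous geometric bursts arriving
## as a Poisson process (the tau_P -> 0 limit with exponential silent
## phase): burst sizes are geometric on {1, 2, ...} with success 1 - p1
compound_poisson_master_moments <- function(rate, p1, tau_m, N = 400) {
  A <- matrix(0, N + 1, N + 1)
  for (m in 0:N) {
    i <- m + 1
    out <- 0
    if (m > 0) { A[i - 1, i] <- A[i - 1, i] + m / tau_m; out <- out + m / tau_m }
    ## burst of size k >= 1 with prob (1-p1) p1^(k-1)
    if (m < N) {
      for (k in 1:(N - m)) {
        A[i + k, i] <- A[i + k, i] + rate * (1 - p1) * p1^(k - 1)
      }
      out <- out + rate * (1 - p1^(N - m))
    }
    A[i, i] <- A[i, i] - out
  }
  A[N + 1, ] <- 1
  b <- c(rep(0, N), 1)
  p <- solve(A, b)
  mvals <- 0:N
  mu <- sum(p * mvals)
  v <- sum(p * mvals^2) - mu^2
  c(mean = mu, variance = v, fano = v / mu)
}
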