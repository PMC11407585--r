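## independently transcribed closed forms of the gene-regulatory function
## (v_max, beta, Omega) for each basic mode with a single binding site,
## in terms of the unbound parameters; used as the oracle for the
## package's generic computation
table_closed_forms <- function(mode_name, eps, base, K_d) {
  p1 <- base@p1; p2 <- base@p2
  tau_A <- base@tau_P / (1 - p1)
  tau_I1 <- (base@tau_S1 + base@tau_S2) / p1
  tau_I2 <- p2 * base@tau_S3 / ((1 - p2) * p1)
  tau_I <- tauS(base) / p1
  dur_row <- function(A, B) {
    ## regulated duration component B (rate-linear in occupancy)
    list(v_max = 1 / ((1 - p1) * (A + eps * B)),
         beta = eps * K_d,
         omega = eps * (A + B) * K_d / (A + eps * B))
  }
  switch(mode_name,
    MEE = dur_row(tau_I, tau_A),
    MEA = dur_row(tau_A + (base@tau_S2 + p2 * base@tau_S3 / (1 - p2)) / p1,
                  base@tau_S1 / p1),
    MFI = dur_row(tau_A + (base@tau_S1 + p2 * base@tau_S3 / (1 - p2)) / p1,
                  base@tau_S2 / p1),
    MCC = dur_row(tau_A + tau_I1, tau_I2),
    MIE = {
      lam <- eps * (1 - p1) / (1 - eps * p1)
      list(v_max = 1 / ((1 - p1) *
                          (tau_A + (1 - eps * p1) / (eps * (1 - p1)) * tau_I)),
           beta = (1 - eps * p1) / (eps * (1 - p1)) * K_d,
           omega = (tau_A + tau_I) * K_d / (lam * tau_A + tau_I))
    },
    MIA = {
      lam <- (1 - eps * p1) / (eps * (1 - p1))
      list(v_max = 1 / ((1 - p1) * (tau_A + lam * tau_I)),
           beta = K_d,
           omega = (tau_A + tau_I) * K_d / (tau_A + lam * tau_I))
    },
    MFC = {
      w <- eps * (1 - p2) / (1 - eps * p2)
      list(v_max = 1 / ((1 - p1) * (tau_A + tau_I1 + w * tau_I2)),
           beta = K_d,
           omega = (tau_A + tau_I1 + tau_I2) * K_d /
             (tau_A + tau_I1 + w * tau_I2))
    },
    MFA = {
      lam <- (1 - eps * p2) / (eps * (1 - p2))
      list(v_max = 1 / ((1 - p1) *
                          (tau_A + tau_I1 + eps * (1 - p2) / (1 - eps * p2) *
                             tau_I2)),
           beta = eps * (1 - p2) / (1 - eps * p2) * K_d,
           omega = (tau_A + tau_I1 + tau_I2) * K_d /
             (lam * (tau_A + tau_I1) + tau_I2))
    })
}

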