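# independent numerical oracle for the three-state splicing scheme:
# dA/dt = -k1 A + k2 BI ; dBI/dt = k1 A - (k2 + k3) BI ; dP/dt = k3 BI
ode_three_state <- function(k1, k2, k3, P_max, times) {
  rhs <- function(t, y, p) {
    list(c(-k1 * y[1] + k2 * y[2],
           k1 * y[1] - (k2 + k3) * y[2],
           k3 * y[2]))
  }
  out <- deSolve::lsoda(c(A = P_max, BI = 0, P = 0), times, rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
  as.data.frame(out)
}

# 2x2 eigen-exponents of the two-step binding system computed directly from
# the rate matrix, independent of the package's trace/determinant shortcut
eigen_two_step <- function(ka, kd, kf, ku, C) {
  M <- matrix(c(-(ka * C + kd + kf), kf,
                -(ka * C - ku),      -ku), nrow = 2)
  sort(-Re(eigen(M)$values), decreasing = TRUE)
}

# convenience: phase fits for a list of simulated sensorgrams
fit_all_phases <- function(sensorgrams, t_assoc = 500) {
  assoc <- lapply(sensorgrams, function(tr) {
    a <- tr[tr$phase == "association", ]
    fit_association(a$time, a$response, conc = attr(tr, "conc"))
  })
  dissoc <- lapply(sensorgrams, function(tr) {
    d <- tr[tr$phase == "dissociation", ]
    fit_dissociation(d$time, d$response, t0 = t_assoc,
                     conc = attr(tr, "conc"))
  })
  list(assoc = assoc, dissoc = dissoc)
}
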