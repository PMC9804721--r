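# Shared parameter sets for the test suite. The consumer is the standard
# worked-example set; resource traits are the package-calibrated defaults.
cp_std <- consumer_params()                 # delta 0.5, T_I 25, beta 150, R_0 0.5
cp_r1 <- consumer_params(R_0 = 1)
cp_r2 <- consumer_params(R_0 = 2)
chp_std <- chemostat_params(S = 1, D = 1)
rt_std <- resource_traits()

# Finite-difference Jacobian of a 2-state RHS, independent of the analytic
# Jacobians used inside the package.
numeric_jacobian <- function(rhs, state, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (rhs(up) - rhs(dn)) / (up[j] - dn[j])
  }
  J
}
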