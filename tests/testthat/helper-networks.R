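# Small fixtures shared across tests (built in code; nothing on disk).

autoreg_h1 <- function(p = 0.5)
  build_autoreg(sigma_b = 0.1, sigma_u = 1, rho_b = 50, rho_u = 1,
                d = 1, h = 1, p = p)

telegraph_net <- function(s_on = 1, s_off = 1, rho0 = 0, rho1 = 10,
                          d = 1, p = 0.5)
  gene_network(data.frame(alpha0 = s_on, alpha1 = s_off, rho0 = rho0,
                          rho1 = rho1, d = d, p = p))

constitutive_net <- function(rho = 2, p = 0.75, d = 1)
  gene_network(data.frame(alpha0 = 0, alpha1 = 0, rho0 = rho, rho1 = 0,
                          d = d, p = p))

# moment state of the spec'd worked 2x2 matching example
example_moment_state <- function(net) {
  st <- moment_state(net, 2)
  st <- moment_entry(st, 0L, 0L, 0.5)
  st <- moment_entry(st, 1L, 0L, 0.5)
  st <- moment_entry(st, 0L, 1L, 2)
  st <- moment_entry(st, 1L, 1L, 4)
  st <- moment_entry(st, 0L, 2L, 6)
  st
}
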