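# Post-translational and post-transcriptional benchmark motifs.
#
# Rate values are package defaults chosen to give moderate molecule numbers
# (tens) and nonlinear loss fluxes comparable to the linear decay rate; see
# the methods vignette. Each system carries a "holimap3" attribute naming
# the tracked species and its gene switch, used by the 3-parameter mapping.

mark3 <- function(rs, track, gene_pair, rho0, rho1, p, d) {
  attr(rs, "holimap3") <- list(track = track, gene_pair = gene_pair,
                               rho0 = rho0, rho1 = rho1, p = p, d = d)
  rs
}

# Two autoregulated genes whose proteins sequester each other into an inert
# complex C.  Negative autoregulation; bursty synthesis.
fixture_sequestration <- function(h = c(1L, 1L),
                                  rho_u = c(40, 30), rho_b = c(4, 3),
                                  d = c(1, 1), p = c(0.5, 0.5),
                                  sigma_b = c(0.02, 0.02),
                                  sigma_u = c(15, 15),
                                  k_bind = 0.01) {
  sp <- c("G1", "G1*", "P1", "G2", "G2*", "P2", "C")
  rx <- list()
  for (j in 1:2) {
    g0 <- paste0("G", j); g1 <- paste0("G", j, "*"); pj <- paste0("P", j)
    rx <- c(rx, list(
      rxn(sigma_b[j], orders = stats::setNames(c(1, h[j]), c(g0, pj)),
          stoich = stats::setNames(c(-1, 1, -h[j]), c(g0, g1, pj))),
      rxn(sigma_u[j], orders = stats::setNames(1, g1),
          stoich = stats::setNames(c(1, -1, h[j]), c(g0, g1, pj))),
      rxn(rho_u[j], orders = stats::setNames(1, g0), burst = pj, p = p[j]),
      rxn(rho_b[j], orders = stats::setNames(1, g1), burst = pj, p = p[j]),
      rxn(d[j], orders = stats::setNames(1, pj),
          stoich = stats::setNames(-1, pj))))
  }
  rx <- c(rx, list(
    rxn(k_bind, orders = c(P1 = 1, P2 = 1), stoich = c(P1 = -1, P2 = -1, C = 1))))
  rs <- reaction_system(sp, rx, pairs = list(c("G1", "G1*"), c("G2", "G2*")))
  mark3(rs, "P1", c("G1", "G1*"), rho_u[1], rho_b[1], p[1], d[1])
}

# One gene whose protein P is reversibly phosphorylated (P -> P1 -> P2) via
# Michaelis-Menten kinetics; the doubly phosphorylated form P2 binds the
# gene (negative autoregulation of synthesis).
fixture_phosphorylation <- function(h = 1L,
                                    rho_u = 60, rho_b = 6, p = 0.5,
                                    d = c(1, 1, 1),
                                    sigma_b = 0.05, sigma_u = 15,
                                    V = c(20, 10, 20, 10),
                                    K = c(20, 20, 20, 20)) {
  sp <- c("G", "G*", "P", "P1", "P2")
  rx <- list(
    rxn(sigma_b, orders = c("G" = 1, P2 = h),
        stoich = stats::setNames(c(-1, 1, -h), c("G", "G*", "P2"))),
    rxn(sigma_u, orders = c("G*" = 1),
        stoich = stats::setNames(c(1, -1, h), c("G", "G*", "P2"))),
    rxn(rho_u, orders = c("G" = 1), burst = "P", p = p),
    rxn(rho_b, orders = c("G*" = 1), burst = "P", p = p),
    rxn(V[1], kind = "mm", mm_sub = "P", mm_K = K[1],
        stoich = c(P = -1, P1 = 1)),
    rxn(V[2], kind = "mm", mm_sub = "P1", mm_K = K[2],
        stoich = c(P = 1, P1 = -1)),
    rxn(V[3], kind = "mm", mm_sub = "P1", mm_K = K[3],
        stoich = c(P1 = -1, P2 = 1)),
    rxn(V[4], kind = "mm", mm_sub = "P2", mm_K = K[4],
        stoich = c(P1 = 1, P2 = -1)),
    rxn(d[1], orders = c(P = 1), stoich = c(P = -1)),
    rxn(d[2], orders = c(P1 = 1), stoich = c(P1 = -1)),
    rxn(d[3], orders = c(P2 = 1), stoich = c(P2 = -1)))
  rs <- reaction_system(sp, rx, pairs = list(c("G", "G*")))
  mark3(rs, "P", c("G", "G*"), rho_u, rho_b, p, d[1])
}

# One gene transcribing mRNA M which represses its own gene (reversible
# binding of one transcript); M decays spontaneously (rate d) and is also
# degraded catalytically by the active form E* of an enzyme switching
# between E and E*.
fixture_mrna_degradation <- function(rho_u = 50, rho_b = 5, p = 0.5, d = 1,
                                     sigma_b = 0.05, sigma_u = 15,
                                     k_on = 2, k_off = 2, alpha = 1) {
  sp <- c("G", "G*", "M", "E", "E*")
  rx <- list(
    rxn(sigma_b, orders = c("G" = 1, M = 1),
        stoich = c("G" = -1, "G*" = 1, M = -1)),
    rxn(sigma_u, orders = c("G*" = 1),
        stoich = c("G" = 1, "G*" = -1, M = 1)),
    rxn(rho_u, orders = c("G" = 1), burst = "M", p = p),
    rxn(rho_b, orders = c("G*" = 1), burst = "M", p = p),
    rxn(d, orders = c(M = 1), stoich = c(M = -1)),
    rxn(k_on, orders = c(E = 1), stoich = c(E = -1, "E*" = 1)),
    rxn(k_off, orders = c("E*" = 1), stoich = c(E = 1, "E*" = -1)),
    rxn(alpha, orders = c(M = 1, "E*" = 1), stoich = c(M = -1)))
  rs <- reaction_system(sp, rx, pairs = list(c("G", "G*"), c("E", "E*")))
  mark3(rs, "M", c("G", "G*"), rho_u, rho_b, p, d)
}

# mRNA (from gene G1) with two microRNA (from gene G2) binding sites:
# M + R <-> C1, C1 + R <-> C2.  Within the complexes the mRNA and microRNA
# are degraded at their own rates.  Gene states switch spontaneously.
fixture_mirna_mrna <- function(rho_u = c(40, 30), rho_b = c(4, 60),
                               p = c(0.5, 0.5),
                               alpha0 = c(1, 1), alpha1 = c(1, 1),
                               d1 = 1, d2 = 1,
                               k_on = c(0.02, 0.02), k_off = c(1, 1),
                               a = c(1, 1), b = c(1, 1)) {
  sp <- c("G1", "G1*", "M", "G2", "G2*", "R", "C1", "C2")
  rx <- list(
    rxn(alpha0[1], orders = c(G1 = 1), stoich = c(G1 = -1, "G1*" = 1)),
    rxn(alpha1[1], orders = c("G1*" = 1), stoich = c(G1 = 1, "G1*" = -1)),
    rxn(rho_u[1], orders = c(G1 = 1), burst = "M", p = p[1]),
    rxn(rho_b[1], orders = c("G1*" = 1), burst = "M", p = p[1]),
    rxn(alpha0[2], orders = c(G2 = 1), stoich = c(G2 = -1, "G2*" = 1)),
    rxn(alpha1[2], orders = c("G2*" = 1), stoich = c(G2 = 1, "G2*" = -1)),
    rxn(rho_u[2], orders = c(G2 = 1), burst = "R", p = p[2]),
    rxn(rho_b[2], orders = c("G2*" = 1), burst = "R", p = p[2]),
    rxn(d1, orders = c(M = 1), stoich = c(M = -1)),
    rxn(d2, orders = c(R = 1), stoich = c(R = -1)),
    rxn(k_on[1], orders = c(M = 1, R = 1), stoich = c(M = -1, R = -1, C1 = 1)),
    rxn(k_off[1], orders = c(C1 = 1), stoich = c(M = 1, R = 1, C1 = -1)),
    rxn(k_on[2], orders = c(C1 = 1, R = 1), stoich = c(C1 = -1, R = -1, C2 = 1)),
    rxn(k_off[2], orders = c(C2 = 1), stoich = c(C1 = 1, R = 1, C2 = -1)),
    rxn(a[1], orders = c(C1 = 1), stoich = c(C1 = -1, R = 1)),   # mRNA lost from C1
    rxn(a[2], orders = c(C1 = 1), stoich = c(C1 = -1, M = 1)),   # microRNA lost from C1
    rxn(b[1], orders = c(C2 = 1), stoich = c(C2 = -1, R = 2)),   # mRNA lost from C2
    rxn(b[2], orders = c(C2 = 1), stoich = c(C2 = -1, C1 = 1)))  # microRNA lost from C2
  rs <- reaction_system(sp, rx,
                        pairs = list(c("G1", "G1*"), c("G2", "G2*")))
  mark3(rs, "M", c("G1", "G1*"), rho_u[1], rho_b[1], p[1], d1)
}
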