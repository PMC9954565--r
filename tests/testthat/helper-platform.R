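# Shared fixtures: the as-built platform and the operating flow rates.
plat <- build_default_platform()
geom <- plat$geometry
marray <- plat$array
flow_op <- per_aperture_rates(geom, Q_inj_uLs = 0.5, ratio = 1.4)

# Fourier series for a slab 0 <= x <= L, C(0) = 1, insulated far end:
# concentration at the far end as a function of Fo = D t / L^2.
slab_far_end <- function(Fo, nmax = 80) {
  n <- 0:nmax
  1 - sum(4 / (pi * (2 * n + 1)) * (-1)^n *
            exp(-(2 * n + 1)^2 * pi^2 * Fo / 4))
}

# Centre concentration of a sphere with fixed surface concentration 1,
# initially 0, as a function of Fo = D t / R^2.
sphere_centre <- function(Fo, nmax = 80) {
  n <- 1:nmax
  1 + 2 * sum((-1)^n * exp(-n^2 * pi^2 * Fo))
}
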