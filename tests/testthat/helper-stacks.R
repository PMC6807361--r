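# Small synthetic stacks used across tests.

# Pure absorber slab: every interaction deposits the full weight, so only
# photons whose first free path exceeds the thickness are transmitted
# (Beer-Lambert analytic oracle).
absorbing_slab <- function(mu_a = 10, d = 0.1, n = 1) {
  layer_stack(layer("absorber", n = n, mu_a = mu_a, mu_s = 0, g = 1,
                    thickness = d))
}

# Vacuum box with matched indices: ballistic transport, exit angles equal
# launch angles (spherical-cap oracle for isotropic sources).
vacuum_stack <- function(d = 0.5) {
  layer_stack(layer("vacuum", n = 1, mu_a = 0, mu_s = 0, g = 1,
                    thickness = d))
}

# Two clear absorbing layers with an index step at their interface
# (normal-incidence boundary physics, no scattering).
two_layer_clear <- function(mu_a = 1) {
  layer_stack(rbind(
    layer("upper", n = 1.33, mu_a = mu_a, mu_s = 0, g = 1, thickness = 0.05),
    layer("lower", n = 1.45, mu_a = mu_a, mu_s = 0, g = 1, thickness = 0.05)))
}
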