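## Shared fixtures: water at 20 C, a standard cell, and a ~6 S / 50 kDa-like
## reference particle (RH = 2 nm, buoyant mass 2.25e-20 g).

water20 <- function() solvent_context(293.15, 0.01002, 0.998)

std_cell <- function() cell_geometry(6.0, 7.2)

std_species <- function(c0 = 1) {
  sedimenting_species(RH_cm = 2e-7, mb_g = 2.25e-20, c0 = c0)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
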