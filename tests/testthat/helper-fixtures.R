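# shared fixture builders for the suite (everything generated in code)

# seeded random 3x3 velocity-gradient tensor
random_gradU <- function(seed, scale = 10) {
  set.seed(seed)
  matrix(stats::rnorm(9, sd = scale), 3, 3)
}

# antisymmetric (rigid-rotation) tensor from a rotation-rate vector
rotation_gradU <- function(omega) {
  matrix(c(0, -omega[3], omega[2],
           omega[3], 0, -omega[1],
           -omega[2], omega[1], 0), 3, 3, byrow = TRUE)
}

# flatten a 3x3 gradU into the row-major 1x9 layout the field tables use
flatten_gradU <- function(gradU) matrix(t(gradU), nrow = 1)

# experimental constant set used as generator truth throughout
constants_experimental <- function() {
  sherwood_constants(1.68, 0.551, gamma = 1.18, provenance = "experimental")
}
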