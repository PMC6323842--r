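# Shared fixtures, built in code.

# compact grid for geometry/dose tests: SI axis 90 voxels covers a 2-3 cm
# sphere plus the +-15 mm travel and penumbra
small_grid <- function() phantom_grid(c(72L, 72L, 90L))

# a noise-free homogeneous reference trace: A = 10 mm, P = 4 s, 100 s
homogeneous_trace <- function(A = 10, P = 4, seed = 1L) {
  simulate_trace(motion_params(A, 0, P, 0, duration_s = 100, seed = seed))
}

# direct evaluation of the cycle waveform, independent of the generator
cos4_displacement <- function(A, P, t) A * (cos(pi * t / P)^4 - 0.5)
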