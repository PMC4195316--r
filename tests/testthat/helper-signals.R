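# Shared fixtures, generated in code at test time.

# short band-limited stimulus on the 1-ms analysis grid
short_noise <- function(cutoff = 20, dur = 30000, dt = 1, seed = 7)
  gen_bandlimited_gaussian(cutoff, dur, dt, seed)

# constant-current continuous signal at the simulation step
const_drive <- function(I, dur = 10000, dt = 0.025)
  continuous_signal(rep(I, round(dur / dt)), dt, "pA")

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
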