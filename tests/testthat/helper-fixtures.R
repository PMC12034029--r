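# shared small fixtures; everything is generated in code

ro_tiny <- function() readout_spec(8, oversampling = 2)
ro_small <- function() readout_spec(32, oversampling = 2)

# order-13 approximation of the classic golden angle on the extended
# full-circle index space (S = 233, increment 144, index space 466); the
# even-increment warning is expected and part of the stated convention
scheme_233_ext <- function() suppressWarnings(raga_scheme(1, 13, "extended"))

expect_exponent_sign <- function(x, printed) {
  expect_equal(sign(x), sign(printed))
  expect_equal(floor(log10(abs(x))), floor(log10(abs(printed))))
}
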