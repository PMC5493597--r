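# shared helpers: independent oracles and small fixture builders

# direct 2D DFT, O(n^4) matrix form — the independent oracle for fft-based
# stages (kept deliberately naive)
direct_dft2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  Er <- exp(-2i * pi * outer(0:(nr - 1), 0:(nr - 1)) / nr)
  Ec <- exp(-2i * pi * outer(0:(nc - 1), 0:(nc - 1)) / nc)
  Er %*% x %*% Ec
}

white_pair <- function(shape, seed, sigma = 1, px = 2) {
  list(a = make_white_noise(generator_spec("white_noise", shape, px,
                                           seed = seed, sigma = sigma)),
       b = make_white_noise(generator_spec("white_noise", shape, px,
                                           seed = seed + 500000L,
                                           sigma = sigma)))
}

white_dataset <- function(n, shape, base_seed, sigma = 1, px = 2) {
  make_condition(n, generator_spec("white_noise", shape, px, seed = 1,
                                   sigma = sigma), base_seed = base_seed)
}

# a micasa_result-shaped object built from explicit curves, for
# compare_conditions unit tests
fake_result <- function(grid, est, lo, hi, label = "x", level = 0.99) {
  ci <- micasa:::ci_function(grid, est, lo, hi, level, dof = 9)
  structure(list(log_spectrum_a = ci, log_spectrum_b = ci,
                 atanh_coherence = ci, var_log_spectrum_a = ci,
                 var_log_spectrum_b = ci, var_atanh_coherence = ci,
                 grid = grid, N = 3, M = 7, NM = 21, label = label,
                 config = analysis_config(confidence_level = level)),
            class = "micasa_result")
}
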