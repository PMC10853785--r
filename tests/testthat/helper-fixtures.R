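# shared fixtures: frozen default circuits and small helpers

p_exp <- default_circuit("experimental")
p_ctrl <- default_circuit("control")

# a hand-built trajectory with known shape (peak exactly 2x plateau)
toy_trajectory <- function(values, dt = 0.5) {
  tr <- data.frame(time_h = seq_along(values) * dt - dt,
                   araC = values, tetR = 1, N = 1,
                   growth_rate = 0, dilution_rate = 0, stage_index = 1L)
  class(tr) <- c("trajectory", "data.frame")
  tr
}

# random valid states/parameters for property-style loops
random_state <- function() system_state(araC = runif(1, 0, 5),
                                        tetR = runif(1, 0, 3),
                                        N = runif(1, 0, 1))
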