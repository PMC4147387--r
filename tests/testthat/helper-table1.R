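# Printed values of the replay fixture's source table, in fixture row order.
table1_expected_labels <- c("536 Kb", "182 Kb", "374 Kb", "1.67 Mb",
                            "502 Kb", "449 Kb", "411 Kb", "160 Kb",
                            "757 Kb", "175 Kb", "410 Kb", "473 Kb")

# Tiny deterministic config for fast pipeline tests.
test_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}
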