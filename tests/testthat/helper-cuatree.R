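# Shared fixtures and small helpers for the suite.

base_cfg <- base_case_config()

# relative difference against a reference value
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# the eight base parameters as a named list of (id, Table-3 DSA bounds and
# printed lower/upper ICERs); frozen from the published one-way table
published_dsa <- data.frame(
  parameter_id = c("reference.p_error", "intervention.p_error",
                   "reference.error_cost", "intervention.error_cost",
                   "reference.labour_cost", "intervention.labour_cost",
                   "reference.utility_decrement",
                   "intervention.utility_decrement"),
  icer_low = c(-36217.1131, -36165.69, -20390.73, -39989.37,
               -36026.31, -38309.93, -48171.29, -35080.89),
  icer_high = c(-36732.82, -36940.98, -55644.98, -32686.06,
                -37184.98, -34433.05, -29429.58, -38119.75),
  stringsAsFactors = FALSE)
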