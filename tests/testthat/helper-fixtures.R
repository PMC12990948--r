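# Write a small two-file study-table fixture and return the paths.
# One study: control + 2 manipulated (one distribution-based, one
# reported-only), plus a second study in another parameter category.
write_demo_tables <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  meta <- data.frame(
    study_id = c("kimA", "kimA", "kimA", "taitB", "taitB"),
    condition_id = c("kimA_ctrl", "kimA_low", "kimA_rep", "taitB_ctrl", "taitB_shift"),
    role = c("control", "manipulated", "manipulated", "control", "manipulated"),
    parameter_category = c("temperature", "temperature", "temperature", "pH", "pH"),
    manipulation_type = c("control", "constant lower setpoint",
                          "constant lower setpoint", "control",
                          "shift to lower setpoint"),
    cell_line = c("CHO DG44", "CHO DG44", "CHO DG44", "CHO GS", "CHO GS"),
    product = c("IgG", "IgG", "IgG", "IgG4", "IgG4"),
    culture_mode = c("batch", "batch", "batch", "fed_batch", "fed_batch"),
    reference = "Demo et al.",
    reported_FI = c(NA, NA, 96.5, NA, NA),
    reported_GI = c(NA, NA, 18.2, NA, NA),
    reported_SI = c(NA, NA, 2.1, NA, NA),
    stringsAsFactors = FALSE)
  dist <- data.frame(
    condition_id = c(rep("kimA_ctrl", 3), rep("kimA_low", 3),
                     rep("taitB_ctrl", 4), rep("taitB_shift", 4)),
    glycan = c("FA2G0", "FA2G1", "FA2G2",
               "FA2G0", "FA2G1", "FA2G1S1",
               "FA2G0", "FA2G1", "FA2G2", "A2G0",
               "FA2G0", "FA2G1", "FA2G2", "A2G0"),
    relative_abundance_percent = c(50, 30, 20,
                                   60, 30, 10,
                                   45, 25, 20, 10,
                                   55, 20, 15, 10),
    stringsAsFactors = FALSE)
  mp <- file.path(dir, "conditions.csv")
  dp <- file.path(dir, "distributions.csv")
  utils::write.csv(meta, mp, row.names = FALSE, na = "")
  utils::write.csv(dist, dp, row.names = FALSE)
  list(meta = mp, dist = dp, dir = dir)
}
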