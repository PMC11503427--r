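# Small cohort fixtures built in code.

toy_cohort <- function(tsh, ft4, ui, period = "T1",
                       anti_tpo = NULL, anti_tpo_pos = NULL) {
  n <- max(length(tsh), length(ft4), length(ui),
           length(anti_tpo), length(anti_tpo_pos))
  if (is.null(anti_tpo)) anti_tpo <- NA_real_
  if (is.null(anti_tpo_pos)) anti_tpo_pos <- NA
  cohort(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    period = rep_len(period, n),
    tsh_uIU_mL = rep_len(tsh, n),
    ft4_ng_dL = rep_len(ft4, n),
    anti_tpo_U_mL = rep_len(anti_tpo, n),
    anti_tpo_pos = rep_len(anti_tpo_pos, n),
    ui_ug_L = rep_len(ui, n),
    stringsAsFactors = FALSE))
}

random_cohort <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  toy_cohort(tsh = rlnorm(n, 0.3, 0.5), ft4 = runif(n, 0.8, 1.8),
             ui = rlnorm(n, 4.8, 0.5),
             period = sample(period_levels(), n, replace = TRUE),
             anti_tpo_pos = runif(n) < 0.1)
}

# comparison helper: drop cohort class and provenance so data-frame equality
# checks only the data
strip_cohort <- function(x) {
  d <- as.data.frame(x)
  attr(d, "provenance") <- NULL
  class(d) <- "data.frame"
  d
}
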