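# shared fixture builders; everything is generated in code

# three-SNP harmonized fixture used by the IVW/Q oracles
h_ivw3 <- function() {
  harmonized_set(beta_exp = c(0.1, 0.2, 0.3), se_exp = c(0.01, 0.01, 0.01),
                 beta_out = c(0.04, 0.12, 0.18), se_out = c(0.01, 0.01, 0.01))
}

# exactly collinear fixture: by = 0.02 + 0.5 * bx
h_egger_collinear <- function() {
  harmonized_set(beta_exp = c(0.1, 0.2, 0.3), se_exp = c(0.01, 0.01, 0.01),
                 beta_out = c(0.07, 0.12, 0.17), se_out = c(0.01, 0.01, 0.01))
}

# equal-weight ratios 0.4 / 0.5 / 0.6
h_ratios3 <- function() {
  harmonized_set(beta_exp = c(1, 1, 1), se_exp = c(0.1, 0.1, 0.1),
                 beta_out = c(0.4, 0.5, 0.6), se_out = c(1, 1, 1))
}

# small well-formed panel as a plain data.frame
toy_panel_df <- function(n = 3) {
  data.frame(
    rsid = paste0("rs", seq_len(n)),
    chromosome = rep("1", n),
    position = seq_len(n) * 1000L,
    effect_allele = rep("A", n), other_allele = rep("G", n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.02, n),
    pvalue = rep(1e-8, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
}

# instrument-selected harmonized set from a synthetic pair / chain
select_and_harmonize <- function(exposure, outcome, ld = NULL) {
  harmonize(select_instruments(exposure, ld), outcome)
}
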