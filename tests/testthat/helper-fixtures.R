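# Small genomes and configs shared across tests. A toy genome keeps
# simulation-heavy tests fast while the bundled mouse genome is used where
# chromosome identity matters.

toy_chromosomes <- function() {
  data.frame(
    name = c("1", "2", "3", "X", "Y"),
    length = c(250e6, 120e6, 60e6, 170e6, 90e6),
    is_sex = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# noiseless study-shaped config (no QC artifacts) on the full mouse genome
noiseless_config <- function(...) {
  sim_config(dispersion = 0, overrep_frac = 0, qc_fail_prob = 0, bias_sd = 0, ...)
}

# a single euploid chromatid configuration on the mouse complement
euploid_configuration <- function(pair_id = "pair01", treatment = "control") {
  chroms <- c(as.character(1:19), "X")
  egg <- stats::setNames(rep(2L, length(chroms)), chroms)
  structure(list(pair_id = pair_id, treatment = treatment,
                 egg = egg, pb = 4L - egg, n_errors = 0L,
                 severity = "euploid", catastrophic = FALSE),
            class = "chromatid_config")
}

# configuration with specified abnormal egg copies, e.g. list(`4` = 4L)
aneuploid_configuration <- function(abnormal, pair_id = "pair01",
                                    treatment = "50nM") {
  cc <- euploid_configuration(pair_id, treatment)
  for (ch in names(abnormal)) cc$egg[ch] <- as.integer(abnormal[[ch]])
  cc$pb <- 4L - cc$egg
  cc$n_errors <- sum(cc$egg != 2L)
  cc$severity <- if (cc$n_errors == 0L) "euploid" else
    if (cc$n_errors <= 3L) "1-3" else ">=4"
  cc
}

# recovery fraction of designated egg copies against simulated truth
recovery_rate <- function(report) {
  truth <- report$truth
  names(truth) <- vapply(truth, `[[`, character(1), "pair_id")
  tot <- 0L; good <- 0L
  for (pid in names(report$callsets)) {
    cs <- report$callsets[[pid]]
    tr <- truth[[pid]]
    ok <- !is.na(cs$egg) & cs$egg == tr$egg[cs$chrom]
    tot <- tot + nrow(cs)
    good <- good + sum(ok)
  }
  good / tot
}
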