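test_that("segregation outcomes always conserve four chromatids per chromosome", {
  cfg <- sim_config()
  configs <- simulate_segregation(cfg, seed = 5)
  expect_equal(length(configs), sum(cfg$groups$n_pairs))
  for (cc in configs) {
    expect_true(all(cc$egg + cc$pb == 4L))
    expect_true(all(cc$egg >= 0L & cc$egg <= 4L))
    expect_false("Y" %in% names(cc$egg))
    expect_equal(cc$n_errors, sum(cc$egg != 2L))
  }
})

test_that("segregation limits: no errors and forced NDJ", {
  cfg0 <- sim_config(groups = data.frame(name = "g", n_pairs = 50L,
                                         p_err = 0, p_cat = 0))
  for (cc in simulate_segregation(cfg0, seed = 1)) {
    expect_true(all(cc$egg == 2L))
  }
  cfg1 <- sim_config(groups = data.frame(name = "g", n_pairs = 50L,
                                         p_err = 1, p_cat = 0),
                     q_ndj = 1)
  for (cc in simulate_segregation(cfg1, seed = 1)) {
    expect_true(all(cc$egg %in% c(0L, 4L)))
  }
})

test_that("error incidence matches the closed-form binomial rate", {
  p <- 0.05
  cfg <- sim_config(groups = data.frame(name = "g", n_pairs = 10000L,
                                        p_err = p, p_cat = 0))
  configs <- simulate_segregation(cfg, seed = 99)
  frac <- mean(vapply(configs, function(cc) cc$n_errors > 0, logical(1)))
  expected <- 1 - (1 - p)^20  # 20 chromosomes at independent risk
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("catastrophic events are whole-complement with 1-4 exceptions", {
  cfg <- sim_config(groups = data.frame(name = "g", n_pairs = 200L,
                                        p_err = 0, p_cat = 1))
  for (cc in simulate_segregation(cfg, seed = 17)) {
    expect_true(cc$catastrophic)
    expect_gte(cc$n_errors, 4L)
    # one whole-complement direction: the majority value is 0 or 4
    major <- as.integer(names(which.max(table(cc$egg))))
    expect_true(major %in% c(0L, 4L))
    n_exc <- sum(cc$egg != major)
    expect_true(n_exc >= 1L && n_exc <= 4L)
  }
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- sim_config()
  a <- simulate_segregation(cfg, seed = 8)
  b <- simulate_segregation(cfg, seed = 8)
  expect_identical(a, b)
  ra <- simulate_read_counts(a[1:4], cfg, seed = 9)
  rb <- simulate_read_counts(b[1:4], cfg, seed = 9)
  expect_identical(ra, rb)
  ma <- simulate_morphokinetics(a, cfg, seed = 10)
  mb <- simulate_morphokinetics(b, cfg, seed = 10)
  expect_identical(ma, mb)
})

test_that("noiseless counts double on a 4-chromatid chromosome", {
  cfg <- noiseless_config()
  cc <- aneuploid_configuration(list(`4` = 4L))
  counts <- simulate_read_counts(list(cc), cfg, seed = 1)
  egg <- counts$pair01_egg
  b <- egg$binning
  full4 <- unique(round(egg$counts[b$chrom == "4" &
                                     b$end - b$start == cfg$window_size], 6))
  full1 <- unique(round(egg$counts[b$chrom == "1" &
                                     b$end - b$start == cfg$window_size], 6))
  expect_length(full4, 1L)
  expect_length(full1, 1L)
  expect_equal(full4 / full1, 2)
  # euploid pair without biases: all full-width autosome bin means equal
  pb <- counts$pair01_pb  # pb lost chromosome 4 entirely
  expect_equal(unique(pb$counts[b$chrom == "4"]), 0)
})

test_that("negative-binomial noise matches its moment closed form", {
  # one chromosome, deterministic expectation mu per bin; draw replicates
  chroms <- data.frame(name = "1", length = 100e6, is_sex = FALSE)
  cfg <- sim_config(groups = data.frame(name = "g", n_pairs = 1L,
                                        p_err = 0, p_cat = 0),
                    chromosomes = chroms, depth = 5e5, dispersion = 50,
                    bias_sd = 0, overrep_frac = 0, qc_fail_prob = 0)
  chroms_v <- "1"
  cc <- structure(list(pair_id = "p", treatment = "g",
                       egg = stats::setNames(2L, "1"),
                       pb = stats::setNames(2L, "1"),
                       n_errors = 0L, severity = "euploid",
                       catastrophic = FALSE), class = "chromatid_config")
  draws <- unlist(lapply(1:100, function(i)
    simulate_read_counts(list(cc), cfg, seed = i)$p_egg$counts))
  mu <- 5e5 / 10  # 10 equal bins
  expect_equal(mean(draws), mu, tolerance = 0.01)
  cv_expected <- sqrt(1 / mu + 1 / 50)
  cv_observed <- stats::sd(draws) / mean(draws)
  # 1000 draws: Monte-Carlo error on the CV is a few percent
  expect_lt(abs(cv_observed - cv_expected) / cv_expected, 0.10)
})

test_that("normal panel is 40,XY: X bins at half the autosome level", {
  cfg <- noiseless_config()
  panel <- simulate_normal_panel(cfg, seed = 2, n_samples = 1)
  expect_equal(length(attr(panel, "copy_map")), 21L)
  expect_equal(unname(attr(panel, "copy_map")[c("1", "X", "Y")]), c(2L, 1L, 1L))
  p <- panel[[1]]
  b <- p$binning
  full <- b$end - b$start == cfg$window_size
  x_bins <- unique(round(p$counts[b$chrom == "X" & full], 6))
  a_bins <- unique(round(p$counts[b$chrom == "1" & full], 6))
  expect_length(x_bins, 1L)
  expect_length(a_bins, 1L)
  expect_equal(x_bins / a_bins, 0.5)
})

test_that("averaging independent noisy panels converges to the noiseless panel", {
  cfg_noisy <- sim_config(dispersion = 20, bias_sd = 0, overrep_frac = 0,
                          qc_fail_prob = 0)
  cfg_clean <- noiseless_config()
  clean <- simulate_normal_panel(cfg_clean, seed = 3, n_samples = 1)[[1]]$counts
  err_of <- function(k) {
    reps <- simulate_normal_panel(cfg_noisy, seed = 3, n_samples = k)
    avg <- rowMeans(vapply(reps, `[[`, numeric(length(clean)), "counts"))
    sqrt(mean((avg - clean)^2))
  }
  e1 <- err_of(4); e2 <- err_of(64)
  # RMS error shrinks like 1/sqrt(k): 16x replicates -> ~4x smaller
  expect_lt(e2 / e1, 0.45)
})

test_that("morphokinetic draws respect class means and the dMI identity", {
  cfg <- sim_config()
  configs <- list(euploid_configuration("e1"),
                  aneuploid_configuration(list(`1` = 4L), "a1"))
  m <- simulate_morphokinetics(configs, cfg, seed = 6)
  mii <- m[m$status == "MII", ]
  expect_equal(mii$dMI, mii$tPB1 - mii$tGVBD)
  expect_true(all(mii$tPB1 > mii$tGVBD))

  # degenerate SD = 0: every record is exactly at the class means
  cfg0 <- sim_config()
  cfg0$morpho$tgvbd_sd[] <- 0
  cfg0$morpho$tpb1_sd[] <- 0
  cfg0$immature$n_gv[] <- 0L
  cfg0$immature$n_gvbd_only[] <- 0L
  m0 <- simulate_morphokinetics(list(euploid_configuration("e1")), cfg0, seed = 1)
  expect_equal(m0$dMI, 9.19 - 0.92)
})

test_that("mean dMI of many euploid draws matches the configured class means", {
  cfg <- sim_config()
  configs <- lapply(sprintf("e%04d", 1:10000), euploid_configuration)
  cfg$immature$n_gv[] <- 0L
  cfg$immature$n_gvbd_only[] <- 0L
  m <- simulate_morphokinetics(configs, cfg, seed = 12)
  sem <- stats::sd(m$dMI) / sqrt(nrow(m))
  expect_lt(abs(mean(m$dMI) - (9.19 - 0.92)), 3 * sem + 0.01)
})

test_that("QC-failure designation drives the mapped fraction below 0.90", {
  cfg <- sim_config(qc_fail_prob = 0.5, dispersion = 0, overrep_frac = 0)
  cc <- euploid_configuration()
  counts <- simulate_read_counts(rep(list(cc), 30), cfg, seed = 13)
  for (s in counts) {
    if (s$truth$qc_fail) expect_lt(s$mapped_fraction, 0.90)
    else expect_gte(s$mapped_fraction, 0.90)
  }
})

test_that("forced overrepresented bins exceed the 1000-count cutoff", {
  cfg <- sim_config(overrep_frac = 0.02, qc_fail_prob = 0)
  cc <- euploid_configuration()
  counts <- simulate_read_counts(list(cc), cfg, seed = 14)
  egg <- counts$pair01_egg
  idx <- egg$truth$overrep_bins
  expect_gt(length(idx), 0)
  expect_true(all(egg$counts[idx] > 1000))
  masked <- filter_bins(egg)
  expect_true(all(masked$mask[idx]))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(q_ndj = 1.5), "probabilities")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(dispersion = -1), "dispersion")
  cfg <- sim_config()
  cc <- euploid_configuration()
  cc$egg <- cc$egg[1:5]  # wrong chromosome set
  expect_error(simulate_read_counts(list(cc), cfg, seed = 1), "chromosomes")
})
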