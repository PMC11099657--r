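# binning and deterministic counts on the toy genome for arithmetic checks
toy_binning <- function() make_binning(toy_chromosomes(), 50e6)

flat_sample <- function(per_bin = 100, id = "s1", role = "egg", mf = 0.98,
                        binning = toy_binning()) {
  binned_counts(id, rep(per_bin, nrow(binning)), binning,
                mapped_fraction = mf, role = role)
}

test_that("QC passes, fails and reports indeterminate correctly", {
  expect_equal(qc_sample(flat_sample(mf = 0.95))$status, "pass")
  expect_equal(qc_sample(flat_sample(mf = 0.90))$status, "pass")
  fail <- qc_sample(flat_sample(mf = 0.89))
  expect_equal(fail$status, "fail")
  expect_match(fail$reason, "mapped fraction")
  ind <- qc_sample(flat_sample(mf = NA))
  expect_equal(ind$status, "indeterminate")
  expect_match(ind$reason, "unavailable")
})

test_that("overrepresented-bin filter masks strictly above the threshold", {
  b <- toy_binning()
  counts <- rep(500, nrow(b))
  s <- filter_bins(binned_counts("s", counts, b))
  expect_false(any(s$mask))

  counts[3] <- 1001
  s <- filter_bins(binned_counts("s", counts, b))
  expect_equal(which(s$mask), 3L)
  expect_equal(s$mask_reason[3], "overrepresented")

  counts[3] <- 1000  # exactly at the threshold is retained
  s <- filter_bins(binned_counts("s", counts, b))
  expect_false(any(s$mask))
})

test_that("normalization scales unmasked autosomal totals to the target", {
  b <- toy_binning()
  auto <- bin_is_autosome <- !(b$chrom %in% c("X", "Y"))
  n_auto <- sum(auto)
  counts <- rep(2e6 / n_auto, nrow(b))
  norm <- normalize_counts(counts, auto)
  expect_equal(attr(norm, "scale_factor"), 0.5)
  expect_equal(sum(norm[auto]), 1e6, tolerance = 1e-9)

  counts1 <- rep(1e6 / n_auto, nrow(b))
  norm1 <- normalize_counts(counts1, auto)
  expect_equal(attr(norm1, "scale_factor"), 1)

  # sex-chromosome bins scale by the same factor as autosomes
  expect_equal(unique(norm[!auto] / counts[!auto]), 0.5)

  # idempotence: normalizing a normalized sample is the identity
  renorm <- normalize_counts(as.numeric(norm), auto)
  expect_equal(as.numeric(renorm), as.numeric(norm), tolerance = 1e-12)

  expect_error(normalize_counts(rep(0, nrow(b)), auto),
               "normalization impossible")
})

test_that("fold change is 1 against itself and masks zero-panel bins", {
  b <- toy_binning()
  auto <- !(b$chrom %in% c("X", "Y"))
  norm <- normalize_counts(rep(100, nrow(b)), auto)
  fc <- fold_change(norm, norm)
  expect_equal(unique(as.numeric(fc)), 1)

  panel <- norm
  panel[2] <- 0
  fc2 <- fold_change(norm, panel)
  expect_true(is.na(fc2[2]))
  expect_equal(attr(fc2, "reason")[2], "zero-panel")
})

test_that("observed copy number is the median fold change times ploidy multiplier", {
  b <- make_binning(data.frame(name = c("7", "X"),
                               length = c(30e6, 30e6),
                               is_sex = c(FALSE, TRUE)), 10e6)
  fc <- c(2, 2, 2, 2, 2, 2)
  cn <- observed_cn(fc, b)
  expect_equal(unname(cn["7"]), 4)  # autosome: x2
  expect_equal(unname(cn["X"]), 2)  # sex chromosome: x1

  fc2 <- c(0.9, 1.0, 1.1, NA, NA, NA)
  cn2 <- observed_cn(fc2, b)
  expect_equal(unname(cn2["7"]), 2)          # median of {0.9, 1, 1.1} x2
  expect_true(is.na(cn2["X"]))               # fully masked chromosome
  expect_equal(unname(attr(cn2, "n_bins_used")["X"]), 0L)
})

test_that("scale invariance: multiplying all counts leaves fold changes unchanged", {
  cfg <- noiseless_config()
  cc <- aneuploid_configuration(list(`4` = 4L))
  counts <- simulate_read_counts(list(cc), cfg, seed = 3)
  panel <- simulate_normal_panel(cfg, seed = 4)
  egg <- counts$pair01_egg
  prof1 <- call_cn_profile(egg, panel)
  egg_scaled <- egg
  # scale but stay below the raw-count overrepresentation cutoff, which is
  # intentionally not scale invariant
  egg_scaled$counts <- egg$counts * 2
  prof2 <- call_cn_profile(egg_scaled, panel)
  expect_equal(prof2$fold_change, prof1$fold_change, tolerance = 1e-12)
  expect_equal(prof2$observed_cn, prof1$observed_cn, tolerance = 1e-12)
})

test_that("noiseless euploid sample against the male panel recovers copy ratios", {
  cfg <- noiseless_config()
  cc <- euploid_configuration()
  counts <- simulate_read_counts(list(cc), cfg, seed = 3)
  panel <- simulate_normal_panel(cfg, seed = 4)
  prof <- call_cn_profile(counts$pair01_egg, panel)
  auto <- setdiff(names(prof$observed_cn), c("X", "Y"))
  # euploid autosomal content matches the panel: observed equals truth
  expect_equal(unname(prof$observed_cn[auto]), rep(2, length(auto)),
               tolerance = 1e-9)
  # egg X carries 2 chromatids against 1 panel copy: fold change 2, x1
  expect_equal(unname(prof$observed_cn["X"]), 2, tolerance = 1e-9)
})

test_that("noiseless 4-chromatid chromosome doubles its bins' fold change", {
  cfg <- noiseless_config()
  cc <- aneuploid_configuration(list(`4` = 4L))
  counts <- simulate_read_counts(list(cc), cfg, seed = 3)
  panel <- simulate_normal_panel(cfg, seed = 4)
  prof <- call_cn_profile(counts$pair01_egg, panel)
  b <- counts$pair01_egg$binning
  fc4 <- unique(round(prof$fold_change[b$chrom == "4"], 9))
  fc1 <- unique(round(prof$fold_change[b$chrom == "1"], 9))
  # within the sample the aberrant chromosome is exactly twice the euploid level
  expect_length(fc4, 1L)
  expect_length(fc1, 1L)
  expect_equal(fc4 / fc1, 2)
  # the autosomal normalization denominator shifts all fold changes by a
  # common factor; the chromosome-level call is restored by designation
  expect_lt(abs(prof$observed_cn[["4"]] / prof$observed_cn[["1"]] - 2), 1e-9)
})

test_that("monotonicity: more chromatids raise a chromosome and depress the rest", {
  cfg <- noiseless_config()
  panel <- simulate_normal_panel(cfg, seed = 4)
  cn_of <- function(copies4) {
    cc <- aneuploid_configuration(list(`4` = copies4))
    counts <- simulate_read_counts(list(cc), cfg, seed = 3)
    call_cn_profile(counts$pair01_egg, panel)$observed_cn
  }
  cn2 <- cn_of(2L); cn3 <- cn_of(3L); cn4 <- cn_of(4L)
  expect_true(cn2[["4"]] < cn3[["4"]] && cn3[["4"]] < cn4[["4"]])
  others <- setdiff(names(cn2), c("4", "Y"))
  expect_true(all(cn3[others] <= cn2[others] + 1e-12))
  expect_true(all(cn4[others] <= cn3[others] + 1e-12))
})

test_that("whole-sample normalization failure yields a flagged all-NA profile", {
  b <- toy_binning()
  counts <- rep(0, nrow(b))
  counts[b$chrom == "X"] <- 100  # all content on a sex chromosome
  s <- binned_counts("deg", counts, b, mapped_fraction = 0.99)
  panel <- flat_sample(100, id = "p", role = "panel")
  prof <- call_cn_profile(s, panel)
  expect_true(prof$normalization_failed)
  expect_true(all(is.na(prof$observed_cn[c("1", "2", "3")])))
})
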