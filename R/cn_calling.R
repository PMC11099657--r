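# Copy-number calling from binned shallow-WGS read counts: per-sample QC,
# overrepresented-bin filtering, autosome-anchored normalization to 1 million
# counts, fold change against the normal panel, and per-chromosome observed
# copy numbers (fold change x2 for autosomes, x1 for sex chromosomes).

#' Construct a binned-counts sample
#'
#' @param sample_id Sample identifier.
#' @param counts Numeric vector of non-negative per-bin read counts, one per
#'   bin of `binning` (in bin order).
#' @param binning A [make_binning()] object.
#' @param mapped_fraction Proportion of reads mapped to the mouse genome, in
#'   \[0,1\] (NA if unknown; QC then reports an indeterminate status).
#' @param role One of "egg", "polar_body", "blastomere", "panel".
#' @return An object of class `binned_counts`.
#' @export
binned_counts <- function(sample_id, counts, binning,
                          mapped_fraction = NA_real_,
                          role = c("egg", "polar_body", "blastomere", "panel")) {
  role <- match.arg(role)
  if (!inherits(binning, "genome_binning")) stop("binning must be a genome_binning")
  counts <- as.numeric(counts)
  if (length(counts) != nrow(binning)) {
    stop(sprintf("counts has %d values but the binning has %d bins",
                 length(counts), nrow(binning)))
  }
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (!is.na(mapped_fraction) &&
      (mapped_fraction < 0 || mapped_fraction > 1)) {
    stop("mapped_fraction must be in [0, 1]")
  }
  structure(list(
    sample_id = as.character(sample_id),
    counts = counts,
    binning = binning,
    total_reads = sum(counts),
    mapped_fraction = mapped_fraction,
    role = role,
    mask = rep(FALSE, length(counts)),
    mask_reason = rep(NA_character_, length(counts))
  ), class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %s (%s): %s reads over %d bins, mapped fraction %s\n",
              x$sample_id, x$role,
              format(round(x$total_reads), big.mark = ","),
              length(x$counts),
              ifelse(is.na(x$mapped_fraction), "NA",
                     sprintf("%.3f", x$mapped_fraction))))
  invisible(x)
}

#' Sample-level quality control on the mapped-read fraction
#'
#' A sample fails QC when its proportion of reads mapped to the mouse genome
#' is below `threshold` (default 90%); failed samples are excluded from all
#' downstream analysis. A missing mapped fraction yields an explicit
#' "indeterminate" status, never a silent pass.
#'
#' @param sample A [binned_counts()] object (or a bare mapped fraction).
#' @param threshold Minimum passing mapped fraction.
#' @return A list with `sample_id`, `status` ("pass"/"fail"/"indeterminate"),
#'   `mapped_fraction` and `reason`.
#' @export
qc_sample <- function(sample, threshold = 0.90) {
  if (inherits(sample, "binned_counts")) {
    mf <- sample$mapped_fraction
    id <- sample$sample_id
  } else {
    mf <- as.numeric(sample)
    id <- NA_character_
  }
  if (is.na(mf)) {
    return(list(sample_id = id, status = "indeterminate",
                mapped_fraction = NA_real_,
                reason = "mapped fraction unavailable"))
  }
  if (mf < threshold) {
    list(sample_id = id, status = "fail", mapped_fraction = mf,
         reason = sprintf("mapped fraction %.3f < %.2f", mf, threshold))
  } else {
    list(sample_id = id, status = "pass", mapped_fraction = mf, reason = NA_character_)
  }
}

#' Mask overrepresented bins
#'
#' Bins with a raw read count strictly greater than `max_count` (default 1000)
#' are considered overrepresented and masked from all downstream computation;
#' the reason is recorded per bin. Filtering is applied to raw counts, before
#' normalization.
#'
#' @param sample A [binned_counts()] object.
#' @param max_count Maximum retained raw count; bins exactly at the threshold
#'   are kept.
#' @return The sample with its `mask`/`mask_reason` fields updated.
#' @export
filter_bins <- function(sample, max_count = 1000) {
  stopifnot(inherits(sample, "binned_counts"))
  over <- sample$counts > max_count
  sample$mask <- sample$mask | over
  sample$mask_reason[over] <- "overrepresented"
  sample
}

#' Normalize bin counts to a fixed autosomal total
#'
#' Computes scale = `target` / sum of unmasked autosomal counts and multiplies
#' every unmasked bin (autosomal and sex) by it, so that the unmasked
#' autosomal total equals `target` (1 million by default). Masked bins are NA.
#'
#' @param counts Numeric vector of per-bin counts.
#' @param autosomal Logical vector: is each bin autosomal?
#' @param mask Logical vector of bins to exclude (default none).
#' @param target Normalization target for the autosomal total.
#' @return Numeric vector of normalized values (NA at masked bins) with
#'   attribute `scale_factor`.
#' @export
normalize_counts <- function(counts, autosomal, mask = NULL, target = 1e6) {
  n <- length(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(autosomal) == n, length(mask) == n)
  denom <- sum(counts[!mask & autosomal])
  if (!is.finite(denom) || denom <= 0) {
    stop("normalization impossible: unmasked autosomal total is zero")
  }
  scale <- target / denom
  out <- counts * scale
  out[mask] <- NA_real_
  attr(out, "scale_factor") <- scale
  out
}

#' Per-bin fold change against the normal panel
#'
#' @param sample_norm,panel_norm Normalized per-bin vectors (NA at masked
#'   bins) from [normalize_counts()], on the same binning.
#' @return Numeric vector of fold changes, NA where either input is masked or
#'   the panel value is zero; attribute `reason` records per-bin exclusion
#'   reasons ("masked" / "zero-panel").
#' @export
fold_change <- function(sample_norm, panel_norm) {
  stopifnot(length(sample_norm) == length(panel_norm))
  fc <- rep(NA_real_, length(sample_norm))
  reason <- rep(NA_character_, length(sample_norm))
  masked <- is.na(sample_norm) | is.na(panel_norm)
  zero_panel <- !masked & panel_norm == 0
  ok <- !masked & !zero_panel
  fc[ok] <- sample_norm[ok] / panel_norm[ok]
  reason[masked] <- "masked"
  reason[zero_panel] <- "zero-panel"
  attr(fc, "reason") <- reason
  fc
}

#' Per-chromosome observed copy number from bin fold changes
#'
#' Summarizes each chromosome's unmasked bin fold changes by their median,
#' then multiplies by two for autosomes and one for sex chromosomes. A
#' chromosome with no unmasked bin gets NA and is flagged.
#'
#' @param fc Per-bin fold-change vector from [fold_change()].
#' @param binning The [make_binning()] object the bins belong to.
#' @return Named numeric vector of observed copy numbers over all chromosomes
#'   of the binning, with attribute `n_bins_used`.
#' @export
observed_cn <- function(fc, binning) {
  stopifnot(inherits(binning, "genome_binning"), length(fc) == nrow(binning))
  chroms <- binning_chrom_names(binning)
  sex <- binning_sex_chroms(binning)
  cn <- stats::setNames(rep(NA_real_, length(chroms)), chroms)
  nb <- stats::setNames(integer(length(chroms)), chroms)
  for (ch in chroms) {
    vals <- fc[binning$chrom == ch]
    vals <- vals[!is.na(vals)]
    nb[ch] <- length(vals)
    if (length(vals)) {
      mult <- if (ch %in% sex) 1 else 2
      cn[ch] <- stats::median(vals) * mult
    }
  }
  attr(cn, "n_bins_used") <- nb
  cn
}

#' Call a copy-number profile for one sample against the normal panel
#'
#' Applies overrepresented-bin filtering to the sample and every panel
#' replicate, normalizes all of them over the shared set of unmasked bins
#' (union mask, so the denominators cover identical bins), averages the
#' normalized panel replicates per bin, computes fold changes, and summarizes
#' observed copy numbers per chromosome. A sample whose unmasked autosomal
#' counts are all zero (possible for whole-complement segregation failures)
#' yields an all-NA profile flagged `normalization_failed` rather than an
#' error, so that the pair can still be designated from its partner.
#'
#' @param sample A [binned_counts()] object.
#' @param panel A [binned_counts()] object or list of them (role "panel");
#'   multiple replicates are averaged per bin after normalization.
#' @param max_count Overrepresentation threshold on raw counts.
#' @param target Autosomal normalization target.
#' @return An object of class `cn_profile`: per-bin `fold_change` (NA where
#'   masked), `excluded` reasons, per-chromosome `observed_cn`,
#'   `n_bins_used`, `scale_factor` and `normalization_failed`.
#' @export
call_cn_profile <- function(sample, panel, max_count = 1000, target = 1e6) {
  stopifnot(inherits(sample, "binned_counts"))
  if (inherits(panel, "binned_counts")) panel <- list(panel)
  stopifnot(length(panel) >= 1L,
            all(vapply(panel, inherits, logical(1), "binned_counts")))
  binning <- sample$binning
  autosomal <- bin_is_autosome(binning)

  sample <- filter_bins(sample, max_count)
  panel <- lapply(panel, filter_bins, max_count = max_count)
  mask <- Reduce(`|`, lapply(panel, `[[`, "mask"), sample$mask)
  reason <- sample$mask_reason
  for (p in panel) {
    fill <- is.na(reason) & !is.na(p$mask_reason)
    reason[fill] <- p$mask_reason[fill]
  }

  norm_failed <- FALSE
  s_norm <- tryCatch(
    normalize_counts(sample$counts, autosomal, mask, target),
    error = function(e) {
      norm_failed <<- TRUE
      rep(NA_real_, length(sample$counts))
    }
  )
  p_norms <- lapply(panel, function(p)
    normalize_counts(p$counts, autosomal, mask, target))
  p_norm <- rowMeans(do.call(cbind, p_norms))

  fc <- fold_change(s_norm, p_norm)
  fc_reason <- attr(fc, "reason")
  fc_reason[!is.na(reason)] <- reason[!is.na(reason)]
  cn <- observed_cn(fc, binning)

  # a chromosome dominated by overrepresented windows has no reliable fold
  # change: the surviving bins are a downward-truncated draw (this arises
  # when one cell of a whole-complement failure concentrates the reads on a
  # few chromosomes); drop its observation so the pair is designated from
  # the partner instead
  over <- sample$mask & sample$mask_reason %in% "overrepresented"
  over_frac <- tapply(over, factor(binning$chrom, levels = names(cn)), mean)
  unreliable <- !is.na(over_frac) & over_frac > 0.5
  cn[unreliable] <- NA_real_

  structure(list(
    sample_id = sample$sample_id,
    role = sample$role,
    fold_change = as.numeric(fc),
    excluded = fc_reason,
    observed_cn = cn,
    n_bins_used = attr(cn, "n_bins_used"),
    overrepresented_chroms = names(cn)[unreliable],
    scale_factor = if (norm_failed) NA_real_ else attr(s_norm, "scale_factor"),
    normalization_failed = norm_failed,
    binning = binning
  ), class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s (%s)%s\n", x$sample_id, x$role,
              if (x$normalization_failed) " [normalization failed]" else ""))
  print(round(x$observed_cn, 2))
  invisible(x)
}
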