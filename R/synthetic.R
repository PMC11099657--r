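# Ground-truthed synthetic data: meiosis-I segregation outcomes per
# chromosome for matched egg/PB pairs (including whole-complement
# "catastrophic" failures), overdispersed binned read counts with shared bin
# biases, a euploid male normal panel, QC artifacts, and
# ploidy-class-conditional morphokinetic times.

#' Morphokinetic class-conditional timing defaults
#'
#' Group means and SEMs (hours) of tGVBD and tPB1 for euploid eggs and eggs
#' with 1-3 or >=4 chromosome segregation errors, with the group sizes the
#' SEMs were computed from; SDs are derived as SEM * sqrt(n).
#'
#' @return A data.frame with one row per ploidy class.
#' @export
morphokinetic_defaults <- function() {
  d <- data.frame(
    class = severity_levels(),
    n = c(27L, 9L, 11L),
    tgvbd_mean = c(0.92, 1.00, 0.95),
    tgvbd_sem = c(0.02, 0.05, 0.03),
    tpb1_mean = c(9.19, 11.23, 13.80),
    tpb1_sem = c(0.11, 0.33, 0.46),
    stringsAsFactors = FALSE
  )
  d$tgvbd_sd <- d$tgvbd_sem * sqrt(d$n)
  d$tpb1_sd <- d$tpb1_sem * sqrt(d$n)
  d
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: three treatment groups (vehicle
#' control and two Nocodazole doses) with 11 / 13 / 23 matched egg/PB pairs;
#' per-chromosome independent mis-segregation probabilities and
#' whole-complement (catastrophic) event probabilities calibrated to the
#' observed aneuploidy incidences (0/11, 1/13, 19/23 with 7/23
#' whole-complement); NDJ:PSSC split 9:1 among independent errors.
#'
#' @param groups data.frame with columns `name`, `n_pairs`, `p_err`
#'   (per-chromosome error probability), `p_cat` (whole-complement event
#'   probability).
#' @param q_ndj Probability an independent error is NDJ (else PSSC).
#' @param p_egg_retain Probability the egg retains the extra chromatids.
#' @param cat_exception_range Integer range of chromosomes segregating
#'   against the whole-complement direction in a catastrophic event.
#' @param cat_pssc_prob Probability a catastrophic exception is a 3/1
#'   (PSSC-like) rather than a 4/0 pattern.
#' @param depth Expected total reads per sample.
#' @param dispersion Negative-binomial size parameter for per-bin counts;
#'   `Inf` gives Poisson noise, `0` gives deterministic (noiseless) counts.
#' @param bias_sd Log-SD of the shared lognormal per-bin bias multipliers
#'   (0 disables biases).
#' @param bias_seed Seed for the shared bias multipliers, so panel and
#'   samples see identical biases.
#' @param overrep_frac Fraction of bins forced overrepresented (count
#'   > 1000) per sample.
#' @param qc_fail_prob Probability a sample is a designated mapping-fraction
#'   QC failure (mapped fraction drawn below 0.90).
#' @param panel_n Number of replicate panel draws averaged into the normal
#'   panel (the reference animal is characterized more deeply than single
#'   gametes).
#' @param window_size Genome window width in bp.
#' @param chromosomes Chromosome table ([mouse_chromosomes()]).
#' @param morpho Morphokinetic class defaults ([morphokinetic_defaults()]).
#' @param immature data.frame with columns `name`, `n_gv`, `n_gvbd_only`:
#'   per-group counts of oocytes that fail to extrude a polar body (arrested
#'   at GV or past GVBD), emulating dose-dependent maturation failure.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(groups = data.frame(
                         name = c("control", "25nM", "50nM"),
                         n_pairs = c(11L, 13L, 23L),
                         p_err = c(0, 0.004, 0.067),
                         p_cat = c(0, 0, 0.30),
                         stringsAsFactors = FALSE),
                       q_ndj = 0.9,
                       p_egg_retain = 0.5,
                       cat_exception_range = c(1L, 4L),
                       cat_pssc_prob = 0.7,
                       depth = 5e4,
                       dispersion = 50,
                       bias_sd = 0.1,
                       bias_seed = 104729L,
                       overrep_frac = 0.005,
                       qc_fail_prob = 0.01,
                       panel_n = 10L,
                       window_size = 1e7,
                       chromosomes = mouse_chromosomes(),
                       morpho = morphokinetic_defaults(),
                       immature = data.frame(
                         name = c("control", "25nM", "50nM"),
                         n_gv = c(1L, 1L, 2L),
                         n_gvbd_only = c(1L, 2L, 6L),
                         stringsAsFactors = FALSE)) {
  stopifnot(is.data.frame(groups),
            all(c("name", "n_pairs", "p_err", "p_cat") %in% names(groups)))
  probs <- c(groups$p_err, groups$p_cat, q_ndj, p_egg_retain, cat_pssc_prob,
             overrep_frac, qc_fail_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0 (0 = noiseless)")
  validate_chromosomes(chromosomes)
  structure(list(
    groups = groups, q_ndj = q_ndj, p_egg_retain = p_egg_retain,
    cat_exception_range = as.integer(cat_exception_range),
    cat_pssc_prob = cat_pssc_prob,
    depth = depth, dispersion = dispersion,
    bias_sd = bias_sd, bias_seed = as.integer(bias_seed),
    overrep_frac = overrep_frac, qc_fail_prob = qc_fail_prob,
    panel_n = as.integer(panel_n),
    window_size = window_size, chromosomes = chromosomes,
    morpho = morpho, immature = immature
  ), class = "sim_config")
}

# chromosomes carried by oocyte-derived samples (no Y)
oocyte_chromosomes <- function(config) {
  setdiff(config$chromosomes$name, "Y")
}

#' Simulate meiosis-I segregation outcomes for matched egg/PB pairs
#'
#' For each pair, each non-Y chromosome's four chromatids are partitioned
#' between egg and first polar body. With probability `p_cat` a pair suffers
#' a whole-complement event: every chromosome segregates to one cell except
#' an independently drawn subset of 1-4 exception chromosomes that carry the
#' opposite 4/0 or a 3/1 pattern. Otherwise each chromosome independently
#' mis-segregates with probability `p_err`, as NDJ (4/0) with probability
#' `q_ndj`, else PSSC (3/1), the direction drawn with `p_egg_retain`.
#' Every outcome satisfies egg + PB = 4 chromatids.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @return A list of `chromatid_config` objects: `pair_id`, `treatment`,
#'   named integer vectors `egg` and `pb`, `n_errors`, `severity`,
#'   `catastrophic`.
#' @export
simulate_segregation <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- oocyte_chromosomes(config)
  nchr <- length(chroms)
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (g in seq_len(nrow(config$groups))) {
      grp <- config$groups[g, ]
      for (i in seq_len(grp$n_pairs)) {
        egg <- stats::setNames(rep(2L, nchr), chroms)
        catastrophic <- stats::runif(1) < grp$p_cat
        if (catastrophic) {
          egg_empties <- stats::runif(1) < 0.5
          k <- sample(seq(config$cat_exception_range[1L],
                          config$cat_exception_range[2L]), 1L)
          exceptions <- sample(chroms, k)
          base <- if (egg_empties) 0L else 4L
          egg[] <- base
          for (ch in exceptions) {
            pssc <- stats::runif(1) < config$cat_pssc_prob
            egg[ch] <- if (egg_empties) (if (pssc) 3L else 4L)
                       else (if (pssc) 1L else 0L)
          }
        } else if (grp$p_err > 0) {
          errs <- stats::runif(nchr) < grp$p_err
          for (j in which(errs)) {
            ndj <- stats::runif(1) < config$q_ndj
            egg_retains <- stats::runif(1) < config$p_egg_retain
            egg[j] <- if (ndj) (if (egg_retains) 4L else 0L)
                      else (if (egg_retains) 3L else 1L)
          }
        }
        pb <- 4L - egg
        n_errors <- sum(egg != 2L)
        out[[length(out) + 1L]] <- structure(list(
          pair_id = sprintf("%s_pair%02d", grp$name, i),
          treatment = grp$name,
          egg = egg, pb = pb,
          n_errors = n_errors,
          severity = severity_class(n_errors),
          catastrophic = catastrophic
        ), class = "chromatid_config")
      }
    }
    out
  })
}

# shared per-bin bias multipliers, drawn once from the dedicated bias seed
bin_biases <- function(config, binning) {
  if (config$bias_sd == 0) return(rep(1, nrow(binning)))
  withr::with_seed(config$bias_seed,
                   stats::rlnorm(nrow(binning), 0, config$bias_sd))
}

# One sample's counts. copy_halves = per-chromosome chromatid (or copy)
# count divided by 2, so a euploid autosome contributes weight 1.
# E[count(b)] = depth * bias(b) * binlen(b)/window * copy_halves(chrom(b)),
# renormalized so the expected total is `depth`.
draw_sample_counts <- function(copy_halves, config, binning, biases) {
  lenfrac <- (binning$end - binning$start) / config$window_size
  ch <- copy_halves[binning$chrom]
  ch[is.na(ch)] <- 0
  w <- biases * lenfrac * ch
  if (sum(w) == 0) return(rep(0, nrow(binning)))
  mu <- config$depth * w / sum(w)
  if (config$dispersion == 0) {
    mu
  } else if (is.infinite(config$dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
}

# overrepresentation + QC metadata applied to a freshly drawn sample
decorate_sample <- function(counts, config, binning) {
  n <- length(counts)
  n_over <- stats::rbinom(1L, n, config$overrep_frac)
  over_idx <- if (n_over > 0) sample.int(n, n_over) else integer(0)
  if (length(over_idx)) {
    counts[over_idx] <- 1001 + stats::rpois(length(over_idx), 300)
  }
  qc_fail <- stats::runif(1) < config$qc_fail_prob
  mapped_fraction <- if (qc_fail) stats::runif(1, 0.80, 0.895)
                     else stats::runif(1, 0.95, 0.999)
  list(counts = counts, overrep_bins = sort(over_idx),
       qc_fail = qc_fail, mapped_fraction = mapped_fraction)
}

#' Simulate binned read counts for matched egg/PB pairs
#'
#' Draws per-bin read counts for every egg and polar-body sample of the
#' given segregation outcomes. The expected count of a bin is proportional
#' to its shared bias multiplier times the chromatid count of its chromosome
#' divided by two; counts are negative-binomial with the configured
#' dispersion (Poisson at `dispersion = Inf`, deterministic at 0). A
#' configured fraction of bins is forced overrepresented (count > 1000), and
#' designated QC-failure samples carry a mapped fraction below 0.90.
#'
#' @param configurations List of `chromatid_config` from
#'   [simulate_segregation()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param binning Optional [make_binning()]; defaults to the config's genome.
#' @return Named list of [binned_counts()] objects (two per pair, ids
#'   `<pair_id>_egg` / `<pair_id>_pb`), each with a `truth` field recording
#'   the chromatid counts, forced overrepresented bins and QC designation.
#' @export
simulate_read_counts <- function(configurations, config, seed, binning = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(binning)) binning <- make_binning(config$chromosomes, config$window_size)
  cfg_chroms <- oocyte_chromosomes(config)
  for (cc in configurations) {
    if (!setequal(names(cc$egg), cfg_chroms)) {
      stop("configuration chromosomes do not match the binning's genome")
    }
  }
  biases <- bin_biases(config, binning)
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (cc in configurations) {
      for (side in c("egg", "pb")) {
        cht <- if (side == "egg") cc$egg else cc$pb
        counts <- draw_sample_counts(cht / 2, config, binning, biases)
        deco <- decorate_sample(counts, config, binning)
        id <- paste0(cc$pair_id, "_", side)
        s <- binned_counts(id, deco$counts, binning,
                           mapped_fraction = deco$mapped_fraction,
                           role = if (side == "egg") "egg" else "polar_body")
        s$truth <- list(chromatids = cht, overrep_bins = deco$overrep_bins,
                        qc_fail = deco$qc_fail)
        out[[id]] <- s
      }
    }
    out
  })
}

#' Simulate the euploid male normal panel
#'
#' Generates reference sample(s) from the 40,XY copy map (two copies of each
#' autosome, one X, one Y) with the same shared bin biases and noise model
#' as the study samples.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param binning Optional [make_binning()].
#' @param n_samples Number of panel replicates (defaults to the config's
#'   `panel_n`; replicates are averaged per bin after normalization when the
#'   panel is used as a reference).
#' @return List of [binned_counts()] (role "panel") with attribute
#'   `copy_map`.
#' @export
simulate_normal_panel <- function(config, seed, binning = NULL,
                                  n_samples = config$panel_n) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(binning)) binning <- make_binning(config$chromosomes, config$window_size)
  chroms <- config$chromosomes$name
  copy_map <- stats::setNames(ifelse(chroms %in% c("X", "Y"), 1L, 2L), chroms)
  biases <- bin_biases(config, binning)
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_len(n_samples), function(i) {
      counts <- draw_sample_counts(copy_map / 2, config, binning, biases)
      binned_counts(sprintf("panel%02d", i), counts, binning,
                    mapped_fraction = 0.99, role = "panel")
    })
    attr(out, "copy_map") <- copy_map
    out
  })
}

#' Simulate morphokinetic records conditional on ploidy class
#'
#' Each matured pair receives tGVBD and tPB1 drawn from its severity class's
#' normal distributions (means and SDs from [morphokinetic_defaults()],
#' SD = printed SEM x sqrt(group n)), rejection-resampled so tPB1 > tGVBD;
#' dMI is set to the exact difference. Additional immature oocytes (GV
#' arrested, or GVBD without polar-body extrusion) are appended per group
#' according to `config$immature`.
#'
#' @param configurations List of `chromatid_config`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A data.frame with columns `sample_id`, `treatment`, `severity`,
#'   `tGVBD`, `tPB1`, `dMI`, `status` ("GV"/"GVBD-only"/"MII") and
#'   `exclusion_flag`.
#' @export
simulate_morphokinetics <- function(configurations, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$morpho
  withr::with_seed(as.integer(seed), {
    rows <- lapply(configurations, function(cc) {
      i <- match(cc$severity, m$class)
      tgvbd <- stats::rnorm(1, m$tgvbd_mean[i], m$tgvbd_sd[i])
      tpb1 <- stats::rnorm(1, m$tpb1_mean[i], m$tpb1_sd[i])
      while (tpb1 <= tgvbd) {
        tgvbd <- stats::rnorm(1, m$tgvbd_mean[i], m$tgvbd_sd[i])
        tpb1 <- stats::rnorm(1, m$tpb1_mean[i], m$tpb1_sd[i])
      }
      data.frame(sample_id = cc$pair_id, treatment = cc$treatment,
                 severity = cc$severity, tGVBD = tgvbd, tPB1 = tpb1,
                 dMI = tpb1 - tgvbd, status = "MII",
                 exclusion_flag = "", stringsAsFactors = FALSE)
    })
    imm <- list()
    eu <- match("euploid", m$class)
    for (g in seq_len(nrow(config$immature))) {
      grp <- config$immature[g, ]
      if (grp$n_gv > 0) {
        imm[[length(imm) + 1L]] <- data.frame(
          sample_id = sprintf("%s_gv%02d", grp$name, seq_len(grp$n_gv)),
          treatment = grp$name, severity = NA_character_,
          tGVBD = NA_real_, tPB1 = NA_real_, dMI = NA_real_,
          status = "GV", exclusion_flag = "", stringsAsFactors = FALSE)
      }
      if (grp$n_gvbd_only > 0) {
        imm[[length(imm) + 1L]] <- data.frame(
          sample_id = sprintf("%s_gvbd%02d", grp$name, seq_len(grp$n_gvbd_only)),
          treatment = grp$name, severity = NA_character_,
          tGVBD = stats::rnorm(grp$n_gvbd_only, m$tgvbd_mean[eu], m$tgvbd_sd[eu]),
          tPB1 = NA_real_, dMI = NA_real_,
          status = "GVBD-only", exclusion_flag = "", stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(rows, imm))
    rownames(out) <- NULL
    out
  })
}
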