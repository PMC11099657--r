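# Cohort-level orchestration: end-to-end pipeline over simulated (or
# supplied) samples, per-chromosome error spectrum, cohort aggregates, and
# the bundled reference cohort of printed karyotype strings.

#' Bundled reference cohort of aneuploid egg / polar-body karyotypes
#'
#' Karyotype strings for the 20 aneuploid matched egg / first-polar-body
#' pairs called in a Nocodazole dose-response IVM experiment (1 pair at
#' 25 nM, 19 at 50 nM), in shallow-NGS nomenclature, together with the
#' reported aneuploidy type. Used as a worked reference set for the parser
#' and classifier.
#'
#' @return A data.frame with columns `sample_id`, `treatment`,
#'   `egg_karyotype`, `pb_karyotype`, `reported_type`.
#' @export
example_aneuploid_pairs <- function() {
  path <- system.file("extdata", "aneuploid_pair_karyotypes.tsv",
                      package = "aneukin", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference cohort group sizes
#'
#' Number of analyzable matched pairs per treatment group in the reference
#' cohort (vehicle control and two Nocodazole doses).
#'
#' @return A data.frame with columns `group`, `n_pairs`.
#' @export
cohort_group_sizes <- function() {
  path <- system.file("extdata", "cohort_groups.tsv",
                      package = "aneukin", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Parse and classify a cohort of karyotype-string pairs
#'
#' Runs [pair_calls_from_karyotypes()] and [classify_sample()] over a table
#' of egg / polar-body karyotype strings.
#'
#' @param pairs A data.frame with columns `sample_id`, `egg_karyotype`,
#'   `pb_karyotype` (and optionally `treatment`); defaults to the bundled
#'   reference cohort.
#' @return A data.frame with one row per pair: `sample_id`, `treatment`,
#'   `aneuploidy_type`, `n_errors`, `n_discordant`, `severity`, plus the
#'   per-pair call sets as attribute `callsets`.
#' @export
#' @examples
#' table(classify_cohort()$aneuploidy_type)
classify_cohort <- function(pairs = example_aneuploid_pairs()) {
  stopifnot(all(c("sample_id", "egg_karyotype", "pb_karyotype") %in% names(pairs)))
  if (!"treatment" %in% names(pairs)) pairs$treatment <- NA_character_
  callsets <- list()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    calls <- pair_calls_from_karyotypes(pairs$egg_karyotype[i],
                                        pairs$pb_karyotype[i],
                                        pair_id = pairs$sample_id[i])
    callsets[[pairs$sample_id[i]]] <<- calls
    k <- classify_sample(calls)
    data.frame(sample_id = pairs$sample_id[i], treatment = pairs$treatment[i],
               aneuploidy_type = k$aneuploidy_type, n_errors = k$n_errors,
               n_discordant = k$n_discordant, severity = k$severity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "callsets") <- callsets
  out
}

#' Aneuploidy incidence per treatment group
#'
#' Computes aneuploid / analyzable pairs per group. Pairs absent from the
#' classified table but counted in `group_sizes` are euploid.
#'
#' @param classified Output of [classify_cohort()] (aneuploid pairs only is
#'   fine) or of [run_pipeline()]'s per-pair table.
#' @param group_sizes data.frame `group`, `n_pairs` of analyzable pairs per
#'   group (default: the bundled reference cohort sizes).
#' @return A data.frame with `group`, `n_pairs`, `n_aneuploid`,
#'   `n_euploid`, `incidence_pct`.
#' @export
cohort_incidence <- function(classified = classify_cohort(),
                             group_sizes = cohort_group_sizes()) {
  stopifnot(all(c("group", "n_pairs") %in% names(group_sizes)))
  grp_col <- if ("treatment" %in% names(classified)) "treatment" else "group"
  aneu <- classified[classified$n_errors > 0L, , drop = FALSE]
  counts <- table(factor(aneu[[grp_col]], levels = group_sizes$group))
  out <- data.frame(
    group = group_sizes$group,
    n_pairs = group_sizes$n_pairs,
    n_aneuploid = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out$n_euploid <- out$n_pairs - out$n_aneuploid
  out$incidence_pct <- 100 * out$n_aneuploid / out$n_pairs
  out
}

#' Per-chromosome spectrum of NDJ and PSSC events
#'
#' Tabulates, over all pairs, how often each chromosome carried an NDJ or a
#' PSSC error (egg-side perspective; each reciprocal event counted once per
#' pair).
#'
#' @param callsets A list of `reciprocal_calls` data.frames, a single one,
#'   or a `cohort_report`.
#' @return An integer matrix chromosomes x c("NDJ", "PSSC").
#' @export
summarize_error_spectrum <- function(callsets) {
  if (inherits(callsets, "cohort_report")) callsets <- callsets$callsets
  if (inherits(callsets, "reciprocal_calls")) callsets <- list(callsets)
  stopifnot(length(callsets) >= 1L)
  chroms <- callsets[[1L]]$chrom
  out <- matrix(0L, nrow = length(chroms), ncol = 2L,
                dimnames = list(chroms, c("NDJ", "PSSC")))
  for (cs in callsets) {
    for (cl in c("NDJ", "PSSC")) {
      hit <- cs$chrom[cs$class == cl]
      out[hit, cl] <- out[hit, cl] + 1L
    }
  }
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates segregation outcomes, the normal panel, binned read counts and
#' morphokinetics for the configured cohort, then applies QC, copy-number
#' calling, reciprocal designation, classification, and the group
#' statistics. Deterministic given (config, seed); QC-failed pairs are
#' excluded and logged, never silently dropped.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory; every stochastic step derives from
#'   it).
#' @param outdir Optional directory; when given, the per-pair table,
#'   call sets, spectrum, morphokinetics and a run log are written there.
#' @return An object of class `cohort_report`: `pairs` (per-pair rows),
#'   `aggregates` (incidence, type and severity counts), `spectrum`,
#'   `stats` (group comparisons and maturation rates), `callsets`,
#'   `profiles`, `truth`, `excluded`, `log`.
#' @export
run_pipeline <- function(config = sim_config(), seed, outdir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for every stochastic step")
  }
  seed <- as.integer(seed)
  stopifnot(inherits(config, "sim_config"))
  binning <- make_binning(config$chromosomes, config$window_size)

  truth <- simulate_segregation(config, seed)
  panel <- simulate_normal_panel(config, seed + 1L, binning)
  samples <- simulate_read_counts(truth, config, seed + 2L, binning)
  morpho <- simulate_morphokinetics(truth, config, seed + 3L)
  morpho <- derive_variables(morpho)

  log <- list(n_pairs_simulated = length(truth),
              n_samples = length(samples))

  # pair-level QC: a pair is analyzable only if both members pass
  excluded <- data.frame(pair_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  analyzable <- list()
  for (cc in truth) {
    qcs <- lapply(c("egg", "pb"), function(side)
      qc_sample(samples[[paste0(cc$pair_id, "_", side)]]))
    bad <- vapply(qcs, function(q) q$status != "pass", logical(1))
    if (any(bad)) {
      excluded <- rbind(excluded, data.frame(
        pair_id = cc$pair_id,
        reason = paste(unlist(lapply(qcs[bad], `[[`, "reason")), collapse = "; "),
        stringsAsFactors = FALSE))
    } else {
      analyzable[[cc$pair_id]] <- cc
    }
  }
  log$n_pairs_qc_failed <- nrow(excluded)
  log$n_pairs_analyzable <- length(analyzable)

  profiles <- list()
  callsets <- list()
  rows <- list()
  for (cc in analyzable) {
    pe <- call_cn_profile(samples[[paste0(cc$pair_id, "_egg")]], panel)
    pp <- call_cn_profile(samples[[paste0(cc$pair_id, "_pb")]], panel)
    profiles[[pe$sample_id]] <- pe
    profiles[[pp$sample_id]] <- pp
    calls <- designate_pair(pe$observed_cn, pp$observed_cn,
                            pair_id = cc$pair_id)
    callsets[[cc$pair_id]] <- calls
    k <- classify_sample(calls)
    rows[[cc$pair_id]] <- data.frame(
      pair_id = cc$pair_id, treatment = cc$treatment,
      egg_karyotype = k$egg_karyotype, pb_karyotype = k$pb_karyotype,
      aneuploidy_type = k$aneuploidy_type, n_errors = k$n_errors,
      n_discordant = k$n_discordant, severity = k$severity,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # merge morphokinetics onto analyzable pairs (sample_id == pair_id)
  m_idx <- match(pairs$pair_id, morpho$sample_id)
  pairs$tGVBD <- morpho$tGVBD[m_idx]
  pairs$tPB1 <- morpho$tPB1[m_idx]
  pairs$dMI <- morpho$dMI[m_idx]

  group_sizes <- data.frame(group = config$groups$name,
                            n_pairs = as.integer(table(
                              factor(pairs$treatment,
                                     levels = config$groups$name))),
                            stringsAsFactors = FALSE)
  incidence <- cohort_incidence(pairs, group_sizes)
  aggregates <- list(
    incidence = incidence,
    type_counts = table(factor(
      pairs$aneuploidy_type[pairs$n_errors > 0L],
      levels = c("NDJ", "PSSC", "NDJ+PSSC"))),
    severity_counts = table(factor(pairs$severity, levels = severity_levels()))
  )

  stats <- list()
  # severity comparisons over analyzable MII pairs (called severity)
  if (length(unique(pairs$severity)) >= 2L &&
      min(table(pairs$severity)) >= 2L) {
    for (v in c("tGVBD", "tPB1", "dMI")) {
      stats[[paste0(v, "_by_severity")]] <-
        tryCatch(compare_groups(pairs, "severity", v),
                 error = function(e) NULL, warning = function(w) NULL)
    }
  }
  # treatment comparisons over all matured oocytes
  mii <- morpho[morpho$status == "MII", , drop = FALSE]
  if (length(unique(mii$treatment)) >= 2L) {
    for (v in c("tGVBD", "tPB1", "dMI")) {
      stats[[paste0(v, "_by_treatment")]] <-
        tryCatch(compare_groups(mii, "treatment", v),
                 error = function(e) NULL, warning = function(w) NULL)
    }
  }
  stats$maturation_by_treatment <- maturation_rates(morpho, "treatment")

  report <- structure(list(
    pairs = pairs, aggregates = aggregates,
    spectrum = summarize_error_spectrum(callsets),
    stats = stats, callsets = callsets, profiles = profiles,
    morphokinetics = morpho, truth = truth,
    excluded = excluded, log = log, seed = seed
  ), class = "cohort_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d analyzable pairs (%d QC-excluded), seed %d\n",
              nrow(x$pairs), nrow(x$excluded), x$seed))
  print(x$aggregates$incidence)
  invisible(x)
}

#' Write a cohort report's artifacts to disk
#'
#' Writes the per-pair table and morphokinetics as CSV, the error spectrum
#' as TSV, and the call sets, aggregates and run log as JSON. File contents
#' are deterministic given the report (no timestamps).
#'
#' @param report A `cohort_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pairs = file.path(outdir, "pairs.csv"),
    morpho = file.path(outdir, "morphokinetics.csv"),
    spectrum = file.path(outdir, "error_spectrum.tsv"),
    callsets = file.path(outdir, "callsets.json"),
    aggregates = file.path(outdir, "aggregates.json"),
    log = file.path(outdir, "log.json")
  )
  utils::write.csv(report$pairs, paths["pairs"], row.names = FALSE)
  utils::write.csv(report$morphokinetics, paths["morpho"], row.names = FALSE)
  spec_df <- data.frame(chrom = rownames(report$spectrum),
                        report$spectrum, check.names = FALSE)
  utils::write.table(spec_df, paths["spectrum"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$callsets, paths["callsets"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    incidence = report$aggregates$incidence,
    type_counts = as.list(report$aggregates$type_counts),
    severity_counts = as.list(report$aggregates$severity_counts),
    seed = report$seed
  ), paths["aggregates"], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(report$log, list(
    excluded = report$excluded)), paths["log"],
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
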