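# Morphokinetic variables of meiotic progression (tGVBD, tPB1, dMI) from
# event-time tables, Grubbs outlier screening, and the group-comparison
# statistics used for time-lapse analyses.

#' Finalize morphokinetic variables and maturation status
#'
#' Event times are hours from t0 (imaging start, defined as 0). dMI is
#' computed exactly as tPB1 - tGVBD. Records lacking tPB1 are classified GV
#' (no tGVBD either) or GVBD-only and keep dMI missing; they are retained
#' for maturation-rate reporting. Records with tPB1 <= tGVBD are flagged
#' "invalid-annotation".
#'
#' @param records A data.frame with columns `tGVBD` and `tPB1` (hours, NA
#'   allowed); other columns pass through.
#' @return The records with `dMI`, `status` and `exclusion_flag` columns
#'   (re)computed.
#' @export
#' @examples
#' derive_variables(data.frame(tGVBD = 0.95, tPB1 = 13.80))$dMI
derive_variables <- function(records) {
  stopifnot(is.data.frame(records), all(c("tGVBD", "tPB1") %in% names(records)))
  if (!"exclusion_flag" %in% names(records)) records$exclusion_flag <- ""
  records$status <- ifelse(!is.na(records$tPB1), "MII",
                           ifelse(!is.na(records$tGVBD), "GVBD-only", "GV"))
  bad <- !is.na(records$tPB1) & !is.na(records$tGVBD) &
    records$tPB1 <= records$tGVBD
  records$exclusion_flag[bad] <- "invalid-annotation"
  records$dMI <- ifelse(bad, NA_real_, records$tPB1 - records$tGVBD)
  records
}

#' Two-sided Grubbs critical value
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return The critical value for G = max|x - mean| / SD.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3L)
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterated two-sided Grubbs outlier exclusion
#'
#' Repeatedly computes G = max|x - mean| / SD, compares it with the
#' two-sided critical value at `alpha`, removes at most one point per
#' iteration, and stops when no further point is rejected. Groups smaller
#' than 3, or with zero spread, are returned unchanged (with a warning for
#' n < 3).
#'
#' @param x Numeric vector of timings.
#' @param alpha Significance level per iteration.
#' @return A list: `retained`, `excluded` (values), `excluded_index`
#'   (positions in the original vector).
#' @export
#' @examples
#' grubbs_exclude(c(8.1, 8.3, 8.2, 8.25, 20.0))$excluded
grubbs_exclude <- function(x, alpha = 0.05) {
  stopifnot(is.numeric(x))
  if (length(x) < 3L) {
    warning("Grubbs test needs at least 3 values; returning all")
    return(list(retained = x, excluded = numeric(0), excluded_index = integer(0)))
  }
  idx <- seq_along(x)
  excluded <- integer(0)
  repeat {
    n <- length(idx)
    if (n < 3L) break
    v <- x[idx]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) break
    dev <- abs(v - mean(v))
    g <- max(dev) / s
    if (g > grubbs_critical(n, alpha)) {
      worst <- which.max(dev)
      excluded <- c(excluded, idx[worst])
      idx <- idx[-worst]
    } else break
  }
  list(retained = x[idx], excluded = x[excluded], excluded_index = excluded)
}

#' Dunn's post hoc test on ranks
#'
#' Pairwise z statistics on mean ranks with tie correction, as used after a
#' Kruskal-Wallis test; p-values are Bonferroni-adjusted across comparisons.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector of the same length.
#' @param p_adjust Adjustment method (see [stats::p.adjust()]).
#' @return A data.frame with `comparison`, `z`, `p_unadj`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  n_tot <- length(values)
  r <- rank(values)
  lev <- unique(groups)
  rbar <- tapply(r, groups, mean)[lev]
  ns <- tapply(r, groups, length)[lev]
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  s2 <- n_tot * (n_tot + 1) / 12 - tie_corr
  combs <- utils::combn(lev, 2L)
  z <- apply(combs, 2L, function(pr) {
    (rbar[pr[1L]] - rbar[pr[2L]]) /
      sqrt(s2 * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    comparison = apply(combs, 2L, paste, collapse = " - "),
    z = as.numeric(z),
    p_unadj = as.numeric(p),
    p_adj = pmin(1, stats::p.adjust(p, method = p_adjust)),
    stringsAsFactors = FALSE
  )
}

# per-group Shapiro-Wilk normality gate; n < 3 or zero spread cannot be
# tested and is treated as compatible with normality
shapiro_gate <- function(values, groups, alpha = 0.05) {
  lev <- unique(as.character(groups))
  res <- lapply(lev, function(g) {
    v <- values[groups == g]
    v <- v[!is.na(v)]
    if (length(v) < 3L || stats::sd(v) == 0) {
      data.frame(group = g, n = length(v), shapiro_p = NA_real_,
                 normal = TRUE, stringsAsFactors = FALSE)
    } else {
      p <- stats::shapiro.test(v)$p.value
      data.frame(group = g, n = length(v), shapiro_p = p,
                 normal = p >= alpha, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Compare a morphokinetic variable across groups
#'
#' Implements the test-selection gate: per-group Shapiro-Wilk normality at
#' `alpha`; when every group is compatible with normality, a Student's
#' t-test for exactly two groups or a one-way ANOVA with Tukey's HSD for
#' more; when any group is non-normal, a Kruskal-Wallis test followed by
#' Dunn's multiple comparisons. Groups with fewer than 2 observations are
#' dropped with a warning. Group means are reported with SEM = SD/sqrt(n).
#'
#' @param records A data.frame of morphokinetic records.
#' @param grouping Name of the grouping column (e.g. "treatment",
#'   "severity").
#' @param variable Name of the numeric column to compare (e.g. "tPB1",
#'   "dMI").
#' @param alpha Normality-gate significance level.
#' @return An object of class `group_comparison`: `variable`, `grouping`,
#'   `test` ("t_test" / "anova_tukey" / "kruskal_dunn"), `p_overall`,
#'   `groups` (n, mean, sd, sem, shapiro_p, normal) and `pairwise`.
#' @export
compare_groups <- function(records, grouping, variable, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            grouping %in% names(records), variable %in% names(records))
  v <- records[[variable]]
  g <- as.character(records[[grouping]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("dropping group(s) with fewer than 2 observations: %s",
                    paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]; g <- g[keep]
  }
  lev <- unique(g)
  if (length(lev) < 2L) stop("need at least two groups with >= 2 observations")

  gate <- shapiro_gate(v, g, alpha)
  stats_df <- do.call(rbind, lapply(lev, function(gr) {
    x <- v[g == gr]
    data.frame(group = gr, n = length(x), mean = mean(x), sd = stats::sd(x),
               sem = stats::sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)
  }))
  stats_df <- merge(stats_df, gate[, c("group", "shapiro_p", "normal")],
                    by = "group", sort = FALSE)

  all_normal <- all(gate$normal)
  gf <- factor(g, levels = lev)
  if (!all_normal) {
    test <- "kruskal_dunn"
    kw <- stats::kruskal.test(v, gf)
    p_overall <- kw$p.value
    pairwise <- dunn_test(v, g)
  } else if (length(lev) == 2L) {
    test <- "t_test"
    tt <- stats::t.test(v[g == lev[1L]], v[g == lev[2L]], var.equal = TRUE)
    p_overall <- tt$p.value
    pairwise <- data.frame(comparison = paste(lev, collapse = " - "),
                           z = NA_real_, p_unadj = tt$p.value,
                           p_adj = tt$p.value, stringsAsFactors = FALSE)
  } else {
    test <- "anova_tukey"
    fit <- stats::aov(v ~ gf)
    p_overall <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$gf
    pairwise <- data.frame(comparison = gsub("-", " - ", rownames(tk), fixed = TRUE),
                           z = NA_real_, p_unadj = NA_real_,
                           p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
    rownames(pairwise) <- NULL
  }
  structure(list(variable = variable, grouping = grouping, test = test,
                 p_overall = p_overall, groups = stats_df, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s: %s, overall p = %.4g\n",
              x$variable, x$grouping, x$test, x$p_overall))
  print(transform(x$groups, mean = round(mean, 3), sd = round(sd, 3),
                  sem = round(sem, 3)))
  invisible(x)
}

#' Maturation-stage proportions per group with a categorical test
#'
#' Tabulates GV / GVBD-only / MII statuses per group and tests the
#' composition with Fisher's exact test when any expected cell count is
#' below 5, otherwise a chi-square test. Empty groups are excluded with a
#' warning.
#'
#' @param records A data.frame with a `status` column (see
#'   [derive_variables()]).
#' @param grouping Name of the grouping column.
#' @return A list: `table` (counts), `proportions`, `test`
#'   ("fisher"/"chisq"), `p_value`.
#' @export
maturation_rates <- function(records, grouping) {
  stopifnot(is.data.frame(records), grouping %in% names(records),
            "status" %in% names(records))
  g <- as.character(records[[grouping]])
  status <- factor(records$status, levels = c("GV", "GVBD-only", "MII"))
  keep <- !is.na(g) & !is.na(status)
  tab <- table(group = g[keep], status = status[keep])
  empty <- rownames(tab)[rowSums(tab) == 0L]
  if (length(empty)) {
    warning(sprintf("excluding empty group(s): %s", paste(empty, collapse = ", ")))
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  }
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  props <- prop.table(tab, margin = 1L)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(table = tab, proportions = props, test = "none",
                p_value = NA_real_))
  }
  expected <- suppressWarnings(stats::chisq.test(tab)$expected)
  if (any(expected < 5)) {
    p <- tryCatch(stats::fisher.test(tab)$p.value,
                  error = function(e)
                    stats::fisher.test(tab, simulate.p.value = TRUE,
                                       B = 10000L)$p.value)
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab)$p.value
    test <- "chisq"
  }
  list(table = tab, proportions = props, test = test, p_value = p)
}
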