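# Reciprocal designation of integer chromatid copies for matched egg /
# polar-body pairs under the meiosis-I conservation constraint (egg + PB = 4
# chromatids per chromosome), classification of errors as NDJ or PSSC,
# sample-level typing and severity, and sex-concordance checks.

#' Designate integer chromatid copies for one chromosome
#'
#' Chooses the integer pair (e, p) with e + p = 4, e, p in 0..4, minimizing
#' the squared distance to the observed values. Ties are broken toward the
#' euploid call (2, 2) (conservative calling); the residual is the Euclidean
#' distance of the winning pair from the observations.
#'
#' @param obs_egg,obs_pb Numeric vectors of observed (fractional) chromatid
#'   copy numbers, equal length.
#' @return A data.frame with columns `egg`, `pb` (integers) and `residual`.
#' @export
#' @examples
#' designate_copies(3.9, 0.1)
designate_copies <- function(obs_egg, obs_pb) {
  stopifnot(length(obs_egg) == length(obs_pb))
  # candidate order encodes the tie-break: nearest to (2,2) wins ties
  cand_e <- c(2L, 1L, 3L, 0L, 4L)
  cand_p <- 4L - cand_e
  n <- length(obs_egg)
  e <- integer(n); p <- integer(n); res <- numeric(n)
  for (i in seq_len(n)) {
    r2 <- (cand_e - obs_egg[i])^2 + (cand_p - obs_pb[i])^2
    k <- which.min(r2)
    e[i] <- cand_e[k]; p[i] <- cand_p[k]; res[i] <- sqrt(r2[k])
  }
  data.frame(egg = e, pb = p, residual = res)
}

# integer in 0..4 nearest to obs (ties toward 2), with absolute residual
designate_one_sided <- function(obs) {
  cand <- c(2L, 1L, 3L, 0L, 4L)
  k <- which.min(abs(cand - obs))
  list(value = cand[k], residual = abs(cand[k] - obs))
}

# Provisional integer designations for the current rescaled observations:
# joint minimization where both sides are observed, complementation from the
# partner where one side is missing. No tolerance is applied here.
provisional_designation <- function(ae, ap) {
  n <- length(ae)
  e <- rep(NA_integer_, n); p <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(ae[i]) && is.na(ap[i])) next
    if (is.na(ae[i])) {
      d <- designate_one_sided(ap[i]); p[i] <- d$value; e[i] <- 4L - d$value
    } else if (is.na(ap[i])) {
      d <- designate_one_sided(ae[i]); e[i] <- d$value; p[i] <- 4L - d$value
    } else {
      d <- designate_copies(ae[i], ap[i]); e[i] <- d$egg; p[i] <- d$pb
    }
  }
  list(e = e, p = p)
}

# One run of the alternating self-calibration from a given starting point:
# (i) provisional integer designation of every chromosome, (ii) per-side
# least-squares refit of each scale against its own designated integers,
# until the designations stabilize. Returns the scales plus the residual
# sum of squares in designated-copy space.
em_calibrate <- function(oe, op, a, b, max_iter = 25L) {
  prev_e <- NULL
  d <- provisional_designation(oe * a, op * b)
  for (iter in seq_len(max_iter)) {
    ie <- !is.na(oe) & !is.na(d$e)
    if (any(ie) && sum(d$e[ie]^2) > 0) {
      se <- sum(oe[ie] * d$e[ie]) / sum(d$e[ie]^2)
      if (is.finite(se) && se > 0) a <- 1 / se
    }
    ip <- !is.na(op) & !is.na(d$p)
    if (any(ip) && sum(d$p[ip]^2) > 0) {
      sp <- sum(op[ip] * d$p[ip]) / sum(d$p[ip]^2)
      if (is.finite(sp) && sp > 0) b <- 1 / sp
    }
    prev_e <- d$e
    d <- provisional_designation(oe * a, op * b)
    if (identical(d$e, prev_e)) break
  }
  ie <- !is.na(oe) & !is.na(d$e)
  ip <- !is.na(op) & !is.na(d$p)
  rss <- sum((oe[ie] * a - d$e[ie])^2) + sum((op[ip] * b - d$p[ip])^2)
  list(a = a, b = b, rss = rss,
       n_euploid = sum(!is.na(d$e) & d$e == 2L & d$p == 2L))
}

# Reciprocal self-calibration of the two observed profiles under the
# conservation constraint. The autosome-anchored 1M normalization scales
# each sample's observed values by an unknown sample-specific factor;
# conservation (true e + p = 4 for every chromosome) identifies both
# factors up to a relabeling ambiguity: a euploid pair and a uniform
# whole-complement mis-segregation produce the same data up to scale, so
# parsimony (aneuploidy is the exception) must break near-ties. Each side's
# scale is fitted against its own provisionally designated integers,
# iterating to a fixed point, from two starting points -- a common scale
# fitted to the per-chromosome sums, and, when identifiable, the joint
# two-scale least-squares solution of a*oe + b*op = 4 (which locates the
# extreme per-side factors of whole-complement segregation failures). The
# converged solution calling fewer euploid chromosomes is accepted only
# when its residual is decisively smaller (less than half) than the more
# parsimonious one's; solutions with equal euploid counts compete on
# residual alone.
reciprocal_scales <- function(oe, op, max_iter = 25L) {
  both <- !is.na(oe) & !is.na(op)
  # one profile entirely missing: its sample was degenerate (reads
  # concentrated on the few chromosomes it carried), so the partner holds
  # essentially the whole complement; anchor the partner's scale on 4
  # copies and refine from there, without a parsimony competitor
  if (all(is.na(oe))) {
    b1 <- 4 * sum(op, na.rm = TRUE) / sum(op^2, na.rm = TRUE)
    f <- em_calibrate(oe, op, NA_real_, b1, max_iter)
    return(c(a = f$a, b = f$b))
  }
  if (all(is.na(op))) {
    a1 <- 4 * sum(oe, na.rm = TRUE) / sum(oe^2, na.rm = TRUE)
    f <- em_calibrate(oe, op, a1, NA_real_, max_iter)
    return(c(a = f$a, b = f$b))
  }
  t <- oe[both] + op[both]
  s0 <- if (length(t) && sum(t^2) > 0) 4 * sum(t) / sum(t^2) else 1
  starts <- list(c(s0, s0))
  if (sum(both) >= 3L) {
    M <- cbind(oe[both], op[both])
    qr_m <- qr(M)
    if (qr_m$rank == 2L) {
      ab <- tryCatch(qr.coef(qr_m, rep(4, sum(both))),
                     error = function(e) c(NA_real_, NA_real_))
      if (all(is.finite(ab)) && all(ab > 0)) {
        starts <- c(starts, list(c(ab[1L], ab[2L])))
      }
    }
  }
  fits <- lapply(starts, function(s)
    em_calibrate(oe, op, s[1L], s[2L], max_iter))
  best <- Reduce(function(f1, f2) {
    if (f1$n_euploid == f2$n_euploid) {
      return(if (f2$rss < f1$rss) f2 else f1)
    }
    pars <- if (f1$n_euploid > f2$n_euploid) f1 else f2
    alt <- if (f1$n_euploid > f2$n_euploid) f2 else f1
    if (pars$rss > 0 && alt$rss < 0.5 * pars$rss) alt else pars
  }, fits)
  c(a = best$a, b = best$b)
}

#' Designate a matched egg / polar-body pair
#'
#' For each chromosome, chooses designated integer chromatid copies (e, p)
#' with e + p = 4 from the two observed copy-number profiles and classifies
#' the chromosome as euploid, PSSC or NDJ. Chromosomes whose best integer
#' fit leaves a residual above `tol` are marked discordant instead of being
#' forced to a call. With `rescale = TRUE` (default) the two profiles are
#' first jointly recalibrated under the conservation constraint (see
#' Details); this is the reciprocal interpretation step that makes
#' whole-complement segregation failures callable.
#'
#' When one side of a chromosome (or a whole sample) has no observed value,
#' the designation is made from the partner alone via e = 4 - p.
#'
#' @param egg_cn,pb_cn Named numeric vectors of observed copy numbers per
#'   chromosome (as from [call_cn_profile()]'s `observed_cn`). Both must
#'   cover the same chromosomes; X is included, Y (if present) is dropped.
#' @param tol Discordance tolerance on the residual (default 0.5, the
#'   half-copy rounding radius).
#' @param rescale Apply the joint conservation-constrained rescaling.
#' @param pair_id Optional identifier stored on the result.
#' @return A data.frame of class `reciprocal_calls` with columns `chrom`,
#'   `obs_egg`, `obs_pb`, `adj_egg`, `adj_pb` (rescaled observations),
#'   `egg`, `pb` (designated integers, NA when discordant), `class`
#'   ("euploid"/"PSSC"/"NDJ"/"discordant") and `residual`; attributes
#'   `pair_id` and `scales`.
#' @export
designate_pair <- function(egg_cn, pb_cn, tol = 0.5, rescale = TRUE,
                           pair_id = NA_character_) {
  if (is.null(names(egg_cn)) || is.null(names(pb_cn))) {
    stop("egg_cn and pb_cn must be named per-chromosome vectors")
  }
  egg_cn <- egg_cn[setdiff(names(egg_cn), "Y")]
  pb_cn <- pb_cn[setdiff(names(pb_cn), "Y")]
  if (!setequal(names(egg_cn), names(pb_cn))) {
    stop("egg and polar-body profiles must cover the same chromosomes")
  }
  chroms <- names(egg_cn)
  oe <- as.numeric(egg_cn)
  op <- as.numeric(pb_cn[chroms])
  if (all(is.na(oe)) && all(is.na(op))) {
    stop("cannot designate: both profiles are entirely missing")
  }

  scales <- if (rescale) reciprocal_scales(oe, op) else c(a = 1, b = 1)
  ae <- oe * scales[["a"]]
  ap <- op * scales[["b"]]

  n <- length(chroms)
  egg <- rep(NA_integer_, n); pb <- rep(NA_integer_, n)
  cls <- rep(NA_character_, n); res <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(ae[i]) && is.na(ap[i])) {
      cls[i] <- "discordant"; next
    }
    if (is.na(ae[i]) || is.na(ap[i])) {
      obs <- if (is.na(ae[i])) ap[i] else ae[i]
      d <- designate_one_sided(obs)
      res[i] <- d$residual
      if (d$residual > tol) { cls[i] <- "discordant"; next }
      if (is.na(ae[i])) { pb[i] <- d$value; egg[i] <- 4L - d$value }
      else { egg[i] <- d$value; pb[i] <- 4L - d$value }
    } else {
      d <- designate_copies(ae[i], ap[i])
      res[i] <- d$residual
      if (d$residual > tol) { cls[i] <- "discordant"; next }
      egg[i] <- d$egg; pb[i] <- d$pb
    }
    cls[i] <- classify_chromosome(egg[i], pb[i])
  }

  out <- data.frame(chrom = chroms, obs_egg = oe, obs_pb = op,
                    adj_egg = ae, adj_pb = ap,
                    egg = egg, pb = pb, class = cls, residual = res,
                    stringsAsFactors = FALSE)
  structure(out, pair_id = pair_id, scales = scales,
            class = c("reciprocal_calls", "data.frame"))
}

severity_levels <- function() c("euploid", "1-3", ">=4")

severity_class <- function(n_errors) {
  ifelse(n_errors == 0L, "euploid", ifelse(n_errors <= 3L, "1-3", ">=4"))
}

#' Classify a designated pair into type and severity
#'
#' Counts the non-euploid, non-discordant chromosomes, assigns the
#' aneuploidy type (euploid / NDJ / PSSC / NDJ+PSSC, the combination when
#' both error classes occur), buckets severity as euploid, 1-3 errors or
#' >=4 errors, and renders the egg and polar-body karyotype strings.
#' Discordant chromosomes are counted separately and never as errors.
#'
#' @param calls A `reciprocal_calls` data.frame from [designate_pair()] (or
#'   [pair_calls_from_karyotypes()]).
#' @param pair_id Identifier; defaults to the one stored on `calls`.
#' @return A list of class `sample_karyotype`: `pair_id`, `egg_karyotype`,
#'   `pb_karyotype`, `aneuploidy_type`, `n_errors`, `n_discordant`,
#'   `severity`.
#' @export
classify_sample <- function(calls, pair_id = attr(calls, "pair_id")) {
  stopifnot(is.data.frame(calls),
            all(c("chrom", "egg", "pb", "class") %in% names(calls)))
  err <- calls$class %in% c("PSSC", "NDJ")
  n_errors <- sum(err)
  n_disc <- sum(calls$class == "discordant")
  type <- if (n_errors == 0L) {
    "euploid"
  } else {
    has_ndj <- any(calls$class == "NDJ")
    has_pssc <- any(calls$class == "PSSC")
    if (has_ndj && has_pssc) "NDJ+PSSC" else if (has_ndj) "NDJ" else "PSSC"
  }
  # discordant chromosomes have no designated value; render them as euploid
  # in the string and report n_discordant alongside
  egg_copies <- stats::setNames(ifelse(is.na(calls$egg), 2L, calls$egg), calls$chrom)
  pb_copies <- stats::setNames(ifelse(is.na(calls$pb), 2L, calls$pb), calls$chrom)
  structure(list(
    pair_id = pair_id,
    egg_karyotype = write_karyotype(egg_copies),
    pb_karyotype = write_karyotype(pb_copies),
    aneuploidy_type = type,
    n_errors = n_errors,
    n_discordant = n_disc,
    severity = severity_class(n_errors)
  ), class = "sample_karyotype")
}

#' @export
print.sample_karyotype <- function(x, ...) {
  cat(sprintf("<sample_karyotype> %s: %s (%d error%s, severity %s)\n",
              x$pair_id, x$aneuploidy_type, x$n_errors,
              if (x$n_errors == 1L) "" else "s", x$severity))
  cat("  egg:", x$egg_karyotype, "\n  pb: ", x$pb_karyotype, "\n")
  invisible(x)
}

#' Build reciprocal calls from a pair of karyotype strings
#'
#' Parses the egg and polar-body karyotype strings and classifies every
#' chromosome's reciprocal pattern; chromosomes whose parsed copies do not
#' sum to 4 are marked discordant.
#'
#' @param egg_karyotype,pb_karyotype Karyotype strings.
#' @param chromosomes Chromosomes the calls should cover.
#' @param pair_id Optional identifier.
#' @return A `reciprocal_calls` data.frame as from [designate_pair()].
#' @export
#' @examples
#' calls <- pair_calls_from_karyotypes("sseq cht(1)x4", "sseq cht(1)x0")
#' subset(calls, class != "euploid")
pair_calls_from_karyotypes <- function(egg_karyotype, pb_karyotype,
                                       chromosomes = c(as.character(1:19), "X"),
                                       pair_id = NA_character_) {
  e <- parse_karyotype(egg_karyotype, chromosomes)
  p <- parse_karyotype(pb_karyotype, chromosomes)
  conserved <- e + p == 4L
  cls <- rep("discordant", length(chromosomes))
  cls[conserved] <- classify_chromosome(e[conserved], p[conserved])
  out <- data.frame(
    chrom = chromosomes,
    obs_egg = as.numeric(e), obs_pb = as.numeric(p),
    adj_egg = as.numeric(e), adj_pb = as.numeric(p),
    egg = ifelse(conserved, e, NA_integer_),
    pb = ifelse(conserved, p, NA_integer_),
    class = cls,
    residual = ifelse(conserved, 0, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(out, pair_id = pair_id, scales = c(a = 1, b = 1),
            class = c("reciprocal_calls", "data.frame"))
}

#' Sex-concordance check on designated X/Y counts
#'
#' In "blastomere" mode, samples are grouped by embryo and an embryo is
#' concordant when all its blastomeres share identical designated (X, Y)
#' counts; the embryo sex is reported as female for (2, 0), male for (1, 1).
#' In "egg_pb" mode each group is one matched egg / polar-body pair and is
#' concordant when both members carry two X and no Y chromosome.
#'
#' @param samples A data.frame with columns `sample_id`, `group` (embryo or
#'   pair identifier), `X`, `Y` (designated integer counts).
#' @param mode "blastomere" or "egg_pb".
#' @return A data.frame with one row per group: `group`, `n`, `concordant`,
#'   `sex` ("female"/"male"/"unknown"; NA in egg_pb mode).
#' @export
sex_concordance <- function(samples, mode = c("blastomere", "egg_pb")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "group", "X", "Y") %in% names(samples)))
  res <- lapply(split(samples, samples$group), function(g) {
    if (mode == "blastomere") {
      if (nrow(g) < 2L) {
        warning(sprintf("group '%s' has fewer than 2 blastomeres; trivially concordant",
                        g$group[1L]))
      }
      conc <- length(unique(paste(g$X, g$Y))) == 1L
      sex <- if (!conc) {
        "unknown"
      } else if (g$X[1L] == 2L && g$Y[1L] == 0L) {
        "female"
      } else if (g$X[1L] == 1L && g$Y[1L] == 1L) {
        "male"
      } else "unknown"
    } else {
      conc <- all(g$X == 2L) && all(g$Y == 0L)
      sex <- NA_character_
    }
    data.frame(group = g$group[1L], n = nrow(g), concordant = conc,
               sex = sex, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
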