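# Shallow-NGS karyotype nomenclature for chromatid copy calls:
#   "sseq cht(<chrom list>)x<copies>, cht(...)x<copies>, ..."
# One clause per abnormal copy value; within a clause X (then Y) come first,
# then autosomes ascending with runs of three or more consecutive autosomes
# collapsed to "a-b"; clauses are ordered by their lowest chromosome (X sorts
# lowest). A fully euploid sample is rendered as a fixed euploid token.

#' Token used for a euploid karyotype
#' @export
euploid_token <- function() "sseq euploid"

# sort key: X before Y before autosomes 1..n
chrom_sort_key <- function(chrom) {
  key <- suppressWarnings(as.numeric(chrom))
  key[chrom == "X"] <- -2
  key[chrom == "Y"] <- -1
  key
}

# "X, 1-6,8-19" style rendering of a chromosome set
format_chrom_list <- function(chroms) {
  sex <- chroms[chroms %in% c("X", "Y")]
  sex <- sex[order(match(sex, c("X", "Y")))]
  nums <- sort(as.integer(chroms[!chroms %in% c("X", "Y")]))
  num_parts <- character(0)
  if (length(nums)) {
    run_id <- cumsum(c(1L, diff(nums) != 1L))
    for (r in split(nums, run_id)) {
      num_parts <- c(num_parts,
                     if (length(r) >= 3L) sprintf("%d-%d", r[1L], r[length(r)])
                     else as.character(r))
    }
  }
  num_str <- paste(num_parts, collapse = ",")
  if (length(sex) && nzchar(num_str)) {
    paste0(paste(sex, collapse = ", "), ", ", num_str)
  } else if (length(sex)) {
    paste(sex, collapse = ", ")
  } else {
    num_str
  }
}

#' Write a karyotype string from designated copy numbers
#'
#' @param copies Named integer vector of designated chromatid copy numbers
#'   (values 0..4), one element per chromosome (e.g. `"1".."19"`, `"X"`).
#'   Chromosomes at the euploid value 2 are omitted from the string.
#' @return A single karyotype string; [euploid_token()] when no chromosome is
#'   abnormal.
#' @export
#' @examples
#' write_karyotype(c("1" = 0, "8" = 0, "4" = 4, "18" = 4, "2" = 2))
write_karyotype <- function(copies) {
  if (is.null(names(copies)) || any(!nzchar(names(copies)))) {
    stop("copies must be a named vector of per-chromosome copy numbers")
  }
  vals <- as.integer(round(copies))
  if (any(is.na(vals)) || any(vals < 0L | vals > 4L)) {
    stop("copy numbers must be integers in 0..4")
  }
  names(vals) <- names(copies)
  ab <- vals[vals != 2L]
  if (!length(ab)) return(euploid_token())
  groups <- split(names(ab), ab)
  first_key <- vapply(groups, function(ch) min(chrom_sort_key(ch)), numeric(1))
  groups <- groups[order(first_key)]
  clauses <- vapply(seq_along(groups), function(i) {
    sprintf("cht(%s)x%s", format_chrom_list(groups[[i]]), names(groups)[i])
  }, character(1))
  paste0("sseq ", paste(clauses, collapse = ", "))
}

#' Parse a karyotype string into designated copy numbers
#'
#' Inverse of [write_karyotype()]; whitespace-tolerant. Chromosomes not
#' mentioned in any clause default to the euploid value 2.
#'
#' @param text A karyotype string.
#' @param chromosomes Character vector of chromosomes the result should cover
#'   (default autosomes 1..19 plus X, the oocyte complement).
#' @return Named integer vector of copy numbers over `chromosomes`.
#' @export
#' @examples
#' parse_karyotype("sseq cht(2,16,18)x4")
parse_karyotype <- function(text, chromosomes = c(as.character(1:19), "X")) {
  if (!is.character(text) || length(text) != 1L) {
    stop("text must be a single character string")
  }
  out <- stats::setNames(rep(2L, length(chromosomes)), chromosomes)
  squished <- gsub("\\s+", " ", trimws(text))
  if (identical(squished, euploid_token())) return(out)
  if (!grepl("^sseq\\b", squished)) {
    stop("karyotype string must start with 'sseq' (position 1)")
  }
  body <- sub("^sseq\\s*", "", squished)
  pat <- "cht\\s*\\(([^()]*)\\)\\s*x\\s*([0-9]+)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1L] == -1L) stop("no cht(...)x<copies> clause found")
  clauses <- regmatches(body, gregexpr(pat, body, perl = TRUE))[[1]]
  leftover <- gsub(pat, "", body, perl = TRUE)
  leftover_clean <- gsub("[,\\s]", "", leftover, perl = TRUE)
  if (nzchar(leftover_clean)) {
    pos <- regexpr(substr(leftover_clean, 1L, 1L), leftover, fixed = TRUE)
    stop(sprintf("malformed karyotype string: unexpected text '%s'",
                 substr(leftover_clean, 1L, 10L)), call. = FALSE)
  }
  seen <- character(0)
  for (clause in clauses) {
    parts <- regmatches(clause, regexec(pat, clause, perl = TRUE))[[1]]
    copies <- as.integer(parts[3L])
    if (is.na(copies) || copies > 4L) {
      stop(sprintf("copy number outside 0..4 in clause '%s'", clause))
    }
    tokens <- trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) stop(sprintf("empty chromosome list in clause '%s'", clause))
    chroms <- character(0)
    for (tok in tokens) {
      if (tok %in% c("X", "Y")) {
        chroms <- c(chroms, tok)
      } else if (grepl("^[0-9]+$", tok)) {
        chroms <- c(chroms, tok)
      } else if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", tok)) {
        ends <- as.integer(strsplit(tok, "-", fixed = FALSE)[[1]])
        if (ends[1L] >= ends[2L]) {
          stop(sprintf("invalid chromosome range '%s'", tok))
        }
        chroms <- c(chroms, as.character(seq(ends[1L], ends[2L])))
      } else {
        stop(sprintf("malformed chromosome token '%s' in clause '%s'", tok, clause))
      }
    }
    bad <- setdiff(chroms, chromosomes)
    if (length(bad)) {
      stop(sprintf("unknown chromosome '%s' in clause '%s'", bad[1L], clause))
    }
    dup <- chroms[chroms %in% seen | duplicated(chroms)]
    if (length(dup)) {
      stop(sprintf("chromosome '%s' appears in more than one clause", dup[1L]))
    }
    seen <- c(seen, chroms)
    out[chroms] <- copies
  }
  out
}

#' Classify a reciprocal (egg, polar body) chromatid pattern
#'
#' Maps designated integer chromatid counts for one chromosome to an error
#' class: (2,2) is euploid; (3,1) and (1,3) are premature separation of sister
#' chromatids (PSSC); (4,0) and (0,4) are non-disjunction (NDJ).
#'
#' @param egg,pb Integer chromatid counts (vectors of equal length); each pair
#'   must sum to 4.
#' @return Character vector of class labels: "euploid", "PSSC" or "NDJ".
#' @export
#' @examples
#' classify_chromosome(c(4, 1, 2), c(0, 3, 2))
classify_chromosome <- function(egg, pb) {
  e <- as.integer(egg); p <- as.integer(pb)
  if (length(e) != length(p)) stop("egg and pb must have equal length")
  if (any(is.na(e)) || any(is.na(p))) stop("chromatid counts must be non-missing")
  if (any(e < 0L | e > 4L | p < 0L | p > 4L)) stop("chromatid counts must be in 0..4")
  if (any(e + p != 4L)) {
    stop("egg + pb must equal 4 chromatids; route non-conserved calls to discordant handling")
  }
  ifelse(e == 2L, "euploid", ifelse(e %in% c(1L, 3L), "PSSC", "NDJ"))
}
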