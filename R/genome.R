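# Mouse chromosome complement and the fixed genome-wide binning shared by all
# downstream modules. Coordinates are 0-based half-open (BED convention).

# GRCm39 chromosome lengths in bp. Only lengths are needed downstream.
.MOUSE_CHROM_LENGTHS <- c(
  "1" = 195154279, "2" = 181755017, "3" = 159745316, "4" = 156860686,
  "5" = 151758149, "6" = 149588044, "7" = 144995196, "8" = 130127694,
  "9" = 124359700, "10" = 130530862, "11" = 121973369, "12" = 120092757,
  "13" = 120883175, "14" = 125139656, "15" = 104073951, "16" = 98008968,
  "17" = 95294699, "18" = 90720763, "19" = 61420004,
  "X" = 169476592, "Y" = 91455967
)

#' Default mouse chromosome table
#'
#' The 19 autosomes plus X and Y with GRCm39 lengths, in canonical order.
#' The Y chromosome is included so that blastomere sex concordance can be
#' assessed; oocyte-derived samples carry no Y signal.
#'
#' @return A data.frame with columns `name` (character), `length` (bp) and
#'   `is_sex` (logical).
#' @export
#' @examples
#' head(mouse_chromosomes())
mouse_chromosomes <- function() {
  data.frame(
    name = names(.MOUSE_CHROM_LENGTHS),
    length = unname(.MOUSE_CHROM_LENGTHS),
    is_sex = names(.MOUSE_CHROM_LENGTHS) %in% c("X", "Y"),
    stringsAsFactors = FALSE
  )
}

#' Read a chromosome table from a two-column TSV
#'
#' Overrides the bundled GRCm39 constants. The file must have two columns,
#' name and length (a header line is optional); any chromosome named `X` or
#' `Y` is treated as a sex chromosome.
#'
#' @param path Path to a tab-separated file with columns name, length.
#' @return A chromosome table as returned by [mouse_chromosomes()].
#' @export
read_chromosome_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("chromosome table must have two columns: name, length")
  # tolerate a header row
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L])))) raw <- raw[-1L, , drop = FALSE]
  tab <- data.frame(
    name = as.character(raw[[1L]]),
    length = as.numeric(raw[[2L]]),
    stringsAsFactors = FALSE
  )
  tab$is_sex <- tab$name %in% c("X", "Y")
  validate_chromosomes(tab)
  tab
}

validate_chromosomes <- function(chromosomes) {
  if (!is.data.frame(chromosomes) ||
      !all(c("name", "length") %in% names(chromosomes))) {
    stop("chromosomes must be a data.frame with columns name and length")
  }
  if (nrow(chromosomes) == 0L) stop("chromosome list is empty")
  if (anyDuplicated(chromosomes$name)) stop("chromosome names must be unique")
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0)) {
    stop("every chromosome length must be a positive number")
  }
  invisible(chromosomes)
}

#' Tile a genome into fixed-width windows
#'
#' Produces the genome-wide binning used by the copy-number caller: each
#' chromosome is tiled without gaps or overlaps into consecutive windows of
#' `window_size` bp, 0-based half-open; only a chromosome's last bin may be
#' shorter. Bin order is chromosome order, then ascending start.
#'
#' @param chromosomes Chromosome table (see [mouse_chromosomes()]).
#' @param window_size Window width in bp (default 10 Mb).
#' @return A data.frame of class `genome_binning` with columns `chrom`,
#'   `start`, `end`, and attributes `window_size` and `chromosomes`.
#' @export
#' @examples
#' b <- make_binning(mouse_chromosomes(), 1e7)
#' nrow(b)
make_binning <- function(chromosomes = mouse_chromosomes(), window_size = 1e7) {
  validate_chromosomes(chromosomes)
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      !is.finite(window_size) || window_size <= 0) {
    stop("window_size must be a single positive number")
  }
  if (!"is_sex" %in% names(chromosomes)) {
    chromosomes$is_sex <- chromosomes$name %in% c("X", "Y")
  }
  pieces <- lapply(seq_len(nrow(chromosomes)), function(i) {
    len <- chromosomes$length[i]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(
      chrom = chromosomes$name[i],
      start = starts,
      end = pmin(starts + window_size, len),
      stringsAsFactors = FALSE
    )
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  structure(bins,
            window_size = window_size,
            chromosomes = chromosomes,
            class = c("genome_binning", "data.frame"))
}

#' @export
print.genome_binning <- function(x, ...) {
  chroms <- attr(x, "chromosomes")
  cat(sprintf("<genome_binning> %d bins over %d chromosomes, window %s bp\n",
              nrow(x), nrow(chroms), format(attr(x, "window_size"),
                                            big.mark = ",", scientific = FALSE)))
  invisible(x)
}

# logical vector: is each bin autosomal?
bin_is_autosome <- function(binning) {
  chroms <- attr(binning, "chromosomes")
  !binning$chrom %in% chroms$name[chroms$is_sex]
}

binning_chrom_names <- function(binning) attr(binning, "chromosomes")$name

binning_sex_chroms <- function(binning) {
  chroms <- attr(binning, "chromosomes")
  chroms$name[chroms$is_sex]
}
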