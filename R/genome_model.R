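#' Genome models: chromosome and arm geometry
#'
#' A genome model holds chromosome lengths and centromere coordinates and
#' derives the p/q arm intervals used by the copy-number analytics (HRD
#' scars, arm-level events, genome fractions). All coordinates are 1-based
#' and inclusive on both ends; length arithmetic is `end - start + 1`.
#' Sex chromosomes (chrX/chrY) are parsed and kept in the chromosome table
#' but flagged, and are excluded from the derived arm list and from all
#' copy-number metrics; variant-level metrics may still use them.
#'
#' @param path Path to a tab-separated arm table with header columns
#'   `chrom`, `length`, `cen_start`, `cen_end` (bp).
#' @return An object of class `genome_model`: a list with tibbles
#'   `chromosomes` (`chrom`, `length`, `cen_start`, `cen_end`, `sex`) and
#'   `arms` (`chrom`, `arm`, `start`, `end`, `length`), the latter
#'   autosomes only, zero-length (acrocentric-like) p arms dropped.
#' @examples
#' g <- hetpanel_genome()
#' nrow(g$chromosomes)  # 24 parsed
#' unique(g$arms$chrom) # 22 autosomes in the arm list
#' @export
load_genome_model <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(req %in% names(tab))) {
    abort(paste0("genome model table must have columns: ",
                 paste(req, collapse = ", ")))
  }
  new_genome_model(tab)
}

#' Build a genome model from a chromosome tibble
#'
#' @param chromosomes Tibble with `chrom`, `length`, `cen_start`, `cen_end`.
#' @return A `genome_model` object (see [load_genome_model()]).
#' @export
new_genome_model <- function(chromosomes) {
  tab <- tibble::as_tibble(chromosomes)
  if (anyDuplicated(tab$chrom)) {
    abort("duplicated chromosome names in genome model")
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    bad <- r$length <= 0 || r$cen_start < 1 || r$cen_end < r$cen_start ||
      r$cen_end > r$length || r$cen_start > r$length
    if (is.na(bad) || bad) {
      abort(sprintf(
        "invalid chromosome geometry in row %d (%s): length=%s cen_start=%s cen_end=%s",
        i, r$chrom, r$length, r$cen_start, r$cen_end))
    }
  }
  tab$sex <- is_sex_chrom(tab$chrom)

  auto <- tab[!tab$sex, ]
  arms <- dplyr::bind_rows(
    tibble::tibble(chrom = auto$chrom, arm = "p",
                   start = 1, end = auto$cen_start - 1),
    tibble::tibble(chrom = auto$chrom, arm = "q",
                   start = auto$cen_end + 1, end = auto$length)
  )
  arms$length <- arms$end - arms$start + 1
  arms <- arms[arms$length > 0, ]
  arms <- dplyr::arrange(arms, match(.data$chrom, tab$chrom), .data$arm)

  structure(list(chromosomes = tab, arms = arms), class = "genome_model")
}

is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes (%d autosomes), %d arms\n",
              nrow(x$chromosomes), sum(!x$chromosomes$sex), nrow(x$arms)))
  invisible(x)
}

#' Write a genome model back to its tab-separated form
#'
#' @param genome A `genome_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_model <- function(genome, path) {
  readr::write_tsv(genome$chromosomes[, c("chrom", "length", "cen_start",
                                          "cen_end")], path, progress = FALSE)
  invisible(path)
}

#' Bundled hg19-like autosome geometry
#'
#' Returns the packaged genome model: the 22 human autosomes plus chrX/chrY
#' with approximate hg19 lengths and centromere coordinates. Adequate for
#' arm-level analytics; not a substitute for exact cytoband annotation.
#'
#' @return A `genome_model`.
#' @export
hetpanel_genome <- function() {
  load_genome_model(system.file("extdata", "genome_hg19like.tsv",
                                package = "hetpanel", mustWork = TRUE))
}

#' Autosome subset of a genome model's chromosome table
#' @param genome A `genome_model`.
#' @return Tibble of autosomal chromosomes.
#' @export
autosomes <- function(genome) {
  genome$chromosomes[!genome$chromosomes$sex, ]
}
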