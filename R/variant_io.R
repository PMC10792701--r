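#' Read somatic variant calls from a single-sample VCF
#'
#' Parses a VCF 4.x file (via VariantAnnotation) into one row per
#' alternate allele. Multi-allelic records are split with per-allele
#' depths. `DP` and `AD` must be present in FORMAT (AD as ref,alt counts);
#' INFO keys `CSQCLASS` (missense/synonymous/other), `REGION`
#' (exonic/splice/...) and `TNC` (trinucleotide context) are picked up
#' when present.
#'
#' @param path Path to the VCF file.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `vaf`, `filter_status`, `consequence_class`, `region`,
#'   `trinucleotide_context`. Copy-number context columns are added later
#'   by [annotate_local_copy_number()].
#' @export
read_somatic_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(v) != 1) {
    abort(sprintf("expected a single-sample VCF, found %d samples", ncol(v)))
  }
  gen <- VariantAnnotation::geno(v)
  if (!all(c("DP", "AD") %in% names(gen))) {
    abort("VCF FORMAT must provide DP and AD")
  }
  ve <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(ve)
  ad <- VariantAnnotation::geno(ve)$AD
  if (length(dim(ad)) != 3 || dim(ad)[3] < 2) {
    abort("AD must carry ref and alt allele depths (Number=R)")
  }
  depth <- as.integer(VariantAnnotation::geno(ve)$DP[, 1])
  alt_count <- as.integer(ad[, 1, 2])
  if (anyNA(depth) || anyNA(alt_count)) {
    bad <- which(is.na(depth) | is.na(alt_count))[1]
    abort(sprintf("missing DP/AD in VCF record %d (%s:%d)", bad,
                  as.character(GenomeInfoDb::seqnames(rr))[bad],
                  BiocGenerics::start(rr)[bad]))
  }
  info <- VariantAnnotation::info(ve)
  grab <- function(key, default) {
    if (key %in% names(info)) {
      x <- info[[key]]
      if (is(x, "List") || is.list(x)) {
        x <- vapply(x, function(e) {
          if (length(e)) as.character(e[1]) else NA_character_
        }, character(1))
      }
      x <- as.character(x)
      ifelse(is.na(x), default, x)
    } else {
      rep(default, length(ve))
    }
  }
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(ve)),
    alt = as.character(VariantAnnotation::alt(ve)),
    depth = depth,
    alt_count = alt_count,
    vaf = ifelse(depth > 0, alt_count / depth, NA_real_),
    filter_status = rr$FILTER,
    consequence_class = grab("CSQCLASS", "other"),
    region = grab("REGION", "exonic"),
    trinucleotide_context = grab("TNC", NA_character_)
  )
}

#' Write a variant tibble as a single-sample VCF 4.2 file
#'
#' Inverse of [read_somatic_vcf()] for the columns the pipeline uses.
#'
#' @param variants Variant tibble (as from [read_somatic_vcf()] or the
#'   simulator).
#' @param path Output path.
#' @param sample_id Sample column name in the VCF.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(variants, path, sample_id = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hetpanel",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class: missense, synonymous or other\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class: exonic, splice or other\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context of the reference strand\">",
    "##FILTER=<ID=lowq,Description=\"Failed caller quality filters\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  v <- dplyr::arrange(variants, .data$chrom, .data$pos)
  tnc <- ifelse(is.na(v$trinucleotide_context), "",
                paste0(";TNC=", v$trinucleotide_context))
  info <- paste0("CSQCLASS=", v$consequence_class,
                 ";REGION=", v$region, tnc)
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tDP:AD\t%d:%d,%d",
                   v$chrom, v$pos, v$ref, v$alt, v$filter_status, info,
                   v$depth, v$depth - v$alt_count, v$alt_count)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Filter somatic variants by caller status, region and evidence
#'
#' Keeps exactly the variants with `filter_status == "PASS"`, region class
#' among `allowed_regions`, `vaf >= min_vaf` and `depth >= min_depth`
#' (thresholds inclusive). Idempotent.
#'
#' @param variants Variant tibble.
#' @param min_vaf Minimum variant allele frequency (fraction, default 0.05).
#' @param min_depth Minimum read depth (default 100).
#' @param allowed_regions Region classes kept (default exonic and splice).
#' @return The filtered tibble.
#' @export
apply_variant_filters <- function(variants, min_vaf = 0.05, min_depth = 100,
                                  allowed_regions = c("exonic", "splice")) {
  dplyr::filter(
    variants,
    .data$filter_status == "PASS",
    .data$region %in% allowed_regions,
    .data$vaf >= min_vaf,
    .data$depth >= min_depth
  )
}

#' Annotate variants with their local copy-number context
#'
#' Maps each variant to the unique copy-number segment containing its
#' position (1-based inclusive on both segment ends) and records the
#' segment's fitted total and minor copy number plus an LOH flag
#' (`minor_cn == 0`). Variants falling in segment gaps receive the
#' diploid default (total 2, minor 1, no LOH); their count is reported as
#' an attribute `n_gap` and a message.
#'
#' @param variants Variant tibble.
#' @param segments Segment tibble with `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`.
#' @return `variants` with columns `local_total_cn`, `local_minor_cn`,
#'   `loh_flag` added, and attribute `n_gap`.
#' @export
annotate_local_copy_number <- function(variants, segments) {
  seg <- dplyr::select(segments, "chrom", "start", "end",
                       "total_cn", "minor_cn")
  hit <- dplyr::left_join(
    dplyr::mutate(variants, .row = dplyr::row_number()),
    seg,
    by = dplyr::join_by("chrom", dplyr::between("pos", "start", "end"))
  )
  dup <- hit$.row[duplicated(hit$.row)]
  if (length(dup)) {
    d <- variants[dup[1], ]
    abort(sprintf("overlapping segments both contain %s:%d",
                  d$chrom, d$pos))
  }
  n_gap <- sum(is.na(hit$total_cn))
  if (n_gap > 0) {
    inform(sprintf(
      "%d variant(s) in segment gaps: assigned default CN 2 (minor 1)",
      n_gap))
  }
  out <- dplyr::mutate(
    hit,
    local_total_cn = ifelse(is.na(.data$total_cn), 2, .data$total_cn),
    local_minor_cn = ifelse(is.na(.data$minor_cn), 1, .data$minor_cn),
    loh_flag = .data$local_minor_cn == 0
  )
  out <- dplyr::select(out, -".row", -"start", -"end",
                       -"total_cn", -"minor_cn")
  attr(out, "n_gap") <- n_gap
  out
}

#' Read a copy-number segment table
#'
#' Accepts either raw segments (`chrom start end logR BAF`) or pre-fitted
#' ones (`chrom start end total_cn minor_cn [clonality]`); both forms may
#' coexist. Coordinates are 1-based inclusive; a `length` column
#' (`end - start + 1`) is added.
#'
#' @param path Path to the TSV.
#' @return Segment tibble.
#' @export
read_segments_table <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(seg))) {
    abort("segment table must have columns chrom, start, end")
  }
  if (!any(c("logR", "total_cn") %in% names(seg))) {
    abort("segment table must carry logR/BAF or total_cn/minor_cn")
  }
  bad <- which(seg$start > seg$end)
  if (length(bad)) {
    abort(sprintf("segment row %d has start > end", bad[1]))
  }
  seg$length <- seg$end - seg$start + 1
  tibble::as_tibble(seg)
}

#' Write a segment table
#' @param segments Segment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_table <- function(segments, path) {
  drop <- intersect("length", names(segments))
  readr::write_tsv(segments[, setdiff(names(segments), drop)], path,
                   progress = FALSE)
  invisible(path)
}

#' Read per-sample cohort metadata
#'
#' The metadata TSV has columns `sample`, `group`, `purity`,
#' `callable_mb`. Purity must lie in (0, 1] and callable megabases must be
#' positive; duplicate sample ids are rejected.
#'
#' @param path Path to the TSV.
#' @return Metadata tibble.
#' @export
read_cohort_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample", "group", "purity", "callable_mb")
  if (!all(req %in% names(meta))) {
    abort(paste0("metadata must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample)) {
    abort(paste0("duplicated sample ids in metadata: ",
                 paste(unique(meta$sample[duplicated(meta$sample)]),
                       collapse = ", ")))
  }
  bad <- which(!(meta$purity > 0 & meta$purity <= 1))
  if (length(bad)) {
    abort(sprintf("sample %s has purity outside (0, 1]", meta$sample[bad[1]]))
  }
  if (any(meta$callable_mb <= 0)) {
    abort("callable_mb must be positive")
  }
  tibble::as_tibble(meta)
}
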