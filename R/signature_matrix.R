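#' The 96 trinucleotide substitution channels
#'
#' Canonical pyrimidine-centric channel order used throughout the package:
#' substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), and within each
#' substitution the 5' base cycles A,C,G,T with the 3' base innermost,
#' i.e. `A[C>A]A, A[C>A]C, ..., T[T>G]T`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(b5) paste0(b5, "[", s, "]", bases)))
  }))
}

comp_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Map an SNV to its pyrimidine-centric 96-channel label
#'
#' Substitutions reported on the purine strand (ref A or G) are
#' reverse-complemented, context included, so every one of the 192
#' strand-specific (ref, alt, trinucleotide) combinations maps onto
#' exactly one of the 96 canonical channels.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide context centred on the variant (the middle
#'   base must equal `ref`).
#' @return Channel label, or `NA` for non-SNVs or malformed context.
#' @export
sbs96_channel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt & nchar(context) == 3 & substr(context, 2, 2) == ref &
    grepl("^[ACGT]{3}$", context)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  flip <- r %in% c("A", "G")
  r[flip] <- comp_base(r[flip])
  a[flip] <- comp_base(a[flip])
  ctx[flip] <- revcomp(ctx[flip])
  out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]",
                    substr(ctx, 3, 3))
  out
}

#' Load a 96-channel signature reference matrix
#'
#' Reads a tab-separated matrix whose first column holds the channel label
#' (e.g. `A[C>A]A`) and whose remaining columns are named signatures.
#' Channels may appear in any order and are reindexed to the canonical
#' order of [sbs96_channels()]. Columns whose sum deviates from 1 by more
#' than `1e-6` are renormalized with a warning; negative entries and
#' unknown or missing channels are errors.
#'
#' @param path Path to the TSV file.
#' @return A `signature_matrix`: numeric 96 x K matrix, rownames channels,
#'   colnames signatures, every column summing to 1.
#' @examples
#' S <- hetpanel_signatures()
#' colSums(S)  # all 1
#' @export
load_signature_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 3) {
    abort("signature matrix needs a channel column and >= 2 signatures")
  }
  channels <- as.character(tab[[1]])
  canon <- sbs96_channels()
  if (nrow(tab) != 96) {
    abort(sprintf("signature matrix must have 96 channel rows, found %d",
                  nrow(tab)))
  }
  unknown <- setdiff(channels, canon)
  if (length(unknown)) {
    abort(paste0("unknown channel labels: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (anyDuplicated(channels)) abort("duplicated channel labels")
  m <- as.matrix(tab[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- channels
  m <- m[canon, , drop = FALSE]
  if (any(m < 0)) abort("negative entries in signature matrix")
  cs <- colSums(m)
  if (any(cs == 0)) abort("signature column with zero sum")
  off <- abs(cs - 1) > 1e-6
  if (any(off)) {
    warn(paste0("renormalizing signature columns not summing to 1: ",
                paste(colnames(m)[off], collapse = ", ")))
  }
  m <- sweep(m, 2, cs, "/")
  structure(m, class = c("signature_matrix", "matrix"))
}

#' Bundled synthetic signature reference
#'
#' Loads the packaged 96 x 8 reference matrix (SBS1, SBS2, SBS4, SBS5,
#' SBS13, SBS30, SBS92, SBS96). These are synthetic signature-like
#' profiles constructed to echo the qualitative shape of the eponymous
#' COSMIC signatures (CpG-focused C>T for SBS1, APOBEC-like T[C>N]N for
#' SBS2/SBS13, broad C>A for SBS4, near-flat clock-like SBS5); they are
#' not the COSMIC reference values. Any user-supplied 96 x K matrix in
#' the same layout can be used instead.
#'
#' @return A `signature_matrix`.
#' @export
hetpanel_signatures <- function() {
  load_signature_matrix(system.file("extdata", "signatures_synthetic96.tsv",
                                    package = "hetpanel", mustWork = TRUE))
}

# Deterministic synthetic signature-like profiles; used to build the
# bundled extdata matrix and as an in-code reference in tests.
build_synthetic_signatures <- function() {
  ch <- sbs96_channels()
  sub <- sub(".*\\[(.*)\\].*", "\\1", ch)
  b5 <- substr(ch, 1, 1)
  b3 <- substr(ch, 7, 7)

  base <- function(w) w / sum(w)
  peak <- function(mask, inside, outside = 1) {
    base(ifelse(mask, inside, outside))
  }

  sigs <- cbind(
    # CpG-deamination-like: C>T at NpCpG
    SBS1  = peak(sub == "C>T" & b3 == "G", 60),
    # APOBEC-like C>T at TpC
    SBS2  = peak(sub == "C>T" & b5 == "T", 45),
    # broad C>A, mild 3' purine preference (tobacco-like)
    SBS4  = base(ifelse(sub == "C>A", ifelse(b3 %in% c("A", "G"), 14, 10), 1)),
    # near-flat clock-like background, mild C>T / T>C excess
    SBS5  = base(ifelse(sub %in% c("C>T", "T>C"), 1.6, 1)),
    # APOBEC-like C>G at TpC
    SBS13 = peak(sub == "C>G" & b5 == "T", 45),
    # C>T away from CpG
    SBS30 = base(ifelse(sub == "C>T" & b3 != "G", 9, 1)),
    # T>C with 5' A preference
    SBS92 = base(ifelse(sub == "T>C", ifelse(b5 == "A", 16, 8), 1)),
    # T>G with 3' T preference
    SBS96 = base(ifelse(sub == "T>G", ifelse(b3 == "T", 20, 8), 1))
  )
  rownames(sigs) <- ch
  structure(sigs, class = c("signature_matrix", "matrix"))
}

#' Write a signature matrix to TSV
#' @param sigs A `signature_matrix` (or plain 96 x K matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(sigs, path) {
  tab <- tibble::as_tibble(unclass(sigs))
  tab <- dplyr::bind_cols(tibble::tibble(channel = rownames(sigs)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
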