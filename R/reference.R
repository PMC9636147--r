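#' Load the mitochondrial reference genome
#'
#' Returns the 16,569-bp reference the package anchors all coordinates to,
#' together with its gene annotation. By default the packaged reference is
#' used: a synthetic stand-in sequence of exact rCRS dimensions carrying the
#' published rCRS gene coordinates (see `inst/extdata/synthetic_rcrs.fasta`).
#' Every downstream computation is coordinate-based, so a user can supply the
#' true rCRS FASTA instead and nothing else changes.
#'
#' The molecule is circular; alignment and coordinates treat it as linear
#' anchored at position 1, so the control region spans the origin (16024-16569
#' joined to 1-576).
#'
#' @param fasta path to a single-record FASTA with the 16,569-bp reference;
#'   `NULL` for the packaged sequence.
#' @param genes path to a gene annotation TSV (columns `gene`, `start`,
#'   `end`, `strand`, `type`); `NULL` for the packaged table.
#' @return An object of class `mt_reference` with elements `bases`
#'   (character vector of length 16,569), `genes` (data frame), `length`
#'   and `circular`.
#' @export
mt_reference <- function(fasta = NULL, genes = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "synthetic_rcrs.fasta",
                         package = "mtfounder", mustWork = TRUE)
  }
  if (is.null(genes)) {
    genes <- system.file("extdata", "rcrs_genes.tsv",
                         package = "mtfounder", mustWork = TRUE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record")
  }
  s <- toupper(as.character(seqs[[1]]))
  if (nchar(s) != 16569L) {
    stop(sprintf("reference length is %d, expected 16569", nchar(s)))
  }
  g <- utils::read.delim(genes, stringsAsFactors = FALSE,
                         comment.char = "#")
  stopifnot(all(c("gene", "start", "end", "strand", "type") %in% names(g)))
  coding <- g[g$type == "protein", , drop = FALSE]
  if (any(coding$start < 577L | coding$end > 16023L)) {
    stop("protein-coding annotation outside the coding region [577, 16023]")
  }
  structure(list(bases = strsplit(s, "")[[1]], genes = g,
                 length = 16569L, circular = TRUE),
            class = "mt_reference")
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %d bp, circular; %d annotated features (%d protein genes)\n",
              x$length, nrow(x$genes), sum(x$genes$type == "protein")))
  invisible(x)
}

#' Apply substitutions to the reference sequence
#'
#' Builds a full-length mitogenome string from the reference and a set of
#' substitution variants; positions in `missing` are written as `N`. Used by
#' the synthetic-panel generator and by tests as the inverse of
#' [call_variants()]. Indels are not supported here (the generator plants
#' substitutions only).
#'
#' @param reference an [mt_reference()].
#' @param variants data frame of variants ([parse_variant()] layout) or a
#'   character vector of variant strings.
#' @param missing integer positions to mask as `N`.
#' @return A single character string of length 16,569.
#' @export
mutate_sequence <- function(reference, variants = NULL, missing = integer()) {
  b <- reference$bases
  if (is.character(variants)) variants <- parse_variant(variants)
  if (!is.null(variants) && nrow(variants)) {
    v <- variants[variants$kind == "substitution", , drop = FALSE]
    if (nrow(v) < nrow(variants)) {
      stop("mutate_sequence handles substitutions only")
    }
    ok <- is.na(v$ref) | v$ref == b[v$pos]
    if (!all(ok)) {
      stop(sprintf("reference allele mismatch at position %d (have %s, variant says %s)",
                   v$pos[!ok][1], b[v$pos[!ok][1]], v$ref[!ok][1]))
    }
    if (any(v$alt == b[v$pos])) {
      stop("alternate allele equals the reference base")
    }
    b[v$pos] <- v$alt
  }
  if (length(missing)) b[missing] <- "N"
  paste(b, collapse = "")
}

# reference base at given positions
ref_base <- function(reference, pos) reference$bases[pos]

# attach reference alleles to pos+alt style variant tables (ref may be NA
# when variants come from tree files written without reference letters)
fill_ref <- function(variants, reference) {
  sub <- variants$kind == "substitution" & is.na(variants$ref)
  variants$ref[sub] <- reference$bases[variants$pos[sub]]
  variants
}
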