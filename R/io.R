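#' Read a mitogenome panel with metadata
#'
#' Loads a FASTA of full-length mitogenomes and a TSV of per-sample metadata
#' (columns `sample_id`, `population`, `region`). Sequences are
#' case-normalised to upper case; IUPAC ambiguity codes are preserved and
#' later treated as missing data by [call_variants()].
#'
#' @param path FASTA file, one record per individual.
#' @param metadata_path TSV with columns `sample_id`, `population`, `region`.
#' @return An object of class `mt_panel`: list with `sequences` (named
#'   character vector) and `meta` (data frame).
#' @section Errors: missing files raise `mtf_missing_file`; duplicate sample
#'   IDs raise `mtf_duplicate_ids`; FASTA records absent from the metadata
#'   (or metadata columns missing) raise `mtf_metadata_mismatch`. Each
#'   condition names the offending IDs.
#' @export
read_fasta_panel <- function(path, metadata_path) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) {
      stop(errorCondition(sprintf("file not found: %s", p),
                          class = c("mtf_missing_file", "error")))
    }
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(errorCondition(sprintf("duplicate sample IDs in FASTA: %s",
                                paste(dup, collapse = ", ")),
                        class = c("mtf_duplicate_ids", "error"),
                        offenders = dup))
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "region")
  if (!all(need %in% names(meta))) {
    stop(errorCondition(sprintf("metadata lacks column(s): %s",
                                paste(setdiff(need, names(meta)),
                                      collapse = ", ")),
                        class = c("mtf_metadata_mismatch", "error")))
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop(errorCondition(sprintf("duplicate sample IDs in metadata: %s",
                                paste(dup, collapse = ", ")),
                        class = c("mtf_duplicate_ids", "error"),
                        offenders = dup))
  }
  orphan <- setdiff(ids, meta$sample_id)
  if (length(orphan)) {
    stop(errorCondition(sprintf("FASTA record(s) missing from metadata: %s",
                                paste(orphan, collapse = ", ")),
                        class = c("mtf_metadata_mismatch", "error"),
                        offenders = orphan))
  }
  x <- toupper(as.character(seqs))
  names(x) <- ids
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(sequences = x, meta = meta), class = "mt_panel")
}

#' @export
print.mt_panel <- function(x, ...) {
  cat(sprintf("<mt_panel> %d sequences (%s)\n", length(x$sequences),
              paste(sprintf("%s: %d", names(table(x$meta$population)),
                            table(x$meta$population)), collapse = ", ")))
  invisible(x)
}

IUPAC_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Call variants against the reference
#'
#' Expresses a mitogenome as its differences from the reference in standard
#' mtDNA nomenclature. Sequences of exactly 16,569 columns are compared
#' position by position (gaps allowed, read as deletions); other lengths are
#' first globally aligned to the reference. Positions carrying IUPAC
#' ambiguity codes are recorded as missing data, never as variants.
#' Insertions are keyed to the preceding rCRS position with suffix numbering
#' (`315.1C`). The call is deterministic for fixed input.
#'
#' @param sequence a mitogenome as a single character string (or anything
#'   coercible via `as.character`).
#' @param reference an [mt_reference()].
#' @param sample_id,population,region metadata attached to the profile.
#' @param max_missing fraction of missing sites above which the profile is
#'   flagged `high_missing` (with a warning).
#' @return A [variant_profile()].
#' @export
call_variants <- function(sequence, reference, sample_id = "sample",
                          population = NA_character_, region = NA_character_,
                          max_missing = 0.05) {
  s <- toupper(as.character(sequence))
  L <- reference$length
  if (nchar(s) != L) {
    s <- align_to_reference(s, reference)
  }
  qry <- strsplit(s, "")[[1]]
  if (length(qry) != L) {
    stop(errorCondition(
      sprintf("sequence length %d incompatible with the %d-bp reference",
              length(qry), L),
      class = c("mtf_alignment_error", "error")))
  }
  ref <- reference$bases
  miss <- which(qry %in% IUPAC_AMBIG)
  del <- which(qry == "-")
  dif <- which(qry != ref & qry %in% c("A", "C", "G", "T"))
  v <- rbind(
    if (length(dif)) data.frame(pos = dif, ref = ref[dif], alt = qry[dif],
                                ins = 0L, back = FALSE,
                                kind = "substitution",
                                stringsAsFactors = FALSE),
    if (length(del)) data.frame(pos = del, ref = ref[del],
                                alt = "d", ins = 0L, back = FALSE,
                                kind = "deletion", stringsAsFactors = FALSE),
    attr(s, "insertions"))
  if (is.null(v)) v <- empty_variants()
  flags <- character()
  if (length(miss) > max_missing * L) {
    warning(sprintf("%s: %.1f%% missing sites", sample_id,
                    100 * length(miss) / L))
    flags <- "high_missing"
  }
  variant_profile(sample_id, v, missing = miss, population = population,
                  region = region, flags = flags)
}

# global alignment of an unaligned mitogenome onto reference coordinates;
# returns a 16,569-column string with "-" for deletions and an "insertions"
# attribute (variant rows keyed to the preceding reference position)
align_to_reference <- function(s, reference) {
  refstr <- paste(reference$bases, collapse = "")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(refstr),
    type = "global", gapOpening = 8, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  out <- character(reference$length)
  ins <- empty_variants()
  rpos <- 0L
  i <- 1L
  n <- length(su)
  k <- 0L # insertion suffix counter
  while (i <= n) {
    if (su[i] == "-") {
      k <- k + 1L
      if (rpos >= 1L && pa[i] %in% c("A", "C", "G", "T")) {
        ins <- rbind(ins, data.frame(pos = rpos, ref = NA_character_,
                                     alt = pa[i], ins = k, back = FALSE,
                                     kind = "insertion",
                                     stringsAsFactors = FALSE))
      }
    } else {
      rpos <- rpos + 1L
      k <- 0L
      out[rpos] <- pa[i]
    }
    i <- i + 1L
  }
  res <- paste(out, collapse = "")
  attr(res, "insertions") <- if (nrow(ins)) ins else NULL
  res
}

#' Call variants for a whole panel
#'
#' @param panel an `mt_panel` from [read_fasta_panel()] (or a compatible
#'   list with `sequences` and `meta`).
#' @param reference an [mt_reference()].
#' @return A named list of [variant_profile()] objects.
#' @export
call_variants_panel <- function(panel, reference) {
  meta <- panel$meta
  out <- lapply(seq_along(panel$sequences), function(i) {
    call_variants(panel$sequences[[i]], reference,
                  sample_id = meta$sample_id[i],
                  population = meta$population[i],
                  region = meta$region[i])
  })
  names(out) <- meta$sample_id
  out
}

#' Load a hotspot (hypervariable position) exclusion list
#'
#' One 1-based rCRS position per line; `#` comments and blank lines allowed;
#' duplicates collapsed. These positions are excluded from founder-lineage
#' definitions, haplogroup scoring and clade dating, mirroring the standard
#' practice of masking known mutational hotspots.
#'
#' @param path plain-text file, or `NULL` for the packaged default list.
#' @return Sorted integer vector of positions (class `mtf_hotspots`).
#' @export
load_hotspots <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hotspots.txt", package = "mtfounder",
                        mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(integer(), class = "mtf_hotspots"))
  pos <- suppressWarnings(as.integer(lines))
  if (anyNA(pos)) {
    stop(errorCondition("non-integer line in hotspot list",
                        class = c("mtf_hotspot_error", "error")))
  }
  if (any(pos < 1L | pos > 16569L)) {
    stop(errorCondition("hotspot position outside 1..16569",
                        class = c("mtf_hotspot_error", "error")))
  }
  structure(sort(unique(pos)), class = "mtf_hotspots")
}

#' @rdname load_hotspots
#' @export
default_hotspots <- function() load_hotspots(NULL)

#' Serialize / restore variant profiles as JSON
#'
#' @param profiles list of [variant_profile()] objects.
#' @param path output (input) JSON file.
#' @return `write_profiles_json` returns `path` invisibly;
#'   `read_profiles_json` returns the list of profiles.
#' @export
write_profiles_json <- function(profiles, path) {
  x <- lapply(profiles, function(p) {
    list(sample_id = p$sample_id,
         variants = format_variant(p$variants),
         missing = p$missing, population = p$population,
         region = p$region, flags = p$flags)
  })
  jsonlite::write_json(unname(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  out <- lapply(x, function(p) {
    v <- if (length(p$variants)) parse_variant(unlist(p$variants))
         else empty_variants()
    variant_profile(p$sample_id, v, missing = unlist(p$missing),
                    population = p$population %||% NA_character_,
                    region = p$region %||% NA_character_,
                    flags = unlist(p$flags) %||% character())
  })
  names(out) <- vapply(out, function(p) p$sample_id, "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
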