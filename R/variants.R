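#' Parse mtDNA variant strings
#'
#' Parses variants written in standard mtDNA nomenclature relative to the
#' rCRS: substitutions as `A2833G` (reference allele optional, `2833G` is
#' accepted), deletions as `8281d`, insertions as `315.1C` (position of the
#' preceding rCRS base, then the insertion index, then the inserted base).
#' A leading `@` marks a back mutation (a reversion to the ancestral state);
#' a bare `@16261` with no alleles is accepted as a reversion marker for use
#' in haplogroup-tree files.
#'
#' @param x character vector of variant strings.
#' @return A data frame with one row per variant and columns `pos`, `ref`,
#'   `alt`, `ins`, `back` and `kind` (`"substitution"`, `"deletion"`,
#'   `"insertion"` or `"back"`).
#' @examples
#' parse_variant(c("A2833G", "@16261", "315.1C", "8281d"))
#' @export
parse_variant <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec(
    "^(@?)([ACGT]?)([0-9]+)(?:\\.([0-9]+))?([ACGTd]?)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop(errorCondition(
      sprintf("malformed variant string(s): %s",
              paste(x[bad], collapse = ", ")),
      class = c("mtf_parse_error", "error"), offenders = x[bad]))
  }
  parts <- do.call(rbind, m)
  back <- parts[, 2] == "@"
  ref <- ifelse(parts[, 3] == "", NA_character_, parts[, 3])
  pos <- as.integer(parts[, 4])
  ins <- ifelse(parts[, 5] == "", 0L, as.integer(parts[, 5]))
  alt <- ifelse(parts[, 6] == "", NA_character_, parts[, 6])
  # a bare position is only meaningful as a reversion marker
  no_alt <- is.na(alt)
  if (any(no_alt & !back)) {
    stop(errorCondition(
      sprintf("variant without alleles must carry '@': %s",
              paste(x[no_alt & !back], collapse = ", ")),
      class = c("mtf_parse_error", "error")))
  }
  if (any(ins > 0L & (is.na(alt) | alt == "d"))) {
    stop(errorCondition("insertion must name the inserted base",
                        class = c("mtf_parse_error", "error")))
  }
  kind <- ifelse(no_alt, "back",
          ifelse(alt == "d", "deletion",
          ifelse(ins > 0L, "insertion", "substitution")))
  if (any(kind == "substitution" & !is.na(ref) & ref == alt)) {
    stop(errorCondition("reference and alternate allele are identical",
                        class = c("mtf_parse_error", "error")))
  }
  if (any(pos < 1L | pos > 16569L)) {
    stop(errorCondition("variant position outside 1..16569",
                        class = c("mtf_parse_error", "error")))
  }
  data.frame(pos = pos, ref = ref, alt = alt, ins = ins, back = back,
             kind = kind, stringsAsFactors = FALSE)
}

#' Format variants as nomenclature strings
#'
#' The inverse of [parse_variant()]: renders a variant table back into
#' canonical strings (`A2833G`, `8281d`, `315.1C`, with `@` prefixed to back
#' mutations). `parse_variant(format_variant(v))` is the identity.
#'
#' @param v a data frame as returned by [parse_variant()].
#' @return character vector of variant strings.
#' @export
format_variant <- function(v) {
  if (nrow(v) == 0L) return(character())
  paste0(ifelse(v$back, "@", ""),
         ifelse(is.na(v$ref), "", v$ref),
         v$pos,
         ifelse(v$ins > 0L, paste0(".", v$ins), ""),
         ifelse(is.na(v$alt), "", v$alt))
}

empty_variants <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             ins = integer(), back = logical(), kind = character(),
             stringsAsFactors = FALSE)
}

order_variants <- function(v) {
  v[order(v$pos, v$ins, v$alt, method = "radix"), , drop = FALSE]
}

#' Construct a variant profile
#'
#' A variant profile is an individual's mitogenome expressed as its set of
#' differences from the rCRS, plus bookkeeping for missing (ambiguous)
#' positions and population metadata. It is the currency passed between all
#' pipeline stages.
#'
#' @param sample_id sample identifier.
#' @param variants data frame in the layout of [parse_variant()].
#' @param missing integer vector of rCRS positions with ambiguous base calls.
#' @param population `"study"` or `"reference"`.
#' @param region free-text geographic label.
#' @param flags character vector of quality flags.
#' @return An object of class `variant_profile`.
#' @export
variant_profile <- function(sample_id, variants = empty_variants(),
                            missing = integer(), population = NA_character_,
                            region = NA_character_, flags = character()) {
  variants <- order_variants(variants)
  key <- paste(variants$pos, variants$ins, variants$kind)
  if (anyDuplicated(key)) {
    stop(errorCondition(
      sprintf("duplicate variant at position %s",
              variants$pos[duplicated(key)][1]),
      class = c("mtf_profile_error", "error")))
  }
  structure(list(sample_id = as.character(sample_id), variants = variants,
                 missing = sort(unique(as.integer(missing))),
                 population = population, region = region, flags = flags),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf("<variant_profile> %s (%s%s)\n", x$sample_id,
              x$population,
              if (!is.na(x$region) && nzchar(x$region))
                paste0("/", x$region) else ""))
  cat(sprintf("  %d variants, %d missing positions%s\n",
              nrow(x$variants), length(x$missing),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  if (nrow(x$variants)) {
    cat("  ", paste(format_variant(x$variants), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

# substitution identity keys "posALT", e.g. "2833G"; the comparison currency
# for classification, founder scanning, dating and distances
substitution_keys <- function(profile, hotspots = NULL) {
  v <- profile$variants
  v <- v[v$kind == "substitution", , drop = FALSE]
  if (length(hotspots)) v <- v[!(v$pos %in% hotspots), , drop = FALSE]
  paste0(v$pos, v$alt)
}

key_pos <- function(keys) as.integer(sub("[ACGT]$", "", keys))

# number of substitution differences between two profiles, ignoring hotspot
# positions and positions missing in either profile
profile_distance <- function(a, b, hotspots = NULL) {
  ka <- substitution_keys(a, hotspots)
  kb <- substitution_keys(b, hotspots)
  miss <- union(a$missing, b$missing)
  if (length(miss)) {
    ka <- ka[!(key_pos(ka) %in% miss)]
    kb <- kb[!(key_pos(kb) %in% miss)]
  }
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
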