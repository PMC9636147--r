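# vertebrate mitochondrial genetic code (translation table 2): standard
# code with AGA/AGG -> Stop, ATA -> Met, TGA -> Trp
MITO_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate coding consequences of a profile's substitutions
#'
#' Translates every substitution falling inside an annotated protein gene
#' with the vertebrate mitochondrial genetic code and reports the amino-acid
#' change; light-strand genes (ND6) are handled on the reverse complement.
#' Variants in RNA genes or the control region are reported as non-coding.
#' Positions inside overlapping genes (ATP8/ATP6, ND4L/ND4) yield one
#' consequence per reading frame.
#'
#' @param profile a [variant_profile()].
#' @param reference an [mt_reference()] (provides the gene annotation and
#'   the codon context).
#' @return Data frame with one row per (substitution, gene): `variant`,
#'   `pos`, `gene`, `codon_number`, `codon_position`, `ref_aa`, `alt_aa`,
#'   `is_synonymous`, `coding`.
#' @export
annotate_coding <- function(profile, reference) {
  v <- profile$variants
  v <- v[v$kind == "substitution", , drop = FALSE]
  genes <- reference$genes
  prot <- genes[genes$type == "protein", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    vs <- format_variant(v[i, , drop = FALSE])
    hits <- prot[prot$start <= p & prot$end >= p, , drop = FALSE]
    if (!nrow(hits)) {
      rows[[length(rows) + 1]] <- data.frame(
        variant = vs, pos = p, gene = NA_character_,
        codon_number = NA_integer_, codon_position = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        is_synonymous = NA, coding = FALSE, stringsAsFactors = FALSE)
      next
    }
    for (j in seq_len(nrow(hits))) {
      g <- hits[j, ]
      cons <- codon_consequence(p, v$alt[i], g, reference)
      rows[[length(rows) + 1]] <- data.frame(
        variant = vs, pos = p, gene = g$gene,
        codon_number = cons$codon_number,
        codon_position = cons$codon_position,
        ref_aa = cons$ref_aa, alt_aa = cons$alt_aa,
        is_synonymous = cons$ref_aa == cons$alt_aa, coding = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(variant = character(), pos = integer(),
                      gene = character(), codon_number = integer(),
                      codon_position = integer(), ref_aa = character(),
                      alt_aa = character(), is_synonymous = logical(),
                      coding = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

codon_consequence <- function(p, alt, gene, reference) {
  b <- reference$bases
  if (gene$strand == "+") {
    idx <- p - gene$start + 1L
    codon_number <- (idx - 1L) %/% 3L + 1L
    codon_position <- (idx - 1L) %% 3L + 1L
    cstart <- gene$start + (codon_number - 1L) * 3L
    codon <- b[cstart:(cstart + 2L)]
    alt_codon <- codon
    alt_codon[codon_position] <- alt
  } else {
    # light-strand gene: transcript is the reverse complement
    idx <- gene$end - p + 1L
    codon_number <- (idx - 1L) %/% 3L + 1L
    codon_position <- (idx - 1L) %% 3L + 1L
    cend <- gene$end - (codon_number - 1L) * 3L
    codon <- unname(COMPLEMENT[b[cend:(cend - 2L)]])
    alt_codon <- codon
    alt_codon[codon_position] <- unname(COMPLEMENT[alt])
  }
  # trailing incomplete codons (post-transcriptionally completed stops)
  # cannot be translated
  if (anyNA(codon) || length(codon) < 3L ||
      (gene$strand == "+" && cstart + 2L > gene$end) ||
      (gene$strand == "-" && cend - 2L < gene$start)) {
    return(list(codon_number = codon_number,
                codon_position = codon_position,
                ref_aa = NA_character_, alt_aa = NA_character_))
  }
  list(codon_number = codon_number, codon_position = codon_position,
       ref_aa = unname(MITO_CODE[paste(codon, collapse = "")]),
       alt_aa = unname(MITO_CODE[paste(alt_codon, collapse = "")]))
}

#' Read a pathogenicity score table
#'
#' TSV with columns `position`, `ref_aa`, `alt_aa`, `score`; scores must lie
#' in [0,1] and the (position, ref_aa, alt_aa) key must be unique. The
#' packaged `pathogenicity_synthetic.tsv` is a small synthetic fixture for
#' tests; real analyses supply the published per-substitution prediction
#' table.
#'
#' @param path TSV path, or `NULL` for the packaged synthetic table.
#' @return Data frame of scores.
#' @export
read_pathogenicity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathogenicity_synthetic.tsv",
                        package = "mtfounder", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "ref_aa", "alt_aa", "score") %in% names(df)))
  if (any(df$score < 0 | df$score > 1)) {
    stop("pathogenicity scores must lie in [0, 1]")
  }
  if (anyDuplicated(df[, c("position", "ref_aa", "alt_aa")])) {
    stop("duplicate (position, ref_aa, alt_aa) key in score table")
  }
  df
}

lookup_scores <- function(cons, table) {
  key <- paste(cons$pos, cons$ref_aa, cons$alt_aa)
  tkey <- paste(table$position, table$ref_aa, table$alt_aa)
  table$score[match(key, tkey)]
}

#' Compare predicted pathogenicity between founder and non-founder lineages
#'
#' Pools the pathogenicity scores of non-synonymous substitutions carried by
#' founder-lineage samples versus non-founder samples and compares the two
#' distributions with a two-sided Mann-Whitney U test (exact for small
#' samples without ties, normal approximation with tie correction
#' otherwise). Per-variant pooling counts each distinct variant once per
#' group (default); per-individual pooling keeps one score per carrier per
#' variant. The scope is either the lineage-defining variants only or all
#' variants carried by the group's samples (default).
#'
#' @param profiles named list of [variant_profile()]s.
#' @param membership membership data frame from
#'   [founder_fraction_summary()] (`sample_id`, `founder`,
#'   `ancestry_class`, `lineage`).
#' @param table score table from [read_pathogenicity_table()].
#' @param reference an [mt_reference()].
#' @param pooling `"per_variant"` or `"per_individual"`.
#' @param scope `"all"` or `"defining"` (lineage signatures only; requires
#'   `lineages`).
#' @param lineages the `founder_lineages` object (needed for
#'   `scope = "defining"`).
#' @return An object of class `load_comparison`: group score vectors, the U
#'   statistic, the two-sided p-value, the direction of effect, and a
#'   per-ancestry-class breakdown with Benjamini-Hochberg adjusted
#'   p-values.
#' @export
lineage_load_comparison <- function(profiles, membership, table,
                                    reference,
                                    pooling = c("per_variant",
                                                "per_individual"),
                                    scope = c("all", "defining"),
                                    lineages = NULL) {
  pooling <- match.arg(pooling)
  scope <- match.arg(scope)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  names(profiles) <- ids
  membership <- membership[membership$sample_id %in% ids, , drop = FALSE]
  groups <- split(membership$sample_id, membership$founder)
  nm <- c(`TRUE` = "founder", `FALSE` = "non_founder")
  names(groups) <- nm[names(groups)]
  for (g in c("founder", "non_founder")) {
    if (is.null(groups[[g]]) || !length(groups[[g]])) {
      stop(errorCondition(sprintf("empty group: %s", g),
                          class = c("mtf_load_error", "error")))
    }
  }
  collect <- function(samples) {
    scs <- lapply(samples, function(id) {
      cons <- annotate_coding(profiles[[id]], reference)
      cons <- cons[cons$coding & !is.na(cons$is_synonymous) &
                     !cons$is_synonymous, , drop = FALSE]
      if (scope == "defining" && !is.null(lineages)) {
        lin <- membership$lineage[membership$sample_id == id]
        sig <- character()
        for (l in lineages) if (l$label %in% lin) sig <- l$shared_variants
        key <- paste0(cons$pos, sub("^.*([ACGT])$", "\\1", cons$variant))
        cons <- cons[key %in% sig, , drop = FALSE]
      }
      cons$score <- lookup_scores(cons, table)
      cons[!is.na(cons$score), c("variant", "score"), drop = FALSE]
    })
    all <- do.call(rbind, scs)
    if (is.null(all) || !nrow(all)) return(numeric())
    if (pooling == "per_variant") {
      all <- all[!duplicated(all$variant), , drop = FALSE]
    }
    all$score
  }
  x <- collect(groups$founder)
  y <- collect(groups$non_founder)
  if (!length(x) || !length(y)) {
    stop(errorCondition("a group has no scored non-synonymous variant",
                        class = c("mtf_load_error", "error")))
  }
  main <- mann_whitney(x, y)
  # per-ancestry-class founder groups vs the non-founder pool
  classes <- sort(unique(stats::na.omit(membership$ancestry_class)))
  brk <- lapply(classes, function(cl) {
    s <- membership$sample_id[membership$founder &
                                membership$ancestry_class %in% cl]
    xs <- collect(s)
    if (!length(xs)) return(NULL)
    mw <- mann_whitney(xs, y)
    data.frame(class = cl, n_scores = length(xs), U = mw$U,
               p_value = mw$p_value, direction = mw$direction,
               stringsAsFactors = FALSE)
  })
  brk <- do.call(rbind, brk)
  if (!is.null(brk)) brk$p_adj_BH <- stats::p.adjust(brk$p_value, "BH")
  structure(list(founder_scores = x, non_founder_scores = y,
                 U = main$U, p_value = main$p_value,
                 direction = main$direction, method = main$method,
                 by_class = brk, pooling = pooling, scope = scope),
            class = "load_comparison")
}

# two-sided Mann-Whitney U; exact when both sides are small and tie-free
mann_whitney <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  dir <- if (mean(x) < mean(y)) "founder < non_founder"
         else if (mean(x) > mean(y)) "founder > non_founder" else "equal"
  list(U = unname(wt$statistic), p_value = wt$p.value, direction = dir,
       method = if (exact) "exact" else "normal_approximation")
}

#' @export
print.load_comparison <- function(x, ...) {
  cat(sprintf("<load_comparison> U=%g, two-sided p=%.4g (%s), %s\n",
              x$U, x$p_value, x$method, x$direction))
  cat(sprintf("  founder: n=%d mean=%.3f | non-founder: n=%d mean=%.3f\n",
              length(x$founder_scores), mean(x$founder_scores),
              length(x$non_founder_scores), mean(x$non_founder_scores)))
  if (!is.null(x$by_class)) print(x$by_class, row.names = FALSE)
  invisible(x)
}
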