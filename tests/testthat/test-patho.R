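test_that("the translation table is the vertebrate mitochondrial code", {
  bio <- Biostrings::getGeneticCode("SGC1")
  ours <- mtfounder:::MITO_CODE
  expect_setequal(names(ours), names(bio))
  expect_equal(unname(ours[names(bio)]), unname(bio),
               ignore_attr = TRUE)
})

test_that("all nine single-base changes of a codon translate correctly", {
  # first ND1 codon of the packaged reference, hand-translated
  cstart <- 3307L
  codon <- paste(REF$bases[cstart:(cstart + 2)], collapse = "")
  for (off in 0:2) {
    p <- cstart + off
    for (nb in setdiff(c("A", "C", "G", "T"), REF$bases[p])) {
      prof <- variant_profile("x", parse_variant(
        paste0(REF$bases[p], p, nb)))
      cons <- annotate_coding(prof, REF)
      expect_equal(nrow(cons), 1)
      alt_codon <- codon
      substr(alt_codon, off + 1, off + 1) <- nb
      expect_equal(cons$ref_aa, unname(mtfounder:::MITO_CODE[codon]))
      expect_equal(cons$alt_aa, unname(mtfounder:::MITO_CODE[alt_codon]))
      expect_equal(cons$is_synonymous, cons$ref_aa == cons$alt_aa)
      expect_equal(cons$codon_number, 1L)
      expect_equal(cons$codon_position, off + 1L)
    }
  }
})

test_that("overlapping genes yield one consequence per frame", {
  p <- 8530L # inside both ATP8 and ATP6
  nb <- setdiff(c("A", "C", "G", "T"), REF$bases[p])[1]
  cons <- annotate_coding(variant_profile("x", parse_variant(
    paste0(REF$bases[p], p, nb))), REF)
  expect_equal(sort(cons$gene), c("ATP6", "ATP8"))
  expect_true(all(cons$coding))
})

test_that("control-region and RNA-gene variants are non-coding", {
  cons <- annotate_coding(mkprof("x", c("100T", "800G", "16400A")), REF)
  expect_equal(cons$coding, c(FALSE, FALSE, FALSE))
  expect_true(all(is.na(cons$ref_aa)))
})

test_that("light-strand genes translate on the reverse complement", {
  # last codon position of the ND6 transcript maps to gene start
  p <- 14200L
  nb <- setdiff(c("A", "C", "G", "T"), REF$bases[p])[1]
  cons <- annotate_coding(variant_profile("x", parse_variant(
    paste0(REF$bases[p], p, nb))), REF)
  expect_equal(cons$gene, "ND6")
  idx <- 14673L - p + 1L
  expect_equal(cons$codon_number, (idx - 1L) %/% 3L + 1L)
  # the translated codon is the complement read 3' -> 5' on heavy strand
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cend <- 14673L - (cons$codon_number - 1L) * 3L
  codon <- paste(comp[REF$bases[cend:(cend - 2L)]], collapse = "")
  expect_equal(cons$ref_aa, unname(mtfounder:::MITO_CODE[codon]))
})

test_that("the packaged score table validates and rejects bad input", {
  tab <- read_pathogenicity_table()
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  expect_false(anyDuplicated(tab[, c("position", "ref_aa", "alt_aa")]) > 0)
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  utils::write.table(data.frame(position = 1, ref_aa = "A", alt_aa = "B",
                                score = 1.5), f, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_pathogenicity_table(f), "0, 1")
})

test_that("exact Mann-Whitney matches full enumeration for small groups", {
  mw <- mtfounder:::mann_whitney
  # the canonical toy: U = 0, exact two-sided p = 0.1
  r <- mw(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(r$direction, "founder < non_founder")
  expect_equal(mw_enum_p(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9)), 0.1)
  # random small tie-free samples agree with enumeration
  set.seed(66)
  for (rep in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- sample(seq(0.01, 0.99, 0.01), n1 + n2)
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    expect_equal(mw(x, y)$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("the U statistic is invariant under monotone score transforms", {
  set.seed(9)
  x <- runif(6)
  y <- runif(5)
  mw <- mtfounder:::mann_whitney
  expect_equal(mw(x, y)$U, mw(x^3, y^3)$U)
  expect_equal(mw(x, y)$U, mw(log(x), log(y))$U)
  expect_equal(mw(x, y)$p_value, mw(x^3, y^3)$p_value)
})

test_that("identical score multisets give p = 1", {
  mw <- mtfounder:::mann_whitney
  r <- mw(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_equal(r$p_value, 1)
})

# non-synonymous single-base change at a given ND1 position, found by
# scanning the packaged reference with the code table
find_missense <- function(from = 3310L, to = 4200L) {
  for (p in from:to) {
    off <- (p - 3307L) %% 3L
    cstart <- p - off
    codon <- paste(REF$bases[cstart:(cstart + 2)], collapse = "")
    for (nb in setdiff(c("A", "C", "G", "T"), REF$bases[p])) {
      alt <- codon
      substr(alt, off + 1, off + 1) <- nb
      a1 <- mtfounder:::MITO_CODE[[codon]]
      a2 <- mtfounder:::MITO_CODE[[alt]]
      if (a1 != a2 && a2 != "*" && a1 != "*") {
        return(list(key = paste0(p, nb), pos = p, ref_aa = a1,
                    alt_aa = a2))
      }
    }
  }
  stop("no missense found")
}

test_that("founder vs non-founder load comparison detects the direction", {
  m1 <- find_missense(3310L)
  m2 <- find_missense(m1$pos + 3L)
  m3 <- find_missense(m2$pos + 3L)
  m4 <- find_missense(m3$pos + 3L)
  profs <- list(mkprof("f1", c(m1$key, m2$key)),
                mkprof("f2", c(m1$key, m2$key)),
                mkprof("n1", m3$key), mkprof("n2", m4$key))
  membership <- data.frame(
    sample_id = c("f1", "f2", "n1", "n2"),
    lineage = c("L", "L", NA, NA),
    ancestry_class = c("West Eurasian", "West Eurasian", NA, NA),
    founder = c(TRUE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  tab <- data.frame(position = c(m1$pos, m2$pos, m3$pos, m4$pos),
                    ref_aa = c(m1$ref_aa, m2$ref_aa, m3$ref_aa, m4$ref_aa),
                    alt_aa = c(m1$alt_aa, m2$alt_aa, m3$alt_aa, m4$alt_aa),
                    score = c(0.1, 0.2, 0.8, 0.9),
                    stringsAsFactors = FALSE)
  res <- lineage_load_comparison(profs, membership, tab, REF)
  expect_equal(sort(res$founder_scores), c(0.1, 0.2))
  expect_equal(sort(res$non_founder_scores), c(0.8, 0.9))
  expect_equal(res$direction, "founder < non_founder")
  expect_equal(res$method, "exact")
  expect_equal(res$U, 0)
  expect_equal(res$by_class$class, "West Eurasian")
  expect_equal(res$by_class$p_adj_BH, res$by_class$p_value)
  # per-variant pooling counts each distinct variant once per group
  expect_length(res$founder_scores, 2)
  # empty group errors by name
  bad <- membership
  bad$founder <- TRUE
  expect_error(lineage_load_comparison(profs, bad, tab, REF),
               class = "mtf_load_error")
})

test_that("planted missense variants match the generator's bookkeeping", {
  cfg <- small_sim(19, study_n = 24L, reference_n = 20L, carriers = 10L,
                   age = 4000, admix = 0.4)
  pan <- simulate_panel(cfg, TREE, REF)
  profs <- call_variants_panel(pan, REF)
  man <- pan$manifest
  expect_gt(nrow(man$scores), 0)
  checked <- 0
  for (i in seq_len(nrow(man$scores))) {
    row <- man$scores[i, ]
    carrier <- NULL
    for (s in man$samples) {
      if (row$variant %in% s$variants) {
        carrier <- s$sample_id
        break
      }
    }
    if (is.null(carrier)) next
    cons <- annotate_coding(profs[[carrier]], REF)
    hit <- cons[cons$pos == row$position & cons$gene == row$gene, ]
    expect_equal(hit$ref_aa, row$ref_aa)
    expect_equal(hit$alt_aa, row$alt_aa)
    expect_false(hit$is_synonymous)
    checked <- checked + 1
    if (checked >= 5) break
  }
  expect_gt(checked, 0)
})
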