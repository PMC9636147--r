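toy_panel <- function() {
  # 8 J1c1 carriers sharing 5000T (founder-like), 6 of haplogroup H with
  # nothing shared, 2 U3b1 with a shared variant below the carrier threshold
  keys_j <- cumulative_profile(TREE, "J1c1")
  keys_h <- cumulative_profile(TREE, "H")
  keys_u <- cumulative_profile(TREE, "U3b1")
  profs <- c(
    lapply(1:8, function(i) mkprof(paste0("J", i),
                                   c(keys_j, "5000T",
                                     paste0(6000 + i, "A")))),
    lapply(1:6, function(i) mkprof(paste0("H", i),
                                   c(keys_h, paste0(7000 + i, "C")))),
    lapply(1:2, function(i) mkprof(paste0("U", i), c(keys_u, "9100T"))))
  names(profs) <- vapply(profs, `[[`, "", "sample_id")
  profs
}

test_that("panels without qualifying groups yield no founder lineages", {
  profs <- toy_panel()[9:16] # H + U only
  calls <- classify_panel(profs, TREE)
  res <- detect_founder_lineages(profs, calls,
                                 scan_config(min_carriers = 4,
                                             min_freq = 0.01), TREE)
  expect_length(res, 0)
})

test_that("a shared private variant defines a founder lineage", {
  profs <- toy_panel()
  calls <- classify_panel(profs, TREE)
  res <- detect_founder_lineages(profs, calls,
                                 scan_config(min_carriers = 4,
                                             min_freq = 0.01), TREE)
  expect_length(res, 1)
  l <- res[[1]]
  expect_equal(l$haplogroup, "J1c1")
  expect_equal(l$carrier_count, 8)
  expect_equal(l$shared_variants, "5000T")
  expect_equal(l$relative_frequency, 8 / 16)
  expect_equal(l$exclusivity, "exclusive")
  expect_equal(l$ancestry_class, "West Eurasian")
})

test_that("exclusivity is violated when the signature occurs outside", {
  profs <- toy_panel()
  calls <- classify_panel(profs, TREE)
  ref_prof <- mkprof("R1", c(cumulative_profile(TREE, "J1c1"), "5000T"),
                     pop = "reference")
  res <- detect_founder_lineages(
    profs, calls, scan_config(min_carriers = 4, min_freq = 0.01,
                              reference_panel = list(ref_prof)), TREE)
  expect_length(res, 1)
  expect_equal(res[[1]]$exclusivity, "violated")
  expect_equal(res[[1]]$nearest_outside_match$sample_id, "R1")
  expect_equal(res[[1]]$nearest_outside_match$overlap, 1L)
  # violated lineages do not count as founder membership
  fs <- founder_fraction_summary(res, profs)
  expect_equal(sum(fs$membership$founder), 0)
})

test_that("profiles without calls raise an error listing them", {
  profs <- toy_panel()
  calls <- classify_panel(profs[-1], TREE)
  err <- tryCatch(detect_founder_lineages(profs, calls, scan_config(),
                                          TREE),
                  error = identity)
  expect_s3_class(err, "mtf_scan_error")
  expect_match(conditionMessage(err), "J1")
})

test_that("raising min_carriers never adds lineages (monotonicity)", {
  profs <- toy_panel()
  calls <- classify_panel(profs, TREE)
  counts <- vapply(c(0, 2, 4, 7, 8), function(mc) {
    length(detect_founder_lineages(profs, calls,
                                   scan_config(min_carriers = mc,
                                               min_freq = 0.01), TREE))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the scan equals the enumeration oracle on random panels", {
  set.seed(1234)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    hgs <- sample(c("J1c1", "H", "U3b1", "M5a1"), n, replace = TRUE)
    profs <- lapply(seq_len(n), function(i) {
      extra <- rand_n_keys(c(5000, 5001, 6000, 7000), "T", 2)
      mkprof(sprintf("s%02d", i),
             unique(c(cumulative_profile(TREE, hgs[i]), extra)))
    })
    names(profs) <- vapply(profs, `[[`, "", "sample_id")
    calls <- classify_panel(profs, TREE)
    mc <- sample(1:4, 1)
    res <- detect_founder_lineages(profs, calls,
                                   scan_config(min_carriers = mc,
                                               min_freq = 0.02), TREE)
    oracle <- founder_oracle(profs, calls, TREE, HOT, mc, 0.02)
    got <- lapply(res, `[[`, "carriers")
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
    # every emitted lineage satisfies its invariants
    for (l in res) {
      expect_gt(l$carrier_count, mc)
      expect_true(all(vapply(l$carriers, function(id)
        all(l$shared_variants %in% prof_keys(profs[[id]])), TRUE)))
      expect_false(any(key_pos(l$shared_variants) %in% HOT))
    }
  }
})

test_that("planted founder clades are recovered exactly (100 panels)", {
  tp <- fp <- fn <- 0
  for (seed in 1:100) {
    cfg <- small_sim(seed, carriers = 6L, admix = 0.3, noise = 0)
    pan <- simulate_panel(cfg, TREE, REF)
    profs <- call_variants_panel(pan, REF)
    pops <- vapply(profs, `[[`, "", "population")
    study <- profs[pops == "study"]
    refp <- profs[pops == "reference"]
    calls <- classify_panel(study, TREE)
    res <- detect_founder_lineages(
      study, calls, scan_config(min_carriers = 4, min_freq = 4 / 144,
                                reference_panel = refp), TREE)
    res <- Filter(function(l) l$exclusivity == "exclusive", res)
    truth <- pan$manifest$lineages[[1]]
    hit <- Filter(function(l)
      setequal(l$carriers, truth$carriers) &&
        setequal(l$shared_variants, truth$signature), res)
    tp <- tp + length(hit)
    fp <- fp + length(res) - length(hit)
    fn <- fn + (length(hit) == 0)
  }
  expect_equal(tp / (tp + fp), 1) # precision
  expect_equal(tp / (tp + fn), 1) # recall
})

test_that("reference scans honour region mode and exclusions", {
  # symmetric: scanning the study panel as its own reference reproduces
  # the same lineage calls
  profs <- toy_panel()
  calls <- classify_panel(profs, TREE)
  whole <- scan_reference_population(profs, calls,
                                     scan_config(min_carriers = 4,
                                                 min_freq = 0.01), TREE)
  direct <- detect_founder_lineages(profs, calls,
                                    scan_config(min_carriers = 4,
                                                min_freq = 0.01), TREE)
  expect_equal(vapply(whole, `[[`, "", "label"),
               vapply(direct, `[[`, "", "label"))
  # a 3-carrier regional cluster passes in region mode (n > 2) but not in
  # whole-panel mode (n > 4)
  keys_k <- cumulative_profile(TREE, "K1a")
  regional <- c(
    lapply(1:3, function(i) mkprof(paste0("K", i), c(keys_k, "8800T"),
                                   pop = "reference", region = "west")),
    lapply(1:27, function(i)
      mkprof(paste0("Z", i),
             c(cumulative_profile(TREE, "H"), paste0(10000 + i, "A")),
             pop = "reference",
             region = if (i <= 13) "west" else "east")))
  names(regional) <- vapply(regional, `[[`, "", "sample_id")
  calls_r <- classify_panel(regional, TREE)
  cfg <- scan_config(min_carriers = 4, min_freq = 4 / 144)
  whole <- scan_reference_population(regional, calls_r, cfg, TREE)
  expect_length(whole, 0)
  byreg <- scan_reference_population(regional, calls_r, cfg, TREE,
                                     by_region = TRUE,
                                     region_min_carriers = 2)
  expect_length(byreg, 1)
  expect_equal(byreg[[1]]$carrier_count, 3)
  # demography-based exclusion drops matching haplogroups
  none <- scan_reference_population(regional, calls_r, cfg, TREE,
                                    by_region = TRUE,
                                    region_min_carriers = 2,
                                    exclude_haplogroups = "K")
  expect_length(none, 0)
})

test_that("founder fractions partition the panel and sum to one", {
  profs <- toy_panel()
  calls <- classify_panel(profs, TREE)
  res <- detect_founder_lineages(profs, calls,
                                 scan_config(min_carriers = 4,
                                             min_freq = 0.01), TREE)
  fs <- founder_fraction_summary(res, profs)
  expect_equal(sum(fs$fractions$fraction), 1)
  expect_equal(fs$fractions$count[fs$fractions$category == "non-founder"],
               8L)
  expect_equal(sum(fs$membership$founder), 8)
  # no lineages -> all non-founder
  fs0 <- founder_fraction_summary(structure(list(),
                                            class = "founder_lineages"),
                                  profs)
  expect_equal(fs0$fractions$fraction, 1)
  expect_equal(fs0$fractions$category, "non-founder")
})
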