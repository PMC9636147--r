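test_that("diversity indices match hand enumeration", {
  # all identical
  same <- lapply(1:3, function(i) mkprof(paste0("s", i), "100T"))
  d0 <- diversity_summary(same, L = 16569)
  expect_equal(d0$haplotype_diversity, 0)
  expect_equal(d0$nucleotide_diversity, 0)
  expect_equal(d0$segregating_sites, 0) # fixed in the panel
  expect_equal(d0$mean_pairwise_differences, 0)
  # 4 haplotypes {AA, AA, AT, TT} over 2 sites
  q <- list(mkprof("1"), mkprof("2"), mkprof("3", "9T"),
            mkprof("4", c("5T", "9T")))
  d <- diversity_summary(q, L = 2)
  expect_equal(d$k, 3)
  expect_equal(d$haplotype_diversity,
               4 / 3 * (1 - (1 / 2)^2 - (1 / 4)^2 - (1 / 4)^2))
  # pairs: 0,1,2,1,2,1 -> mean 7/6
  expect_equal(d$mean_pairwise_differences, 7 / 6)
  expect_equal(d$nucleotide_diversity, 7 / 12)
  # n < 2 flagged
  expect_true("n_too_small" %in% diversity_summary(q[1])$flags)
})

test_that("bottlenecked panels show lower haplotype diversity", {
  set.seed(303)
  h_study <- h_ref <- numeric(50)
  for (i in 1:50) {
    cfg <- small_sim(i, study_n = 20L, reference_n = 20L, carriers = 12L,
                     admix = 0.2)
    pan <- simulate_panel(cfg, TREE, REF)
    profs <- call_variants_panel(pan, REF)
    pops <- vapply(profs, `[[`, "", "population")
    h_study[i] <-
      diversity_summary(profs[pops == "study"])$haplotype_diversity
    h_ref[i] <-
      diversity_summary(profs[pops == "reference"])$haplotype_diversity
  }
  expect_lt(mean(h_study), mean(h_ref))
})

test_that("pairwise distances equal direct symmetric differences", {
  profs <- list(mkprof("a", c("10A", "20C")), mkprof("b", "20C"),
                mkprof("c", c("30T")))
  D <- pairwise_distances(profs)
  expect_equal(unname(D["a", "b"]), 1)
  expect_equal(unname(D["a", "c"]), 3)
  expect_equal(unname(D["b", "c"]), 2)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
})

test_that("two identical populations give a null AMOVA", {
  profs <- c(lapply(1:4, function(i) mkprof(paste0("a", i), "10A")),
             lapply(1:4, function(i) mkprof(paste0("b", i), "10A")))
  D <- pairwise_distances(profs)
  res <- amova(D, rep(c("p1", "p2"), each = 4), n_permutations = 99,
               seed = 3)
  expect_equal(res$phi[["phi_ST"]], 0)
  expect_equal(res$p_values[["phi_ST"]], 1)
})

test_that("AMOVA reproduces the hand-worked two-population toy", {
  # populations of 4, fixed 3-substitution difference, no within variation:
  # SS_total = (16 ordered cross pairs * 9) * 2 / (2 * 8) = 18,
  # SS_within = 0, df = (1, 6), n0 = 4 -> sigma_a = 4.5, 100% among
  profs <- c(lapply(1:4, function(i) mkprof(paste0("a", i))),
             lapply(1:4, function(i)
               mkprof(paste0("b", i), c("100T", "200C", "300G"))))
  D <- pairwise_distances(profs)
  res <- amova(D, rep(c("p1", "p2"), each = 4), n_permutations = 199,
               seed = 11)
  expect_equal(res$components$SS, c(18, 0))
  expect_equal(res$components$df, c(1, 6))
  expect_equal(res$components$variance, c(4.5, 0))
  expect_equal(res$components$percent, c(100, 0))
  expect_equal(sum(res$components$percent), 100)
  expect_equal(res$phi[["phi_ST"]], 1)
  # permutation p reproducible bit-exactly under the seed
  res2 <- amova(D, rep(c("p1", "p2"), each = 4), n_permutations = 199,
                seed = 11)
  expect_identical(res$p_values, res2$p_values)
})

test_that("AMOVA percent components always sum to 100", {
  set.seed(21)
  for (rep in 1:10) {
    profs <- lapply(1:12, function(i)
      mkprof(paste0("s", i),
             rand_n_keys(seq(100, 900, 100), "T", 4)))
    D <- pairwise_distances(profs)
    groups <- sample(rep(c("x", "y", "z"), each = 4))
    res <- amova(D, groups, n_permutations = 9, seed = rep)
    expect_equal(sum(res$components$percent), 100)
  }
})

test_that("nested AMOVA partitions three strata coherently", {
  set.seed(31)
  profs <- lapply(1:16, function(i)
    mkprof(paste0("s", i),
           rand_n_keys(seq(100, 900, 100), "T", 4)))
  D <- pairwise_distances(profs)
  groups <- rep(c("p1", "p2"), each = 8)
  regions <- rep(c("r1", "r2", "r3", "r4"), each = 4)
  res <- amova(D, groups, subgroups = regions, n_permutations = 19,
               seed = 5)
  expect_equal(nrow(res$components), 3)
  expect_equal(sum(res$components$percent), 100)
  expect_equal(sum(res$components$df), 15)
  expect_named(res$p_values, c("phi_CT", "phi_SC", "phi_ST"))
})

test_that("negative variance components are reported as-is", {
  # groups cutting across the real structure produce negative among-group
  # components; they must not be truncated to zero
  profs <- c(lapply(1:4, function(i) mkprof(paste0("a", i))),
             lapply(1:4, function(i)
               mkprof(paste0("b", i), c("100T", "200C"))))
  D <- pairwise_distances(profs)
  groups <- c("x", "y", "x", "y", "x", "y", "x", "y")
  res <- amova(D, groups, n_permutations = 9, seed = 2)
  expect_lt(res$components$variance[1], 0)
  expect_lt(res$components$percent[1], 0)
  expect_equal(sum(res$components$percent), 100)
})

test_that("pairwise Phi-ST equals the two-group AMOVA internally", {
  set.seed(17)
  profs <- lapply(1:15, function(i)
    mkprof(paste0("s", i),
           rand_n_keys(seq(100, 600, 100), "G", 3)))
  D <- pairwise_distances(profs)
  groups <- rep(c("x", "y", "z"), each = 5)
  pp <- pairwise_phist(D, groups, n_permutations = 49, seed = 9)
  expect_true(isSymmetric(pp$phi_st))
  expect_equal(diag(pp$phi_st), c(x = 0, y = 0, z = 0))
  idx <- which(groups %in% c("x", "z"))
  direct <- amova(D[idx, idx], groups[idx], n_permutations = 49,
                  seed = 9 + 1003L)
  expect_equal(pp$phi_st["x", "z"], direct$phi[["phi_ST"]])
  expect_equal(pp$p_values["x", "z"], direct$p_values[["phi_ST"]])
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(41)
  ps <- numeric(200)
  for (r in 1:200) {
    profs <- lapply(1:12, function(i)
      mkprof(paste0("s", i),
             rand_n_keys(seq(100, 900, 100), "A", 3)))
    D <- pairwise_distances(profs)
    res <- amova(D, sample(rep(c("x", "y"), each = 6)),
                 n_permutations = 99, seed = r)
    ps[r] <- res$p_values[["phi_ST"]]
  }
  # discrete permutation p-values: check calibration coarsely
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("chi-squared composition test matches hand computation", {
  # proportional rows -> statistic 0, p 1
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  r0 <- composition_chi2(prop)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # diagonal 2x2
  r1 <- suppressWarnings(composition_chi2(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(r1$statistic, 20)
  expect_equal(r1$df, 1)
  # zero margins dropped with warning
  m <- matrix(c(10, 5, 8, 0, 0, 0, 12, 3, 7), 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(r2 <- composition_chi2(m), "zero-margin")
  expect_equal(ncol(r2$observed), 2)
  # low expected counts warn
  expect_warning(composition_chi2(matrix(c(2, 3, 3, 2), 2)), "below 5")
})

test_that("chi-squared p-values are uniform under homogeneity", {
  set.seed(55)
  ps <- replicate(500, {
    tab <- matrix(stats::rmultinom(1, 200, rep(1 / 6, 6)), nrow = 2)
    composition_chi2(tab)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})
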