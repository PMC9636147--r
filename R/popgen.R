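#' Haplotype and nucleotide diversity
#'
#' Standard molecular-diversity summaries of a panel: number of distinct
#' haplotypes k, unbiased haplotype diversity
#' `H = n/(n-1) * (1 - sum(p_i^2))` over haplotype frequencies, number of
#' segregating substitution sites S, mean pairwise substitution differences,
#' and nucleotide diversity `pi` (mean pairwise differences per callable
#' site).
#'
#' @param profiles list of [variant_profile()]s.
#' @param L callable sites for the per-site scaling of `pi`.
#' @param hotspots positions excluded from the comparisons (`NULL` to keep
#'   everything).
#' @return An object of class `diversity_summary`.
#' @export
diversity_summary <- function(profiles, L = 16569L, hotspots = NULL) {
  n <- length(profiles)
  keys <- lapply(profiles, substitution_keys, hotspots = hotspots)
  hap <- vapply(keys, function(k) paste(sort(k), collapse = "|"), "")
  k <- length(unique(hap))
  p <- as.numeric(table(hap)) / n
  H <- if (n < 2) NA_real_ else n / (n - 1) * (1 - sum(p^2))
  # segregating sites: positions whose state varies within the panel (a
  # variant fixed in all members does not segregate)
  allk <- unlist(keys)
  S <- if (!length(allk)) 0L else {
    cnt <- table(allk)
    posn <- key_pos(names(cnt))
    sum(vapply(unique(posn), function(p) {
      ck <- cnt[posn == p]
      !(length(ck) == 1L && ck[[1]] == n)
    }, TRUE))
  }
  mpd <- if (n < 2) NA_real_ else {
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        tot <- tot + length(setdiff(keys[[i]], keys[[j]])) +
          length(setdiff(keys[[j]], keys[[i]]))
      }
    }
    tot / choose(n, 2)
  }
  structure(list(n = n, k = k, haplotype_diversity = H,
                 segregating_sites = S, mean_pairwise_differences = mpd,
                 nucleotide_diversity = if (is.na(mpd)) NA_real_ else
                   mpd / L,
                 flags = if (n < 2) "n_too_small" else character()),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("<diversity_summary> n=%d k=%d H=%s S=%d mpd=%s pi=%s\n",
              x$n, x$k, format(x$haplotype_diversity, digits = 4),
              x$segregating_sites,
              format(x$mean_pairwise_differences, digits = 4),
              format(x$nucleotide_diversity, digits = 4)))
  invisible(x)
}

#' Pairwise substitution-distance matrix
#'
#' Number of differing substitution sites between every pair of profiles,
#' the molecular distance underlying AMOVA and Phi-ST. Computed via a
#' binary incidence matrix over the union of observed variants, so panels
#' of ~1,000 mitogenomes stay fast.
#'
#' @param profiles list of [variant_profile()]s.
#' @param hotspots positions excluded (`NULL` keeps all, the default: the
#'   paper-style distance uses the full haplotype).
#' @return A symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames.
#' @export
pairwise_distances <- function(profiles, hotspots = NULL) {
  keys <- lapply(profiles, substitution_keys, hotspots = hotspots)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  sites <- unique(unlist(keys))
  if (!length(sites)) {
    D <- matrix(0, length(keys), length(keys),
                dimnames = list(ids, ids))
    return(D)
  }
  X <- do.call(rbind, lapply(keys, function(k)
    as.numeric(sites %in% k)))
  cnt <- rowSums(X)
  shared <- tcrossprod(X)
  D <- outer(cnt, cnt, "+") - 2 * shared
  dimnames(D) <- list(ids, ids)
  D
}

ss_within <- function(D2, groups) {
  tot <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      tot <- tot + sum(D2[idx, idx]) / (2 * length(idx))
    }
  }
  tot
}

#' Analysis of molecular variance (AMOVA)
#'
#' One-level (among groups / within groups) or nested two-level (among
#' groups / among subgroups within groups / within subgroups) partition of
#' squared molecular distances, with variance components from the expected
#' mean squares, Phi statistics, and permutation p-values
#' `p = (#{Phi_perm >= Phi_obs} + 1) / (n_perm + 1)` from random
#' reassignment of individuals. Variance components can be negative and are
#' reported as-is; percent variation sums to 100 across strata.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param groups group (population) label per sample.
#' @param subgroups optional region label per sample for the nested design.
#' @param n_permutations number of label permutations.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return An object of class `amova_result` with `components` (data frame:
#'   stratum, df, SS, variance, percent), `phi` (named vector),
#'   `p_values`, `n_permutations` and `seed`.
#' @export
amova <- function(D, groups, subgroups = NULL, n_permutations = 9999L,
                  seed) {
  if (missing(seed)) stop("amova requires an explicit seed")
  stopifnot(isSymmetric(unname(D)), all(diag(D) == 0))
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 1)) warning("group(s) of size 1 present")
  D2 <- D^2
  if (is.null(subgroups)) {
    res <- amova_one_level(D2, groups)
    phi_obs <- res$phi[["phi_ST"]]
    set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      perm <- sample(groups)
      phi_p <- amova_one_level(D2, perm)$phi[["phi_ST"]]
      if (phi_p >= phi_obs - 1e-12) exceed <- exceed + 1L
    }
    res$p_values <- c(phi_ST = (exceed + 1) / (n_permutations + 1))
  } else {
    subgroups <- as.character(subgroups)
    res <- amova_nested(D2, groups, subgroups)
    set.seed(seed)
    ex <- c(phi_CT = 0L, phi_SC = 0L, phi_ST = 0L)
    for (i in seq_len(n_permutations)) {
      # permute individuals freely for phi_ST/phi_CT, and within groups for
      # phi_SC (the within-group stratified scheme)
      perm_all <- sample(seq_along(groups))
      rn <- amova_nested(D2, groups[perm_all], subgroups[perm_all])
      perm_w <- stats::ave(seq_along(groups), groups,
                           FUN = function(ix) ix[sample.int(length(ix))])
      rw <- amova_nested(D2, groups, subgroups[perm_w])
      if (rn$phi[["phi_ST"]] >= res$phi[["phi_ST"]] - 1e-12)
        ex[["phi_ST"]] <- ex[["phi_ST"]] + 1L
      if (rn$phi[["phi_CT"]] >= res$phi[["phi_CT"]] - 1e-12)
        ex[["phi_CT"]] <- ex[["phi_CT"]] + 1L
      if (rw$phi[["phi_SC"]] >= res$phi[["phi_SC"]] - 1e-12)
        ex[["phi_SC"]] <- ex[["phi_SC"]] + 1L
    }
    res$p_values <- (ex + 1) / (n_permutations + 1)
  }
  res$n_permutations <- n_permutations
  res$seed <- seed
  class(res) <- "amova_result"
  res
}

amova_one_level <- function(D2, groups) {
  N <- nrow(D2)
  G <- length(unique(groups))
  ss_tot <- sum(D2) / (2 * N)
  ss_wit <- ss_within(D2, groups)
  ss_amg <- ss_tot - ss_wit
  df_amg <- G - 1
  df_wit <- N - G
  ms_amg <- ss_amg / df_amg
  ms_wit <- ss_wit / df_wit
  ng <- as.numeric(table(groups))
  n0 <- (N - sum(ng^2) / N) / df_amg
  s2_wit <- ms_wit
  s2_amg <- (ms_amg - ms_wit) / n0
  tot <- s2_amg + s2_wit
  # a panel with zero molecular variance has, by convention, no structure
  frac <- function(a, b) if (b == 0) 0 else a / b
  list(components = data.frame(
    stratum = c("among_groups", "within_groups"),
    df = c(df_amg, df_wit), SS = c(ss_amg, ss_wit),
    variance = c(s2_amg, s2_wit),
    percent = if (tot == 0) c(0, 100) else 100 * c(s2_amg, s2_wit) / tot,
    stringsAsFactors = FALSE),
    phi = c(phi_ST = frac(s2_amg, tot)))
}

amova_nested <- function(D2, groups, subgroups) {
  N <- nrow(D2)
  sub_id <- paste(groups, subgroups, sep = "\r")
  G <- length(unique(groups))
  S <- length(unique(sub_id))
  ss_tot <- sum(D2) / (2 * N)
  ss_ws <- ss_within(D2, sub_id)
  ss_wg <- ss_within(D2, groups)
  ss_as <- ss_wg - ss_ws     # among subgroups within groups
  ss_ag <- ss_tot - ss_wg    # among groups
  df_ag <- G - 1
  df_as <- S - G
  df_ws <- N - S
  ms_ag <- ss_ag / df_ag
  ms_as <- ss_as / df_as
  ms_ws <- ss_ws / df_ws
  ng <- tapply(rep(1, N), groups, sum)
  ns <- tapply(rep(1, N), sub_id, sum)
  grp_of_sub <- sub("\r.*$", "", names(ns))
  sum_ns2_over_ng <- sum(tapply(ns^2, grp_of_sub, sum) /
                           ng[names(tapply(ns^2, grp_of_sub, sum))])
  n1 <- (N - sum_ns2_over_ng) / df_as
  n2 <- (sum_ns2_over_ng - sum(ns^2) / N) / df_ag
  n3 <- (N - sum(ng^2) / N) / df_ag
  s2_c <- ms_ws
  s2_b <- (ms_as - s2_c) / n1
  s2_a <- (ms_ag - s2_c - n2 * s2_b) / n3
  tot <- s2_a + s2_b + s2_c
  frac <- function(a, b) if (b == 0) 0 else a / b
  list(components = data.frame(
    stratum = c("among_groups", "among_subgroups_within_groups",
                "within_subgroups"),
    df = c(df_ag, df_as, df_ws), SS = c(ss_ag, ss_as, ss_ws),
    variance = c(s2_a, s2_b, s2_c),
    percent = if (tot == 0) c(0, 0, 100) else
      100 * c(s2_a, s2_b, s2_c) / tot,
    stringsAsFactors = FALSE),
    phi = c(phi_CT = frac(s2_a, tot),
            phi_SC = frac(s2_b, s2_b + s2_c),
            phi_ST = frac(s2_a + s2_b, tot)))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$components, row.names = FALSE)
  cat("Phi: ", paste(sprintf("%s=%.4f", names(x$phi), x$phi),
                     collapse = "  "), "\n")
  cat("p:   ", paste(sprintf("%s=%.4g", names(x$p_values), x$p_values),
                     collapse = "  "),
      sprintf("  (%d permutations, seed %s)\n", x$n_permutations, x$seed))
  invisible(x)
}

#' Pairwise Phi-ST matrix
#'
#' Phi-ST for every pair of groups from two-group AMOVA on the
#' corresponding submatrix, with permutation p-values.
#'
#' @inheritParams amova
#' @return List with symmetric `phi_st` and `p_values` matrices.
#' @export
pairwise_phist <- function(D, groups, n_permutations = 9999L, seed) {
  if (missing(seed)) stop("pairwise_phist requires an explicit seed")
  gs <- sort(unique(as.character(groups)))
  k <- length(gs)
  phi <- matrix(0, k, k, dimnames = list(gs, gs))
  pv <- matrix(NA_real_, k, k, dimnames = list(gs, gs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      idx <- which(groups %in% c(gs[i], gs[j]))
      res <- amova(D[idx, idx, drop = FALSE], groups[idx],
                   n_permutations = n_permutations,
                   seed = seed + i * 1000L + j)
      phi[i, j] <- phi[j, i] <- res$phi[["phi_ST"]]
      pv[i, j] <- pv[j, i] <- res$p_values[["phi_ST"]]
    }
  }
  list(phi_st = phi, p_values = pv)
}

#' Pearson chi-squared test of composition homogeneity
#'
#' Tests whether the category composition (e.g. South Asian founder /
#' European founder / European non-founder lineages) is homogeneous across
#' groups. Zero-margin rows and columns are dropped with a warning; a
#' warning is also emitted when any expected count falls below 5.
#'
#' @param counts a groups x categories matrix or table of nonnegative
#'   integers.
#' @return List with `statistic`, `df`, `p_value`, `expected` and the
#'   (possibly reduced) `observed` table.
#' @export
composition_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("zero-margin row/column dropped")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least a 2x2 table after dropping zero margins")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("expected count(s) below 5; chi-squared approximation is weak")
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected, observed = counts)
}
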