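# shared test builders and independent oracles

# random posALT keys over fixed positions; empty selection stays empty
rand_keys <- function(positions, suffix, p = 0.5) {
  sel <- positions[as.logical(stats::rbinom(length(positions), 1, p))]
  if (!length(sel)) character(0) else paste0(sel, suffix)
}

# up to nmax keys drawn without replacement from positions
rand_n_keys <- function(positions, suffix, nmax) {
  k <- sample(0:nmax, 1)
  if (k == 0) character(0) else paste0(sample(positions, k), suffix)
}

# profile from posALT keys, e.g. mkprof("a", c("10A", "20C"))
mkprof <- function(id, keys = character(), pop = "study",
                   region = NA_character_, missing = integer()) {
  stopifnot(all(grepl("^[0-9]+[ACGT]$", keys)))
  v <- if (length(keys)) {
    data.frame(pos = as.integer(sub("[ACGT]$", "", keys)),
               ref = NA_character_, alt = sub("^[0-9]+", "", keys),
               ins = 0L, back = FALSE, kind = "substitution",
               stringsAsFactors = FALSE)
  } else {
    parse_variant(character(0))
  }
  variant_profile(id, v, missing = missing, population = pop,
                  region = region)
}

prof_keys <- function(p) {
  v <- p$variants[p$variants$kind == "substitution", ]
  sort(paste0(v$pos, v$alt))
}

# Prim MST total length over a distance matrix (independent oracle)
mst_length <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  total <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    total <- total + best[nxt]
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  total
}

hamming_matrix <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(X[i, ] != X[j, ])
  }
  D
}

# exhaustive Steiner-tree parsimony length: minimum over subsets (of size
# <= n_obs - 2) of candidate auxiliary binary vectors of the MST length on
# observed + auxiliary nodes
steiner_parsimony_length <- function(X, max_extra = nrow(X) - 2) {
  s <- ncol(X)
  all_vec <- as.matrix(expand.grid(rep(list(0:1), s)))
  obs_key <- apply(X, 1, paste, collapse = "")
  cand <- all_vec[!(apply(all_vec, 1, paste, collapse = "") %in% obs_key),
                  , drop = FALSE]
  n_obs <- nrow(X)
  full <- rbind(X, cand)
  Dall <- hamming_matrix(full)
  best <- mst_length(Dall[seq_len(n_obs), seq_len(n_obs), drop = FALSE])
  for (k in seq_len(max(0, max_extra))) {
    if (k > nrow(cand)) break
    idx <- utils::combn(nrow(cand), k)
    for (col in seq_len(ncol(idx))) {
      sel <- c(seq_len(n_obs), n_obs + idx[, col])
      len <- mst_length(Dall[sel, sel, drop = FALSE])
      if (len < best) best <- len
    }
  }
  best
}

# total length of a haplotype_network / parsimony spanning-tree length
network_length <- function(net) sum(net$edges$length)

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  idx <- utils::combn(length(vals), n1)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  us <- apply(idx, 2, function(ix) ustat(vals[ix], vals[-ix]))
  lo <- mean(us <= u_obs + 1e-12)
  hi <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# founder-scan oracle: derive maximal qualifying carrier sets directly from
# the definitions (per haplogroup, per shared variant), independent of the
# scan's internal bookkeeping
founder_oracle <- function(profiles, calls, tree, hotspots, min_carriers,
                           min_freq, panel_size = length(profiles)) {
  hg <- vapply(calls, `[[`, "", "haplogroup")
  ids <- vapply(profiles, `[[`, "", "sample_id")
  out <- list()
  for (g in unique(hg)) {
    members <- ids[hg == g]
    expected <- if (g %in% tree$nodes) tree$cumulative[[g]] else character()
    carrier_sets <- list()
    for (id in members) {
      p <- profiles[[match(id, ids)]]
      keys <- setdiff(substitution_keys(p, hotspots), expected)
      for (k in keys) {
        carrier_sets[[k]] <- sort(c(carrier_sets[[k]], id))
      }
    }
    sets <- unique(carrier_sets)
    ok <- Filter(function(s) length(s) > min_carriers &&
                   length(s) / panel_size >= min_freq, sets)
    ok <- ok[order(-vapply(ok, length, 1L),
                   vapply(ok, paste, "", collapse = ","))]
    kept <- list()
    for (s in ok) {
      if (!any(vapply(kept, function(kk) length(intersect(kk, s)) > 0,
                      TRUE))) {
        kept <- c(kept, list(s))
      }
    }
    out <- c(out, kept)
  }
  out
}

small_sim <- function(seed, study_n = 20L, reference_n = 20L,
                      carriers = 6L, age = 2000, hg = "U3b1",
                      noise = 0, admix = 0.3,
                      backbone = c("H", "H1", "H3", "J1c", "J2b", "T2",
                                   "K1a", "U3", "W", "X", "I"),
                      lambda = 3) {
  simulation_config(
    seed = seed, study_n = study_n, reference_n = reference_n,
    founders = data.frame(haplogroup = hg, carriers = as.integer(carriers),
                          age_years = age, signature_length = 2L,
                          stringsAsFactors = FALSE),
    hotspot_noise_rate = noise, admixture_fraction = admix,
    backbone_haplogroups = backbone, reference_private_lambda = lambda)
}

REF <- mt_reference()
TREE <- load_haplotree()
HOT <- default_hotspots()
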