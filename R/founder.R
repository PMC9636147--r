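#' Founder-scan configuration
#'
#' Parameters of the founder-lineage definition: a founder lineage is a
#' group of more than `min_carriers` same-haplogroup sequences that share at
#' least one non-hotspot mutation beyond the haplogroup's own cumulative
#' profile, reach a relative frequency of at least `min_freq` in the scanned
#' population, and whose full shared signature is absent from the reference
#' panel (exclusivity). The defaults encode the study design this package
#' reproduces: `min_carriers = 4` with a strict `>`, and
#' `min_freq = 4/144` (0.0278), the frequency of four carriers in a
#' 144-sample panel.
#'
#' @param min_carriers lineages must have strictly more carriers than this.
#' @param min_freq minimum relative frequency (carriers / panel size).
#' @param hotspots hypervariable positions excluded from signatures.
#' @param reference_panel list of [variant_profile()]s used for the
#'   exclusivity check (may be `NULL` to skip it).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(min_carriers = 4L, min_freq = 4 / 144,
                        hotspots = default_hotspots(),
                        reference_panel = NULL) {
  stopifnot(min_carriers >= 0, min_freq > 0, min_freq <= 1)
  structure(list(min_carriers = as.integer(min_carriers),
                 min_freq = min_freq, hotspots = hotspots,
                 reference_panel = reference_panel),
            class = "scan_config")
}

#' Detect founder lineages in a study panel
#'
#' For each called haplogroup, finds maximal carrier sets sharing at least
#' one non-hotspot substitution not explained by the haplogroup's cumulative
#' profile, applies the carrier-count and relative-frequency thresholds, and
#' checks exclusivity against the reference panel. A lineage whose full
#' shared signature also occurs in a reference profile is reported with
#' `exclusivity = "violated"` rather than silently dropped. Nested candidate
#' groups are collapsed to the maximal carrier set; the signature of a
#' lineage is the set of qualifying variants shared by *all* its carriers,
#' and per-variant carrier coverage is reported so partially shared variants
#' remain visible. Output order is deterministic: frequency descending, then
#' label.
#'
#' @param profiles named list of [variant_profile()]s (the scanned panel).
#' @param calls matching named list of `haplogroup_call`s.
#' @param config a [scan_config()].
#' @param tree the haplotree used for the calls (for cumulative profiles).
#' @param panel_size denominator for relative frequency; defaults to
#'   `length(profiles)`.
#' @return An object of class `founder_lineages`: a list of lineage records,
#'   each with `label`, `haplogroup`, `shared_variants`, `carriers`,
#'   `carrier_count`, `relative_frequency`, `exclusivity`,
#'   `nearest_outside_match`, `ancestry_class` and `variant_coverage`.
#' @export
detect_founder_lineages <- function(profiles, calls, config = scan_config(),
                                    tree = load_haplotree(),
                                    panel_size = length(profiles)) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  names(profiles) <- ids
  have <- vapply(calls, function(x) x$sample_id, "")
  missing <- setdiff(ids, have)
  if (length(missing)) {
    stop(errorCondition(sprintf("profiles without haplogroup calls: %s",
                                paste(missing, collapse = ", ")),
                        class = c("mtf_scan_error", "error"),
                        offenders = missing))
  }
  hg <- stats::setNames(vapply(calls, function(x) x$haplogroup, ""), have)
  hot <- config$hotspots
  lineages <- list()
  for (g in unique(hg[ids])) {
    members <- ids[hg[ids] == g]
    expected <- if (g %in% tree$nodes) tree$cumulative[[g]] else character()
    # qualifying variants per member: non-hotspot substitutions beyond the
    # haplogroup's cumulative profile
    qual <- lapply(members, function(id)
      setdiff(substitution_keys(profiles[[id]], hot), expected))
    names(qual) <- members
    allv <- unique(unlist(qual))
    if (!length(allv)) next
    carrier_sets <- lapply(allv, function(v)
      sort(members[vapply(qual, function(q) v %in% q, TRUE)]))
    names(carrier_sets) <- allv
    keysets <- unique(carrier_sets)
    sizes <- vapply(keysets, length, 1L)
    keep <- sizes > config$min_carriers &
      (sizes / panel_size) >= config$min_freq
    keysets <- keysets[keep]
    if (!length(keysets)) next
    # collapse nested carrier sets to the maximal ones; among overlapping
    # but non-nested sets keep the larger (deterministic resolution so each
    # sample belongs to at most one lineage per haplogroup)
    keysets <- keysets[order(-vapply(keysets, length, 1L),
                             vapply(keysets, paste, "", collapse = ","))]
    kept <- list()
    for (s in keysets) {
      overlap <- any(vapply(kept, function(k) length(intersect(k, s)) > 0,
                            TRUE))
      if (!overlap) kept <- c(kept, list(s))
    }
    for (s in kept) {
      shared <- allv[vapply(carrier_sets, function(cs) all(s %in% cs), TRUE)]
      shared <- sort(shared)
      coverage <- vapply(allv[vapply(carrier_sets, function(cs)
        length(intersect(cs, s)) > 0, TRUE)], function(v)
          length(intersect(carrier_sets[[v]], s)) / length(s), 0)
      excl <- check_exclusivity(shared, config$reference_panel, hot)
      label <- paste0(g, "+", paste(shared, collapse = "-"))
      lineages[[length(lineages) + 1]] <- structure(list(
        label = label, haplogroup = g, shared_variants = shared,
        carriers = s, carrier_count = length(s),
        relative_frequency = length(s) / panel_size,
        exclusivity = excl$verdict,
        nearest_outside_match = excl$nearest,
        ancestry_class = macrogroup_of(g),
        variant_coverage = coverage), class = "founder_lineage")
    }
  }
  ord <- order(-vapply(lineages, `[[`, 0, "relative_frequency"),
               vapply(lineages, `[[`, "", "label"))
  structure(lineages[ord], class = "founder_lineages",
            panel_size = panel_size)
}

check_exclusivity <- function(shared, reference_panel, hotspots) {
  if (is.null(reference_panel) || !length(reference_panel)) {
    return(list(verdict = "exclusive", nearest = NULL))
  }
  overlaps <- vapply(reference_panel, function(p)
    length(intersect(substitution_keys(p, hotspots), shared)), 1L)
  best <- which.max(overlaps)
  nearest <- list(sample_id = reference_panel[[best]]$sample_id,
                  overlap = overlaps[[best]])
  verdict <- if (max(overlaps) == length(shared)) "violated" else "exclusive"
  list(verdict = verdict, nearest = nearest)
}

#' @export
print.founder_lineages <- function(x, ...) {
  cat(sprintf("<founder_lineages> %d lineage(s) in a panel of %d\n",
              length(x), attr(x, "panel_size")))
  for (l in x) {
    cat(sprintf("  %-12s n=%-3d f=%.4f %-9s [%s] %s\n", l$haplogroup,
                l$carrier_count, l$relative_frequency, l$exclusivity,
                l$ancestry_class, paste(l$shared_variants, collapse = "-")))
  }
  invisible(x)
}

#' Scan a reference population for its own founder lineages
#'
#' Applies the founder definition to the host/reference population, with the
#' frequency threshold expressed on the study panel's scale
#' (`min_freq` from the study design, e.g. 4/144). In whole-panel mode the
#' carrier threshold is the study one; in region-subdivided mode each
#' geographic region is scanned separately with the alternative carrier
#' threshold (`region_min_carriers`, default `> 2`), the regional group
#' sizes being closer to the study panel's. Regions (or haplogroup prefixes)
#' with known distinct demography can be excluded.
#'
#' @param profiles named list of reference [variant_profile()]s.
#' @param calls matching `haplogroup_call`s.
#' @param config a [scan_config()]; its `min_freq` is the study-derived
#'   threshold, its `reference_panel` the exclusivity panel (typically the
#'   study profiles, so the roles are symmetric).
#' @param tree the haplotree.
#' @param by_region if `TRUE`, subdivide by each profile's `region`.
#' @param region_min_carriers carrier threshold in region mode (strict `>`).
#' @param exclude_regions regions dropped before scanning.
#' @param exclude_haplogroups haplogroup-name prefixes whose lineages are
#'   dropped from the result (e.g. a lineage characteristic of a population
#'   with known particular demographic history).
#' @return A `founder_lineages` object.
#' @export
scan_reference_population <- function(profiles, calls,
                                      config = scan_config(),
                                      tree = load_haplotree(),
                                      by_region = FALSE,
                                      region_min_carriers = 2L,
                                      exclude_regions = character(),
                                      exclude_haplogroups = character()) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  names(profiles) <- ids
  names(calls) <- vapply(calls, function(x) x$sample_id, "")
  if (!by_region) {
    res <- detect_founder_lineages(profiles, calls[ids], config, tree)
  } else {
    regions <- vapply(profiles, function(p)
      if (is.na(p$region)) "" else p$region, "")
    found <- list()
    for (r in setdiff(unique(regions), exclude_regions)) {
      sub <- ids[regions == r]
      if (!length(sub)) {
        warning(sprintf("region %s empty after exclusion; skipped", r))
        next
      }
      cfg <- config
      cfg$min_carriers <- as.integer(region_min_carriers)
      res_r <- detect_founder_lineages(profiles[sub], calls[sub], cfg, tree,
                                       panel_size = length(sub))
      found <- c(found, unclass(res_r))
    }
    res <- structure(found, class = "founder_lineages",
                     panel_size = length(profiles))
  }
  if (length(exclude_haplogroups) && length(res)) {
    drop <- vapply(res, function(l)
      any(startsWith(l$haplogroup, exclude_haplogroups)), TRUE)
    res <- structure(unclass(res)[!drop], class = "founder_lineages",
                     panel_size = attr(res, "panel_size"))
  }
  res
}

#' Summarise founder vs non-founder membership
#'
#' Partitions every sample of the panel into founder carriers (by detected
#' lineage and ancestry class) and non-founder lineages, and tabulates
#' counts and fractions. Fractions sum to 1 per population; each sample
#' belongs to at most one lineage by the maximal-carrier-set collapse.
#'
#' @param lineages a `founder_lineages` object.
#' @param profiles the scanned panel (named list of profiles).
#' @return A list with `membership` (data frame: sample_id, lineage label or
#'   NA, ancestry class) and `fractions` (data frame of per-class carrier
#'   counts and fractions).
#' @export
founder_fraction_summary <- function(lineages, profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  lineage_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  class_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (l in lineages) {
    if (l$exclusivity != "exclusive") next
    lineage_of[l$carriers] <- l$label
    class_of[l$carriers] <- l$ancestry_class
  }
  membership <- data.frame(sample_id = ids,
                           lineage = unname(lineage_of[ids]),
                           ancestry_class = unname(class_of[ids]),
                           founder = !is.na(lineage_of[ids]),
                           stringsAsFactors = FALSE)
  n <- length(ids)
  lv <- sort(unique(stats::na.omit(membership$ancestry_class)))
  founder_rows <- if (length(lv)) {
    cls <- table(factor(membership$ancestry_class, levels = lv))
    data.frame(category = paste0("founder (", names(cls), ")"),
               count = as.integer(cls),
               fraction = as.integer(cls) / n, stringsAsFactors = FALSE)
  } else NULL
  fractions <- rbind(
    founder_rows,
    data.frame(category = "non-founder", count = sum(!membership$founder),
               fraction = sum(!membership$founder) / n,
               stringsAsFactors = FALSE))
  list(membership = membership, fractions = fractions)
}

#' Write founder lineages as TSV
#'
#' @param lineages a `founder_lineages` object.
#' @param path output TSV.
#' @export
write_lineages_tsv <- function(lineages, path) {
  df <- data.frame(
    label = vapply(lineages, `[[`, "", "label"),
    haplogroup = vapply(lineages, `[[`, "", "haplogroup"),
    signature = vapply(lineages, function(l)
      paste(l$shared_variants, collapse = " "), ""),
    carriers = vapply(lineages, function(l)
      paste(l$carriers, collapse = ","), ""),
    carrier_count = vapply(lineages, `[[`, 0L, "carrier_count"),
    relative_frequency = vapply(lineages, `[[`, 0, "relative_frequency"),
    exclusivity = vapply(lineages, `[[`, "", "exclusivity"),
    ancestry_class = vapply(lineages, `[[`, "", "ancestry_class"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
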