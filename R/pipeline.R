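#' Build a validated pipeline run configuration
#'
#' Collects every input path and stage parameter of the full workflow
#' (variants -> classify -> scan -> date -> network -> stats -> load ->
#' report). Either `fasta`+`metadata` point to an on-disk panel, or
#' `panel` is an in-memory panel (e.g. from [simulate_panel()]). A
#' serialized copy of the config is written into the output directory at
#' run time.
#'
#' @param fasta,metadata panel FASTA and metadata TSV (or `NULL` when
#'   `panel` is given).
#' @param panel optional in-memory `mt_panel`.
#' @param tree_path haplotree TSV (`NULL` = packaged mini-tree).
#' @param hotspots_path hotspot list (`NULL` = packaged list).
#' @param scores_path pathogenicity TSV (`NULL` = packaged synthetic table;
#'   `NA` to use the manifest scores of a simulated panel if present).
#' @param min_carriers,min_freq founder-scan thresholds ([scan_config()]).
#' @param mu,L,correction clock parameters ([rho_to_years()]).
#' @param n_permutations,seed AMOVA permutations and global seed.
#' @param outdir output directory.
#' @param networks build per-lineage networks (set `FALSE` to skip).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, metadata = NULL, panel = NULL,
                       tree_path = NULL, hotspots_path = NULL,
                       scores_path = NULL,
                       min_carriers = 4L, min_freq = 4 / 144,
                       mu = 2.355e-8, L = NULL, correction = "none",
                       n_permutations = 999L, seed = 1L,
                       outdir = tempfile("mtfounder_run_"),
                       networks = TRUE) {
  if (is.null(panel) && (is.null(fasta) || is.null(metadata))) {
    stop("either panel or fasta+metadata must be supplied")
  }
  structure(list(fasta = fasta, metadata = metadata, panel = panel,
                 tree_path = tree_path, hotspots_path = hotspots_path,
                 scores_path = scores_path,
                 min_carriers = as.integer(min_carriers),
                 min_freq = min_freq, mu = mu, L = L,
                 correction = correction,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), outdir = outdir,
                 networks = isTRUE(networks)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                conditionMessage(e)),
                        class = c("mtf_stage_error", "error"),
                        stage = name))
  })
}

#' Run the full founder-lineage workflow
#'
#' Executes all stages in dependency order, writes per-stage artifacts into
#' the output directory (`profiles.json`, `calls.tsv`, `founders.tsv`,
#' `ages.tsv`, `networks/`, `stats.tsv`, `load.tsv`, `report.json`,
#' `config.yml`), and returns the machine-readable study report. The
#' between-population AMOVA is run twice: on the full panel and after
#' removing all carriers of detected founder lineages, quantifying how much
#' of the between-population variance the founder lineages explain.
#' Network-rendering failures degrade to warnings; everything else aborts
#' with the failing stage named. A fixed seed yields an identical report.
#'
#' @param config a [run_config()].
#' @param reference an [mt_reference()].
#' @return An object of class `study_report` (also written as JSON).
#' @export
run_pipeline <- function(config, reference = mt_reference()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(
    min_carriers = config$min_carriers, min_freq = config$min_freq,
    mu = config$mu, correction = config$correction,
    n_permutations = config$n_permutations, seed = config$seed,
    fasta = config$fasta, metadata = config$metadata),
    file.path(config$outdir, "config.yml"))
  hot <- if (is.null(config$hotspots_path)) default_hotspots()
         else load_hotspots(config$hotspots_path)
  L <- if (is.null(config$L)) 16569L - length(hot) else config$L
  tree <- stage("tree", load_haplotree(config$tree_path))

  panel <- stage("input", {
    if (!is.null(config$panel)) config$panel
    else read_fasta_panel(config$fasta, config$metadata)
  })
  digest_inputs <- c(
    fasta = if (!is.null(config$fasta)) unname(tools::md5sum(config$fasta))
            else NA_character_,
    metadata = if (!is.null(config$metadata))
      unname(tools::md5sum(config$metadata)) else NA_character_)

  profiles <- stage("variants", call_variants_panel(panel, reference))
  write_profiles_json(profiles, file.path(config$outdir, "profiles.json"))
  pops <- vapply(profiles, `[[`, "", "population")
  study <- profiles[pops == "study"]
  refpanel <- profiles[pops == "reference"]

  calls <- stage("classify", classify_panel(profiles, tree, hot))
  write_calls_tsv(calls, file.path(config$outdir, "calls.tsv"))

  cfg <- scan_config(config$min_carriers, config$min_freq, hot,
                     reference_panel = refpanel)
  lineages <- stage("scan", detect_founder_lineages(
    study, calls[names(study)], cfg, tree))
  write_lineages_tsv(lineages, file.path(config$outdir, "founders.tsv"))
  fsum <- founder_fraction_summary(lineages, study)

  ages <- stage("date", if (length(lineages)) {
    date_founder_lineages(lineages, study, mu = config$mu, L = L,
                          correction = config$correction,
                          exclusions = hot)
  } else NULL)
  if (!is.null(ages)) {
    utils::write.table(ages, file.path(config$outdir, "ages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (config$networks && length(lineages)) {
    netdir <- file.path(config$outdir, "networks")
    dir.create(netdir, showWarnings = FALSE)
    for (l in lineages) {
      tryCatch({
        clade <- study[l$carriers]
        net <- build_mj_network(clade, hotspots = hot)
        render_network(net, gml_path = file.path(
          netdir, paste0(l$haplogroup, ".gml")))
        root <- infer_root_profile(clade, hotspots = hot)
        ptree <- extract_parsimony_tree(net, root)
        writeLines(tree_newick(ptree),
                   file.path(netdir, paste0(l$haplogroup, ".nwk")))
      }, error = function(e) {
        warning(sprintf("network stage skipped for %s: %s", l$label,
                        conditionMessage(e)))
      })
    }
  }

  stats_res <- stage("stats", {
    div <- list(study = diversity_summary(study, L = L),
                reference = if (length(refpanel))
                  diversity_summary(refpanel, L = L) else NULL)
    regions <- vapply(study, function(p)
      if (is.na(p$region)) "" else p$region, "")
    div_by_region <- lapply(split(study, regions), diversity_summary,
                            L = L)
    D <- pairwise_distances(profiles)
    ids <- rownames(D)
    am <- if (length(refpanel)) {
      amova(D, pops[ids], n_permutations = config$n_permutations,
            seed = config$seed)
    } else NULL
    founder_ids <- fsum$membership$sample_id[fsum$membership$founder]
    keep <- setdiff(ids, founder_ids)
    am2 <- if (length(refpanel) &&
               length(unique(pops[keep])) > 1) {
      amova(D[keep, keep, drop = FALSE], pops[keep],
            n_permutations = config$n_permutations,
            seed = config$seed)
    } else NULL
    am_regions <- if (length(unique(regions[nzchar(regions)])) > 1) {
      sd_ids <- names(study)
      amova(D[sd_ids, sd_ids, drop = FALSE], regions,
            n_permutations = config$n_permutations,
            seed = config$seed + 1L)
    } else NULL
    # regional composition: SA founder / WE founder / non-founder
    cls <- ifelse(!fsum$membership$founder, "non-founder",
                  fsum$membership$ancestry_class)
    comp <- table(regions, cls)
    chi <- if (nrow(comp) > 1 && ncol(comp) > 1) {
      tryCatch(suppressWarnings(composition_chi2(comp)),
               error = function(e) NULL)
    } else NULL
    list(diversity = div, diversity_by_region = div_by_region,
         amova = am, amova_no_founders = am2,
         amova_regions = am_regions, composition = comp, chi2 = chi)
  })

  load_res <- stage("load", {
    table <- if (is.null(config$scores_path)) {
      if (!is.null(panel$manifest) &&
          nrow(panel$manifest$scores)) {
        panel$manifest$scores[, c("position", "ref_aa", "alt_aa", "score")]
      } else read_pathogenicity_table(NULL)
    } else read_pathogenicity_table(config$scores_path)
    tryCatch(lineage_load_comparison(study, fsum$membership, table,
                                     reference),
             mtf_load_error = function(e) NULL)
  })

  report <- structure(list(
    diversity = list(
      study = unclass(stats_res$diversity$study),
      reference = if (!is.null(stats_res$diversity$reference))
        unclass(stats_res$diversity$reference) else NULL,
      by_region = lapply(stats_res$diversity_by_region, unclass)),
    haplogroup_composition = as.list(table(vapply(
      calls[names(study)], `[[`, "", "haplogroup"))),
    founder_lineages = lapply(lineages, function(l)
      l[c("label", "haplogroup", "shared_variants", "carrier_count",
          "relative_frequency", "exclusivity", "ancestry_class")]),
    founder_fractions = fsum$fractions,
    ages = ages,
    amova = amova_report(stats_res$amova),
    amova_no_founders = amova_report(stats_res$amova_no_founders),
    amova_regions = amova_report(stats_res$amova_regions),
    composition_chi2 = if (!is.null(stats_res$chi2))
      stats_res$chi2[c("statistic", "df", "p_value")] else NULL,
    pathogenicity = if (!is.null(load_res)) list(
      U = load_res$U, p_value = load_res$p_value,
      direction = load_res$direction,
      founder_mean = mean(load_res$founder_scores),
      non_founder_mean = mean(load_res$non_founder_scores)) else NULL,
    provenance = list(package_version =
                        as.character(utils::packageVersion("mtfounder")),
                      seed = config$seed,
                      n_permutations = config$n_permutations,
                      input_digests = as.list(digest_inputs))),
    class = "study_report")
  jsonlite::write_json(unclass(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.table(fsum$fractions,
                     file.path(config$outdir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report
}

amova_report <- function(x) {
  if (is.null(x)) return(NULL)
  list(components = x$components, phi = as.list(x$phi),
       p_values = as.list(x$p_values))
}

#' Validate a study report against the shipped schema
#'
#' Checks that every field the packaged `report_schema.json` requires is
#' present (and non-null where the run produced the corresponding stage).
#'
#' @param report a `study_report` (or the parsed JSON thereof).
#' @return `TRUE` invisibly; errors describe missing fields.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report_schema.json",
                                            package = "mtfounder",
                                            mustWork = TRUE),
                                simplifyVector = TRUE)
  miss <- setdiff(schema$required, names(report))
  if (length(miss)) {
    stop(sprintf("report lacks required field(s): %s",
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Render a human-readable report summary
#'
#' Writes a markdown summary and a founder/non-founder proportion chart
#' (per population); the chart fractions equal the report fractions
#' exactly.
#'
#' @param report a `study_report`.
#' @param path output markdown file.
#' @param figure_path output PNG (`NULL` to skip).
#' @return Invisibly, the markdown path.
#' @export
report_render <- function(report, path, figure_path = NULL) {
  f <- report$founder_fractions
  lines <- c(
    "# Founder-lineage study report", "",
    sprintf("- Study panel: n = %d, %d haplotypes, haplotype diversity %s",
            report$diversity$study$n, report$diversity$study$k,
            format(report$diversity$study$haplotype_diversity,
                   digits = 4)),
    sprintf("- Detected founder lineages: %d",
            length(report$founder_lineages)), "",
    "## Founder / non-founder partition", "",
    sprintf("- %s: %d (%.1f%%)", f$category, f$count, 100 * f$fraction),
    "")
  if (!is.null(report$amova)) {
    lines <- c(lines, "## AMOVA (study vs reference)", "",
               sprintf("- Among-population variation: %.2f%% (p = %.4g)",
                       report$amova$components$percent[1],
                       report$amova$p_values$phi_ST))
    if (!is.null(report$amova_no_founders)) {
      lines <- c(lines,
                 sprintf("- After removing founder carriers: %.2f%% (p = %.4g)",
                         report$amova_no_founders$components$percent[1],
                         report$amova_no_founders$p_values$phi_ST))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$pathogenicity)) {
    lines <- c(lines, "## Pathogenicity load", "",
               sprintf("- Mann-Whitney U = %g, p = %.4g (%s)",
                       report$pathogenicity$U, report$pathogenicity$p_value,
                       report$pathogenicity$direction), "")
  }
  writeLines(lines, path)
  if (!is.null(figure_path)) {
    grDevices::png(figure_path, width = 700, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::barplot(f$fraction, names.arg = f$category, las = 2,
                      ylab = "fraction of panel",
                      main = "Founder vs non-founder lineages")
  }
  invisible(path)
}
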