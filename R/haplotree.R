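#' Load a phylotree-style haplogroup tree
#'
#' Reads a TSV with columns `node`, `parent` and `variants` (space-separated
#' defining variants in mtDNA nomenclature; `@`-prefixed entries are back
#' mutations that remove the position from the cumulative profile). Exactly
#' one node must have an empty parent: the root, whose defining set must be
#' empty — it represents the reference lineage itself, since all variants
#' are expressed relative to the rCRS.
#'
#' The package ships a ~58-node mini-tree fixture
#' (`inst/extdata/minitree.tsv`) covering the M5, U3, J1, J2, K and H
#' branches relevant to founder scans of a bottlenecked West-Eurasian/South-
#' Asian panel; a full phylotree export in the same format can be supplied
#' instead.
#'
#' @param path tree TSV, or `NULL` for the packaged mini-tree.
#' @return An object of class `haplotree`: data frame of nodes plus
#'   cumulative expected substitution profiles per node.
#' @export
load_haplotree <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "minitree.tsv", package = "mtfounder",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = NULL)
  stopifnot(all(c("node", "parent", "variants") %in% names(df)))
  df$parent[is.na(df$parent)] <- ""
  df$variants[is.na(df$variants)] <- ""
  if (anyDuplicated(df$node)) {
    stop(errorCondition(sprintf("duplicate node name: %s",
                                df$node[duplicated(df$node)][1]),
                        class = c("mtf_tree_error", "error")))
  }
  root <- df$node[df$parent == ""]
  if (length(root) != 1L) {
    stop(errorCondition("tree must have exactly one root (empty parent)",
                        class = c("mtf_tree_error", "error")))
  }
  if (nzchar(trimws(df$variants[df$node == root]))) {
    stop(errorCondition("root node must have an empty defining set",
                        class = c("mtf_tree_error", "error")))
  }
  orphan <- setdiff(df$parent[df$parent != ""], df$node)
  if (length(orphan)) {
    stop(errorCondition(sprintf("orphan parent reference(s): %s",
                                paste(orphan, collapse = ", ")),
                        class = c("mtf_tree_error", "error")))
  }
  defining <- lapply(df$variants, function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(empty_variants())
    parse_variant(strsplit(s, "[[:space:]]+")[[1]])
  })
  names(defining) <- df$node
  # depth + cycle check by walking to the root
  depth <- integer(nrow(df))
  names(depth) <- df$node
  parent <- stats::setNames(df$parent, df$node)
  for (n in df$node) {
    seen <- character()
    cur <- n
    d <- 0L
    while (parent[[cur]] != "") {
      if (cur %in% seen) {
        stop(errorCondition(sprintf("cycle through node %s", cur),
                            class = c("mtf_tree_error", "error")))
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      d <- d + 1L
      if (d > nrow(df)) {
        stop(errorCondition("cycle in tree", class = c("mtf_tree_error",
                                                       "error")))
      }
    }
    depth[n] <- d
  }
  # cumulative profiles: parent's profile updated by the node's defining
  # variants; back mutations remove the position
  cum <- vector("list", nrow(df))
  names(cum) <- df$node
  for (n in df$node[order(depth)]) {
    base <- if (parent[[n]] == "") character() else cum[[parent[[n]]]]
    dv <- defining[[n]]
    for (i in seq_len(nrow(dv))) {
      if (dv$back[i]) {
        base <- base[key_pos(base) != dv$pos[i]]
      } else if (dv$kind[i] == "substitution") {
        base <- base[key_pos(base) != dv$pos[i]]
        base <- c(base, paste0(dv$pos[i], dv$alt[i]))
      } # indel defining variants are ignored in the substitution profile
    }
    cum[[n]] <- sort(base)
  }
  structure(list(nodes = df$node, parent = parent, depth = depth,
                 defining = defining, cumulative = cum, root = root,
                 source = path),
            class = "haplotree")
}

#' @export
print.haplotree <- function(x, ...) {
  cat(sprintf("<haplotree> %d nodes, root %s, max depth %d\n",
              length(x$nodes), x$root, max(x$depth)))
  invisible(x)
}

#' Cumulative expected profile of a haplogroup node
#'
#' @param tree a [load_haplotree()] tree.
#' @param node node name.
#' @return Character vector of expected substitutions as `posALT` keys.
#' @export
cumulative_profile <- function(tree, node) {
  if (!node %in% tree$nodes) stop(sprintf("unknown node: %s", node))
  tree$cumulative[[node]]
}

#' Assign a haplogroup by set-overlap scoring
#'
#' Scores every tree node against the profile with the Kulczynski measure
#' `0.5 * (|found & expected| / |expected| + |found & expected| / |found|)`
#' and returns the best node. Hotspot positions are excluded from both sets,
#' as are expected variants at positions missing in the profile. Empty-set
#' conventions: a ratio with empty denominator counts as 1, so the empty
#' profile scores 1 on the reference (root) lineage. Ties are broken by
#' depth (deepest wins), then lexicographically by name.
#'
#' @param profile a [variant_profile()].
#' @param tree a [load_haplotree()] tree.
#' @param hotspots positions excluded from scoring (default: packaged list).
#' @return An object of class `haplogroup_call` with the winning node, the
#'   score, and the found / missing-expected / private variant accounting.
#' @export
classify_haplogroup <- function(profile, tree,
                                hotspots = default_hotspots()) {
  found <- substitution_keys(profile, hotspots)
  if (length(profile$missing)) {
    found <- found[!(key_pos(found) %in% profile$missing)]
  }
  sc <- score_all_nodes(found, tree, hotspots, profile$missing)
  best <- order(-sc$score, -tree$depth[sc$node], sc$node)[1]
  node <- sc$node[best]
  expected <- usable_expected(tree$cumulative[[node]], hotspots,
                              profile$missing)
  structure(list(sample_id = profile$sample_id, haplogroup = node,
                 score = sc$score[best],
                 found_variants = sort(intersect(found, expected)),
                 missing_expected_variants = sort(setdiff(expected, found)),
                 private_variants = sort(setdiff(found, expected))),
            class = "haplogroup_call")
}

usable_expected <- function(expected, hotspots, missing) {
  p <- key_pos(expected)
  expected[!(p %in% hotspots) & !(p %in% missing)]
}

kulczynski <- function(found, expected) {
  i <- length(intersect(found, expected))
  t1 <- if (length(expected) == 0L) 1 else i / length(expected)
  t2 <- if (length(found) == 0L) 1 else i / length(found)
  0.5 * (t1 + t2)
}

score_all_nodes <- function(found, tree, hotspots, missing) {
  score <- vapply(tree$nodes, function(n) {
    kulczynski(found, usable_expected(tree$cumulative[[n]], hotspots,
                                      missing))
  }, 0)
  list(node = tree$nodes, score = unname(score))
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("<haplogroup_call> %s -> %s (score %.3f; %d found, %d missing, %d private)\n",
              x$sample_id, x$haplogroup, x$score, length(x$found_variants),
              length(x$missing_expected_variants),
              length(x$private_variants)))
  invisible(x)
}

#' Classify a list of profiles
#'
#' @param profiles list of [variant_profile()] objects.
#' @inheritParams classify_haplogroup
#' @return Named list of `haplogroup_call` objects.
#' @export
classify_panel <- function(profiles, tree, hotspots = default_hotspots()) {
  out <- lapply(profiles, classify_haplogroup, tree = tree,
                hotspots = hotspots)
  names(out) <- vapply(profiles, function(p) p$sample_id, "")
  out
}

#' Map a haplogroup to its continental ancestry class
#'
#' Longest-prefix match against a prefix table mapping haplogroup labels to
#' ancestry classes. The packaged default follows the conventional reading
#' of the human mtDNA phylogeny for a West-Eurasian/South-Asian panel:
#' M (except M1) is South Asian; U, K, H, V, HV, R0, J, T, JT, N1, N2, W, X
#' and I are West Eurasian; M1 and U6 are flagged North African; anything
#' unmatched is `other`.
#'
#' @param haplogroup haplogroup name(s), or a `haplogroup_call`.
#' @param table data frame with columns `prefix`, `class`; `NULL` for the
#'   packaged table.
#' @return Character vector of ancestry classes.
#' @export
macrogroup_of <- function(haplogroup, table = NULL) {
  if (inherits(haplogroup, "haplogroup_call")) {
    haplogroup <- haplogroup$haplogroup
  }
  if (is.null(table)) table <- read_macrogroups()
  # a prefix only matches at a label-token boundary: "M1" matches "M1a"
  # but not "M18" (the 8 continues the same number)
  matches <- function(h, pre) {
    if (!startsWith(h, pre)) return(FALSE)
    if (nchar(h) == nchar(pre)) return(TRUE)
    last <- substr(pre, nchar(pre), nchar(pre))
    nxt <- substr(h, nchar(pre) + 1L, nchar(pre) + 1L)
    grepl("[0-9]", last) != grepl("[0-9]", nxt)
  }
  vapply(haplogroup, function(h) {
    hit <- table$prefix[vapply(table$prefix, matches, TRUE, h = h)]
    if (!length(hit)) return("other")
    table$class[table$prefix == hit[which.max(nchar(hit))][1]][1]
  }, "", USE.NAMES = FALSE)
}

read_macrogroups <- function() {
  utils::read.delim(system.file("extdata", "macrogroups.tsv",
                                package = "mtfounder", mustWork = TRUE),
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Write haplogroup calls as TSV
#'
#' @param calls list of `haplogroup_call` objects.
#' @param path output TSV.
#' @export
write_calls_tsv <- function(calls, path) {
  df <- data.frame(
    sample_id = vapply(calls, `[[`, "", "sample_id"),
    haplogroup = vapply(calls, `[[`, "", "haplogroup"),
    score = vapply(calls, `[[`, 0, "score"),
    private_variants = vapply(calls, function(x)
      paste(x$private_variants, collapse = " "), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
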