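#' Build a median-joining haplotype network
#'
#' Implements the median-joining construction on the binary encoding of the
#' segregating substitution sites of the input profiles. Starting from the
#' epsilon-relaxed minimum spanning network over the observed haplotypes,
#' the algorithm repeatedly generates median (majority-consensus) vectors of
#' node triples that are at least partly linked, adds the medians of minimal
#' connection cost (within `epsilon`), prunes obsolete median vectors
#' (unsampled nodes of degree <= 2), and recomputes the spanning network
#' until convergence. With `epsilon = 0` and tree-like data the result is
#' the parsimony tree of the minimum spanning network. The node set is
#' canonically ordered, so the result is invariant to input permutation.
#'
#' @param profiles list of [variant_profile()]s (>= 2 distinct haplotypes).
#' @param epsilon the median-joining tolerance (default 0).
#' @param site_weights optional named numeric vector of weights per variant
#'   key (`posALT`); by default all segregating sites have weight 1 and
#'   hotspot sites weight 0.
#' @param hotspots hotspot positions (down-weighted to 0 by default).
#' @param max_sites refuse above this many segregating sites unless `force`.
#' @param force build even above `max_sites`.
#' @return An object of class `haplotype_network`: `nodes` (data frame:
#'   `id`, `is_median`, `multiplicity`, `samples`, `populations`), `edges`
#'   (data frame: `from`, `to`, `length`, `variants`), the binary `states`
#'   matrix (nodes x sites), the site `keys` and `weights`, and `epsilon`.
#' @export
build_mj_network <- function(profiles, epsilon = 0, site_weights = NULL,
                             hotspots = default_hotspots(),
                             max_sites = 200L, force = FALSE) {
  enc <- encode_haplotypes(profiles)
  if (ncol(enc$states) > max_sites && !force) {
    stop(errorCondition(
      sprintf(paste0("%d segregating sites exceed the limit of %d; median ",
                     "generation is combinatorial in the number of sites. ",
                     "Partition the panel (e.g. per lineage) or use ",
                     "force = TRUE."), ncol(enc$states), max_sites),
      class = c("mtf_network_error", "error")))
  }
  w <- rep(1, ncol(enc$states))
  names(w) <- colnames(enc$states)
  w[key_pos(colnames(enc$states)) %in% hotspots] <- 0
  if (!is.null(site_weights)) {
    w[names(site_weights)] <- site_weights
  }
  it <- mj_iterate(enc$states, nrow(enc$states), w, epsilon)
  build_network_object(it$X, it$E, w, enc, nrow(enc$states), epsilon)
}

# the median-joining loop: MSN, obsolete-median pruning, median addition,
# until convergence; rows 1..n_obs of X are terminals and are never pruned
mj_iterate <- function(X, n_obs, w, epsilon) {
  repeat {
    E <- msn_edges(X, w, epsilon)
    deg <- tabulate(c(E$from, E$to), nbins = nrow(X))
    obsolete <- which(deg <= 2 & seq_len(nrow(X)) > n_obs)
    if (length(obsolete)) {
      X <- X[-obsolete, , drop = FALSE]
      next
    }
    cand <- median_candidates(X, E, w)
    if (is.null(cand)) break
    X <- rbind(X, cand)
  }
  list(X = X, E = msn_edges(X, w, epsilon))
}

# distinct haplotypes as a binary matrix over segregating substitution keys
encode_haplotypes <- function(profiles) {
  keysets <- lapply(profiles, substitution_keys)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  pops <- vapply(profiles, function(p)
    if (is.na(p$population)) "" else p$population, "")
  hapkey <- vapply(keysets, function(k) paste(sort(k), collapse = "|"), "")
  uniq <- !duplicated(hapkey)
  if (sum(uniq) < 2L) {
    stop(errorCondition("need at least 2 distinct haplotypes",
                        class = c("mtf_network_error", "error")))
  }
  sites <- sort(unique(unlist(keysets)))
  X <- do.call(rbind, lapply(keysets[uniq], function(k)
    as.integer(sites %in% k)))
  colnames(X) <- sites
  rownames(X) <- NULL
  members <- split(ids, match(hapkey, hapkey[uniq]))
  pop_of <- split(pops, match(hapkey, hapkey[uniq]))
  # canonical node order: by decreasing multiplicity then state string
  ord <- order(-vapply(members, length, 1L),
               apply(X, 1, paste, collapse = ""))
  list(states = X[ord, , drop = FALSE], members = members[ord],
       populations = pop_of[ord])
}

weighted_dist <- function(X, w) {
  D <- matrix(0, nrow(X), nrow(X))
  for (i in seq_len(nrow(X) - 1)) {
    for (j in (i + 1):nrow(X)) {
      D[i, j] <- D[j, i] <- sum(w * (X[i, ] != X[j, ]))
    }
  }
  D
}

# epsilon-relaxed minimum spanning network: an edge (u,v) is feasible iff
# d(u,v) <= lambda(u,v) + epsilon, where lambda is the single-linkage merge
# height (the level at which u and v first become connected when all edges
# are admitted in ascending distance order). epsilon = 0 gives the union of
# all minimum spanning trees.
msn_edges <- function(X, w, epsilon) {
  D <- weighted_dist(X, w)
  n <- nrow(D)
  if (n == 1L) return(data.frame(from = integer(), to = integer(),
                                 length = numeric()))
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  lambda <- as.matrix(stats::cophenetic(hc))
  keep <- which(upper.tri(D) & D <= lambda + epsilon + 1e-9, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2],
             length = D[keep], stringsAsFactors = FALSE)
}

# candidate median vectors for triples with at least two linked pairs;
# returns the distinct medians achieving the minimal connection cost, or
# NULL when no triple yields a new node
median_candidates <- function(X, E, w) {
  n <- nrow(X)
  adj <- matrix(FALSE, n, n)
  adj[cbind(E$from, E$to)] <- TRUE
  adj[cbind(E$to, E$from)] <- TRUE
  existing <- apply(X, 1, paste, collapse = "")
  best_cost <- Inf
  best <- list()
  for (u in seq_len(n - 2)) {
    for (v in (u + 1):(n - 1)) {
      for (t in (v + 1):n) {
        if (adj[u, v] + adj[u, t] + adj[v, t] < 2) next
        m <- as.integer(X[u, ] + X[v, ] + X[t, ] >= 2)
        mk <- paste(m, collapse = "")
        if (mk %in% existing) next
        cost <- sum(w * (X[u, ] != m)) + sum(w * (X[v, ] != m)) +
          sum(w * (X[t, ] != m))
        if (cost < best_cost - 1e-9) {
          best_cost <- cost
          best <- list(m)
        } else if (cost <= best_cost + 1e-9 &&
                   !any(vapply(best, function(b) all(b == m), TRUE))) {
          best <- c(best, list(m))
        }
      }
    }
  }
  if (!length(best)) return(NULL)
  out <- do.call(rbind, best)
  colnames(out) <- colnames(X)
  out
}

build_network_object <- function(X, E, w, enc, n_obs, epsilon) {
  n <- nrow(X)
  is_median <- seq_len(n) > n_obs
  mult <- integer(n)
  samples <- character(n)
  pops <- character(n)
  mult[seq_len(n_obs)] <- vapply(enc$members, length, 1L)
  samples[seq_len(n_obs)] <- vapply(enc$members, paste, "", collapse = ",")
  pops[seq_len(n_obs)] <- vapply(enc$populations, function(p)
    paste(sort(unique(p)), collapse = ","), "")
  ids <- ifelse(is_median, paste0("mv", cumsum(is_median)),
                paste0("hap", seq_len(n)))
  edge_variants <- vapply(seq_len(nrow(E)), function(i) {
    diffs <- which(X[E$from[i], ] != X[E$to[i], ])
    paste(colnames(X)[diffs], collapse = " ")
  }, "")
  structure(list(
    nodes = data.frame(id = ids, is_median = is_median,
                       multiplicity = mult, samples = samples,
                       populations = pops, stringsAsFactors = FALSE),
    edges = data.frame(from = ids[E$from], to = ids[E$to],
                       length = E$length, variants = edge_variants,
                       stringsAsFactors = FALSE),
    states = X, keys = colnames(X), weights = w, epsilon = epsilon),
    class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes (%d observed, %d median), %d edges, total length %g\n",
              nrow(x$nodes), sum(!x$nodes$is_median),
              sum(x$nodes$is_median), nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

network_igraph <- function(network) {
  nodes <- network$nodes
  nodes$is_median <- as.integer(nodes$is_median) # GML has no booleans
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$weight <- network$edges$length
  g
}

#' Extract a maximum-parsimony tree rendering from a network
#'
#' Builds the minimum-length tree spanning the observed haplotypes and the
#' supplied root: the median-joining loop is re-run with the root included
#' as a terminal (so root-adjacent median vectors exist), terminals are
#' then connected along network shortest paths (metric-closure Prim with
#' canonical tie-breaks), and dangling median chains are pruned. Branches
#' are annotated with their variant strings; losing a derived allele along
#' the root-to-tip direction is rendered with the `@` back-mutation
#' prefix.
#'
#' @param network a [build_mj_network()] result.
#' @param root the root haplotype as a [variant_profile()].
#' @return An object of class `parsimony_tree`: `edges` (data frame with
#'   `parent`, `child`, `length`, `label`), `root` node id, and the node
#'   table. Convert with [tree_newick()].
#' @export
extract_parsimony_tree <- function(network, root) {
  obs <- !network$nodes$is_median
  X_obs <- network$states[obs, , drop = FALSE]
  obs_ids <- network$nodes$id[obs]
  w <- network$weights
  rk <- substitution_keys(root)
  rstate <- as.integer(colnames(X_obs) %in% rk)
  root_row <- which(apply(X_obs, 1, function(r) all(r == rstate)))
  if (!length(root_row)) {
    # the root is a terminal of the tree: re-run the median-joining loop
    # with it included so root-adjacent median vectors can be generated
    X_obs <- rbind(X_obs, rstate)
    obs_ids <- c(obs_ids, "root")
    root_row <- nrow(X_obs)
  }
  it <- mj_iterate(X_obs, nrow(X_obs), w, network$epsilon)
  X <- it$X
  n_term <- nrow(X_obs)
  ids <- c(obs_ids,
           if (nrow(X) > n_term) paste0("mv", seq_len(nrow(X) - n_term)))
  old <- network$nodes[match(obs_ids, network$nodes$id), , drop = FALSE]
  nodes <- data.frame(
    id = ids,
    is_median = c(ifelse(is.na(old$id), TRUE, FALSE),
                  rep(TRUE, nrow(X) - n_term)),
    multiplicity = c(ifelse(is.na(old$id), 0L, old$multiplicity),
                     integer(nrow(X) - n_term)),
    samples = c(ifelse(is.na(old$id), "", old$samples),
                character(nrow(X) - n_term)),
    populations = c(ifelse(is.na(old$id), "", old$populations),
                    character(nrow(X) - n_term)),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[it$E$from], to = ids[it$E$to],
                      length = it$E$length, stringsAsFactors = FALSE)
  root_id <- ids[root_row]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    stop(errorCondition("network is not connected",
                        class = c("mtf_network_error", "error")))
  }
  # check rooting ambiguity: other terminals at distance 0 from the root
  zero <- which(apply(X_obs, 1, function(r)
    sum(w * (r != rstate)) == 0))
  if (length(zero) > 1L) {
    warning(sprintf("ambiguous rooting; alternatives: %s",
                    paste(setdiff(obs_ids[zero], root_id),
                          collapse = ", ")))
  }
  # median vectors are optional Steiner points: build the tree over the
  # terminals (observed haplotypes + the root), connecting them along
  # network shortest paths. A plain spanning tree of the whole network
  # would be forced through every median and overshoot the parsimony
  # length.
  terminals <- union(nodes$id[!nodes$is_median], root_id)
  Dsp <- igraph::distances(g, v = terminals, to = terminals,
                           weights = igraph::E(g)$weight)
  # Prim over the terminal metric closure, deterministic by node order
  nt <- length(terminals)
  in_tree <- c(TRUE, logical(nt - 1))
  best <- Dsp[1, ]
  via <- rep(terminals[1], nt)
  eids <- integer()
  for (k in seq_len(nt - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    sp <- igraph::shortest_paths(g, from = via[nxt],
                                 to = terminals[nxt],
                                 weights = igraph::E(g)$weight,
                                 output = "epath")$epath[[1]]
    eids <- union(eids, as.integer(sp))
    in_tree[nxt] <- TRUE
    upd <- Dsp[nxt, ] < best
    best[upd] <- Dsp[nxt, upd]
    via[upd] <- terminals[nxt]
  }
  sub <- igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
  mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
  el <- igraph::as_data_frame(mst, what = "edges")[, c("from", "to")]
  # drop dangling median chains left by overlapping paths
  unlabeled <- setdiff(nodes$id[nodes$is_median], root_id)
  repeat {
    deg <- table(c(el$from, el$to))
    drop <- intersect(unlabeled, names(deg)[deg == 1])
    if (!length(drop)) break
    el <- el[!(el$from %in% drop | el$to %in% drop), , drop = FALSE]
  }
  # orient away from the root
  adj <- split(c(el$to, el$from), c(el$from, el$to))
  state_of <- function(id) X[match(id, nodes$id), ]
  rows <- list()
  queue <- root_id
  seen <- root_id
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    for (nb in setdiff(adj[[cur]], seen)) {
      seen <- c(seen, nb)
      queue <- c(queue, nb)
      ps <- state_of(cur)
      cs <- state_of(nb)
      diffs <- which(ps != cs)
      # losing a derived allele along the root-to-tip direction is a back
      # mutation, rendered with the "@" prefix
      lab <- vapply(diffs, function(k) {
        key <- colnames(X)[k]
        if (ps[k] == 1L && cs[k] == 0L) paste0("@", key) else key
      }, "")
      rows[[length(rows) + 1]] <- data.frame(
        parent = cur, child = nb,
        length = sum(network$weights[diffs]),
        label = paste(lab, collapse = " "), stringsAsFactors = FALSE)
    }
  }
  structure(list(edges = do.call(rbind, rows), root = root_id,
                 nodes = nodes), class = "parsimony_tree")
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("<parsimony_tree> rooted at %s, %d branches, length %g\n",
              x$root, nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

#' Serialize a parsimony tree as Newick
#'
#' Median vectors become unlabeled internal nodes; observed haplotypes keep
#' their node ids (as tip or internal labels).
#'
#' @param tree a [extract_parsimony_tree()] result.
#' @return A single Newick string.
#' @export
tree_newick <- function(tree) {
  kids <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
  medians <- tree$nodes$id[tree$nodes$is_median]
  lab <- function(id) if (id %in% medians) "" else id
  rec <- function(id, len) {
    ch <- kids[[id]]
    body <- if (is.null(ch)) lab(id) else {
      paste0("(", paste(vapply(ch, function(i)
        rec(tree$edges$child[i], tree$edges$length[i]), ""),
        collapse = ","), ")", lab(id))
    }
    if (is.na(len)) body else paste0(body, ":", format(len))
  }
  paste0(rec(tree$root, NA), ";")
}

#' Write a network to disk and draw it
#'
#' Writes the network as a GML graph-exchange file and (optionally) a static
#' figure with nodes scaled by carrier multiplicity and coloured by
#' population label; median vectors are drawn as small grey points.
#'
#' @param network a [build_mj_network()] result.
#' @param gml_path output GML file (`NULL` to skip).
#' @param figure_path output PNG file (`NULL` to skip).
#' @param seed layout seed for reproducibility.
#' @return Invisibly, the paths written.
#' @export
render_network <- function(network, gml_path = NULL, figure_path = NULL,
                           seed = 1L) {
  g <- network_igraph(network)
  written <- character()
  if (!is.null(gml_path)) {
    igraph::write_graph(g, gml_path, format = "gml")
    written <- c(written, gml_path)
  }
  if (!is.null(figure_path)) {
    pops <- network$nodes$populations
    pal <- c(study = "#D55E00", reference = "#0072B2")
    col <- ifelse(network$nodes$is_median, "grey60",
                  ifelse(pops %in% names(pal), pal[pops], "#999999"))
    size <- ifelse(network$nodes$is_median, 3,
                   6 + 3 * sqrt(network$nodes$multiplicity))
    grDevices::png(figure_path, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    set.seed(seed)
    igraph::plot.igraph(g, vertex.color = col, vertex.size = size,
                        vertex.label = ifelse(network$nodes$is_median, NA,
                                              network$nodes$id),
                        edge.label = network$edges$variants,
                        edge.label.cex = 0.7)
    written <- c(written, figure_path)
  }
  invisible(written)
}
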