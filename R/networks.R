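#' Best-neighbor edge filter
#'
#' Keeps an edge iff it is the maximum-scoring edge incident on at least one
#' of its two endpoints (first-order neighbors only). Ties are kept: if a
#' node has several incident edges sharing its maximum score, all of them
#' survive, so the result is deterministic.
#'
#' @param edges Data frame with columns `pos_i`, `pos_j` and a score column
#'   (`score` or `corrected_mi`).
#' @return The surviving subset of `edges` (same columns, original order).
#' @export
best_neighbor_filter <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  score <- if ("score" %in% names(edges)) edges$score else edges$corrected_mi
  if (is.null(score)) stop("edges need a 'score' or 'corrected_mi' column", call. = FALSE)
  nodes <- unique(c(edges$pos_i, edges$pos_j))
  best <- vapply(nodes, function(v) {
    max(score[edges$pos_i == v | edges$pos_j == v])
  }, numeric(1))
  names(best) <- as.character(nodes)
  keep <- score >= best[as.character(edges$pos_i)] |
    score >= best[as.character(edges$pos_j)]
  edges[keep, , drop = FALSE]
}

#' Core and extended covariation networks
#'
#' Builds the covariation network tiers: *core* edges are the significant
#' pairs whose corrected-MI score falls in the top `core_pct`, *extended*
#' edges those in the top `extended_pct` but not the core (both restricted
#' to significant pairs). The percentile pool is, by default, the set of
#' significant pairs; with `percentile_basis = "all"` the top fractions are
#' computed over all scored pairs (and then intersected with the significant
#' set). Clusters are the connected components of the core graph with at
#' least `min_size` members; the best-neighbor filter ([best_neighbor_filter()])
#' annotates a backbone edge subset for inspection, and can instead define
#' the components via `cluster_on = "best_neighbor"`. Extended edges are
#' attached to a cluster when incident on one of its members (first-order
#' neighbors only).
#'
#' @param cov A `CovariationResult`.
#' @param core_pct Top fraction for the core tier (default 0.01).
#' @param extended_pct Top fraction for core + extended (default 0.02).
#' @param min_size Minimum members for a reported cluster (default 3).
#' @param percentile_basis `"significant"` (default) or `"all"`.
#' @param cluster_on `"core"` (components of the full core graph, default)
#'   or `"best_neighbor"` (components of the filtered backbone).
#' @return Object of class `NetworkSet`: `core_edges` and `extended_edges`
#'   (data frames with `pos_i`, `pos_j`, `score`, `tier`, `cluster_id`,
#'   and, for core, `backbone`), `clusters` (list of `id`, `members`,
#'   `n_core_members`, `edges`, `extended_attached`), plus the parameters.
#'   No edge passing the thresholds yields an empty `NetworkSet`.
#' @export
build_networks <- function(cov, core_pct = 0.01, extended_pct = 0.02,
                           min_size = 3L,
                           percentile_basis = c("significant", "all"),
                           cluster_on = c("core", "best_neighbor")) {
  percentile_basis <- match.arg(percentile_basis)
  cluster_on <- match.arg(cluster_on)
  if (extended_pct < core_pct) stop("extended_pct must be >= core_pct", call. = FALSE)
  pt <- pair_table(cov)
  pt$score <- pt$corrected_mi
  base <- if (percentile_basis == "significant") pt[pt$significant, , drop = FALSE] else pt
  core_idx <- top_fraction_idx(base$score, core_pct)
  ext_idx <- setdiff(top_fraction_idx(base$score, extended_pct), core_idx)
  keep_cols <- c("pos_i", "pos_j", "score", "z", "percentile")
  core <- base[core_idx, , drop = FALSE]
  ext <- base[ext_idx, , drop = FALSE]
  # both tiers are subsets of the significant pair set
  core <- core[core$significant, keep_cols, drop = FALSE]
  ext <- ext[ext$significant, keep_cols, drop = FALSE]
  core$tier <- rep("core", nrow(core))
  ext$tier <- rep("extended", nrow(ext))

  backbone <- best_neighbor_filter(core)
  core$backbone <- interaction(core$pos_i, core$pos_j) %in%
    interaction(backbone$pos_i, backbone$pos_j)

  comp_edges <- if (cluster_on == "core") core else core[core$backbone, , drop = FALSE]
  clusters <- list()
  core$cluster_id <- rep(NA_integer_, nrow(core))
  ext$cluster_id <- rep(NA_integer_, nrow(ext))
  if (nrow(comp_edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(comp_edges$pos_i),
                 to = as.character(comp_edges$pos_j)),
      directed = FALSE)
    comp <- igraph::components(g)
    member_sets <- split(as.integer(names(comp$membership)), comp$membership)
    member_sets <- Filter(function(m) length(m) >= min_size, member_sets)
    # deterministic ordering: largest first, ties by smallest member position
    ord <- order(-vapply(member_sets, length, integer(1)),
                 vapply(member_sets, min, integer(1)))
    member_sets <- member_sets[ord]
    for (k in seq_along(member_sets)) {
      members <- sort(member_sets[[k]])
      in_core <- core$pos_i %in% members & core$pos_j %in% members
      touch_ext <- ext$pos_i %in% members | ext$pos_j %in% members
      core$cluster_id[in_core] <- k
      ext$cluster_id[touch_ext & is.na(ext$cluster_id)] <- k
      clusters[[k]] <- list(
        id = k, members = members, n_core_members = length(members),
        edges = core[in_core, , drop = FALSE],
        extended_attached = ext[touch_ext, , drop = FALSE])
    }
  }
  rownames(core) <- rownames(ext) <- NULL
  structure(
    list(core_edges = core, extended_edges = ext, clusters = clusters,
         min_cluster_size = min_size, core_pct = core_pct,
         extended_pct = extended_pct, percentile_basis = percentile_basis,
         cluster_on = cluster_on, group_label = cov$group_label),
    class = "NetworkSet"
  )
}

#' @export
print.NetworkSet <- function(x, ...) {
  cat(sprintf(
    "NetworkSet '%s': %d core + %d extended edges, %d clusters (min size %d)\n",
    x$group_label, nrow(x$core_edges), nrow(x$extended_edges),
    length(x$clusters), x$min_cluster_size))
  for (cl in x$clusters) {
    cat(sprintf("  cluster %d: %d members (%s)\n", cl$id, cl$n_core_members,
                paste(cl$members, collapse = ", ")))
  }
  invisible(x)
}

#' Per-position cumulative covariation scores and hubs
#'
#' For every position, sums the corrected-MI scores of its significant
#' incident pairs (each edge contributes to both endpoints) and counts its
#' significant partners (degree). The top-k positions by cumulative score
#' are reported; ties are broken by smaller reference number.
#'
#' @param cov A `CovariationResult`.
#' @param k Number of top positions to report (default 10).
#' @return Object of class `HubReport`: `scores` (data frame `position`,
#'   `cumulative`, `degree`, descending by cumulative) and `top` (first `k`
#'   rows). No significant edges yields empty data frames.
#' @export
hub_report <- function(cov, k = 10L) {
  pt <- pair_table(cov)
  sig <- pt[pt$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    empty <- data.frame(position = integer(0), cumulative = numeric(0),
                        degree = integer(0))
    return(structure(list(scores = empty, top = empty, k = k),
                     class = "HubReport"))
  }
  nodes <- sort(unique(c(sig$pos_i, sig$pos_j)))
  cum <- vapply(nodes, function(v) {
    sum(sig$corrected_mi[sig$pos_i == v | sig$pos_j == v])
  }, numeric(1))
  deg <- vapply(nodes, function(v) {
    sum(sig$pos_i == v | sig$pos_j == v)
  }, numeric(1))
  scores <- data.frame(position = nodes, cumulative = cum,
                       degree = as.integer(deg))
  scores <- scores[order(-scores$cumulative, scores$position), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, top = head(scores, k), k = k),
            class = "HubReport")
}

#' @export
print.HubReport <- function(x, ...) {
  cat(sprintf("HubReport: %d scored positions, top %d:\n",
              nrow(x$scores), nrow(x$top)))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Export a network edge list
#'
#' Writes the core + extended edges as TSV (`pos_i`, `pos_j`, `score`,
#' `tier`, `cluster_id`) or SIF (`pos_i  mi  pos_j`) for use in standard
#' graph tools, and optionally a JSON cluster summary.
#'
#' @param net A `NetworkSet`.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @param cluster_json Optional path for a JSON summary of cluster
#'   memberships and sizes.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path, format = c("tsv", "sif"),
                                cluster_json = NULL) {
  format <- match.arg(format)
  cols <- c("pos_i", "pos_j", "score", "tier", "cluster_id")
  all_edges <- rbind(net$core_edges[, cols, drop = FALSE],
                     net$extended_edges[, cols, drop = FALSE])
  if (format == "tsv") {
    write.table(all_edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(sprintf("%d\tmi\t%d", all_edges$pos_i, all_edges$pos_j), path)
  }
  if (!is.null(cluster_json)) {
    jsonlite::write_json(
      lapply(net$clusters, function(cl) {
        list(id = cl$id, members = cl$members,
             n_core_members = cl$n_core_members,
             n_core_edges = nrow(cl$edges),
             n_extended_attached = nrow(cl$extended_attached))
      }),
      cluster_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
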