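#' Pairwise Jaccard distances between patients
#'
#' `d(i, j) = 1 - |Ri intersect Rj| / |Ri union Rj|` over the binary rows of
#' the patient-by-edge matrix. Two all-zero rows are at distance 0 by
#' convention (reported when it occurs).
#'
#' @param matrix Binary patients x edges matrix from [build_matrix()].
#' @return Symmetric distance matrix with patient dimnames, zero diagonal,
#'   entries in `[0, 1]`.
#' @export
jaccard_distances <- function(matrix) {
  if (nrow(matrix) < 2) abort("need at least 2 patients")
  d <- as.matrix(dist(matrix > 0, method = "binary"))
  if (anyNA(d)) {
    inform("jaccard_distances: all-zero patient pairs set to distance 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Embed patients by PCA of the Jaccard similarity matrix
#'
#' Principal components are computed on the column-centred similarity matrix
#' `1 - D`. The embedding retains `use_components` components, or more if
#' needed to reach `target_variance` cumulative explained variance. Signs
#' are fixed deterministically (the largest-magnitude loading of each
#' component is forced positive) so repeated runs are identical.
#'
#' @param distances Jaccard distance matrix from [jaccard_distances()].
#' @param target_variance Cumulative explained-variance target, default 0.95.
#' @param use_components Minimum number of components, default 3.
#' @return List of class `snpheat_embedding`: `scores` (patients x
#'   components), `ev_ratio` (all components), `n_components`.
#' @export
embed_patients <- function(distances, target_variance = 0.95, use_components = 3) {
  S <- 1 - distances
  pc <- prcomp(S, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-12) {
    warn("embed_patients: all patients identical; single zero component")
    scores <- matrix(0, nrow(S), 1, dimnames = list(rownames(S), "PC1"))
    return(structure(list(scores = scores, ev_ratio = 1, n_components = 1L),
                     class = "snpheat_embedding"))
  }
  ev <- pc$sdev^2 / tot
  ncomp <- max(min(use_components, ncol(pc$x)),
               which(cumsum(ev) >= target_variance)[1])
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  for (c in seq_len(ncomp)) {
    if (pc$rotation[which.max(abs(pc$rotation[, c])), c] < 0) {
      scores[, c] <- -scores[, c]
    }
  }
  structure(list(scores = scores, ev_ratio = ev, n_components = as.integer(ncomp)),
            class = "snpheat_embedding")
}

#' @export
print.snpheat_embedding <- function(x, ...) {
  cat("<snpheat_embedding> ", nrow(x$scores), " patients x ", x$n_components,
      " components (", round(100 * sum(x$ev_ratio[seq_len(x$n_components)]), 1),
      "% variance)\n", sep = "")
  invisible(x)
}

#' K-means clustering of the patient embedding
#'
#' @param embedding A `snpheat_embedding`.
#' @param k Number of clusters (>= 2, <= patients - 1).
#' @param rng_seed RNG seed; fixed seeds give identical assignments.
#' @param n_init Number of random k-means restarts, default 10.
#' @return List of class `snpheat_clusters`: `assignment` tibble (patient,
#'   cluster), `k`, `silhouette` (mean width), `inertia` (total
#'   within-cluster sum of squares), `rng_seed`.
#' @export
cluster_patients <- function(embedding, k, rng_seed = 1, n_init = 10) {
  x <- embedding$scores
  if (k < 2) abort("k must be at least 2")
  if (k > nrow(x) - 1) abort("k must be at most patients - 1")
  if (k > nrow(unique(round(x, 12)))) abort("k exceeds the number of distinct points")
  km <- with_rng(rng_seed, kmeans(x, centers = k, nstart = n_init, iter.max = 100))
  sil <- mean(cluster::silhouette(km$cluster, dist(x))[, "sil_width"])
  structure(list(assignment = tibble(patient = rownames(x),
                                     cluster = as.integer(km$cluster)),
                 k = as.integer(k), silhouette = sil,
                 inertia = km$tot.withinss, rng_seed = rng_seed),
            class = "snpheat_clusters")
}

#' @export
print.snpheat_clusters <- function(x, ...) {
  cat("<snpheat_clusters> k = ", x$k, ", mean silhouette = ",
      round(x$silhouette, 3), ", inertia = ", signif(x$inertia, 4), "\n", sep = "")
  invisible(x)
}

#' Select the number of clusters
#'
#' Fits k-means across `k_range` and reports the silhouette and inertia
#' (elbow) curves. The selected k maximises the mean silhouette width (ties
#' resolved toward the smaller k); the inertia curve is reported alongside
#' for manual override.
#'
#' @inheritParams cluster_patients
#' @param k_range Candidate values of k, default `2:10`.
#' @return List of class `snpheat_kselect`: `k` (selected), `diagnostics`
#'   tibble (k, silhouette, inertia), `fits` (the per-k cluster objects).
#' @export
choose_k <- function(embedding, k_range = 2:10, rng_seed = 1, n_init = 10) {
  n_distinct <- nrow(unique(round(embedding$scores, 12)))
  k_range <- k_range[k_range <= min(nrow(embedding$scores) - 1, n_distinct)]
  if (!length(k_range)) abort("no feasible k in k_range")
  fits <- lapply(k_range, function(k) {
    cluster_patients(embedding, k, rng_seed = rng_seed, n_init = n_init)
  })
  diag <- tibble(k = as.integer(k_range),
                 silhouette = vapply(fits, `[[`, double(1), "silhouette"),
                 inertia = vapply(fits, `[[`, double(1), "inertia"))
  best <- which.max(diag$silhouette)
  structure(list(k = diag$k[best], diagnostics = diag,
                 fits = setNames(fits, paste0("k", k_range))),
            class = "snpheat_kselect")
}

#' @export
print.snpheat_kselect <- function(x, ...) {
  cat("<snpheat_kselect> selected k = ", x$k, " (silhouette ",
      round(x$diagnostics$silhouette[x$diagnostics$k == x$k], 3), ")\n", sep = "")
  invisible(x)
}

#' Cluster-representative regulatory edges and TFs
#'
#' An edge represents a cluster when it is present in at least `min_fraction`
#' of that cluster's patients; the representative TFs of a cluster are the
#' TFs of its representative edges.
#'
#' @param clusters A `snpheat_clusters`.
#' @param matrix Binary patient x edge matrix (same patients).
#' @param min_fraction Presence fraction, default 0.5.
#' @return Tibble (`cluster`, `edge`, `tf`, `target`, `fraction`); the
#'   per-cluster TF sets are in attribute `tfs`.
#' @export
cluster_representatives <- function(clusters, matrix, min_fraction = 0.5) {
  asg <- clusters$assignment
  if (!all(asg$patient %in% rownames(matrix))) {
    abort("cluster assignment and matrix patients do not match")
  }
  rows <- purrr::map_dfr(sort(unique(asg$cluster)), function(cl) {
    pats <- asg$patient[asg$cluster == cl]
    frac <- colMeans(matrix[pats, , drop = FALSE] > 0)
    keep <- which(frac >= min_fraction)
    if (!length(keep)) return(NULL)
    edge <- colnames(matrix)[keep]
    parts <- strsplit(edge, "->", fixed = TRUE)
    tibble(cluster = cl, edge = edge,
           tf = vapply(parts, `[[`, character(1), 1),
           target = vapply(parts, `[[`, character(1), 2),
           fraction = unname(frac[keep]))
  })
  attr(rows, "tfs") <- lapply(split(rows$tf, rows$cluster), function(x) sort(unique(x)))
  rows
}

# modularity of a membership vector on an undirected simple graph
undirected_modularity <- function(g, membership) {
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, membership)
}

#' Girvan-Newman modularisation
#'
#' Repeatedly removes the edge with the highest edge betweenness (recomputed
#' after every removal; ties broken by lexicographic edge label so runs are
#' deterministic) and returns the component partition with the highest
#' Newman modularity seen along the removal sequence. Edge direction is
#' ignored; duplicate undirected edges and self-loops are collapsed before
#' modularisation.
#'
#' @param network A `snpheat_network` (or an edge tibble with
#'   source/target columns).
#' @return List of class `snpheat_modules`: `membership` tibble (node,
#'   module), `modularity`, `n_modules`.
#' @export
girvan_newman <- function(network) {
  if (!inherits(network, "snpheat_network")) network <- signalling_network(network)
  g0 <- igraph::simplify(network_igraph(network, directed = FALSE),
                         remove.multiple = TRUE, remove.loops = TRUE)
  part_of <- function(g) {
    m <- igraph::components(g)$membership
    m[match(network$nodes, names(m))]
  }
  best_mem <- part_of(g0)
  best_mod <- undirected_modularity(g0, best_mem)
  g <- g0
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    top <- which(eb >= max(eb) - 1e-9)
    if (length(top) > 1) {
      ends <- igraph::ends(g, igraph::E(g)[top])
      lab <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]), sep = "|")
      top <- top[order(lab)][1]
    }
    g <- igraph::delete_edges(g, top[1])
    mem <- part_of(g)
    mod <- undirected_modularity(g0, mem)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_mem <- mem
    }
  }
  # relabel modules contiguously in order of first appearance
  ids <- as.integer(factor(best_mem, levels = unique(best_mem)))
  structure(list(membership = tibble(node = network$nodes, module = ids),
                 modularity = best_mod, n_modules = max(ids)),
            class = "snpheat_modules")
}

#' @export
print.snpheat_modules <- function(x, ...) {
  cat("<snpheat_modules> ", x$n_modules, " modules, modularity = ",
      round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Hypergeometric overrepresentation analysis
#'
#' One-sided (upper-tail) hypergeometric test of each annotation set against
#' the query, over a fixed universe, with Benjamini-Hochberg adjustment
#' across all tested sets. Query members outside the universe are dropped
#' with a warning; annotation sets are intersected with the universe.
#'
#' @param query Character vector of query identifiers.
#' @param annotation_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector defining the background.
#' @return Tibble sorted by adjusted p: `set`, `overlap`, `query_size`,
#'   `set_size`, `universe_size`, `p`, `p_adj`.
#' @export
ora <- function(query, annotation_sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(paste0("ora: ", length(outside), " query id(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::imap_dfr(annotation_sets, function(members, name) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(query, members))
    n_s <- length(members)
    tibble(set = name, overlap = k, query_size = n_q, set_size = n_s,
           universe_size = n_u,
           p = phyper(k - 1, n_s, n_u - n_s, n_q, lower.tail = FALSE))
  })
  rows |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    arrange(.data$p_adj, .data$p, .data$set)
}
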