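# In-memory null-ensemble cache. Nulls depend only on (kernel, regulons,
# seed count, mode, R, rng seed, variant), so patients sharing a seed count
# share an ensemble.
.null_cache <- new.env(parent = emptyenv())

null_cache_key <- function(kernel, regulons, n_seeds, R, mode, rng_seed, variant,
                           eligible) {
  digest::digest(list(kernel_hash(kernel),
                      if (is.null(regulons)) NULL else
                        digest::digest(as.data.frame(regulons[, c("tf", "target")])),
                      n_seeds, R, mode, rng_seed, variant, eligible),
                 algo = "xxhash64")
}

#' @rdname run_patient
#' @export
clear_null_cache <- function() {
  rm(list = ls(.null_cache), envir = .null_cache)
  invisible(NULL)
}

get_null_cached <- function(kernel, regulons, n_seeds, R, mode, rng_seed,
                            variant, eligible, real_seeds = NULL,
                            degrees = NULL, cache = TRUE) {
  if (mode == "degree_matched") cache <- FALSE  # depends on the actual seeds
  key <- null_cache_key(kernel, regulons, n_seeds, R, mode, rng_seed, variant,
                        eligible)
  if (cache && !is.null(.null_cache[[key]])) return(.null_cache[[key]])
  nul <- build_null(kernel, regulons, n_seeds, R = R, mode = mode,
                    real_seeds = real_seeds, degrees = degrees,
                    rng_seed = rng_seed, variant = variant, eligible = eligible)
  if (cache) .null_cache[[key]] <- nul
  nul
}

#' Run the propagation pipeline for one patient
#'
#' Seeds are the patient's SNP-affected genes intersected with the network;
#' unit heat is propagated through the signalling kernel, Z-filtered against
#' a random-seed null of matching size, and the significant nodes (plus the
#' seeds, which are always retained as injection points) induce the
#' patient's signalling subnetwork. TF heat is then pushed one step through
#' the regulon layer and Z-filtered against the same ensemble's regulatory
#' null; significant TF-to-target edges connect retained TFs to significant
#' targets.
#'
#' @param patient Patient identifier.
#' @param affected_genes Character vector of the patient's SNP-affected genes.
#' @param kernel A `snpheat_kernel` built on the giant component.
#' @param regulons Regulon tibble.
#' @param network The `snpheat_network` the kernel was built from (for the
#'   induced subnetwork and degree matching).
#' @param R Null replicates per ensemble.
#' @param threshold Z threshold (strict), default 2.
#' @param mode Null seed sampling mode.
#' @param rng_seed Seed for the null ensemble RNG.
#' @param variant Regulatory-propagation variant.
#' @param cache Reuse cached ensembles for repeated seed counts.
#' @return List of class `snpheat_patient`: `patient`, `seeds`,
#'   `dropped_seeds`, `signalling` (Z table), `sig_nodes`, `subnetwork`
#'   (edge tibble), `regulatory` (Z table), `reg_edges` (tf, target, heat, z),
#'   `reason` (non-`NULL` for empty results).
#' @export
run_patient <- function(patient, affected_genes, kernel, regulons, network,
                        R = 10000, threshold = 2,
                        mode = c("uniform", "degree_matched"),
                        rng_seed = 1, variant = c("text", "printed"),
                        cache = TRUE) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  seeds <- intersect(unique(as.character(affected_genes)), kernel$nodes)
  dropped <- setdiff(unique(as.character(affected_genes)), seeds)
  empty_z <- function(layer) {
    structure(tibble(node = character(), heat = double(), null_mean = double(),
                     null_sd = double(), z = double(), significant = logical()),
              layer = layer, class = c("snpheat_zscores", class(tibble())))
  }
  if (!length(seeds)) {
    return(structure(list(patient = patient, seeds = character(),
                          dropped_seeds = dropped,
                          signalling = empty_z("signalling"),
                          sig_nodes = character(),
                          subnetwork = tibble(source = character(), target = character()),
                          regulatory = empty_z("regulatory"),
                          reg_edges = tibble(tf = character(), target = character(),
                                             heat = double(), z = double()),
                          reason = "no usable seeds in the network"),
                     class = "snpheat_patient"))
  }
  h <- propagate_signalling(seeds, kernel)
  nul <- get_null_cached(kernel, regulons, length(seeds), R, mode, rng_seed,
                         variant, eligible = kernel$nodes, real_seeds = seeds,
                         degrees = out_degrees(network), cache = cache)
  zs <- z_filter(h, nul, layer = "signalling", threshold = threshold)
  sig_nodes <- zs$node[zs$significant]
  retained <- union(sig_nodes, seeds)
  sub <- filter(network$edges, .data$source %in% retained,
                .data$target %in% retained)[, c("source", "target")]
  reg <- propagate_regulatory(h, regulons, variant = variant, nodes = kernel$nodes)
  zr <- z_filter(reg, nul, layer = "regulatory", threshold = threshold)
  sig_tg <- zr$node[zr$significant]
  # significant regulatory edges: heated, retained TF -> significant target
  redges <- as_tibble(regulons) |>
    distinct(.data$tf, .data$target) |>
    filter(.data$target %in% sig_tg, .data$tf %in% retained) |>
    mutate(tf_heat = setNames(h$heat, h$node)[.data$tf]) |>
    filter(.data$tf_heat > 0) |>
    left_join(zr[, c("node", "heat", "z")], by = c(target = "node")) |>
    select("tf", "target", "heat", "z") |>
    arrange(.data$tf, .data$target)
  structure(list(patient = patient, seeds = sort(seeds), dropped_seeds = dropped,
                 signalling = zs, sig_nodes = sort(sig_nodes), subnetwork = sub,
                 regulatory = zr, reg_edges = redges, reason = NULL),
            class = "snpheat_patient")
}

#' @export
print.snpheat_patient <- function(x, ...) {
  cat("<snpheat_patient> ", x$patient, ": ", length(x$seeds), " seeds, ",
      length(x$sig_nodes), " significant signalling nodes, ",
      nrow(x$reg_edges), " significant regulatory edges\n", sep = "")
  invisible(x)
}

#' Aggregate patient results across a cohort
#'
#' Counts, per signalling node, per regulatory target and per TF-to-target
#' edge, the number of patients in whose significant networks it appears,
#' and flags the commonly perturbed items (count strictly greater than
#' `common_threshold`; pass a value below 1 to use a cohort fraction).
#'
#' @param results List of `snpheat_patient` objects.
#' @param common_threshold Count threshold (default 100, strict greater-than)
#'   or a fraction of the cohort when < 1.
#' @return List of class `snpheat_cohort`: `node_counts` (node, layer,
#'   n_patients, common), `edge_counts` (tf, target, n_patients, common),
#'   `n_patients`, `threshold`.
#' @export
summarise_cohort <- function(results, common_threshold = 100) {
  if (!length(results)) {
    return(structure(list(node_counts = tibble(node = character(), layer = character(),
                                               n_patients = integer(), common = logical()),
                          edge_counts = tibble(tf = character(), target = character(),
                                               n_patients = integer(), common = logical()),
                          n_patients = 0L, threshold = common_threshold),
                     class = "snpheat_cohort"))
  }
  n_pat <- length(results)
  thr <- if (common_threshold < 1) common_threshold * n_pat else common_threshold
  sig_nodes <- purrr::map_dfr(results, function(r) {
    bind_rows(tibble(node = union(r$sig_nodes, r$seeds), layer = "signalling"),
              tibble(node = r$regulatory$node[r$regulatory$significant],
                     layer = "regulatory"))
  })
  node_counts <- sig_nodes |>
    count(.data$node, .data$layer, name = "n_patients") |>
    mutate(common = .data$n_patients > thr) |>
    arrange(.data$layer, dplyr::desc(.data$n_patients), .data$node)
  edge_counts <- purrr::map_dfr(results, function(r) r$reg_edges[, c("tf", "target")]) |>
    count(.data$tf, .data$target, name = "n_patients") |>
    mutate(common = .data$n_patients > thr) |>
    arrange(dplyr::desc(.data$n_patients), .data$tf, .data$target)
  structure(list(node_counts = node_counts, edge_counts = edge_counts,
                 n_patients = n_pat, threshold = thr),
            class = "snpheat_cohort")
}

#' @export
print.snpheat_cohort <- function(x, ...) {
  cat("<snpheat_cohort> ", x$n_patients, " patients; ",
      nrow(x$node_counts), " perturbed nodes (",
      sum(x$node_counts$common), " common at > ", x$threshold, "); ",
      nrow(x$edge_counts), " regulatory edges\n", sep = "")
  invisible(x)
}

#' Combine two disease cohorts into one labelled network
#'
#' Takes the cohort summaries of two diseases computed over the same
#' underlying networks and produces the union, with each node and edge
#' labelled `shared`, or specific to either cohort; per-disease patient
#' counts are carried unchanged (no re-normalisation).
#'
#' @param summary_a,summary_b `snpheat_cohort` objects.
#' @param labels Length-2 character vector naming the two cohorts.
#' @return List with `nodes` and `edges` tibbles carrying `count_<label>`
#'   columns and a `status` label.
#' @export
combine_diseases <- function(summary_a, summary_b, labels = c("A", "B")) {
  ha <- attr(summary_a, "network_hash")
  hb <- attr(summary_b, "network_hash")
  if (!is.null(ha) && !is.null(hb) && !identical(ha, hb)) {
    abort("cohort summaries were built over different networks")
  }
  join2 <- function(a, b, keys) {
    out <- dplyr::full_join(a, b, by = keys, suffix = c("_a", "_b")) |>
      mutate(count_a = dplyr::coalesce(.data$n_patients_a, 0L),
             count_b = dplyr::coalesce(.data$n_patients_b, 0L),
             status = dplyr::case_when(
               .data$count_a > 0 & .data$count_b > 0 ~ "shared",
               .data$count_a > 0 ~ paste0(labels[1], "-specific"),
               TRUE ~ paste0(labels[2], "-specific")))
    names(out)[names(out) == "count_a"] <- paste0("count_", labels[1])
    names(out)[names(out) == "count_b"] <- paste0("count_", labels[2])
    out[, c(keys, paste0("count_", labels), "status")]
  }
  list(nodes = join2(summary_a$node_counts, summary_b$node_counts,
                     c("node", "layer")),
       edges = join2(summary_a$edge_counts, summary_b$edge_counts,
                     c("tf", "target")))
}

#' Binary patient-by-regulatory-edge matrix
#'
#' Columns are the union of significant TF-to-target edges across patients
#' (deterministic lexicographic order, labelled `"TF->TG"`); rows are
#' ordered by patient id. Entry 1 marks the edge as present in that
#' patient's significant regulatory network. This matrix is the input to
#' patient stratification.
#'
#' @param results List of `snpheat_patient` objects (>= 2).
#' @return Binary integer matrix with dimnames.
#' @export
build_matrix <- function(results) {
  if (length(results) < 2) abort("build_matrix needs at least 2 patients")
  edges <- purrr::map(results, function(r) {
    if (nrow(r$reg_edges)) paste0(r$reg_edges$tf, "->", r$reg_edges$target)
    else character()
  })
  cols <- sort(unique(unlist(edges)))
  if (!length(cols)) abort("all patient results are empty; nothing to cluster")
  pats <- vapply(results, `[[`, character(1), "patient")
  ord <- order(pats)
  m <- matrix(0L, length(results), length(cols),
              dimnames = list(pats[ord], cols))
  for (i in seq_along(ord)) {
    m[i, match(edges[[ord[i]]], cols)] <- 1L
  }
  m
}
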