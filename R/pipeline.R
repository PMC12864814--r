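#' Pipeline parameters
#'
#' Validated parameter bundle for [run_pipeline()]. Defaults follow the
#' published protocol where one exists (Z > 2, 5 kb promoters, grade A/B/C
#' regulons, ">100 patients" commonality on full-size cohorts) and the
#' package defaults elsewhere.
#'
#' @param score_fraction TFBS presence threshold as a fraction of the
#'   maximum motif score.
#' @param upstream_bp Promoter extent upstream of the TSS.
#' @param m,b Retain-parameter heuristic constants ([compute_alpha()]).
#' @param alpha Optional explicit retain parameter (overrides the heuristic).
#' @param R Null replicates per ensemble.
#' @param z_threshold Significance threshold on Z (strict, > 0).
#' @param common_threshold Patient-count threshold for "commonly perturbed"
#'   (a fraction of the cohort when < 1).
#' @param min_fraction Cluster-representative edge fraction.
#' @param k Fixed cluster count, or `NULL` to select by silhouette.
#' @param k_range Candidate k values when selecting.
#' @param rng_seed Master RNG seed for nulls and clustering.
#' @param mode Null seed sampling mode.
#' @param dangling Sink handling in the weighted adjacency.
#' @param variant Regulatory-propagation variant.
#' @param cohort_mode `"union"` (per-patient runs aggregated) or `"pooled"`
#'   (one run from the pooled seed set).
#' @param allowed_grades Regulon confidence grades retained.
#' @return Validated list of class `snpheat_params`.
#' @export
pipeline_params <- function(score_fraction = 0.8, upstream_bp = 5000,
                            m = -0.02935302, b = 0.74842057, alpha = NULL,
                            R = 1000, z_threshold = 2, common_threshold = 100,
                            min_fraction = 0.5, k = NULL, k_range = 2:10,
                            rng_seed = 1,
                            mode = c("uniform", "degree_matched"),
                            dangling = c("self_loop", "zero_row"),
                            variant = c("text", "printed"),
                            cohort_mode = c("union", "pooled"),
                            allowed_grades = c("A", "B", "C")) {
  stopifnot(score_fraction > 0, score_fraction <= 1, upstream_bp >= 0, R >= 1)
  if (z_threshold <= 0) abort("z_threshold must be positive")
  if (!is.null(alpha) && (alpha < 0.01 || alpha > 0.99)) {
    abort("explicit alpha must lie in [0.01, 0.99]")
  }
  if (common_threshold < 0) abort("common_threshold must be non-negative")
  if (min_fraction <= 0 || min_fraction > 1) abort("min_fraction must be in (0, 1]")
  structure(list(score_fraction = score_fraction, upstream_bp = upstream_bp,
                 m = m, b = b, alpha = alpha, R = as.integer(R),
                 z_threshold = z_threshold, common_threshold = common_threshold,
                 min_fraction = min_fraction, k = k, k_range = k_range,
                 rng_seed = as.integer(rng_seed), mode = match.arg(mode),
                 dangling = match.arg(dangling), variant = match.arg(variant),
                 cohort_mode = match.arg(cohort_mode),
                 allowed_grades = allowed_grades),
            class = "snpheat_params")
}

default_input_files <- function(input_dir) {
  list(network = file.path(input_dir, "network.tsv"),
       regulons = file.path(input_dir, "regulons.tsv"),
       genotypes = file.path(input_dir, "genotypes.vcf"),
       genome = file.path(input_dir, "genome.fa"),
       gene_models = file.path(input_dir, "gene_models.tsv"),
       motifs = file.path(input_dir, "motifs.jaspar"),
       enhancers = file.path(input_dir, "enhancers.bed"),
       peaks = file.path(input_dir, "peaks.bed"),
       mirna_sites = file.path(input_dir, "mirna_sites.bed"),
       mirna_seeds = file.path(input_dir, "mirna_seeds.tsv"))
}

#' Run the full pipeline on an input directory
#'
#' Reads every input, annotates carried variants to SNP-affected genes,
#' builds the diffusion kernel on the giant component, runs every patient
#' through both propagation layers with the random-seed null, aggregates
#' the cohort, stratifies patients, modularises the cohort signalling
#' network, and writes all result tables plus a provenance manifest.
#'
#' @param input_dir Directory holding the inputs (file names as written by
#'   [write_fixture()]; individual paths can be overridden via `files`).
#' @param out_dir Output directory (created).
#' @param params A [pipeline_params()].
#' @param files Optional named list overriding individual input paths.
#' @param annotation_gmt Optional GMT file for overrepresentation analysis
#'   of the commonly perturbed signalling nodes.
#' @return Invisible list with all intermediate and final objects.
#' @export
run_pipeline <- function(input_dir, out_dir, params = pipeline_params(),
                         files = NULL, annotation_gmt = NULL) {
  t0 <- Sys.time()
  paths <- modifyList(default_input_files(input_dir), as.list(files %||% list()))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  network <- read_network(paths$network)
  regulons <- read_regulons(paths$regulons, allowed_grades = params$allowed_grades)
  genotypes <- read_genotypes(paths$genotypes)
  genome <- read_fasta(paths$genome)
  gene_models <- read_gene_models(paths$gene_models)
  motifs <- read_jaspar(paths$motifs)
  enhancers <- if (file.exists(paths$enhancers)) read_bed(paths$enhancers)
  peaks <- if (file.exists(paths$peaks)) read_bed(paths$peaks)
  mirna_sites <- if (file.exists(paths$mirna_sites)) read_bed(paths$mirna_sites)
  mirna_seeds <- if (file.exists(paths$mirna_seeds)) read_mirna_seeds(paths$mirna_seeds)
  variants <- vcf_variants(paths$genotypes)

  # --- annotation ---
  promoters <- build_promoters(gene_models, upstream_bp = params$upstream_bp)
  calls <- annotate_variants(variants, genome, motifs, promoters,
                             enhancers = enhancers, mirna_sites = mirna_sites,
                             mirna_seeds = mirna_seeds,
                             score_fraction = params$score_fraction)
  surviving <- epigenetic_filter(calls, peaks)
  affected <- collect_affected(genotypes, surviving)
  sets <- affected_sets(affected)
  readr::write_tsv(calls, file.path(out_dir, "binding_calls.tsv"), progress = FALSE)
  readr::write_tsv(surviving, file.path(out_dir, "binding_calls_active.tsv"),
                   progress = FALSE)
  readr::write_tsv(affected, file.path(out_dir, "affected_genes.tsv"),
                   progress = FALSE)

  # --- propagation substrate ---
  gc_net <- giant_component(network)
  alpha <- if (is.null(params$alpha)) {
    compute_alpha(nrow(gc_net$edges), m = params$m, b = params$b)
  } else {
    structure(list(alpha = params$alpha, edge_count = nrow(gc_net$edges),
                   m = NA_real_, b = NA_real_, clamped = FALSE),
              class = "snpheat_alpha")
  }
  adj <- build_weighted_adjacency(gc_net, dangling = params$dangling)
  kernel <- compute_kernel(adj, alpha)

  # --- per-patient propagation ---
  clear_null_cache()
  if (params$cohort_mode == "pooled") {
    pooled <- sort(unique(unlist(sets)))
    results <- list(run_patient("pooled", pooled, kernel, regulons, gc_net,
                                R = params$R, threshold = params$z_threshold,
                                mode = params$mode, rng_seed = params$rng_seed,
                                variant = params$variant))
  } else {
    results <- purrr::imap(sets, function(genes, pat) {
      suppressWarnings(
        run_patient(pat, genes, kernel, regulons, gc_net,
                    R = params$R, threshold = params$z_threshold,
                    mode = params$mode, rng_seed = params$rng_seed,
                    variant = params$variant))
    })
  }
  pat_dir <- file.path(out_dir, "patients")
  for (r in results) write_patient_result(r, file.path(pat_dir, r$patient))
  readr::write_tsv(purrr::map_dfr(results, glance),
                   file.path(out_dir, "patient_summary.tsv"), progress = FALSE)

  # --- cohort aggregation ---
  cohort <- summarise_cohort(results, common_threshold = params$common_threshold)
  attr(cohort, "network_hash") <- digest::digest(gc_net$edges)
  readr::write_tsv(cohort$node_counts, file.path(out_dir, "node_frequency.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$edge_counts, file.path(out_dir, "edge_frequency.tsv"),
                   progress = FALSE)

  # --- stratification (union mode, >= 2 non-empty patients) ---
  strat <- NULL
  usable <- sum(vapply(results, function(r) nrow(r$reg_edges) > 0, logical(1)))
  if (params$cohort_mode == "union" && usable >= 2) {
    m <- build_matrix(results)
    write_matrix_triplet(m, out_dir)
    d <- jaccard_distances(m)
    emb <- embed_patients(d)
    ks <- choose_k(emb, k_range = params$k_range, rng_seed = params$rng_seed)
    cl <- if (is.null(params$k)) ks$fits[[paste0("k", ks$k)]] else
      cluster_patients(emb, params$k, rng_seed = params$rng_seed)
    reps <- cluster_representatives(cl, m, min_fraction = params$min_fraction)
    readr::write_tsv(cl$assignment, file.path(out_dir, "clusters.tsv"),
                     progress = FALSE)
    readr::write_tsv(reps, file.path(out_dir, "cluster_representatives.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(selected_k = ks$k, used_k = cl$k,
           silhouette = cl$silhouette,
           diagnostics = ks$diagnostics,
           explained_variance = emb$ev_ratio[seq_len(emb$n_components)]),
      file.path(out_dir, "cluster_diagnostics.json"), auto_unbox = TRUE,
      digits = NA)
    strat <- list(matrix = m, distances = d, embedding = emb, kselect = ks,
                  clusters = cl, representatives = reps)
  }

  # --- modularisation of the cohort signalling network ---
  sig_nodes <- unique(cohort$node_counts$node[cohort$node_counts$layer == "signalling"])
  mods <- NULL
  if (length(sig_nodes) > 1) {
    sub <- filter(gc_net$edges, .data$source %in% sig_nodes,
                  .data$target %in% sig_nodes)
    mods <- girvan_newman(signalling_network(sub, nodes = sig_nodes))
    readr::write_tsv(mods$membership, file.path(out_dir, "modules.tsv"),
                     progress = FALSE)
  }

  # --- overrepresentation of commonly perturbed nodes ---
  enrich <- NULL
  if (!is.null(annotation_gmt) && file.exists(annotation_gmt) && length(sig_nodes)) {
    enrich <- ora(sig_nodes, read_gmt(annotation_gmt), universe = gc_net$nodes)
    readr::write_tsv(enrich, file.path(out_dir, "enrichment.tsv"), progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("snpheat")),
    params = unclass(params),
    inputs = lapply(paths[file.exists(unlist(paths))],
                    function(p) unname(tools::md5sum(p))),
    n_patients = length(results),
    alpha = alpha$alpha,
    giant_component = list(nodes = length(gc_net$nodes), edges = nrow(gc_net$edges)),
    stages = c("annotate", "propagate", "cohort",
               if (!is.null(strat)) "cluster", if (!is.null(mods)) "modules",
               if (!is.null(enrich)) "enrich"),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(params = params, network = network, giant = gc_net,
                 regulons = regulons, calls = calls, surviving = surviving,
                 affected = affected, sets = sets, alpha = alpha,
                 kernel = kernel, results = results, cohort = cohort,
                 stratification = strat, modules = mods, enrichment = enrich,
                 manifest = manifest))
}

# variant records (id, chrom, pos, ref, alt) from the VCF fixed columns
vcf_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  tibble(id = fx[, "ID"], chrom = fx[, "CHROM"],
         pos = as.integer(fx[, "POS"]), ref = fx[, "REF"], alt = fx[, "ALT"])
}

# sparse triplet text export of the patient x edge matrix
write_matrix_triplet <- function(m, out_dir) {
  idx <- which(m != 0, arr.ind = TRUE)
  trip <- tibble(row = idx[, 1], col = idx[, 2], value = m[idx]) |>
    arrange(.data$row, .data$col)
  readr::write_tsv(trip, file.path(out_dir, "matrix_triplets.tsv"), progress = FALSE)
  writeLines(rownames(m), file.path(out_dir, "matrix_rows.txt"))
  writeLines(colnames(m), file.path(out_dir, "matrix_cols.txt"))
  invisible(out_dir)
}
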