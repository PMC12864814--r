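#' Synthetic fixture specification
#'
#' Describes the synthetic study: a toy genome with planted regulatory
#' variants, a directed signalling network with heavy-tailed out-degrees and
#' planted seed-to-cascade structure, a graded regulon layer with
#' cluster-specific signatures, and a patient cohort with planted cluster
#' labels. The same spec and seed always reproduce identical fixtures.
#'
#' The defaults are the desk-scale study conditions used throughout the
#' package's tests: a 500-node network with roughly 2,000 edges, 40 TFs,
#' 60 patients in 3 planted clusters, and a 5% noise-variant carriage rate.
#'
#' @param n_nodes Network nodes.
#' @param n_edges Approximate directed edge count (background edges are drawn
#'   from a heavy-tailed out-degree law to emulate signalling hubs).
#' @param n_tfs Total TFs in the regulon layer.
#' @param n_clusters Planted patient clusters.
#' @param seeds_per_cluster SNP-affected seed genes per cluster panel.
#' @param cascade_per_cluster Designed cascade relay nodes per cluster.
#' @param tfs_per_cluster Designated TFs per cluster.
#' @param targets_per_tf Targets of each designated TF.
#' @param n_patients Cohort size.
#' @param noise_rate Bernoulli carriage probability of non-panel variants.
#' @param n_noise_genes Genes reachable through noise variants (each wired to
#'   a dedicated noise TF so incidental variants perturb a few
#'   patient-specific regulatory edges, as in a real cohort).
#' @param noise_targets_per_tf Targets of each noise TF.
#' @param slot_bp Genome bases reserved per gene.
#' @param n_motifs Motif count (length-8 PFMs).
#' @return List of class `snpheat_spec`.
#' @export
fixture_spec <- function(n_nodes = 500, n_edges = 2000, n_tfs = 40,
                         n_clusters = 3, seeds_per_cluster = 5,
                         cascade_per_cluster = 3, tfs_per_cluster = 3,
                         targets_per_tf = 6, n_patients = 60,
                         noise_rate = 0.2, n_noise_genes = 12,
                         noise_targets_per_tf = 3,
                         slot_bp = 9000, n_motifs = 6) {
  spec <- list(n_nodes = n_nodes, n_edges = n_edges, n_tfs = n_tfs,
               n_clusters = n_clusters, seeds_per_cluster = seeds_per_cluster,
               cascade_per_cluster = cascade_per_cluster,
               tfs_per_cluster = tfs_per_cluster,
               targets_per_tf = targets_per_tf, n_patients = n_patients,
               noise_rate = noise_rate, n_noise_genes = n_noise_genes,
               noise_targets_per_tf = noise_targets_per_tf,
               slot_bp = slot_bp, n_motifs = n_motifs)
  reserved <- n_clusters * (seeds_per_cluster + cascade_per_cluster + tfs_per_cluster) +
    2 * (n_noise_genes + 2)
  if (reserved + 10 > n_nodes) abort("fixture spec infeasible: too few nodes")
  if (n_tfs < n_clusters * tfs_per_cluster + n_noise_genes + 2) {
    abort("fixture spec infeasible: n_tfs too small for designated + noise TFs")
  }
  if (n_clusters < 2 || n_patients < 2 * n_clusters) {
    abort("fixture spec needs >= 2 clusters and >= 2 patients per cluster")
  }
  structure(spec, class = "snpheat_spec")
}

#' Generate the signalling network and regulon fixtures
#'
#' Builds a directed network in which each planted cluster has a seed panel
#' wired into a designed cascade (relay nodes fanning into designated TFs,
#' all reachable within two hops) that receives no edges from the
#' heavy-tailed background graph, plus regulons in which each designated TF
#' carries a cluster-specific target signature. Generation-time checks
#' assert that the giant component covers at least 90% of nodes and that
#' every seed panel reaches its designated TFs within 4 directed hops.
#'
#' @param spec A [fixture_spec()].
#' @param rng_seed Integer seed.
#' @return List: `network`, `regulons`, `truth` (panels, cascades,
#'   designated TFs, reserved nodes).
#' @export
gen_network_fixture <- function(spec, rng_seed = 1) {
  with_rng(rng_seed, {
    nodes <- sprintf("P%03d", seq_len(spec$n_nodes))
    nc <- spec$n_clusters
    per <- spec$seeds_per_cluster + spec$cascade_per_cluster + spec$tfs_per_cluster
    n_noise <- spec$n_noise_genes + 2  # promoter/enhancer noise genes + miRNA hosts
    reserved <- nodes[seq_len(nc * per + 2 * n_noise)]
    noise_genes <- reserved[nc * per + seq_len(n_noise)]
    noise_tfs <- reserved[nc * per + n_noise + seq_len(n_noise)]
    background <- setdiff(nodes, reserved)
    panels <- cascades <- desig_tfs <- list()
    edges <- list()
    for (c in seq_len(nc)) {
      blk <- reserved[((c - 1) * per + 1):(c * per)]
      s <- blk[seq_len(spec$seeds_per_cluster)]
      d <- blk[spec$seeds_per_cluster + seq_len(spec$cascade_per_cluster)]
      t <- blk[spec$seeds_per_cluster + spec$cascade_per_cluster +
                 seq_len(spec$tfs_per_cluster)]
      panels[[c]] <- s
      cascades[[c]] <- c(d, t)
      desig_tfs[[c]] <- t
      edges[[length(edges) + 1]] <- tibble(
        source = rep(s, each = length(d)), target = rep(d, length(s)))
      edges[[length(edges) + 1]] <- tibble(
        source = rep(d, each = length(t)), target = rep(t, length(d)))
      # anchor the planted block to the giant component via TF out-edges
      edges[[length(edges) + 1]] <- tibble(
        source = rep(t, each = 2), target = sample_exact(background, 2 * length(t)))
    }
    # noise mini-cascades: each noise gene feeds a dedicated low-connectivity
    # TF, so incidentally carried variants perturb a small private regulon
    edges[[length(edges) + 1]] <- tibble(source = noise_genes, target = noise_tfs)
    edges[[length(edges) + 1]] <- tibble(
      source = rep(noise_tfs, each = 2),
      target = sample_exact(background, 2 * length(noise_tfs)))
    n_reserved_edges <- sum(vapply(edges, nrow, integer(1)))
    # heavy-tailed background out-degrees (signalling hubs)
    nb <- length(background)
    want <- max(spec$n_edges - n_reserved_edges, nb)
    degs <- sample(1:40, nb, replace = TRUE, prob = (1:40)^-1.5)
    degs <- pmax(1L, as.integer(round(degs * want / sum(degs))))
    bg_edges <- tibble(
      source = rep(background, degs),
      target = sample(background, sum(degs), replace = TRUE))
    edges[[length(edges) + 1]] <- distinct(bg_edges)
    net <- signalling_network(bind_rows(edges), nodes = nodes)
    gc <- giant_component(net)
    if (length(gc$nodes) < 0.9 * spec$n_nodes) {
      abort("fixture network giant component below 90% of nodes")
    }
    # reachability check: every seed reaches its designated TFs within 4 hops
    g <- network_igraph(net)
    for (c in seq_len(nc)) {
      dmat <- igraph::distances(g, v = panels[[c]], to = desig_tfs[[c]], mode = "out")
      if (any(dmat > 4)) abort("fixture: seed panel does not reach its TFs in 4 hops")
    }
    # regulons: designated TFs get cluster-specific signatures, background
    # TFs get Zipf-like target counts over a shared gene pool
    shared_pool <- sprintf("G%03d", 1:120)
    reg <- list()
    for (c in seq_len(nc)) {
      pool <- sprintf("TG_c%d_%02d", c, 1:(2 * spec$targets_per_tf))
      for (t in desig_tfs[[c]]) {
        reg[[length(reg) + 1]] <- tibble(
          tf = t, target = sample_exact(pool, spec$targets_per_tf))
      }
    }
    for (i in seq_along(noise_tfs)) {
      reg[[length(reg) + 1]] <- tibble(
        tf = noise_tfs[i],
        target = sprintf("NTG_%02d_%d", i, seq_len(spec$noise_targets_per_tf)))
    }
    bg_tfs <- sample_exact(background,
                           spec$n_tfs - nc * spec$tfs_per_cluster - length(noise_tfs))
    for (t in bg_tfs) {
      k <- sample(1:30, 1, prob = (1:30)^-1.2)
      reg[[length(reg) + 1]] <- tibble(tf = t, target = sample_exact(shared_pool, k))
    }
    reg <- bind_rows(reg) |>
      mutate(confidence = sample(c("A", "B", "C"), n(), replace = TRUE))
    list(network = net,
         regulons = regulon_set(reg),
         truth = list(panels = panels, cascades = cascades,
                      designated_tfs = desig_tfs, background_tfs = bg_tfs,
                      noise_genes = noise_genes, noise_tfs = noise_tfs,
                      reserved = reserved))
  })
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

motif_consensus <- function(motif) {
  paste(rownames(motif$log_odds)[apply(motif$log_odds, 2, which.max)], collapse = "")
}

# Generate n_motifs length-8 consensus PFMs with pairwise-distant consensi.
gen_motifs <- function(n_motifs) {
  motifs <- list()
  cons_seen <- character()
  while (length(motifs) < n_motifs) {
    cons <- rand_dna(8)
    ok <- all(vapply(c(cons_seen, revcomp(cons_seen)), function(x) {
      sum(strsplit(x, "")[[1]] != strsplit(cons, "")[[1]]) >= 3
    }, logical(1)), cons != revcomp(cons))
    if (!ok) next
    id <- sprintf("MOTIF%02d", length(motifs) + 1)
    counts <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")), 1:8)] <- 10
    motifs[[id]] <- motif_matrix(id, counts)
    cons_seen <- c(cons_seen, cons)
  }
  motifs
}

# Plant a TFBS design into `chars` (character vector genome): the motif
# consensus sits at [pos-3, pos+4], ref/alt differ at motif offset 4.
# Returns list(chars, ref, alt).
plant_tfbs <- function(chars, pos, motif, effect) {
  cons <- strsplit(motif_consensus(motif), "")[[1]]
  bases <- c("A", "C", "G", "T")
  window <- (pos - 3):(pos + 4)
  if (effect == "loss") {
    chars[window] <- cons
    ref <- cons[4]
    alt <- sample_exact(setdiff(bases, ref), 1)
  } else {
    ref <- sample_exact(setdiff(bases, cons[4]), 1)
    cons_broken <- cons
    cons_broken[4] <- ref
    chars[window] <- cons_broken
    alt <- cons[4]
  }
  list(chars = chars, ref = ref, alt = alt)
}

# Verify that a planted variant yields exactly the designed calls across all
# motifs; used for rejection sampling at generation time.
tfbs_design_ok <- function(chars, pos, vid, ref, alt, motif_id, effect, motifs) {
  genome <- Biostrings::DNAStringSet(c(chrT = paste(chars, collapse = "")))
  vr <- tibble(id = vid, chrom = "chrT", pos = pos, ref = ref, alt = alt)
  for (m in motifs) {
    call <- suppressWarnings(call_tfbs_change(vr, m, genome))
    want <- if (m$id == motif_id) effect else NA_character_
    got <- if (is.null(call)) NA_character_ else call$effect
    if (!identical(want, got)) return(FALSE)
  }
  TRUE
}

#' Generate the genome-level fixtures
#'
#' Emits a toy genome (one chromosome, one slot per gene), gene models on
#' both strands, consensus motifs, enhancer / ChIP-seq peak / miRNA-site
#' region tables, and a designed-variant table in which every TFBS or
#' miRNA-site gain/loss call is analytically certain (consensus-match
#' construction, verified by running the annotation scan at generation time
#' and re-rolling the local sequence on the rare spurious match). Designs
#' include peak-filter negative controls and strict promoter-boundary cases.
#'
#' @param spec A [fixture_spec()].
#' @param net Network fixture from [gen_network_fixture()].
#' @param rng_seed Integer seed.
#' @return List: `genome` (DNAStringSet), `gene_models`, `motifs`,
#'   `enhancers`, `peaks`, `mirna_sites`, `mirna_seeds`, `variants`,
#'   `designed_calls` (with `in_peak` and `surviving` flags).
#' @export
gen_genome_fixture <- function(spec, net, rng_seed = 1) {
  with_rng(rng_seed + 1L, {
    motifs <- gen_motifs(spec$n_motifs)
    seed_genes <- unlist(net$truth$panels)
    noise_genes <- net$truth$noise_genes[seq_len(spec$n_noise_genes)]
    mirna_genes <- net$truth$noise_genes[spec$n_noise_genes + 1:2]
    pool <- setdiff(net$network$nodes,
                    c(net$truth$reserved, net$truth$background_tfs))
    extra <- sample_exact(pool, 4)
    negctl_genes <- extra[1:2]
    boundary_genes <- extra[3:4]
    n_enh <- min(4, spec$n_noise_genes)
    genes <- tibble(
      gene = c(seed_genes, noise_genes, mirna_genes, negctl_genes, boundary_genes),
      role = c(rep("panel", length(seed_genes)),
               rep(c("noise_promoter", "noise_enhancer"),
                   c(spec$n_noise_genes - n_enh, n_enh)),
               rep("mirna", 2), rep("negative_control", 2),
               c("boundary_in", "boundary_out")))
    ng <- nrow(genes)
    slot <- spec$slot_bp
    chars <- strsplit(rand_dna(ng * slot), "")[[1]]
    g0 <- (seq_len(ng) - 1L) * slot + 1L
    strand <- rep(c("+", "-"), length.out = ng)
    # enhancer and miRNA sites sit downstream of the + strand promoter span;
    # keep their host genes on + so the intervals cannot overlap a promoter
    strand[genes$role %in% c("boundary_in", "boundary_out",
                             "noise_enhancer", "mirna")] <- "+"
    tss <- ifelse(strand == "+", g0 + 6499L, g0 + 2500L)
    fee <- ifelse(strand == "+", tss + 200L, tss - 200L)
    gene_models <- tibble(gene = genes$gene, chrom = "chrT", strand = strand,
                          tss = tss, first_exon_end = fee)
    enhancers <- genes$role == "noise_enhancer"
    enh_tbl <- tibble(chrom = "chrT", start = g0[enhancers] + 6999L,
                      end = g0[enhancers] + 7499L, name = genes$gene[enhancers],
                      strand = "*")
    mir <- genes$role == "mirna"
    mir_tbl <- tibble(chrom = "chrT", start = g0[mir] + 7599L,
                      end = g0[mir] + 7629L,
                      name = paste0(c("mir1", "mir2"), "|", genes$gene[mir]),
                      mirna = c("mir1", "mir2"), gene = genes$gene[mir],
                      strand = "*")
    mirna_seeds <- setNames(c(rand_dna(7), rand_dna(7)), c("mir1", "mir2"))

    designs <- list()
    peaks <- list()
    motif_cycle <- rep(names(motifs), length.out = ng)
    effect_cycle <- rep(c("loss", "gain"), length.out = ng)
    for (i in seq_len(ng)) {
      role <- genes$role[i]
      vid <- sprintf("rs%04d", i)
      if (role == "mirna") {
        which_m <- if (genes$gene[i] == mir_tbl$gene[1]) 1 else 2
        site <- mir_tbl[which_m, ]
        pos <- site$start + 10L
        match7 <- strsplit(revcomp(mirna_seeds[[site$mirna]]), "")[[1]]
        eff <- effect_cycle[i]
        win <- (pos - 3):(pos + 3)
        ok <- FALSE
        for (try in 1:50) {
          chars[(site$start):(site$end)] <- strsplit(rand_dna(31), "")[[1]]
          if (eff == "loss") {
            chars[win] <- match7
            ref <- match7[4]
            alt <- sample_exact(setdiff(c("A", "C", "G", "T"), ref), 1)
          } else {
            ref <- sample_exact(setdiff(c("A", "C", "G", "T"), match7[4]), 1)
            broken <- match7; broken[4] <- ref
            chars[win] <- broken
            alt <- match7[4]
          }
          site_ref <- paste(chars[site$start:site$end], collapse = "")
          site_alt <- site_ref
          substr(site_alt, pos - site$start + 1L, pos - site$start + 1L) <- alt
          m7 <- paste(match7, collapse = "")
          want_ref <- eff == "loss"
          if (grepl(m7, site_ref, fixed = TRUE) == want_ref &&
                grepl(m7, site_alt, fixed = TRUE) == !want_ref) { ok <- TRUE; break }
        }
        if (!ok) abort("fixture: could not plant a clean miRNA design")
        designs[[i]] <- tibble(variant = vid, chrom = "chrT", pos = pos,
                               ref = ref, alt = alt, element_class = "mirna_site",
                               factor = site$mirna, effect = eff,
                               gene = genes$gene[i],
                               site_start = site$start, site_end = site$end,
                               in_peak = NA)
        next
      }
      element <- switch(role, noise_enhancer = "enhancer", "promoter")
      pos <- switch(role,
                    noise_enhancer = g0[i] + 7249L,
                    boundary_in = tss[i] - 5000L,
                    boundary_out = tss[i] - 5001L,
                    if (strand[i] == "+") tss[i] - 1000L else tss[i] + 1000L)
      m <- motifs[[motif_cycle[i]]]
      eff <- effect_cycle[i]
      ok <- FALSE
      for (try in 1:50) {
        local <- (pos - 20):(pos + 20)
        chars[local] <- strsplit(rand_dna(length(local)), "")[[1]]
        planted <- plant_tfbs(chars, pos, m, eff)
        if (tfbs_design_ok(planted$chars, pos, vid, planted$ref, planted$alt,
                           m$id, eff, motifs)) {
          chars <- planted$chars
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("fixture: could not plant a clean TFBS design")
      in_peak <- role %!in% c("negative_control", "boundary_out")
      if (in_peak) {
        peaks[[length(peaks) + 1]] <- tibble(chrom = "chrT", start = pos - 12L,
                                             end = pos + 12L,
                                             name = sprintf("peak%03d", i),
                                             strand = "*")
      }
      designs[[i]] <- tibble(variant = vid, chrom = "chrT", pos = pos,
                             ref = planted$ref, alt = planted$alt,
                             element_class = element, factor = m$id,
                             effect = eff, gene = genes$gene[i],
                             site_start = pos - 7L, site_end = pos + 7L,
                             in_peak = in_peak)
    }
    designed <- bind_rows(designs) |>
      mutate(role = genes$role,
             # boundary_out sits one base outside its promoter: no element
             # assignment, hence no call, despite the planted motif change
             expected_call = .data$role != "boundary_out",
             surviving = .data$expected_call &
               (.data$element_class == "mirna_site" | .data$in_peak))
    genome <- Biostrings::DNAStringSet(c(chrT = paste(chars, collapse = "")))
    variants <- designed[, c("variant", "chrom", "pos", "ref", "alt")] |>
      rename(id = "variant")
    list(genome = genome, gene_models = gene_models, motifs = motifs,
         enhancers = enh_tbl, peaks = bind_rows(peaks), mirna_sites = mir_tbl,
         mirna_seeds = mirna_seeds, variants = variants,
         designed_calls = designed, genes = genes)
  })
}

#' Generate a patient cohort with planted cluster structure
#'
#' Each cluster's patients carry that cluster's full variant panel; every
#' other designed variant (noise, miRNA, controls) is carried independently
#' with probability `noise_rate`. Labels are recorded in the truth object.
#'
#' @param spec A [fixture_spec()].
#' @param net Network fixture (for the panel-to-gene map).
#' @param genome_fix Genome fixture (for the variant-to-gene map).
#' @param rng_seed Integer seed.
#' @return List: `genotypes` (carries tibble with `patients` attribute),
#'   `labels` (named integer vector), `gt_codes` (patient x variant genotype
#'   strings for VCF export).
#' @export
gen_cohort <- function(spec, net, genome_fix, rng_seed = 1) {
  with_rng(rng_seed + 2L, {
    patients <- sprintf("pat%03d", seq_len(spec$n_patients))
    labels <- setNames(rep(seq_len(spec$n_clusters), length.out = spec$n_patients),
                       patients)
    labels <- labels[order(names(labels))]
    dc <- genome_fix$designed_calls
    panel_variants <- lapply(net$truth$panels, function(genes) {
      dc$variant[dc$gene %in% genes & dc$role == "panel"]
    })
    other_variants <- dc$variant[dc$role != "panel"]
    gt <- matrix("0/0", spec$n_patients, nrow(dc),
                 dimnames = list(patients, dc$variant))
    for (p in patients) {
      carried <- panel_variants[[labels[[p]]]]
      noise <- other_variants[stats::runif(length(other_variants)) < spec$noise_rate]
      carried <- c(carried, noise)
      gt[p, carried] <- sample(c("0/1", "1/1"), length(carried), replace = TRUE)
    }
    idx <- which(gt != "0/0", arr.ind = TRUE)
    genotypes <- tibble(patient = rownames(gt)[idx[, 1]],
                        variant = colnames(gt)[idx[, 2]]) |>
      arrange(.data$patient, .data$variant)
    attr(genotypes, "patients") <- patients
    list(genotypes = genotypes, labels = labels, gt_codes = gt)
  })
}

#' Generate the complete fixture bundle
#'
#' Chains [gen_network_fixture()], [gen_genome_fixture()] and [gen_cohort()],
#' derives the ground truth (per-patient affected genes, designed cascades,
#' planted labels, designed calls), and verifies at generation time that the
#' annotation modules reproduce the designed calls exactly.
#'
#' @param spec A [fixture_spec()].
#' @param rng_seed Integer seed; the whole bundle is a pure function of
#'   (spec, seed).
#' @param check Run the generation-time truth/file consistency check.
#' @return List of class `snpheat_fixture` with all inputs plus `truth`.
#' @export
gen_fixture <- function(spec = fixture_spec(), rng_seed = 1, check = TRUE) {
  net <- gen_network_fixture(spec, rng_seed)
  gf <- gen_genome_fixture(spec, net, rng_seed)
  coh <- gen_cohort(spec, net, gf, rng_seed)
  surviving <- filter(gf$designed_calls, .data$surviving)
  affected_truth <- inner_join(coh$genotypes,
                               surviving[, c("variant", "gene")],
                               by = "variant") |>
    distinct(.data$patient, .data$gene)
  truth <- list(
    panels = net$truth$panels,
    cascades = net$truth$cascades,
    designated_tfs = net$truth$designated_tfs,
    labels = coh$labels,
    designed_calls = gf$designed_calls,
    affected = lapply(split(affected_truth$gene,
                            factor(affected_truth$patient,
                                   levels = attr(coh$genotypes, "patients"))),
                      sort))
  fix <- structure(list(spec = spec, rng_seed = rng_seed,
                        network = net$network, regulons = net$regulons,
                        genome = gf$genome, gene_models = gf$gene_models,
                        motifs = gf$motifs, enhancers = gf$enhancers,
                        peaks = gf$peaks, mirna_sites = gf$mirna_sites,
                        mirna_seeds = gf$mirna_seeds, variants = gf$variants,
                        genotypes = coh$genotypes, gt_codes = coh$gt_codes,
                        truth = truth),
                   class = "snpheat_fixture")
  if (check) check_fixture(fix)
  fix
}

# generation-time self-check: the annotation pipeline must reproduce the
# designed calls and affected sets exactly
check_fixture <- function(fix) {
  promoters <- build_promoters(fix$gene_models)
  calls <- suppressWarnings(
    annotate_variants(fix$variants, fix$genome, fix$motifs, promoters,
                      enhancers = fix$enhancers, mirna_sites = fix$mirna_sites,
                      mirna_seeds = fix$mirna_seeds))
  designed <- fix$truth$designed_calls |>
    filter(.data$expected_call) |>
    select("variant", "element_class", "factor", "effect", "gene") |>
    arrange(.data$variant, .data$factor)
  got <- calls |>
    select("variant", "element_class", "factor", "effect", "gene") |>
    arrange(.data$variant, .data$factor)
  if (!isTRUE(all.equal(as.data.frame(designed), as.data.frame(got),
                        check.attributes = FALSE))) {
    abort("fixture self-check failed: emitted calls differ from designed calls")
  }
  surviving <- epigenetic_filter(calls, fix$peaks)
  want <- sort(fix$truth$designed_calls$variant[fix$truth$designed_calls$surviving])
  if (!identical(sort(unique(surviving$variant)), want)) {
    abort("fixture self-check failed: peak filter outcome differs from design")
  }
  invisible(TRUE)
}

#' Write a fixture bundle to an input directory
#'
#' Emits every pipeline input in its on-disk dialect: edge-list TSV, regulon
#' TSV (with a few deliberately off-grade rows to exercise the grade
#' filter), VCF 4.2, FASTA, gene-model TSV, JASPAR PFM text, BED files and a
#' truth JSON.
#'
#' @param fix A `snpheat_fixture`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(fix$network, file.path(dir, "network.tsv"))
  reg_out <- bind_rows(as_tibble(fix$regulons),
                       tibble(tf = fix$regulons$tf[1],
                              target = paste0("DROPPED", 1:3),
                              confidence = "D"))
  write_regulons(reg_out, file.path(dir, "regulons.tsv"))
  write_fasta(fix$genome, file.path(dir, "genome.fa"))
  readr::write_tsv(fix$gene_models, file.path(dir, "gene_models.tsv"),
                   progress = FALSE)
  write_jaspar(fix$motifs, file.path(dir, "motifs.jaspar"))
  write_bed(fix$enhancers, file.path(dir, "enhancers.bed"))
  write_bed(fix$peaks, file.path(dir, "peaks.bed"))
  write_bed(fix$mirna_sites[, c("chrom", "start", "end", "name")],
            file.path(dir, "mirna_sites.bed"))
  readr::write_tsv(tibble(mirna = names(fix$mirna_seeds), seed = fix$mirna_seeds),
                   file.path(dir, "mirna_seeds.tsv"), progress = FALSE)
  write_vcf(fix$variants, fix$gt_codes, file.path(dir, "genotypes.vcf"))
  jsonlite::write_json(
    list(labels = as.list(fix$truth$labels),
         panels = fix$truth$panels,
         cascades = fix$truth$cascades,
         designated_tfs = fix$truth$designated_tfs,
         affected = fix$truth$affected,
         designed_calls = fix$truth$designed_calls),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

# minimal VCF 4.2 writer for the fixture cohort
write_vcf <- function(variants, gt_codes, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrT>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(gt_codes)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i], variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT",
            gt_codes[, variants$id[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
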