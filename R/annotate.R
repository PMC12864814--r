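#' Build promoter regions from gene models
#'
#' A promoter spans from `upstream_bp` upstream of the transcription start
#' site (TSS) through the end of the first exon, strand-aware: on the plus
#' strand it runs from `tss - upstream_bp` to `first_exon_end`; on the minus
#' strand from `first_exon_end` to `tss + upstream_bp`. Intervals are clipped
#' at position 1 (and at the chromosome end when lengths are supplied).
#'
#' @param gene_models Tibble from [read_gene_models()].
#' @param upstream_bp Bases upstream of the TSS, default 5000.
#' @param chrom_sizes Optional named vector of chromosome lengths for clipping.
#' @return Region tibble (`chrom`, `start`, `end`, `name` = gene, `strand`),
#'   1-based closed.
#' @export
build_promoters <- function(gene_models, upstream_bp = 5000, chrom_sizes = NULL) {
  gm <- as_tibble(gene_models)
  ok <- ifelse(gm$strand == "+", gm$first_exon_end >= gm$tss,
               gm$first_exon_end <= gm$tss)
  if (any(!ok)) {
    warn(paste0("build_promoters: rejecting ", sum(!ok),
                " model(s) whose first-exon end lies upstream of the TSS: ",
                paste(head(gm$gene[!ok], 5), collapse = ", ")))
    gm <- gm[ok, , drop = FALSE]
  }
  start <- ifelse(gm$strand == "+", gm$tss - upstream_bp, gm$first_exon_end)
  end <- ifelse(gm$strand == "+", gm$first_exon_end, gm$tss + upstream_bp)
  start <- pmax(start, 1L)
  if (!is.null(chrom_sizes)) end <- pmin(end, chrom_sizes[gm$chrom])
  tibble(chrom = gm$chrom, start = as.integer(start), end = as.integer(end),
         name = gm$gene, strand = gm$strand)
}

# Overlap join between variant spans and a region tibble; returns indices.
overlap_pairs <- function(v_chrom, v_start, v_end, regions) {
  out <- list()
  for (chr in unique(v_chrom)) {
    vi <- which(v_chrom == chr)
    ri <- which(regions$chrom == chr)
    if (!length(ri)) next
    q <- IRanges::IRanges(v_start[vi], v_end[vi])
    s <- IRanges::IRanges(regions$start[ri], regions$end[ri])
    hits <- IRanges::findOverlaps(q, s)
    out[[chr]] <- data.frame(variant = vi[S4Vectors::queryHits(hits)],
                             region = ri[S4Vectors::subjectHits(hits)])
  }
  if (!length(out)) return(data.frame(variant = integer(), region = integer()))
  do.call(rbind, out)
}

#' Assign variants to regulatory elements
#'
#' Each variant is intersected with promoters, enhancers and miRNA target
#' sites; a variant can receive several assignments (for example, the
#' promoter of one gene and an enhancer annotated to another). Variants
#' overlapping nothing receive no rows and drop out of downstream annotation.
#'
#' @param variants Tibble with columns `id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param promoters,enhancers,mirna_sites Region tibbles (1-based closed)
#'   whose `name` column carries the annotated gene; for miRNA sites the name
#'   is `"<mirna>|<gene>"` (or supply `mirna`/`gene` columns).
#' @return Tibble with one row per (variant, element) assignment: `variant`,
#'   `element_class`, `factor_hint` (miRNA for sites, NA otherwise), `gene`,
#'   `region_start`, `region_end`.
#' @export
assign_regions <- function(variants, promoters, enhancers = NULL,
                           mirna_sites = NULL) {
  v <- as_tibble(variants)
  v_end <- v$pos + nchar(v$ref) - 1L
  one <- function(regions, class) {
    if (is.null(regions) || nrow(regions) == 0) return(NULL)
    hp <- overlap_pairs(v$chrom, v$pos, v_end, regions)
    if (!nrow(hp)) return(NULL)
    r <- regions[hp$region, , drop = FALSE]
    if (class == "mirna_site") {
      if (!all(c("mirna", "gene") %in% names(r))) {
        parts <- strsplit(r$name, "|", fixed = TRUE)
        r$mirna <- vapply(parts, `[[`, character(1), 1)
        r$gene <- vapply(parts, function(p) p[[min(2, length(p))]], character(1))
      }
      fac <- r$mirna
      gene <- r$gene
    } else {
      fac <- NA_character_
      gene <- r$name
    }
    tibble(variant = v$id[hp$variant], element_class = class,
           factor_hint = fac, gene = gene,
           region_start = r$start, region_end = r$end)
  }
  bind_rows(one(promoters, "promoter"), one(enhancers, "enhancer"),
            one(mirna_sites, "mirna_site"))
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Best log-odds score of motif over all L-windows of seq (both strands).
# Non-ACGT characters score -Inf in their window.
best_motif_score <- function(seq, motif) {
  L <- motif$length
  n <- nchar(seq)
  if (n < L) return(-Inf)
  best <- -Inf
  for (s in c(seq, revcomp(seq))) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    for (st in 1:(n - L + 1)) {
      win <- idx[st:(st + L - 1)]
      sc <- if (anyNA(win)) -Inf else
        sum(motif$log_odds[cbind(win, seq_len(L))])
      if (sc > best) best <- sc
    }
  }
  best
}

# Start (in local ref coordinates) of the best-scoring forward/reverse window.
best_motif_window <- function(seq, motif) {
  L <- motif$length
  n <- nchar(seq)
  best <- -Inf; best_at <- 1L
  fwd <- strsplit(seq, "")[[1]]
  rev_ <- strsplit(revcomp(seq), "")[[1]]
  idx_f <- match(fwd, c("A", "C", "G", "T"))
  idx_r <- match(rev_, c("A", "C", "G", "T"))
  for (st in 1:(n - L + 1)) {
    for (strand in 1:2) {
      win <- if (strand == 1) idx_f[st:(st + L - 1)] else idx_r[st:(st + L - 1)]
      sc <- if (anyNA(win)) -Inf else sum(motif$log_odds[cbind(win, seq_len(L))])
      at <- if (strand == 1) st else n - (st + L - 1) + 1L
      if (sc > best) { best <- sc; best_at <- at }
    }
  }
  list(score = best, start = best_at)
}

# Extract 1-based closed subsequence from a DNAStringSet, or NULL if out of range
extract_seq <- function(genome, chrom, start, end) {
  if (chrom %!in% names(genome)) return(NULL)
  len <- Biostrings::width(genome[chrom])
  if (start < 1 || end > len) return(NULL)
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Call a TFBS gain or loss at one variant
#'
#' Scores the motif over every window of motif length that contains the
#' variant, on both strands, separately for the reference and alternate
#' alleles. A site is "present" when the best log-odds score reaches
#' `score_fraction` of the motif's maximum achievable score. A call is a
#' `loss` when the site is present under the reference allele only, a `gain`
#' when present under the alternate only, and no call otherwise.
#'
#' @param variant One-row tibble or list with `id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param motif A motif from [motif_matrix()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param score_fraction Fraction of the maximum motif score that defines
#'   site presence (default 0.8).
#' @return One-row tibble (`variant`, `factor`, `effect`, `site_start`,
#'   `site_end`, `ref_score`, `alt_score`) or `NULL` when there is no change.
#' @export
call_tfbs_change <- function(variant, motif, genome, score_fraction = 0.8) {
  L <- motif$length
  pos <- variant$pos
  nr <- nchar(variant$ref)
  ref_seq <- extract_seq(genome, variant$chrom, pos - (L - 1L), pos + nr - 1L + (L - 1L))
  if (is.null(ref_seq)) {
    warn(paste0("call_tfbs_change: variant ", variant$id,
                " too close to the sequence edge; skipped"))
    return(NULL)
  }
  obs_ref <- substr(ref_seq, L, L + nr - 1L)
  if (obs_ref != toupper(variant$ref)) {
    warn(paste0("call_tfbs_change: reference allele mismatch for ", variant$id,
                " (genome has ", obs_ref, "); skipped"))
    return(NULL)
  }
  alt_seq <- paste0(substr(ref_seq, 1, L - 1L), toupper(variant$alt),
                    substr(ref_seq, L + nr, nchar(ref_seq)))
  thr <- score_fraction * motif$max_score
  ref_best <- best_motif_window(ref_seq, motif)
  alt_best <- best_motif_window(alt_seq, motif)
  ref_present <- ref_best$score >= thr
  alt_present <- alt_best$score >= thr
  if (ref_present == alt_present) return(NULL)
  effect <- if (ref_present) "loss" else "gain"
  win <- if (ref_present) ref_best else alt_best
  site_start <- pos - (L - 1L) + (win$start - 1L)
  tibble(variant = variant$id, factor = motif$id, effect = effect,
         site_start = as.integer(site_start),
         site_end = as.integer(min(site_start + L - 1L, pos + nr - 1L + (L - 1L))),
         ref_score = ref_best$score, alt_score = alt_best$score)
}

#' Call a miRNA target-site gain or loss at one variant
#'
#' A target site is "present" when the reverse complement of the miRNA seed
#' (miRNA nucleotides 2-8, a 7-mer) occurs as an exact substring of the site
#' sequence. Gain and loss are decided exactly as for TFBS calls.
#'
#' @param variant One-row tibble or list with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param mirna_seed The 7-mer seed sequence (5'->3').
#' @param genome A [Biostrings::DNAStringSet].
#' @param site One-row region (`chrom`, `start`, `end`) of the annotated site.
#' @return One-row tibble (`variant`, `effect`, `site_start`, `site_end`) or
#'   `NULL` when there is no change.
#' @export
call_mirna_change <- function(variant, mirna_seed, genome, site) {
  if (nchar(mirna_seed) < 7) abort("miRNA seed must be at least 7 nucleotides")
  match7 <- revcomp(toupper(mirna_seed))
  ref_seq <- extract_seq(genome, site$chrom, site$start, site$end)
  if (is.null(ref_seq)) return(NULL)
  pos <- variant$pos
  nr <- nchar(variant$ref)
  if (pos < site$start || pos + nr - 1L > site$end) return(NULL)
  off <- pos - site$start + 1L
  if (substr(ref_seq, off, off + nr - 1L) != toupper(variant$ref)) {
    warn(paste0("call_mirna_change: reference allele mismatch for ", variant$id))
    return(NULL)
  }
  alt_seq <- paste0(substr(ref_seq, 1, off - 1L), toupper(variant$alt),
                    substr(ref_seq, off + nr, nchar(ref_seq)))
  ref_present <- grepl(match7, ref_seq, fixed = TRUE)
  alt_present <- grepl(match7, alt_seq, fixed = TRUE)
  if (ref_present == alt_present) return(NULL)
  tibble(variant = variant$id,
         effect = if (ref_present) "loss" else "gain",
         site_start = site$start, site_end = site$end)
}

#' Annotate variants with binding-site gains and losses
#'
#' Drives the full annotation: assigns variants to regulatory elements, then
#' scans every motif at promoter/enhancer assignments and the annotated seed
#' at miRNA-site assignments.
#'
#' @inheritParams assign_regions
#' @inheritParams call_tfbs_change
#' @param motifs Named list of motifs from [read_jaspar()].
#' @param mirna_seeds Named character vector of seeds from
#'   [read_mirna_seeds()]; required when `mirna_sites` is supplied.
#' @return Binding-call tibble: `variant`, `element_class`, `factor`, `effect`,
#'   `gene`, `chrom`, `site_start`, `site_end`.
#' @export
annotate_variants <- function(variants, genome, motifs, promoters,
                              enhancers = NULL, mirna_sites = NULL,
                              mirna_seeds = NULL, score_fraction = 0.8) {
  v <- as_tibble(variants)
  asg <- assign_regions(v, promoters, enhancers, mirna_sites)
  if (is.null(asg) || nrow(asg) == 0) {
    return(tibble(variant = character(), element_class = character(),
                  factor = character(), effect = character(), gene = character(),
                  chrom = character(), site_start = integer(), site_end = integer()))
  }
  vmap <- split(seq_len(nrow(v)), v$id)
  calls <- purrr::pmap(asg, function(variant, element_class, factor_hint, gene,
                                     region_start, region_end) {
    vr <- v[vmap[[variant]][1], ]
    if (element_class %in% c("promoter", "enhancer")) {
      hits <- purrr::compact(lapply(motifs, function(m) {
        call_tfbs_change(vr, m, genome, score_fraction = score_fraction)
      }))
      if (!length(hits)) return(NULL)
      bind_rows(hits) |>
        mutate(element_class = element_class, gene = gene, chrom = vr$chrom)
    } else {
      if (is.null(mirna_seeds) || factor_hint %!in% names(mirna_seeds)) {
        warn(paste0("annotate_variants: no seed sequence for miRNA ", factor_hint))
        return(NULL)
      }
      hit <- call_mirna_change(vr, mirna_seeds[[factor_hint]], genome,
                               list(chrom = vr$chrom, start = region_start,
                                    end = region_end))
      if (is.null(hit)) return(NULL)
      hit |> mutate(element_class = "mirna_site", factor = factor_hint,
                    gene = gene, chrom = vr$chrom)
    }
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    return(tibble(variant = character(), element_class = character(),
                  factor = character(), effect = character(), gene = character(),
                  chrom = character(), site_start = integer(), site_end = integer()))
  }
  out |>
    select("variant", "element_class", "factor", "effect", "gene", "chrom",
           "site_start", "site_end") |>
    distinct() |>
    arrange(.data$variant, .data$element_class, .data$factor, .data$gene)
}

#' Filter binding calls for epigenetic activity
#'
#' TFBS calls (promoter and enhancer classes) survive only when their site
#' interval overlaps at least one ChIP-seq peak in the union of the supplied
#' peak sets; miRNA-site calls pass through unfiltered.
#'
#' @param calls Binding-call tibble from [annotate_variants()].
#' @param peaks Region tibble (union of all peak files), 1-based closed.
#' @return The surviving subset of `calls`.
#' @export
epigenetic_filter <- function(calls, peaks) {
  if (nrow(calls) == 0) return(calls)
  tfbs <- calls$element_class %in% c("promoter", "enhancer")
  if (is.null(peaks) || nrow(peaks) == 0) {
    warn("epigenetic_filter: empty peak union; ALL TFBS calls dropped")
    return(calls[!tfbs, , drop = FALSE])
  }
  keep <- !tfbs
  if (any(tfbs)) {
    sub <- calls[tfbs, , drop = FALSE]
    hp <- overlap_pairs(sub$chrom, sub$site_start, sub$site_end, peaks)
    keep[which(tfbs)[unique(hp$variant)]] <- TRUE
  }
  calls[keep, , drop = FALSE]
}

#' Collect per-patient SNP-affected genes
#'
#' Joins carried variants to surviving binding calls: a patient's affected
#' set is the union of genes hit through any surviving call of any carried
#' variant. Provenance (variant, factor, effect, element class) is retained;
#' a gene appears once per patient in the derived sets even when hit by
#' several variants.
#'
#' @param genotypes Carries tibble from [read_genotypes()].
#' @param calls Surviving binding calls from [epigenetic_filter()].
#' @return Provenance tibble (`patient`, `gene`, `variant`, `factor`,
#'   `effect`, `element_class`) with attribute `patients` (all patient ids).
#' @export
collect_affected <- function(genotypes, calls) {
  out <- inner_join(genotypes, calls, by = "variant",
                    relationship = "many-to-many") |>
    select("patient", "gene", "variant", "factor", "effect", "element_class") |>
    distinct() |>
    arrange(.data$patient, .data$gene, .data$variant)
  attr(out, "patients") <- attr(genotypes, "patients") %||% sort(unique(genotypes$patient))
  out
}

#' @rdname collect_affected
#' @param affected Provenance tibble from [collect_affected()].
#' @return `affected_sets()`: named list mapping every patient (including
#'   those with no affected genes) to a character vector of gene ids.
#' @export
affected_sets <- function(affected) {
  patients <- attr(affected, "patients") %||% sort(unique(affected$patient))
  sets <- split(affected$gene, factor(affected$patient, levels = patients))
  lapply(sets, function(g) sort(unique(g)))
}
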