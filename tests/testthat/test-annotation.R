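# A consensus motif with counts 10/0 and pseudocount 0.5 only reaches 80% of
# its maximum score on an exact match, so "site present" means the consensus
# (or its reverse complement) occurs in a window containing the variant.
consensus_motif <- function(cons, id = "M") {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, nchar(cons), dimnames = list(bases, NULL))
  counts[cbind(match(strsplit(cons, "")[[1]], bases), seq_len(nchar(cons)))] <- 10
  motif_matrix(id, counts)
}

test_that("promoters follow the 5kb-upstream-to-first-exon-end rule on both strands", {
  gm <- tibble::tibble(gene = c("g+", "g-", "gclip"), chrom = "c1",
                       strand = c("+", "-", "+"),
                       tss = c(10001, 20000, 3000),
                       first_exon_end = c(10400, 19600, 3100))
  pr <- build_promoters(gm)
  # + strand: TSS 10001 - 5000 .. first-exon end (0-based half-open [5000,10400))
  expect_equal(pr$start[pr$name == "g+"], 5001)
  expect_equal(pr$end[pr$name == "g+"], 10400)
  # - strand mirror: [19599,25000) half-open == 1-based 19600..25000
  expect_equal(pr$start[pr$name == "g-"], 19600)
  expect_equal(pr$end[pr$name == "g-"], 25000)
  # clamp at chromosome start
  expect_equal(pr$start[pr$name == "gclip"], 1)

  bad <- tibble::tibble(gene = "gx", chrom = "c1", strand = "+",
                        tss = 5000, first_exon_end = 4000)
  expect_warning(out <- build_promoters(bad), "rejecting")
  expect_equal(nrow(out), 0)
})

test_that("variants can hit multiple elements or none", {
  v <- tibble::tibble(id = c("v1", "v2", "v3"), chrom = "c1",
                      pos = c(6000, 20000, 99999), ref = "A", alt = "G")
  prom <- tibble::tibble(chrom = "c1", start = 5001, end = 10400,
                         name = "gene1", strand = "+")
  enh <- tibble::tibble(chrom = "c1", start = c(19900, 19950),
                        end = c(20100, 20050),
                        name = c("geneE1", "geneE2"), strand = "*")
  asg <- assign_regions(v, prom, enhancers = enh)
  expect_equal(asg$gene[asg$variant == "v1"], "gene1")
  expect_setequal(asg$gene[asg$variant == "v2"], c("geneE1", "geneE2"))
  expect_false("v3" %in% asg$variant)
})

test_that("TFBS calls detect loss, gain and reverse-strand sites with hand-scored PWMs", {
  m <- consensus_motif("ACGT")
  # one mismatch scores 3*log(3.5) + log(1/6) < 0.8 * 4*log(3.5): presence
  # needs the exact consensus
  mism <- 3 * log(10.5 / 12 / 0.25) + log(0.5 / 12 / 0.25)
  expect_lt(mism, 0.8 * m$max_score)
  genome <- Biostrings::DNAStringSet(c(c1 = "TTTTTACGTTTTTT"))
  v <- tibble::tibble(id = "v1", chrom = "c1", pos = 8, ref = "G", alt = "T")
  call <- call_tfbs_change(v, m, genome)
  expect_equal(call$effect, "loss")
  # a ref allele that contradicts the genome is skipped with a warning
  v2 <- tibble::tibble(id = "v2", chrom = "c1", pos = 8, ref = "C", alt = "A")
  expect_warning(expect_null(call_tfbs_change(v2, m, genome)), "mismatch")
  # gain is the mirror: ref lacks the site, alt completes it
  genome3 <- Biostrings::DNAStringSet(c(c1 = "TTTTTACTTTTTTT"))
  v3 <- tibble::tibble(id = "v3", chrom = "c1", pos = 8, ref = "T", alt = "G")
  expect_equal(call_tfbs_change(v3, m, genome3)$effect, "gain")

  # reverse-complement detection: AACG present only as CGTT on the + text
  m2 <- consensus_motif("AACG")
  genome4 <- Biostrings::DNAStringSet(c(c1 = "TTTTTCGTTTTTTT"))
  v4 <- tibble::tibble(id = "v4", chrom = "c1", pos = 7, ref = "G", alt = "C")
  expect_equal(call_tfbs_change(v4, m2, genome4)$effect, "loss")

  # degenerate same-allele input cannot change anything
  v5 <- tibble::tibble(id = "v5", chrom = "c1", pos = 8, ref = "G", alt = "G")
  expect_null(call_tfbs_change(v5, m, genome))
  # too close to the sequence edge
  v6 <- tibble::tibble(id = "v6", chrom = "c1", pos = 1, ref = "T", alt = "A")
  expect_warning(expect_null(call_tfbs_change(v6, m, genome)), "edge")
})

test_that("swapping ref and alt flips every TFBS and miRNA call (antisymmetry)", {
  fix <- small_fixture()
  promoters <- build_promoters(fix$gene_models)
  fwd <- suppressWarnings(
    annotate_variants(fix$variants, fix$genome, fix$motifs, promoters,
                      enhancers = fix$enhancers, mirna_sites = fix$mirna_sites,
                      mirna_seeds = fix$mirna_seeds))
  swapped <- dplyr::mutate(fix$variants, tmp = ref, ref = alt, alt = tmp)[, 1:5]
  # swapped reference alleles no longer match the genome, so scan per variant
  # with a genome patched to the alt allele
  rev <- purrr::map_dfr(seq_len(nrow(swapped)), function(i) {
    v <- swapped[i, ]
    g <- as.character(fix$genome[[v$chrom]])
    substr(g, v$pos, v$pos + nchar(v$ref) - 1) <- v$ref
    patched <- Biostrings::DNAStringSet(stats::setNames(g, v$chrom))
    suppressWarnings(
      annotate_variants(v, patched, fix$motifs, promoters,
                        enhancers = fix$enhancers, mirna_sites = fix$mirna_sites,
                        mirna_seeds = fix$mirna_seeds))
  })
  both <- dplyr::inner_join(fwd, rev, by = c("variant", "element_class", "factor", "gene"),
                            suffix = c("_fwd", "_rev"))
  expect_equal(nrow(both), nrow(fwd))
  expect_true(all(ifelse(both$effect_fwd == "gain", "loss", "gain") == both$effect_rev))
})

test_that("tightening score_fraction only removes calls, never flips them", {
  fix <- small_fixture()
  promoters <- build_promoters(fix$gene_models)
  loose <- suppressWarnings(
    annotate_variants(fix$variants, fix$genome, fix$motifs, promoters,
                      enhancers = fix$enhancers, score_fraction = 0.8))
  tight <- suppressWarnings(
    annotate_variants(fix$variants, fix$genome, fix$motifs, promoters,
                      enhancers = fix$enhancers, score_fraction = 0.95))
  key <- function(x) paste(x$variant, x$factor, x$gene, x$element_class)
  common <- dplyr::inner_join(loose, tight,
                              by = c("variant", "factor", "gene", "element_class"))
  expect_true(all(common$effect.x == common$effect.y))
})

test_that("miRNA seed matching calls gain and loss by exact 7-mer presence", {
  seed <- "GAAAGCT"                 # match site = reverse complement AGCTTTC
  site <- list(chrom = "c1", start = 5, end = 24)
  g <- paste0("TTTT", "TTTAGCTTTCTTTTTTTTTT")
  genome <- Biostrings::DNAStringSet(c(c1 = g))
  v_loss <- tibble::tibble(id = "v1", chrom = "c1", pos = 11, ref = "T", alt = "G")
  expect_equal(call_mirna_change(v_loss, seed, genome, site)$effect, "loss")
  g2 <- paste0("TTTT", "TTTAGCATTCTTTTTTTTTT")
  genome2 <- Biostrings::DNAStringSet(c(c1 = g2))
  v_gain <- tibble::tibble(id = "v2", chrom = "c1", pos = 11, ref = "A", alt = "T")
  expect_equal(call_mirna_change(v_gain, seed, genome2, site)$effect, "gain")
  v_none <- tibble::tibble(id = "v3", chrom = "c1", pos = 20, ref = "T", alt = "A")
  expect_null(call_mirna_change(v_none, seed, genome2, site))
  expect_error(call_mirna_change(v_none, "ACGT", genome2, site), "7")
})

test_that("the peak filter keeps overlapping TFBS calls and all miRNA calls", {
  calls <- tibble::tibble(
    variant = c("v1", "v2", "v3"),
    element_class = c("promoter", "enhancer", "mirna_site"),
    factor = "f", effect = "loss", gene = "g", chrom = "c1",
    site_start = c(101, 101, 101), site_end = c(110, 110, 110))
  # half-open BED [105,200) overlaps 1-based 106..200: site 101..110 overlaps
  peaks <- tibble::tibble(chrom = "c1", start = 106, end = 200, name = "p")
  kept <- epigenetic_filter(calls, peaks)
  expect_setequal(kept$variant, c("v1", "v2", "v3"))
  # BED [110,200) -> 1-based 111..200: no overlap with 101..110
  peaks2 <- tibble::tibble(chrom = "c1", start = 111, end = 200, name = "p")
  kept2 <- epigenetic_filter(calls, peaks2)
  expect_setequal(kept2$variant, "v3")  # only the miRNA call passes
  expect_warning(none <- epigenetic_filter(calls, peaks[0, ]), "ALL TFBS")
  expect_setequal(none$variant, "v3")
  # output is always a subset of input
  expect_true(all(kept2$variant %in% calls$variant))
})

test_that("affected sets union genes over carried variants with provenance", {
  gt <- tibble::tibble(patient = c("p1", "p1", "p2"),
                       variant = c("rs1", "rs2", "rs9"))
  attr(gt, "patients") <- c("p1", "p2", "p3")
  calls <- tibble::tibble(variant = c("rs1", "rs2"),
                          element_class = c("promoter", "enhancer"),
                          factor = c("TF1", "TF2"), effect = c("loss", "gain"),
                          gene = c("G", "G"), chrom = "c1",
                          site_start = 1L, site_end = 10L)
  aff <- collect_affected(gt, calls)
  sets <- affected_sets(aff)
  expect_equal(sets$p1, "G")                       # one gene, two provenances
  expect_equal(nrow(aff[aff$patient == "p1", ]), 2)
  expect_equal(sets$p2, character(0))              # carried variant, no call
  expect_equal(sets$p3, character(0))              # carries nothing
})

test_that("fixture cohort affected sets equal the designed ground truth", {
  fix <- small_fixture()
  promoters <- build_promoters(fix$gene_models)
  calls <- suppressWarnings(
    annotate_variants(fix$variants, fix$genome, fix$motifs, promoters,
                      enhancers = fix$enhancers, mirna_sites = fix$mirna_sites,
                      mirna_seeds = fix$mirna_seeds))
  surviving <- epigenetic_filter(calls, fix$peaks)
  sets <- affected_sets(collect_affected(fix$genotypes, surviving))
  expect_equal(sets, fix$truth$affected)
})
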