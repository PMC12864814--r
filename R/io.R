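#' Construct a directed signalling network
#'
#' A signalling network is the substrate for heat diffusion: a set of protein
#' nodes and directed edges. Duplicate (source, target) pairs are collapsed;
#' self-loops are retained (they contribute to out-degree). Extra columns on
#' the edge table (sign, interaction type) are carried along but ignored by
#' propagation.
#'
#' @param edges Data frame with character columns `source` and `target`.
#' @param nodes Optional character vector of node identifiers; defaults to the
#'   union of edge endpoints. Isolated nodes may be added here.
#' @return An object of class `snpheat_network` with elements `edges`
#'   (a tibble) and `nodes` (character).
#' @export
signalling_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    abort("edge table must have `source` and `target` columns")
  }
  edges <- edges |>
    mutate(source = as.character(.data$source), target = as.character(.data$target)) |>
    distinct(.data$source, .data$target, .keep_all = TRUE)
  if (any(is.na(edges$source) | is.na(edges$target) |
            edges$source == "" | edges$target == "")) {
    abort("edge endpoints must be non-empty identifiers")
  }
  nodes <- sort(unique(c(edges$source, edges$target, as.character(nodes))))
  structure(list(edges = edges, nodes = nodes), class = "snpheat_network")
}

#' @export
print.snpheat_network <- function(x, ...) {
  cat("<snpheat_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges\n", sep = "")
  invisible(x)
}

#' Read a directed edge list
#'
#' Reads a two-column (or more) delimited edge list into a
#' [signalling_network()]. Duplicate edges are dropped and the retained
#' node/edge counts are reported.
#'
#' @param path Path to a TSV/CSV edge list.
#' @param source_col,target_col Names of the source and target columns.
#' @param col_names Whether the file has a header row (passed to readr). When
#'   `FALSE` the first two columns are used as source and target.
#' @param delim Field delimiter, default tab.
#' @return A `snpheat_network`.
#' @export
read_network <- function(path, source_col = "source", target_col = "target",
                         col_names = TRUE, delim = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_delim(path, delim = delim, col_names = col_names,
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort(paste0("empty edge list: ", path))
  if (!isTRUE(col_names)) {
    source_col <- names(df)[1]
    target_col <- names(df)[2]
  }
  for (col in c(source_col, target_col)) {
    if (col %!in% names(df)) {
      abort(paste0("edge list ", path, " is missing required column `", col, "`"))
    }
  }
  df <- rename(df, source = !!source_col, target = !!target_col)
  n_in <- nrow(df)
  net <- signalling_network(df)
  inform(paste0("read_network: ", length(net$nodes), " nodes, ", nrow(net$edges),
                " edges (", n_in - nrow(net$edges), " duplicates dropped)"))
  net
}

#' Largest weakly-connected component of a network
#'
#' Propagation and null-seed sampling operate on the giant component, the
#' largest set of nodes mutually reachable when edge direction is ignored.
#'
#' @param network A `snpheat_network`.
#' @return A `snpheat_network` restricted to the giant component.
#' @export
giant_component <- function(network) {
  g <- network_igraph(network, directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  edges <- filter(network$edges, .data$source %in% keep, .data$target %in% keep)
  signalling_network(edges, nodes = keep)
}

# igraph view of a snpheat_network (isolated nodes preserved)
network_igraph <- function(network, directed = TRUE) {
  igraph::graph_from_data_frame(network$edges[, c("source", "target")],
                                directed = directed,
                                vertices = data.frame(name = network$nodes))
}

# out-degrees over all nodes (0 for sinks)
out_degrees <- function(network) {
  d <- table(factor(network$edges$source, levels = network$nodes))
  setNames(as.integer(d), network$nodes)
}

#' Write a network to disk
#'
#' @param network A `snpheat_network`.
#' @param path Output path.
#' @param format `"tsv"` (source/target columns), `"sif"` (Cytoscape simple
#'   interaction format) or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(network$edges[, c("source", "target")], path, progress = FALSE)
  } else if (format == "sif") {
    lines <- paste(network$edges$source, "directed", network$edges$target, sep = "\t")
    iso <- setdiff(network$nodes, c(network$edges$source, network$edges$target))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(network_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a TF-target regulon table
#'
#' Reads a delimited table with columns `tf`, `target` and `confidence` and
#' keeps records whose evidence grade is in `allowed_grades`. Per-TF target
#' sets are deduplicated (keeping the best grade, A < B < C).
#'
#' @param path Path to the regulon TSV.
#' @param allowed_grades Evidence grades to retain, default A/B/C.
#' @return A tibble with columns `tf`, `target`, `confidence` and class
#'   `snpheat_regulons`.
#' @export
read_regulons <- function(path, allowed_grades = c("A", "B", "C")) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("tf", "target", "confidence")) {
    if (col %!in% names(df)) {
      abort(paste0("regulon table ", path, " is missing required column `", col, "`"))
    }
  }
  regulon_set(df, allowed_grades = allowed_grades)
}

#' @rdname read_regulons
#' @param records Data frame with columns `tf`, `target`, `confidence`.
#' @export
regulon_set <- function(records, allowed_grades = c("A", "B", "C")) {
  df <- as_tibble(records) |>
    mutate(tf = as.character(.data$tf), target = as.character(.data$target),
           confidence = as.character(.data$confidence))
  unknown <- setdiff(unique(df$confidence), c("A", "B", "C", "D", "E"))
  bad <- df$confidence %!in% allowed_grades
  if (length(unknown)) {
    warn(paste0("regulons: dropping ", sum(df$confidence %in% unknown),
                " records with unknown grade(s): ",
                paste(unknown, collapse = ", ")))
  }
  dropped <- sum(bad)
  if (dropped > 0 && !length(unknown)) {
    inform(paste0("regulons: ", dropped, " records outside allowed grades dropped"))
  }
  df <- df[!bad, , drop = FALSE] |>
    arrange(.data$tf, .data$target, .data$confidence) |>
    distinct(.data$tf, .data$target, .keep_all = TRUE)
  class(df) <- c("snpheat_regulons", class(df))
  df
}

#' @rdname read_regulons
#' @export
write_regulons <- function(records, path) {
  readr::write_tsv(as_tibble(records)[, c("tf", "target", "confidence")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read per-patient genotypes
#'
#' Returns the "carries" relation: one row per (patient, variant) with at
#' least one alternate allele. Heterozygous and homozygous-alternate calls
#' are treated equivalently; `0/0` and missing calls are excluded. Patients
#' with zero carried variants are retained (zero rows here, but listed in the
#' `patients` attribute) so that they yield empty results downstream.
#'
#' @param path Path to a VCF (4.x, with GT fields) or a TSV with columns
#'   `patient`, `variant`, `genotype`.
#' @param dialect `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return Tibble with columns `patient`, `variant`; attribute `patients`
#'   holds all patient ids seen in the file.
#' @export
read_genotypes <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- vcfR::getID(vcf)
    if (anyNA(ids)) abort("VCF variants must have IDs")
    rownames(gt) <- ids
    patients <- colnames(gt)
    carries <- function(g) {
      !is.na(g) & grepl("[1-9]", g) & grepl("^[0-9.]([/|][0-9.])*$", g)
    }
    malformed <- !is.na(gt) & !grepl("^[0-9.]([/|][0-9.])*$", gt)
    if (any(malformed)) {
      warn(paste0("read_genotypes: skipped ", sum(malformed), " malformed GT field(s)"))
    }
    idx <- which(carries(gt), arr.ind = TRUE)
    out <- tibble(patient = patients[idx[, 2]], variant = rownames(gt)[idx[, 1]])
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    for (col in c("patient", "variant", "genotype")) {
      if (col %!in% names(df)) {
        abort(paste0("genotype table ", path, " is missing required column `", col, "`"))
      }
    }
    patients <- unique(as.character(df$patient))
    ok <- grepl("^[0-9.]([/|][0-9.])*$", df$genotype)
    if (any(!ok)) {
      warn(paste0("read_genotypes: skipped ", sum(!ok), " malformed genotype record(s)"))
    }
    df <- df[ok & grepl("[1-9]", df$genotype), , drop = FALSE]
    out <- tibble(patient = as.character(df$patient), variant = as.character(df$variant))
  }
  out <- distinct(arrange(out, .data$patient, .data$variant))
  attr(out, "patients") <- sort(patients)
  out
}

#' Read a BED file of genomic regions
#'
#' BED coordinates are 0-based half-open on disk; this reader converts them to
#' the package-internal 1-based closed convention (`start = BED start + 1`),
#' so a BED line `chr1 100 200` covers 1-based positions 101..200. Records
#' with `start >= end` are rejected with their line number.
#'
#' @param path Path to a BED3+ file.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based closed),
#'   `name`, `strand` (`"*"` when absent).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (ncol(df) < 3) abort(paste0("BED file ", path, " needs at least 3 columns"))
  bad <- which(df$X2 >= df$X3)
  if (length(bad)) {
    warn(paste0("read_bed: rejecting ", length(bad), " record(s) with start >= end",
                " at line(s) ", paste(head(bad, 5), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  tibble(
    chrom = as.character(df$X1),
    start = as.integer(df$X2) + 1L,
    end = as.integer(df$X3),
    name = if (ncol(df) >= 4) as.character(df$X4) else NA_character_,
    strand = if (ncol(df) >= 6) as.character(df$X6) else "*"
  )
}

#' Write regions back to BED (internal 1-based closed to 0-based half-open)
#' @param regions Tibble as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                   regions$name %||% ".",
                   0L,
                   if ("strand" %in% names(regions)) regions$strand else "*")
  readr::write_tsv(as_tibble(df), path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], sequences upper-cased.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' @rdname read_fasta
#' @param seqs Named DNAStringSet or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses JASPAR 2016-style PFM text (`>ID name` headers, then four rows
#' `A [ ... ]` etc.) and attaches a log-odds form computed with a pseudocount
#' and background base probabilities, so no entry is `-Inf`.
#'
#' @param path Path to the PFM file.
#' @param pseudocount Added to every count cell before normalisation.
#' @param background Background base probabilities (A, C, G, T).
#' @return Named list of motifs; each motif is a list with `id`, `counts`
#'   (4 x L), `log_odds` (4 x L, natural log) and `max_score`.
#' @export
read_jaspar <- function(path, pseudocount = 0.5, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) abort(paste0("no motif headers in ", path))
  motifs <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    block <- lines[(starts[i] + 1):(starts[i] + 4)]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?", "", l)
      l <- gsub("\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    motifs[[id]] <- motif_matrix(id, counts, pseudocount = pseudocount,
                                 background = background)
  }
  motifs
}

#' @rdname read_jaspar
#' @param id Motif identifier.
#' @param counts 4 x L non-negative count matrix with rows A, C, G, T.
#' @export
motif_matrix <- function(id, counts, pseudocount = 0.5, background = rep(0.25, 4)) {
  if (!is.matrix(counts) || nrow(counts) != 4) abort("counts must be a 4 x L matrix")
  if (ncol(counts) < 4) abort(paste0("motif ", id, ": length must be >= 4"))
  if (any(counts < 0)) abort(paste0("motif ", id, ": counts must be non-negative"))
  if (any(colSums(counts) <= 0)) abort(paste0("motif ", id, ": zero-sum column"))
  rownames(counts) <- c("A", "C", "G", "T")
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log(p / background)
  structure(list(id = id, counts = counts, log_odds = lo,
                 max_score = sum(apply(lo, 2, max)),
                 length = ncol(counts)),
            class = "snpheat_motif")
}

#' @export
print.snpheat_motif <- function(x, ...) {
  cons <- paste(rownames(x$log_odds)[apply(x$log_odds, 2, which.max)], collapse = "")
  cat("<snpheat_motif> ", x$id, " (L=", x$length, ", consensus ", cons, ")\n", sep = "")
  invisible(x)
}

#' Write motifs in JASPAR PFM text format
#' @param motifs Named list of motifs from [read_jaspar()]/[motif_matrix()].
#' @param path Output path.
#' @export
write_jaspar <- function(motifs, path) {
  out <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$id, " ", m$id),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, "  [ ", paste(format(m$counts[b, ]), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read gene models
#'
#' @param path TSV with columns `gene`, `chrom`, `strand`, `tss`,
#'   `first_exon_end` (1-based positions; `first_exon_end` is the first-exon
#'   boundary farthest from the TSS in transcription direction).
#' @return Tibble of gene models.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "chrom", "strand", "tss", "first_exon_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("gene model table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(df$strand %!in% c("+", "-"))) abort("gene model strand must be + or -")
  as_tibble(df[, need])
}

#' Read miRNA seed sequences
#' @param path TSV with columns `mirna`, `seed` (the 7-mer, miRNA nucleotides
#'   2-8, 5'->3').
#' @return Named character vector of seeds.
#' @export
read_mirna_seeds <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("mirna", "seed") %in% names(df))) {
    abort("miRNA seed table needs columns `mirna` and `seed`")
  }
  setNames(toupper(df$seed), df$mirna)
}

#' Read GMT-style annotation sets for overrepresentation analysis
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) unique(x[-(1:2)])),
           vapply(lines, `[[`, character(1), 1))
}

#' Write a per-patient result directory
#'
#' Emits `nodes.tsv` (id, layer, heat, Z, significance, seed flag),
#' `edges.tsv` (signalling subnetwork + significant regulatory edges) and a
#' machine-readable `summary.json`. Empty results produce valid files with
#' header rows only.
#'
#' @param result A `snpheat_patient` from [run_patient()].
#' @param dir Output directory (created if needed).
#' @export
write_patient_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- bind_rows(
    result$signalling |>
      mutate(layer = "signalling", is_seed = .data$node %in% result$seeds) |>
      filter(.data$significant | .data$is_seed),
    result$regulatory |>
      mutate(layer = "regulatory", is_seed = FALSE) |>
      filter(.data$significant)
  )
  if (nrow(nodes) == 0) {
    nodes <- tibble(node = character(), heat = double(), null_mean = double(),
                    null_sd = double(), z = double(), significant = logical(),
                    layer = character(), is_seed = logical())
  }
  readr::write_tsv(nodes, file.path(dir, "nodes.tsv"), progress = FALSE)
  edges <- bind_rows(
    result$subnetwork |> mutate(layer = "signalling"),
    result$reg_edges |>
      select(source = "tf", target = "target") |>
      mutate(layer = "regulatory")
  )
  if (nrow(edges) == 0) {
    edges <- tibble(source = character(), target = character(), layer = character())
  }
  readr::write_tsv(edges, file.path(dir, "edges.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(patient = result$patient,
         n_seeds = length(result$seeds),
         dropped_seeds = result$dropped_seeds,
         n_significant_signalling = sum(result$signalling$significant),
         n_significant_regulatory = sum(result$regulatory$significant),
         n_regulatory_edges = nrow(result$reg_edges),
         reason = result$reason),
    file.path(dir, "summary.json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
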