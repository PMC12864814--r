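#' Retain parameter from network size
#'
#' The retain parameter alpha — the fraction of heat a node passes onward per
#' diffusion step — is set from the edge count of the network by the
#' log-linear heuristic `alpha = m * log10(edge_count) + b`, then clamped to
#' `[0.01, 0.99]` to guarantee an invertible, non-trivial kernel.
#'
#' @param edge_count Number of directed edges (>= 1).
#' @param m,b Slope and intercept of the heuristic. The defaults are the
#'   published calibration for human signalling networks.
#' @return List of class `snpheat_alpha`: `alpha`, `edge_count`, `m`, `b`,
#'   `clamped`.
#' @export
compute_alpha <- function(edge_count, m = -0.02935302, b = 0.74842057) {
  if (length(edge_count) != 1 || is.na(edge_count) || edge_count < 1) {
    abort("edge_count must be a single value >= 1 (no propagation is possible otherwise)")
  }
  raw <- m * log10(edge_count) + b
  alpha <- min(max(raw, 0.01), 0.99)
  if (alpha != raw) {
    warn(paste0("compute_alpha: raw alpha ", format(raw), " clamped to ", alpha))
  }
  structure(list(alpha = alpha, edge_count = edge_count, m = m, b = b,
                 clamped = alpha != raw),
            class = "snpheat_alpha")
}

#' @export
print.snpheat_alpha <- function(x, ...) {
  cat("<snpheat_alpha> alpha = ", format(x$alpha, digits = 10),
      " (from ", x$edge_count, " edges",
      if (x$clamped) ", clamped", ")\n", sep = "")
  invisible(x)
}

#' Degree-weighted adjacency matrix
#'
#' Entry (i, j) is `1/outdeg(i)` when the edge i -> j exists and 0 otherwise,
#' so each node splits its outgoing heat equally over its out-edges. Sink
#' nodes (out-degree 0) are handled by `dangling`: `"self_loop"` (default)
#' places weight 1 at (i, i) so every row sums to 1 and total heat is
#' conserved; `"zero_row"` leaves the row zero (heat leaks at sinks).
#'
#' @param network A [signalling_network()].
#' @param dangling Sink-node treatment.
#' @return List of class `snpheat_adjacency`: `matrix` (sparse, rows =
#'   sources), `nodes`, `dangling`.
#' @export
build_weighted_adjacency <- function(network, dangling = c("self_loop", "zero_row")) {
  dangling <- match.arg(dangling)
  nodes <- network$nodes
  if (!length(nodes)) abort("network has no nodes")
  n <- length(nodes)
  i <- match(network$edges$source, nodes)
  j <- match(network$edges$target, nodes)
  deg <- tabulate(i, nbins = n)
  x <- 1 / deg[i]
  if (dangling == "self_loop") {
    sinks <- which(deg == 0)
    i <- c(i, sinks); j <- c(j, sinks); x <- c(x, rep(1, length(sinks)))
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                            dimnames = list(nodes, nodes))
  structure(list(matrix = A, nodes = nodes, dangling = dangling),
            class = "snpheat_adjacency")
}

#' Diffusion kernel
#'
#' Closed-form steady state of heat diffusion with restart:
#' `K = (1 - alpha) * (I - alpha * A_w)^{-1}`, computed by an exact dense
#' solve (no iterative truncation). Row i of K gives the equilibrium heat
#' distribution of one unit injected at node i; when all rows of `A_w` sum to
#' 1 every row of K sums to 1.
#'
#' @param adjacency A `snpheat_adjacency` (or a plain row-normalised matrix).
#' @param alpha Retain parameter in `[0, 0.99]` (a `snpheat_alpha` or a
#'   number; 0 is allowed for the identity-limit check).
#' @return List of class `snpheat_kernel`: `K` (dense, dimnames = nodes),
#'   `nodes`, `alpha`, `dangling`.
#' @export
compute_kernel <- function(adjacency, alpha) {
  if (inherits(alpha, "snpheat_alpha")) alpha <- alpha$alpha
  if (alpha < 0 || alpha > 0.99) abort("alpha must lie in [0, 0.99]")
  A <- if (inherits(adjacency, "snpheat_adjacency")) adjacency$matrix else Matrix::Matrix(adjacency)
  nodes <- rownames(A)
  n <- nrow(A)
  K <- (1 - alpha) * solve(as.matrix(Matrix::Diagonal(n) - alpha * A))
  dimnames(K) <- list(nodes, nodes)
  structure(list(K = K, nodes = nodes, alpha = alpha,
                 dangling = if (inherits(adjacency, "snpheat_adjacency"))
                   adjacency$dangling else NA_character_),
            class = "snpheat_kernel")
}

#' @export
print.snpheat_kernel <- function(x, ...) {
  cat("<snpheat_kernel> ", length(x$nodes), " nodes, alpha = ",
      format(x$alpha, digits = 6), "\n", sep = "")
  invisible(x)
}

# stable content hash of a kernel (used as null-ensemble cache key)
kernel_hash <- function(kernel) {
  digest::digest(list(kernel$nodes, round(kernel$K, 12)), algo = "xxhash64")
}

#' Propagate unit heat from seed nodes through the signalling network
#'
#' One unit of heat is injected at each distinct seed (SNP-affected protein)
#' and diffused to equilibrium through the kernel: the output heat is the
#' column-wise sum of the seed rows of K. Seeds absent from the kernel's node
#' set are dropped with a warning and reported in the `dropped` attribute.
#' With conserving (self-loop) dangling handling total heat equals the number
#' of retained seeds.
#'
#' @param seeds Character vector of seed node ids.
#' @param kernel A `snpheat_kernel`.
#' @return Tibble (`node`, `heat`) over all kernel nodes, with attributes
#'   `seeds` (retained) and `dropped`.
#' @export
propagate_signalling <- function(seeds, kernel) {
  seeds <- unique(as.character(seeds))
  keep <- seeds[seeds %in% kernel$nodes]
  dropped <- setdiff(seeds, keep)
  if (length(dropped)) {
    warn(paste0("propagate_signalling: ", length(dropped),
                " seed(s) not in the network dropped: ",
                paste(head(dropped, 5), collapse = ", ")))
  }
  heat <- if (length(keep)) {
    Matrix::colSums(kernel$K[match(keep, kernel$nodes), , drop = FALSE])
  } else {
    warn("propagate_signalling: zero retained seeds; empty heat vector")
    setNames(rep(0, length(kernel$nodes)), kernel$nodes)
  }
  out <- tibble(node = kernel$nodes, heat = as.numeric(heat))
  attr(out, "seeds") <- keep
  attr(out, "dropped") <- dropped
  attr(out, "layer") <- "signalling"
  out
}

# Sparse operators for the one-step regulatory layer, restricted to TFs in
# `nodes`. M[tf, tg] = 1/#targets(tf); P is the 0/1 support pattern.
regulatory_operator <- function(regulons, nodes) {
  reg <- as_tibble(regulons) |>
    distinct(.data$tf, .data$target) |>
    filter(.data$tf %in% nodes)
  tfs <- sort(unique(reg$tf))
  tgs <- sort(unique(reg$target))
  if (!length(tfs)) {
    return(list(tfs = character(), targets = character(), M = NULL, P = NULL))
  }
  i <- match(reg$tf, tfs)
  j <- match(reg$target, tgs)
  ntg <- tabulate(i, nbins = length(tfs))
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1 / ntg[i],
                            dims = c(length(tfs), length(tgs)),
                            dimnames = list(tfs, tgs))
  P <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(tfs), length(tgs)),
                            dimnames = list(tfs, tgs))
  list(tfs = tfs, targets = tgs, M = M, P = P, n_targets = setNames(ntg, tfs))
}

# Matrix form of the one-step push: H is replicates x TFs (>= 0); returns
# replicates x targets. variant "text": sum_i H_i/#TG_i averaged over the
# number of heated regulators of each target; "printed": each term divided by
# #TG_i twice, no averaging.
push_regulatory <- function(H, op, variant = c("text", "printed")) {
  variant <- match.arg(variant)
  H <- as.matrix(H)
  if (is.null(op$M)) return(matrix(0, nrow(H), 0))
  heated <- H > 0
  if (variant == "printed") {
    M2 <- op$M
    M2@x <- M2@x^2
    return(as.matrix((H * heated) %*% M2))
  }
  numer <- as.matrix((H * heated) %*% op$M)
  denom <- as.matrix((heated * 1) %*% op$P)
  out <- numer / pmax(denom, 1)
  out[denom == 0] <- 0
  out
}

#' One-step regulatory propagation of TF heat to target genes
#'
#' Heat that reached a transcription factor in the signalling layer is pushed
#' one step through the regulon layer. Under the default (`variant =
#' "text"`) each heated TF distributes its heat equally over its targets and
#' the target's incoming contributions are averaged over its number of
#' heated regulators:
#' `H(TG) = (sum over heated regulators TF of H_TF / #targets(TF)) / #heated_regulators(TG)`.
#' `variant = "printed"` instead divides each TF's contribution by its target
#' count twice and does not average (an alternative reading of the published
#' formula; see the methods vignette).
#'
#' @param signalling_heat Heat tibble from [propagate_signalling()] (or a
#'   named numeric vector).
#' @param regulons A regulon tibble ([read_regulons()]).
#' @param variant `"text"` (default) or `"printed"`.
#' @param nodes Signalling node set used to restrict eligible TFs; defaults
#'   to the names of `signalling_heat`.
#' @return Tibble (`target`, `heat`, `n_heated_regulators`) over targets with
#'   at least one heated regulator.
#' @export
propagate_regulatory <- function(signalling_heat, regulons,
                                 variant = c("text", "printed"), nodes = NULL) {
  variant <- match.arg(variant)
  if (is.data.frame(signalling_heat)) {
    h <- setNames(signalling_heat$heat, signalling_heat$node)
  } else {
    h <- signalling_heat
  }
  nodes <- nodes %||% names(h)
  op <- regulatory_operator(regulons, nodes)
  if (!length(op$tfs)) {
    return(tibble(target = character(), heat = double(),
                  n_heated_regulators = integer()))
  }
  htf <- matrix(ifelse(is.na(h[op$tfs]), 0, h[op$tfs]), nrow = 1)
  out <- push_regulatory(htf, op, variant = variant)
  nreg <- as.vector((matrix(htf > 0, nrow = 1) * 1) %*% op$P)
  keep <- nreg > 0
  res <- tibble(target = op$targets[keep], heat = as.vector(out)[keep],
                n_heated_regulators = as.integer(nreg[keep]))
  attr(res, "layer") <- "regulatory"
  res
}
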