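#' Sample random seed sets for the null model
#'
#' Draws `R` random seed sets of the same size as the real seed set.
#' `"uniform"` samples nodes without replacement; `"degree_matched"` replaces
#' each real seed by a random node of comparable out-degree (exact degree
#' when at least 20 candidates share it, otherwise a log2-spaced degree bin,
#' widened until non-empty), without replacement within a replicate. The
#' degree-matched mode controls for hub bias in the null.
#'
#' @param n_seeds Number of seeds per replicate (uniform mode).
#' @param nodes Eligible node ids (normally the giant-component node set).
#' @param R Number of replicates.
#' @param mode `"uniform"` or `"degree_matched"`.
#' @param real_seeds Real seed ids (required for degree matching).
#' @param degrees Named out-degree vector over `nodes` (required for degree
#'   matching), e.g. from a network's edge table.
#' @param rng_seed Integer seed; fixed seeds give byte-identical replicates.
#' @return R x n_seeds integer matrix of indices into `nodes`, with `nodes`
#'   as an attribute.
#' @export
sample_seed_sets <- function(n_seeds, nodes, R, mode = c("uniform", "degree_matched"),
                             real_seeds = NULL, degrees = NULL, rng_seed = NULL) {
  mode <- match.arg(mode)
  N <- length(nodes)
  if (mode == "uniform" && n_seeds > N) abort("n_seeds exceeds the eligible node count")
  idx <- with_rng(rng_seed, {
    if (mode == "uniform") {
      t(vapply(seq_len(R), function(r) sort(sample.int(N, n_seeds)),
               integer(n_seeds)))
    } else {
      if (is.null(real_seeds) || is.null(degrees)) {
        abort("degree_matched sampling requires real_seeds and degrees")
      }
      deg <- degrees[nodes]
      real_deg <- degrees[real_seeds]
      # candidate pool per real seed: exact degree if populous, else log2 bin
      pools <- lapply(real_deg, function(d) {
        exact <- which(deg == d)
        if (length(exact) >= 20) return(exact)
        bin <- floor(log2(d + 1))
        pool <- which(floor(log2(deg + 1)) == bin)
        w <- 1L
        while (length(pool) < 1) {
          pool <- which(abs(floor(log2(deg + 1)) - bin) <= w)
          w <- w + 1L
          warn("sample_seed_sets: widened an empty degree bin")
        }
        pool
      })
      t(vapply(seq_len(R), function(r) {
        used <- integer(0)
        for (p in pools) {
          avail <- setdiff(p, used)
          if (!length(avail)) avail <- setdiff(seq_len(N), used)
          used <- c(used, sample_exact(avail, 1))
        }
        sort(used)
      }, integer(length(real_seeds))))
    }
  })
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = R)
  attr(idx, "nodes") <- nodes
  idx
}

#' Build a random-seed null ensemble
#'
#' For each of `R` replicates a random seed set is propagated through the
#' kernel and (per replicate) one step further through the regulon layer;
#' per-node means and standard deviations of the null heat are recorded for
#' both layers. Uses the linearity of the kernel (the heat of a seed set is
#' the sum of the corresponding kernel rows), so `R = 10000` is desk-scale.
#' Standard deviations are population SDs (divide by R).
#'
#' @param kernel A `snpheat_kernel`.
#' @param regulons Regulon tibble (or `NULL` to skip the regulatory layer).
#' @param n_seeds Seed-set size (the real seed count of the patient).
#' @param R Number of replicates (published protocol: 10000).
#' @param mode,real_seeds,degrees,rng_seed Passed to [sample_seed_sets()].
#' @param variant Regulatory-propagation variant, see [propagate_regulatory()].
#' @param eligible Optional node subset to sample seeds from; defaults to all
#'   kernel nodes (use the giant component in pipelines).
#' @return List of class `snpheat_null`: `sig_mean`, `sig_sd` (named over
#'   kernel nodes), `reg_mean`, `reg_sd` (named over regulon targets),
#'   `n_seeds`, `R`, `mode`, `rng_seed`.
#' @export
build_null <- function(kernel, regulons, n_seeds, R = 10000,
                       mode = c("uniform", "degree_matched"),
                       real_seeds = NULL, degrees = NULL, rng_seed = 1,
                       variant = c("text", "printed"), eligible = NULL) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  eligible <- eligible %||% kernel$nodes
  idx <- sample_seed_sets(n_seeds, eligible, R, mode = mode,
                          real_seeds = real_seeds, degrees = degrees,
                          rng_seed = rng_seed)
  # linearity fast path: heat of a seed set = sum of its kernel rows
  S <- Matrix::sparseMatrix(i = rep(seq_len(R), ncol(idx)),
                            j = match(eligible[as.vector(idx)], kernel$nodes),
                            x = 1, dims = c(R, length(kernel$nodes)))
  H <- as.matrix(S %*% kernel$K)
  colnames(H) <- kernel$nodes
  sig_mean <- colMeans(H)
  sig_sd <- sqrt(pmax(colMeans(H^2) - sig_mean^2, 0))
  reg_mean <- reg_sd <- NULL
  if (!is.null(regulons)) {
    op <- regulatory_operator(regulons, kernel$nodes)
    if (length(op$tfs)) {
      Hr <- push_regulatory(H[, op$tfs, drop = FALSE], op, variant = variant)
      reg_mean <- setNames(colMeans(Hr), op$targets)
      reg_sd <- setNames(sqrt(pmax(colMeans(Hr^2) - reg_mean^2, 0)), op$targets)
    }
  }
  structure(list(sig_mean = setNames(sig_mean, kernel$nodes),
                 sig_sd = setNames(sig_sd, kernel$nodes),
                 reg_mean = reg_mean, reg_sd = reg_sd,
                 n_seeds = n_seeds, R = R, mode = mode, rng_seed = rng_seed,
                 variant = variant),
            class = "snpheat_null")
}

#' @export
print.snpheat_null <- function(x, ...) {
  cat("<snpheat_null> R = ", x$R, ", n_seeds = ", x$n_seeds, ", mode = ",
      x$mode, "\n", sep = "")
  invisible(x)
}

# Reference implementation: per-replicate full propagation (no linearity
# shortcut). Used as the oracle for the fast path in tests.
build_null_naive <- function(kernel, regulons, n_seeds, R, mode = "uniform",
                             real_seeds = NULL, degrees = NULL, rng_seed = 1,
                             variant = "text", eligible = NULL) {
  eligible <- eligible %||% kernel$nodes
  idx <- sample_seed_sets(n_seeds, eligible, R, mode = mode,
                          real_seeds = real_seeds, degrees = degrees,
                          rng_seed = rng_seed)
  H <- matrix(0, R, length(kernel$nodes), dimnames = list(NULL, kernel$nodes))
  op <- if (is.null(regulons)) {
    list(tfs = character(), targets = character(), M = NULL, P = NULL)
  } else {
    regulatory_operator(regulons, kernel$nodes)
  }
  Hr <- matrix(0, R, length(op$targets), dimnames = list(NULL, op$targets))
  for (r in seq_len(R)) {
    hv <- suppressWarnings(propagate_signalling(eligible[idx[r, ]], kernel))
    H[r, ] <- hv$heat
    if (length(op$tfs)) {
      rg <- propagate_regulatory(hv, regulons, variant = variant,
                                 nodes = kernel$nodes)
      Hr[r, match(rg$target, op$targets)] <- rg$heat
    }
  }
  m <- colMeans(H)
  mr <- colMeans(Hr)
  structure(list(sig_mean = m,
                 sig_sd = sqrt(pmax(colMeans(H^2) - m^2, 0)),
                 reg_mean = mr,
                 reg_sd = sqrt(pmax(colMeans(Hr^2) - mr^2, 0)),
                 n_seeds = n_seeds, R = R, mode = mode, rng_seed = rng_seed,
                 variant = variant),
            class = "snpheat_null")
}

#' Z-score filter against a null ensemble
#'
#' Per node, `Z = (H_real - mean(H_random)) / SD(H_random)`; a node is
#' significant when `Z` strictly exceeds the threshold (one-sided, upper
#' tail: only excess heat over the random expectation is meaningful). When
#' the null SD is zero the node is significant iff its real heat exceeds the
#' null mean (Z is reported as `Inf`, `0` or `-Inf`).
#'
#' @param heat Heat tibble from [propagate_signalling()] /
#'   [propagate_regulatory()] (or a named numeric vector).
#' @param null A `snpheat_null`.
#' @param layer `"signalling"` or `"regulatory"`; defaults to the heat
#'   vector's layer tag.
#' @param threshold Significance threshold on Z, default 2 (strict).
#' @return Tibble of class `snpheat_zscores`: `node`, `heat`, `null_mean`,
#'   `null_sd`, `z`, `significant`.
#' @export
z_filter <- function(heat, null, layer = NULL, threshold = 2) {
  if (threshold <= 0) abort("Z threshold must be positive")
  if (is.data.frame(heat)) {
    layer <- layer %||% attr(heat, "layer")
    h <- setNames(heat$heat, heat[[1]])
  } else {
    h <- heat
  }
  if (is.null(layer)) abort("layer must be given for plain heat vectors")
  if (layer == "signalling") {
    mu <- null$sig_mean; s <- null$sig_sd
  } else {
    if (is.null(null$reg_mean)) abort("null ensemble has no regulatory layer")
    mu <- null$reg_mean; s <- null$reg_sd
  }
  # align: nodes absent from the heat vector carry zero real heat
  hh <- setNames(rep(0, length(mu)), names(mu))
  common <- intersect(names(h), names(hh))
  hh[common] <- h[common]
  z <- ifelse(s > 0, (hh - mu) / s,
              ifelse(hh > mu, Inf, ifelse(hh < mu, -Inf, 0)))
  out <- tibble(node = names(mu), heat = as.numeric(hh),
                null_mean = as.numeric(mu), null_sd = as.numeric(s),
                z = as.numeric(z),
                significant = as.numeric(z) > threshold)
  attr(out, "layer") <- layer
  attr(out, "threshold") <- threshold
  class(out) <- c("snpheat_zscores", class(out))
  out
}
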