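# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# desk-scale spec used by most integration tests
small_spec <- function() {
  # same operating regime as the default conditions (seed panels comparable,
  # narrow TF fan-out) at a sixth of the node count
  fixture_spec(n_nodes = 150, n_edges = 600, n_tfs = 30, n_clusters = 3,
               seeds_per_cluster = 5, tfs_per_cluster = 2, n_patients = 18,
               n_noise_genes = 6)
}

small_fixture <- function() {
  cached("small_fixture", function() suppressMessages(gen_fixture(small_spec(), rng_seed = 11)))
}

small_kernel <- function() {
  cached("small_kernel", function() {
    fix <- small_fixture()
    gc_net <- giant_component(fix$network)
    list(gc = gc_net,
         kernel = compute_kernel(build_weighted_adjacency(gc_net),
                                 compute_alpha(nrow(gc_net$edges))))
  })
}

# the full default-conditions fixture (used by acceptance-grade tests)
default_fixture <- function() {
  cached("default_fixture", function() suppressMessages(gen_fixture(fixture_spec(), rng_seed = 1)))
}

default_cohort_run <- function() {
  cached("default_cohort_run", function() {
    fix <- default_fixture()
    gc_net <- giant_component(fix$network)
    kernel <- compute_kernel(build_weighted_adjacency(gc_net),
                             compute_alpha(nrow(gc_net$edges)))
    clear_null_cache()
    results <- lapply(names(fix$truth$affected), function(p) {
      suppressWarnings(run_patient(p, fix$truth$affected[[p]], kernel,
                                   fix$regulons, gc_net, R = 1000, rng_seed = 7))
    })
    names(results) <- names(fix$truth$affected)
    list(fix = fix, gc = gc_net, kernel = kernel, results = results)
  })
}

# tiny hand-checkable networks
chain_ab <- function() {
  signalling_network(tibble::tibble(source = c("A", "B"), target = c("B", "B")))
}

random_network <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  edges <- expand.grid(source = sprintf("n%02d", 1:n),
                       target = sprintf("n%02d", 1:n),
                       stringsAsFactors = FALSE)
  edges <- edges[stats::runif(nrow(edges)) < p & edges$source != edges$target, ]
  signalling_network(edges, nodes = sprintf("n%02d", 1:n))
}

# independent truncated power-series evaluation of the kernel
power_series_kernel <- function(adj, alpha, t_max = 200) {
  A <- as.matrix(adj$matrix)
  n <- nrow(A)
  term <- diag(n)
  acc <- diag(n)
  for (t in seq_len(t_max)) {
    term <- alpha * (term %*% A)
    acc <- acc + term
  }
  (1 - alpha) * acc
}

# independent brute-force double loop over (TF, TG) pairs
brute_force_regulatory <- function(heat, regulons, variant = "text") {
  h <- stats::setNames(heat$heat, heat$node)
  reg <- unique(as.data.frame(regulons)[, c("tf", "target")])
  reg <- reg[reg$tf %in% names(h), ]
  out <- list()
  for (tg in sort(unique(reg$target))) {
    tfs <- reg$tf[reg$target == tg]
    heated <- tfs[h[tfs] > 0]
    if (!length(heated)) next
    contrib <- vapply(heated, function(tf) {
      ntg <- sum(reg$tf == tf)
      if (variant == "text") h[[tf]] / ntg else h[[tf]] / ntg^2
    }, double(1))
    out[[tg]] <- if (variant == "text") sum(contrib) / length(heated) else sum(contrib)
  }
  tibble::tibble(target = names(out), heat = unname(unlist(out)))
}

# direct Newman modularity of a partition on an undirected simple graph
direct_modularity <- function(edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  nodes <- names(membership)
  deg <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_len(m)) {
    deg[edges$source[i]] <- deg[edges$source[i]] + 1
    deg[edges$target[i]] <- deg[edges$target[i]] + 1
  }
  q <- 0
  for (i in seq_len(m)) {
    if (membership[edges$source[i]] == membership[edges$target[i]]) q <- q + 1 / m
  }
  for (cl in unique(membership)) {
    q <- q - (sum(deg[membership == cl]) / (2 * m))^2
  }
  q
}
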