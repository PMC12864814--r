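test_that("Jaccard distances follow the set-overlap definition", {
  m <- rbind(p1 = c(1, 1, 1, 0, 0),   # {a,b,c}
             p2 = c(0, 1, 1, 1, 0),   # {b,c,d}
             p3 = c(1, 1, 1, 0, 0),
             p4 = c(0, 0, 0, 0, 1),
             p5 = c(0, 0, 0, 0, 0),
             p6 = c(0, 0, 0, 0, 0))
  d <- suppressMessages(jaccard_distances(m))
  expect_equal(d["p1", "p2"], 0.5)   # overlap 2 of union 4
  expect_equal(d["p1", "p3"], 0)     # identical rows
  expect_equal(d["p1", "p4"], 1)     # disjoint non-empty rows
  expect_equal(d["p5", "p6"], 0)     # all-zero convention
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("the embedding is deterministic with non-increasing variance ratios", {
  run <- default_cohort_run()
  m <- build_matrix(run$results)
  d <- jaccard_distances(m)
  e1 <- embed_patients(d)
  e2 <- embed_patients(d)
  expect_identical(e1$scores, e2$scores)   # sign convention fixes runs
  expect_true(all(diff(e1$ev_ratio) <= 1e-12))
  expect_lte(sum(e1$ev_ratio), 1 + 1e-9)
  expect_gte(e1$n_components, 3)
  # planted structure: the leading components separate the clusters
  lab <- run$fix$truth$labels[rownames(e1$scores)]
  between <- sapply(1:3, function(c) mean(e1$scores[lab == c, 1]))
  expect_gt(max(between) - min(between), stats::sd(e1$scores[, 1]))

  same <- matrix(1, 4, 4, dimnames = list(paste0("p", 1:4), paste0("e", 1:4)))
  expect_warning(e0 <- embed_patients(suppressMessages(jaccard_distances(same))),
                 "identical")
  expect_true(all(e0$scores == 0))
})

test_that("k selection recovers the planted cluster count and labels", {
  run <- default_cohort_run()
  m <- build_matrix(run$results)
  emb <- embed_patients(jaccard_distances(m))
  ks <- choose_k(emb, rng_seed = 7)
  expect_equal(ks$k, 3)
  cl <- ks$fits[[paste0("k", ks$k)]]
  lab <- run$fix$truth$labels[cl$assignment$patient]
  expect_gte(mclust::adjustedRandIndex(cl$assignment$cluster, lab), 0.8)
  # determinism and input-order invariance (up to relabelling)
  cl2 <- cluster_patients(emb, 3, rng_seed = 7)
  expect_identical(cl$assignment, cl2$assignment)
  perm <- sample(nrow(m))
  emb_p <- embed_patients(jaccard_distances(m[perm, ]))
  cl_p <- cluster_patients(emb_p, 3, rng_seed = 7)
  ord <- match(cl$assignment$patient, cl_p$assignment$patient)
  expect_equal(mclust::adjustedRandIndex(cl$assignment$cluster,
                                         cl_p$assignment$cluster[ord]), 1)
  expect_error(cluster_patients(emb, 1), "at least 2")
  expect_error(cluster_patients(emb, nrow(m)), "at most")
})

test_that("cluster representatives require the presence fraction", {
  asg <- structure(list(assignment = tibble::tibble(
    patient = sprintf("p%02d", 1:20),
    cluster = rep(1:2, each = 10)), k = 2L), class = "snpheat_clusters")
  m <- matrix(0L, 20, 3,
              dimnames = list(sprintf("p%02d", 1:20),
                              c("T1->a", "T1->b", "T2->c")))
  m[1:9, "T1->a"] <- 1L    # 9/10 of cluster 1
  m[1:4, "T1->b"] <- 1L    # 4/10 of cluster 1
  m[11:20, "T2->c"] <- 1L  # all of cluster 2
  reps <- cluster_representatives(asg, m, min_fraction = 0.5)
  expect_setequal(reps$edge[reps$cluster == 1], "T1->a")
  expect_setequal(reps$edge[reps$cluster == 2], "T2->c")
  expect_equal(attr(reps, "tfs")[["1"]], "T1")
  expect_equal(attr(reps, "tfs")[["2"]], "T2")
})

test_that("Girvan-Newman splits the two-triangle bridge and maximises modularity", {
  edges <- tibble::tibble(
    source = c("a", "b", "c", "d", "e", "f", "c"),
    target = c("b", "c", "a", "e", "f", "d", "d"))
  net <- signalling_network(edges)
  # brute-force check that the bridge has the strictly highest betweenness
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  lab <- apply(igraph::ends(g, igraph::E(g)), 1,
               function(x) paste(sort(x), collapse = "|"))
  expect_equal(lab[which.max(eb)], "c|d")
  mod <- girvan_newman(net)
  mem <- setNames(mod$membership$module, mod$membership$node)
  expect_equal(length(unique(mem[c("a", "b", "c")])), 1)
  expect_equal(length(unique(mem[c("d", "e", "f")])), 1)
  expect_false(mem[["a"]] == mem[["d"]])
  # the reported modularity matches an independent direct evaluation
  expect_equal(mod$modularity, direct_modularity(edges, mem), tolerance = 1e-12)
  # deterministic across runs
  expect_identical(girvan_newman(net)$membership, mod$membership)
})

test_that("degenerate graphs modularise to singletons", {
  net <- signalling_network(tibble::tibble(source = character(),
                                           target = character()),
                            nodes = c("x", "y", "z"))
  mod <- girvan_newman(net)
  expect_equal(mod$n_modules, 3)
  expect_equal(mod$modularity, 0)
  one <- girvan_newman(signalling_network(tibble::tibble(source = "x", target = "x")))
  expect_equal(one$n_modules, 1)
})

test_that("ORA reproduces the exact hypergeometric tail and BH adjustment", {
  universe <- sprintf("u%02d", 1:20)
  query <- universe[1:5]
  sets <- list(S = c(universe[1:3], universe[10:11]))   # overlap 3, size 5
  out <- ora(query, sets, universe)
  expect_equal(out$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(out$overlap, 3)
  # zero overlap has upper-tail p = 1
  out0 <- ora(query, list(S0 = universe[10:14]), universe)
  expect_equal(out0$p, 1)
  # hand-computed Benjamini-Hochberg on three sets
  p_target <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p_target, "BH"), c(0.03, 0.03, 0.04))
  expect_warning(ora(c(query, "alien"), sets, universe), "outside the universe")
  expect_error(ora(query, sets, character()), "empty universe")
})

test_that("ORA p-values agree with Monte-Carlo resampling within 3 SE", {
  universe <- sprintf("u%03d", 1:40)
  set.seed(99)
  anno <- list(A = sample(universe, 8), B = sample(universe, 15))
  query <- sample(universe, 10)
  out <- ora(query, anno, universe)
  B <- 4000
  for (nm in names(anno)) {
    hits <- vapply(seq_len(B), function(i) {
      length(intersect(sample(universe, 10), anno[[nm]]))
    }, double(1))
    k <- out$overlap[out$set == nm]
    p_mc <- mean(hits >= k)
    se <- sqrt(p_mc * (1 - p_mc) / B)
    expect_lt(abs(out$p[out$set == nm] - p_mc), 3 * se + 1e-9)
  }
})
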