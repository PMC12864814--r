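test_that("empty and identical patients behave deterministically", {
  kern <- small_kernel()
  fix <- small_fixture()
  empty <- suppressWarnings(run_patient("p0", character(), kern$kernel,
                                        fix$regulons, kern$gc, R = 10))
  expect_equal(empty$reason, "no usable seeds in the network")
  expect_equal(nrow(empty$subnetwork), 0)

  genes <- fix$truth$affected[[1]]
  a <- suppressWarnings(run_patient("pA", genes, kern$kernel, fix$regulons,
                                    kern$gc, R = 200, rng_seed = 5))
  b <- suppressWarnings(run_patient("pB", genes, kern$kernel, fix$regulons,
                                    kern$gc, R = 200, rng_seed = 5))
  expect_equal(a$sig_nodes, b$sig_nodes)
  expect_equal(a$reg_edges, b$reg_edges)
})

test_that("patient results respect their structural invariants", {
  run <- default_cohort_run()
  for (r in run$results[1:8]) {
    retained <- union(r$sig_nodes, r$seeds)
    expect_true(all(r$subnetwork$source %in% retained))
    expect_true(all(r$subnetwork$target %in% retained))
    # induced-subgraph rule: every network edge among retained nodes is kept
    induced <- dplyr::filter(run$gc$edges, source %in% retained,
                             target %in% retained)
    expect_equal(nrow(r$subnetwork), nrow(induced))
    if (nrow(r$reg_edges)) {
      expect_true(all(r$reg_edges$tf %in% retained))
      sig_tg <- r$regulatory$node[r$regulatory$significant]
      expect_true(all(r$reg_edges$target %in% sig_tg))
    }
  }
})

test_that("patients whose seeds sit upstream of a designed cascade recover it", {
  run <- default_cohort_run()
  for (r in run$results) {
    lab <- run$fix$truth$labels[[r$patient]]
    expect_true(all(run$fix$truth$cascades[[lab]] %in% r$sig_nodes),
                label = paste("cascade recovery for", r$patient))
  }
})

test_that("cohort counts use a strict greater-than commonality threshold", {
  run <- default_cohort_run()
  res <- run$results
  summ <- summarise_cohort(res, common_threshold = 20)
  # every count is reproducible from the per-patient results
  node <- summ$node_counts$node[summ$node_counts$layer == "signalling"][1]
  recount <- sum(vapply(res, function(r) node %in% union(r$sig_nodes, r$seeds),
                        logical(1)))
  expect_equal(summ$node_counts$n_patients[1], recount)
  expect_true(all(summ$node_counts$common ==
                    (summ$node_counts$n_patients > 20)))
  # boundary: exactly at the threshold is NOT common
  at <- summ$node_counts[summ$node_counts$n_patients == 20, ]
  if (nrow(at)) expect_false(any(at$common))
  # permutation invariance
  summ2 <- summarise_cohort(rev(res), common_threshold = 20)
  expect_equal(dplyr::arrange(summ$node_counts, node, layer),
               dplyr::arrange(summ2$node_counts, node, layer))
  # fractional threshold
  summ_f <- summarise_cohort(res, common_threshold = 1 / 3)
  expect_equal(summ_f$threshold, length(res) / 3)
})

test_that("combining two cohorts labels shared and specific features", {
  run <- default_cohort_run()
  res <- run$results
  a <- summarise_cohort(res[1:30], common_threshold = 5)
  b <- summarise_cohort(res[31:60], common_threshold = 5)
  comb <- combine_diseases(a, b, labels = c("CD", "UC"))
  both <- comb$nodes[comb$nodes$count_CD > 0 & comb$nodes$count_UC > 0, ]
  expect_true(all(both$status == "shared"))
  only_a <- comb$nodes[comb$nodes$count_UC == 0, ]
  expect_true(all(only_a$status == "CD-specific"))
  # counts carried through unchanged
  j <- dplyr::inner_join(comb$nodes, a$node_counts, by = c("node", "layer"))
  expect_equal(j$count_CD, j$n_patients)
})

test_that("the binary matrix has deterministic columns and correct support", {
  run <- default_cohort_run()
  res <- run$results
  m <- build_matrix(res)
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(colnames(m), sort(colnames(m)))
  expect_equal(rownames(m), sort(vapply(res, `[[`, character(1), "patient")))
  # column support equals the cohort edge counts (cross-module consistency)
  summ <- summarise_cohort(res, common_threshold = 10)
  key <- paste0(summ$edge_counts$tf, "->", summ$edge_counts$target)
  expect_equal(unname(colSums(m)[key]), summ$edge_counts$n_patients)
  # row sums equal each patient's significant edge count
  expect_equal(unname(rowSums(m)),
               vapply(res[order(vapply(res, `[[`, character(1), "patient"))],
                      function(r) nrow(r$reg_edges), integer(1)) |> as.numeric())
  expect_error(build_matrix(res[1]), "at least 2")
})
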