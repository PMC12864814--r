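test_that("the retain-parameter heuristic evaluates and clamps correctly", {
  expect_equal(compute_alpha(10)$alpha, -0.02935302 * 1 + 0.74842057,
               tolerance = 1e-12)
  expect_equal(compute_alpha(10)$alpha, 0.71906755, tolerance = 1e-8)
  expect_equal(compute_alpha(100)$alpha, 0.68971453, tolerance = 1e-8)
  expect_equal(compute_alpha(51792)$alpha,
               -0.02935302 * log10(51792) + 0.74842057, tolerance = 1e-12)
  expect_equal(compute_alpha(51792)$alpha, 0.61004, tolerance = 1e-4)
  expect_false(compute_alpha(51792)$clamped)
  expect_warning(hi <- compute_alpha(1e60), "clamped")
  expect_equal(hi$alpha, 0.01)
  expect_error(compute_alpha(0), "edge_count")
})

test_that("degree-weighted adjacency splits rows by out-degree and handles sinks", {
  net <- signalling_network(tibble::tibble(source = c("A", "A", "X"),
                                           target = c("B", "C", "A")))
  adj <- build_weighted_adjacency(net)
  A <- as.matrix(adj$matrix)
  expect_equal(A["A", c("B", "C")], c(B = 0.5, C = 0.5))
  expect_equal(A["B", "B"], 1)               # sink gets a self-loop
  expect_equal(unname(rowSums(A)), rep(1, 4))
  adj0 <- build_weighted_adjacency(net, dangling = "zero_row")
  expect_equal(sum(as.matrix(adj0$matrix)["B", ]), 0)
})

test_that("kernel matches the hand-inverted 2x2 system and the identity limit", {
  adj <- build_weighted_adjacency(chain_ab())
  for (a in c(0.3, 0.5, 0.9)) {
    K <- compute_kernel(adj, a)$K
    expect_equal(unname(K), rbind(c(1 - a, a), c(0, 1)), tolerance = 1e-12)
  }
  expect_equal(unname(compute_kernel(adj, 0)$K), diag(2))
  # K = (1 - a)(I + a A_w) + O(a^2)
  K_small <- compute_kernel(adj, 0.01)$K
  approx <- 0.99 * (diag(2) + 0.01 * as.matrix(adj$matrix))
  expect_lt(max(abs(K_small - approx)), 0.01^2 * 2)
})

test_that("kernel equals the truncated power series and rows sum to one", {
  for (s in 1:5) {
    net <- random_network(20, seed = s)
    adj <- build_weighted_adjacency(net)
    alpha <- compute_alpha(nrow(net$edges))$alpha
    K <- compute_kernel(adj, alpha)$K
    expect_lt(max(abs(K - power_series_kernel(adj, alpha))), 1e-8)
    expect_lt(max(abs(rowSums(K) - 1)), 1e-9)
    expect_true(all(K >= -1e-12))  # non-negative up to solver round-off
  }
})

test_that("signalling heat: hand case, conservation, linearity, monotonicity", {
  adj <- build_weighted_adjacency(chain_ab())
  K <- compute_kernel(adj, 0.5)
  h <- propagate_signalling("A", K)
  expect_equal(h$heat, c(0.5, 0.5))     # from the hand-derived kernel

  net <- random_network(25, seed = 42)
  kernel <- compute_kernel(build_weighted_adjacency(net),
                           compute_alpha(nrow(net$edges)))
  s1 <- net$nodes[1:4]
  s2 <- net$nodes[10:12]
  h1 <- propagate_signalling(s1, kernel)
  h2 <- propagate_signalling(s2, kernel)
  h12 <- propagate_signalling(c(s1, s2), kernel)
  expect_equal(sum(h1$heat), 4, tolerance = 1e-9)       # one unit per seed
  expect_equal(sum(h12$heat), 7, tolerance = 1e-9)
  expect_equal(h12$heat, h1$heat + h2$heat, tolerance = 1e-12)  # linearity
  expect_true(all(h12$heat >= h1$heat - 1e-12))         # adding seeds only adds heat

  # a gene affected by several SNPs still injects a single unit
  expect_equal(propagate_signalling(c("A", "A"), K)$heat, c(0.5, 0.5))
  expect_warning(hd <- propagate_signalling(c("A", "ZZZ"), K), "dropped")
  expect_equal(attr(hd, "dropped"), "ZZZ")
  suppressWarnings(expect_warning(h0 <- propagate_signalling("ZZZ", K),
                                  "zero retained"))
  expect_equal(sum(h0$heat), 0)
})

test_that("zero_row dangling intentionally breaks conservation at sinks", {
  sink_net <- signalling_network(tibble::tibble(source = "A", target = "B"))
  adj <- build_weighted_adjacency(sink_net, dangling = "zero_row")
  K <- compute_kernel(adj, 0.5)
  expect_lt(sum(propagate_signalling("A", K)$heat), 1)
})

test_that("regulatory propagation matches the hand-computed shared-target case", {
  heat <- tibble::tibble(node = c("TF1", "TF2"), heat = c(0.6, 0.3))
  regs <- tibble::tibble(
    tf = c("TF1", "TF1", "TF1", "TF2", "TF2"),
    target = c("TG", "x1", "x2", "TG", "y1"),
    confidence = "A")
  out <- propagate_regulatory(heat, regs)
  # (0.6/3 + 0.3/2) / 2 regulators = 0.175
  expect_equal(out$heat[out$target == "TG"], 0.175, tolerance = 1e-12)
  expect_equal(out$heat[out$target == "x1"], 0.2)  # single regulator: h/n
  expect_equal(out$n_heated_regulators[out$target == "TG"], 2L)
  # printed-formula variant: each contribution divided twice by #TG_TF
  out_p <- propagate_regulatory(heat, regs, variant = "printed")
  expect_equal(out_p$heat[out_p$target == "TG"], 0.6 / 9 + 0.3 / 4,
               tolerance = 1e-12)
  # all-zero TF heat gives an empty vector
  none <- propagate_regulatory(tibble::tibble(node = c("TF1", "TF2"), heat = 0), regs)
  expect_equal(nrow(none), 0)
})

test_that("regulatory propagation equals the brute-force (TF, TG) double loop", {
  run <- list(fix = small_fixture())
  kern <- small_kernel()
  seeds <- run$fix$truth$panels[[1]]
  h <- propagate_signalling(seeds, kern$kernel)
  for (variant in c("text", "printed")) {
    got <- propagate_regulatory(h, run$fix$regulons, variant = variant)
    want <- brute_force_regulatory(h, run$fix$regulons, variant = variant)
    got <- got[order(got$target), ]
    expect_equal(got$target, want$target)
    expect_equal(got$heat, want$heat, tolerance = 1e-12)
  }
})

test_that("TFs outside the signalling node set are excluded from the push", {
  heat <- tibble::tibble(node = "TF1", heat = 1)
  regs <- tibble::tibble(tf = c("TF1", "GHOST"), target = c("TG", "TG"),
                         confidence = "A")
  out <- propagate_regulatory(heat, regs, nodes = "TF1")
  # GHOST is not a signalling node: it neither contributes nor counts as a
  # regulator, so TG receives TF1's full unit
  expect_equal(out$heat[out$target == "TG"], 1)
})
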