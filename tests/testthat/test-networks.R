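test_that("gene networks deduplicate, canonicalize and guard self-loops", {
  g <- gene_network(data.frame(a = c("B", "A", "A"), b = c("A", "B", "C")))
  expect_equal(nrow(g), 2L)  # (A,B) twice -> once
  expect_equal(g$from, c("A", "A"))
  expect_equal(g$to, c("B", "C"))
  expect_equal(network_nodes(g), c("A", "B", "C"))

  expect_error(gene_network(data.frame(a = "A", b = "A")), "self-loop")
  expect_warning(g2 <- gene_network(data.frame(a = c("A", "A"), b = c("A", "B")),
                                    self_loops = "drop"), "self-loop")
  expect_equal(nrow(g2), 1L)

  # isolated nodes survive
  g3 <- gene_network(data.frame(a = "A", b = "B"), nodes = c("Z", "A"))
  expect_equal(network_nodes(g3), c("A", "B", "Z"))
  expect_equal(n_edges(gene_network()), 0L)
})

test_that("edge-list and SIF files round-trip", {
  g <- gene_network(data.frame(a = c("MYC", "BAX"), b = c("PCNA", "MYC")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, path)
  back <- read_network(path)
  expect_equal(as.data.frame(back), as.data.frame(g))

  # reciprocal rows collapse on read
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tB", "B\tA"), p2)
  expect_equal(n_edges(read_network(p2)), 1L)

  # SIF: relation column ignored, headerless
  p3 <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("MYC\tactivates\tPCNA", "PCNA\tinhibits\tMYC", "MYC\tpd\tBAX"), p3)
  sif <- read_network(p3)
  expect_equal(n_edges(sif), 2L)

  # self-loop row errors by default, skippable with warning
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tA", "A\tB"), p4)
  expect_error(read_network(p4), "self-loop")
  expect_warning(ok <- read_network(p4, self_loops = "drop"))
  expect_equal(n_edges(ok), 1L)
})

test_that("to_undirected drops direction, sign and multiplicity", {
  # A->B and B->A collapse; inhibitory sign discarded; 3 directed edges on 2 pairs -> 2
  df <- data.frame(src = c("A", "B", "A"), tgt = c("B", "A", "C"),
                   sign = c("+", "-", "?"), stringsAsFactors = FALSE)
  g <- to_undirected(df)
  expect_equal(n_edges(g), 2L)
  expect_equal(as.data.frame(g), data.frame(from = c("A", "A"), to = c("B", "C")),
               ignore_attr = TRUE)
  expect_warning(to_undirected(data.frame(a = "X", b = "X")), "self-loop")
})

test_that("compare_networks reproduces published worked rows and identities", {
  # tp=11, fp=16, fn=17 -> precision .41, recall .39, f .40 (2 d.p.)
  nets <- networks_with_counts(tp = 11, fp = 16, fn = 17)
  cmp <- compare_networks(nets$gold, nets$est)
  expect_equal(cmp$tp, 11L)
  expect_equal(cmp$fp, 16L)
  expect_equal(cmp$fn, 17L)
  expect_equal(round(cmp$precision, 2), 0.41)
  expect_equal(round(cmp$recall, 2), 0.39)
  expect_equal(round(cmp$fscore, 2), 0.40)

  nets2 <- networks_with_counts(tp = 15, fp = 23, fn = 13)
  expect_equal(round(compare_networks(nets2$gold, nets2$est)$fscore, 2), 0.45)

  # identity: est == gold
  g <- random_network(10, 12, seed = 3)
  id <- compare_networks(g, g)
  expect_equal(c(id$precision, id$recall, id$fscore), c(1, 1, 1))

  # zero-denominator conventions
  empty <- gene_network()
  z <- compare_networks(empty, empty)
  expect_equal(c(z$precision, z$recall, z$fscore), c(0, 0, 0))
})

test_that("fscore_between is symmetric and consistent with compare_networks", {
  # |a|=27, |b|=30, 12 common -> 24/57 = 0.42 (2 d.p.)
  nets <- networks_with_counts(tp = 12, fp = 18, fn = 15)
  expect_equal(n_edges(nets$est), 30L)
  expect_equal(n_edges(nets$gold), 27L)
  f <- fscore_between(nets$gold, nets$est)
  expect_equal(f, 24 / 57)
  expect_equal(round(f, 2), 0.42)
  expect_equal(f, fscore_between(nets$est, nets$gold))
  expect_equal(f, compare_networks(nets$gold, nets$est)$fscore)

  a <- gene_network(data.frame(x = "A", y = "B"))
  b <- gene_network(data.frame(x = "C", y = "D"))
  expect_equal(fscore_between(a, b), 0)
  expect_equal(fscore_between(a, a), 1)
  expect_equal(fscore_between(gene_network(), gene_network()), 0)
})

test_that("comparison counts reconcile with a brute-force membership oracle", {
  set.seed(42)
  for (rep in 1:20) {
    g1 <- random_network(8, sample(0:10, 1))
    g2 <- random_network(8, sample(0:10, 1))
    cmp <- compare_networks(g1, g2)
    # oracle: pairwise membership over all possible node pairs
    pairs <- t(combn(sort(union(network_nodes(g1), network_nodes(g2))), 2))
    in1 <- apply(pairs, 1, function(pr) {
      any(g1$from == pr[1] & g1$to == pr[2])
    })
    in2 <- apply(pairs, 1, function(pr) {
      any(g2$from == pr[1] & g2$to == pr[2])
    })
    expect_equal(cmp$tp, sum(in1 & in2))
    expect_equal(cmp$fp, sum(!in1 & in2))
    expect_equal(cmp$fn, sum(in1 & !in2))
    expect_equal(cmp$tp + cmp$fp, n_edges(g2))
    expect_equal(cmp$tp + cmp$fn, n_edges(g1))
    # monotonicity: adding a gold edge to the estimate never lowers recall
    missing_gold <- which(in1 & !in2)
    if (length(missing_gold)) {
      pr <- pairs[missing_gold[1], ]
      g2plus <- gene_network(rbind(as.matrix(g2), pr))
      expect_gte(compare_networks(g1, g2plus)$recall, cmp$recall)
    }
    # adding a non-gold edge never raises precision
    spare <- which(!in1 & !in2)
    if (length(spare) && n_edges(g2) > 0) {
      pr <- pairs[spare[1], ]
      g2noise <- gene_network(rbind(as.matrix(g2), pr))
      expect_lte(compare_networks(g1, g2noise)$precision, cmp$precision)
    }
  }
})
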