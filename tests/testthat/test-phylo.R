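test_that("p-distances and the Poisson correction follow their definitions", {
  aln <- as_alignment(c(a = "MKLVAGHTWC", b = "MKLVAGHTWC"))
  expect_equal(pairwise_distances(aln, "p")["a", "b"], 0)

  # 3 mismatches over 10 comparable columns
  aln2 <- as_alignment(c(a = "MKLVAGHTWC", b = "MALVAGYTWA"))
  expect_equal(pairwise_distances(aln2, "p")["a", "b"], 0.3)
  expect_equal(pairwise_distances(aln2, "poisson")["a", "b"], -log(0.7))

  # gapped columns are pairwise-deleted
  aln3 <- as_alignment(c(a = "MK-VAGHTWC", b = "MAL-AGYTWA"))
  expect_equal(pairwise_distances(aln3, "p")["a", "b"], 3 / 8)

  expect_error(pairwise_distances(as_alignment(c(a = "--AA", b = "AA--")),
                                  "p"),
               "no comparable")
  expect_error(pairwise_distances(as_alignment(c(a = "MKLV", b = "AREW")),
                                  "poisson"),
               "saturated")
})

test_that("NJ recovers additive trees exactly, lengths included", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  dm <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(dm)
  expect_equal(ape::dist.topo(nj, ape::unroot(tr)), 0, ignore_attr = TRUE)
  d2 <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
  expect_lt(max(abs(d2 - dm)), 1e-9)

  # random additive matrices from random trees
  set.seed(51)
  for (case in 1:10) {
    rt <- ape::rtree(sample(5:12, 1))
    rt$edge.length <- rt$edge.length + 0.05
    dmr <- ape::cophenetic.phylo(rt)
    njr <- neighbor_joining(dmr)
    expect_equal(ape::dist.topo(njr, ape::unroot(rt)), 0,
                 ignore_attr = TRUE)
    dr <- ape::cophenetic.phylo(njr)[rownames(dmr), colnames(dmr)]
    expect_lt(max(abs(dr - dmr)), 1e-8)
  }
})

test_that("NJ agrees with the independent reference implementation", {
  set.seed(52)
  for (case in 1:8) {
    n <- sample(5:10, 1)
    labs <- paste0("t", seq_len(n))
    # random (noisy, non-additive) symmetric distance matrix
    d <- matrix(stats::runif(n * n, 0.1, 1.5), n, n,
                dimnames = list(labs, labs))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    mine <- neighbor_joining(d)
    ref <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("NJ needs three taxa and is invariant to label order", {
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  tr <- ape::rtree(8)
  dm <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(dm))
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
})

test_that("bootstrap supports are percentages of replicate bipartitions", {
  root <- list(id = "r", residues = random_aa_string(300))
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.3,(c:0.1,d:0.1):0.3,e:0.4);")
  aln <- evolve_on_tree(root, tree, rate = 1, seed = 61L)
  bt1 <- bootstrap_support(aln, 1L, seed = 62L)
  expect_true(all(as.integer(bt1$node.label) %in% c(0L, 100L)))
  bt <- bootstrap_support(aln, 50L, seed = 63L)
  expect_true(all(as.integer(bt$node.label) >= 0 &
                    as.integer(bt$node.label) <= 100))
  # deterministic under a fixed seed
  bt2 <- bootstrap_support(aln, 50L, seed = 63L)
  expect_identical(bt$node.label, bt2$node.label)
})

test_that("monophyly matches brute-force bipartition enumeration", {
  set.seed(53)
  for (case in 1:6) {
    tr <- ape::rtree(sample(5:10, 1))
    parts <- oracle_bipartitions(tr)
    tips <- tr$tip.label
    for (rep in 1:20) {
      labs <- sample(tips, sample(seq_along(tips), 1))
      expected <- any(vapply(parts, function(p) {
        setequal(p, labs) || setequal(setdiff(tips, p), labs)
      }, logical(1))) || length(labs) <= 1 || length(labs) == length(tips)
      expect_equal(is_monophyletic(tr, labs), expected)
    }
  }
  expect_error(is_monophyletic(ape::rtree(4), "nope"), "not in tree")
})

test_that("sister groups come from the rooted topology", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,e:3);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_equal(sister_group(tr, c("a", "b")), c("c", "d"))
  expect_equal(sister_group(tr, c("a", "b", "c", "d")), "e")
  expect_error(sister_group(tr, c("a", "c")), "not monophyletic")
  expect_error(sister_group(ape::unroot(tr), c("a", "b")), "rooted")
})

test_that("outgroup rooting bisects the subtending edge", {
  tr <- ape::read.tree(text = "(a:1,b:2,(c:3,d:4):0.5);")
  rooted <- root_on_outgroup(tr, "d")
  expect_true(ape::is.rooted(rooted))
  # all pairwise path lengths preserved
  d0 <- ape::cophenetic.phylo(tr)
  d1 <- ape::cophenetic.phylo(rooted)[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d1 - d0)), 1e-9)
  # d subtends the root on its own pendant edge
  expect_equal(sister_group(rooted, "d"), c("a", "b", "c"))

  expect_error(root_on_outgroup(tr, c("a", "b", "c", "d")), "every leaf")
  expect_error(root_on_outgroup(tr, c("a", "c")), "not a clade")
})
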