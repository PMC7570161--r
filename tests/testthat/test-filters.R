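test_that("rows with excessive core gaps are rejected, gap-free rows never", {
  rows <- c(
    good = paste(rep("M", 30), collapse = ""),
    half = paste0(paste(rep("-", 10), collapse = ""),
                  paste(rep("M", 20), collapse = "")),
    bad = paste(rep("-", 30), collapse = "")
  )
  aln <- as_alignment(rows)
  rep1 <- reject_poorly_aligned(aln, c(0L, 30L), 0.5)
  expect_setequal(rep1$kept, c("good", "half"))
  expect_equal(rep1$dropped$id, "bad")
  expect_equal(rep1$dropped$reason, "poorly_aligned")

  # gap-free rows survive any threshold
  rep2 <- reject_poorly_aligned(aln, c(0L, 30L), 0.01)
  expect_true("good" %in% rep2$kept)

  expect_error(reject_poorly_aligned(aln, c(0L, 31L), 0.5), "outside")
})

test_that("corrupting one row of sixty keeps the dropped fraction below 2%", {
  set.seed(71)
  rows <- vapply(1:60, function(i) random_aa_string(120), "")
  names(rows) <- paste0("r", 1:60)
  rows["r13"] <- paste0(paste(rep("-", 100), collapse = ""),
                        substring(rows["r13"], 101, 120))
  rep <- reject_poorly_aligned(as_alignment(rows), c(0L, 100L), 0.5)
  expect_equal(rep$dropped$id, "r13")
  expect_lt(rep$fraction_dropped, 0.02)
})

test_that("filters are idempotent", {
  set.seed(72)
  rows <- vapply(1:20, function(i) random_aa_string(50), "")
  names(rows) <- paste0("r", 1:20)
  rows["r5"] <- paste(rep("-", 50), collapse = "")
  aln <- as_alignment(rows)
  r1 <- reject_poorly_aligned(aln, c(0L, 50L), 0.5)
  aln2 <- as_alignment(rows[r1$kept])
  r2 <- reject_poorly_aligned(aln2, c(0L, 50L), 0.5)
  expect_setequal(r2$kept, r1$kept)
  expect_equal(nrow(r2$dropped), 0L)
})

redundancy_fixture <- function() {
  set.seed(73)
  tr <- ape::rtree(10)
  tr$tip.label <- paste0("leaf", 1:10)
  recs <- protein_records(tr$tip.label,
                          vapply(1:10, function(i) random_aa_string(40), ""),
                          species = paste0("sp", rep(1:5, each = 2)))
  list(tree = tr, records = recs)
}

test_that("redundancy reduction keeps whitelisted species and respects caps", {
  fx <- redundancy_fixture()
  clades <- list(all = fx$tree$tip.label)

  # cap not binding: everything kept
  r_all <- reduce_redundancy(fx$tree, fx$records, clades,
                             list(whitelist = character(0),
                                  max_per_clade = 10L, min_dist = 0))
  expect_setequal(r_all$kept, fx$tree$tip.label)

  r5 <- reduce_redundancy(fx$tree, fx$records, clades,
                          list(whitelist = character(0),
                               max_per_clade = 5L, min_dist = 0))
  expect_length(r5$kept, 5L)
  expect_equal(unique(r5$dropped$reason), "redundant")

  # whitelisted species always survive
  rw <- reduce_redundancy(fx$tree, fx$records, clades,
                          list(whitelist = c("sp1", "sp3"),
                               max_per_clade = 5L, min_dist = 0))
  wl_ids <- fx$records$id[fx$records$species %in% c("sp1", "sp3")]
  expect_true(all(wl_ids %in% rw$kept))

  # absent whitelist species warn but do not fail
  expect_warning(
    reduce_redundancy(fx$tree, fx$records, clades,
                      list(whitelist = "missing_species",
                           max_per_clade = 5L, min_dist = 0)),
    "absent"
  )
})

test_that("greedy maximin selection is deterministic and idempotent", {
  fx <- redundancy_fixture()
  clades <- list(all = fx$tree$tip.label)
  rules <- list(whitelist = character(0), max_per_clade = 4L, min_dist = 0)
  r1 <- reduce_redundancy(fx$tree, fx$records, clades, rules)
  r2 <- reduce_redundancy(fx$tree, fx$records, clades, rules)
  expect_identical(r1$kept, r2$kept)

  # independent re-implementation of the greedy order
  d <- ape::cophenetic.phylo(fx$tree)
  ids <- sort(fx$tree$tip.label)
  sub <- d[ids, ids]
  far <- which(sub == max(sub), arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  keyz <- apply(far, 1, function(ij) paste(sort(ids[ij]), collapse = "\r"))
  sel <- sort(ids[far[order(keyz)[1], ]])
  pool <- setdiff(ids, sel)
  while (length(sel) < 4) {
    mind <- vapply(pool, function(x) min(d[x, sel]), 0)
    cand <- sort(pool[mind == max(mind)])[1]
    sel <- c(sel, cand)
    pool <- setdiff(pool, cand)
  }
  expect_setequal(r1$kept, sel)

  # applying the filter to its own output changes nothing
  keep2 <- reduce_redundancy(ape::keep.tip(fx$tree, r1$kept),
                             fx$records[fx$records$id %in% r1$kept, ],
                             list(all = r1$kept), rules)
  expect_setequal(keep2$kept, r1$kept)
})
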