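test_that("pattern_filter returns exactly the subjects carrying the pattern", {
  corp <- clean_corpus()
  pat <- compile_pattern("FxGxxxHxxxH")
  hits <- pattern_filter(pat, corp$records)
  got <- unique(hits$id)
  # at zero noise, exactly the type IIb records with a penultimate H
  truth_h <- vapply(seq_len(nrow(corp$truth)), function(i) {
    tr <- corp$truth[i, ]
    if (is.na(tr$fmo_start) || tr$family %in% c("NMO", "classG")) {
      return(FALSE)
    }
    s <- corp$records$residues[corp$records$id == tr$id]
    substring(s, tr$fmo_start + 11L, tr$fmo_start + 11L) == "H"
  }, logical(1))
  expect_setequal(got, corp$truth$id[truth_h])
  expect_true(all(corp$truth$family[match(got, corp$truth$id)] == "typeIIb"))

  # empty corpus and too-long patterns give empty results
  expect_equal(nrow(pattern_filter(pat, corp$records[0, ])), 0L)
  long_pat <- compile_pattern(paste(rep("A", 600), collapse = ""))
  expect_equal(nrow(pattern_filter(long_pat, corp$records)), 0L)
})

test_that("self-alignment equals the sum of diagonal substitution scores", {
  set.seed(41)
  q <- random_aa_string(50)
  mat <- blosum62()
  al <- anchored_align(q, q, 10L, 5L)
  chars <- strsplit(q, "")[[1]]
  expect_equal(al$score, sum(mat[cbind(chars, chars)]))
  expect_equal(al$query_span, c(0L, 50L))
  expect_equal(al$subject_span, c(0L, 50L))
})

test_that("loosening the anchor constraint never lowers the score", {
  set.seed(42)
  for (case in 1:25) {
    a <- random_aa_string(30)
    b <- random_aa_string(30)
    narrow <- anchored_align(a, b, 5L, 4L)$score    # covers columns 5..8
    wide <- anchored_align(a, b, 0L, 30L)$score     # must cover everything
    expect_gte(narrow, wide)
  }
})

test_that("unknown residues are rejected against the matrix", {
  expect_error(anchored_align("MKL", "MK1", 0L, 2L), "not covered")
})

test_that("unrelated sequences score below self-alignment", {
  set.seed(43)
  q <- random_aa_string(50)
  r <- random_aa_string(50)
  self <- anchored_align(q, q, 0L, 10L)$score
  other <- anchored_align(q, r, 0L, 10L)$score
  expect_lt(other, self)
})

test_that("bit scores and e-values follow the Karlin-Altschul closed forms", {
  b <- bit_score(100)
  expect_equal(b, (0.267 * 100 - log(0.041)) / log(2))
  # doubling the database doubles the e-value
  expect_equal(evalue(b, 200, 2e6), 2 * evalue(b, 200, 1e6))
  # bit = 0 gives evalue m * n_db
  expect_equal(evalue(0, 137, 1000), 137000)
  # monotone decreasing in score
  es <- vapply(seq(10, 200, by = 10),
               function(s) evalue(bit_score(s), 100, 1e5), 0)
  expect_true(all(diff(es) < 0))
  expect_error(bit_score(10, lambda = 0), "positive")
  expect_error(evalue(10, 0, 10), ">= 1")
})

test_that("e-value bins partition the published ranges", {
  expect_equal(bin_evalue(c(0, 1e-71)), c("strong", "strong"))
  expect_equal(bin_evalue(1e-70), "mid")
  expect_equal(bin_evalue(1e-50), "mid")
  expect_equal(bin_evalue(1e-40), "weak")
  expect_equal(bin_evalue(1e-5), "weak")      # closed at the threshold
  expect_true(is.na(bin_evalue(2e-5)))
})

test_that("the pattern gate overrides similarity (PHI semantics)", {
  # subjects nearly identical to the query but without the pattern: no hits
  set.seed(44)
  core <- random_aa_string(200)
  query <- protein_records("q", paste0(substring(core, 1, 100),
                                       "FLGAGVHAAAHP",
                                       substring(core, 101, 200)))
  query$group <- "typeIIb"
  # same sequence with the motif histidine knocked out
  subj <- protein_records("s", gsub("FLGAGVHAAAHP", "FLGAGVAAAAHP",
                                    query$residues))
  hits <- run_phi_search(query, c(typeIIb = "FxGxxxHxxxH"), subj)
  expect_equal(nrow(hits), 0L)

  # with the motif intact the (self-like) subject is a strong hit
  subj2 <- protein_records("s2", query$residues)
  hits2 <- run_phi_search(query, c(typeIIb = "FxGxxxHxxxH"), subj2)
  expect_equal(hits2$subject, "s2")
  expect_equal(hits2$bin, "strong")
})

test_that("abundance aggregation conserves counts and renders N(M) cells", {
  corp <- clean_corpus()
  truth <- corp$truth
  pick <- function(fam) {
    corp$records[corp$records$id == truth$id[truth$family == fam][1], ]
  }
  queries <- rbind(pick("typeIIb"), pick("BVMO"))
  queries$group <- c("typeIIb", "BVMO")
  hits <- run_phi_search(queries,
                         c(typeIIb = "FxGxxxHxxxH", BVMO = "FxGxxxHxxxW"),
                         corp$records, corp$taxonomy)
  expect_gt(nrow(hits), 0L)
  # hit set is always inside the pattern-filter set
  for (g in unique(hits$group)) {
    pat <- compile_pattern(c(typeIIb = "FxGxxxHxxxH",
                             BVMO = "FxGxxxHxxxW")[[g]])
    allowed <- unique(pattern_filter(pat, corp$records)$id)
    expect_true(all(hits$subject[hits$group == g] %in% allowed))
  }
  ab <- aggregate_abundance(hits, corp$taxonomy)
  for (g in unique(ab$group)) {
    for (tx in unique(ab$taxon[ab$group == g])) {
      cell <- ab[ab$group == g & ab$taxon == tx, ]
      expect_equal(cell$homologs[cell$bin == "total"],
                   sum(cell$homologs[cell$bin != "total"]))
      expect_true(all(cell$species <= cell$homologs))
    }
  }
  rendered <- render_abundance(ab)
  tot <- rendered[rendered$bin == "total" & rendered$homologs > 0, ][1, ]
  expect_equal(tot$cell, sprintf("%d(%d)", tot$homologs, tot$species))
  tax_missing <- corp$taxonomy[corp$taxonomy$id != hits$subject[1], ]
  expect_error(aggregate_abundance(hits, tax_missing),
               "missing from taxonomy")
})
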