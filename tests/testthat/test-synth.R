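test_that("default family specs encode the published motif statistics", {
  specs <- default_family_specs()
  expect_length(specs, 10L)
  iib <- specs$typeIIb
  expect_equal(unname(iib$diagnostic_distribution$penultimate["H"]), 0.70)
  expect_equal(unname(iib$diagnostic_distribution$last["P"]), 1)
  expect_equal(unname(iib$nadph$emissions[["3"]]["N"]), 0.57)
  expect_equal(unname(specs$BVMO$diagnostic_distribution$penultimate["W"]), 1)
  expect_true(isTRUE(specs$NMO$fmo$relaxed))
  expect_null(specs$classG$fmo)
  expect_equal(iib$nterm_extension_len, 160L)
  expect_true(all(vapply(specs, function(s) s$nterm_extension_len, 0L) ==
                    ifelse(names(specs) == "typeIIb", 160L, 0L)))
})

test_that("zero-noise corpora match the family templates at the truth offsets", {
  corp <- clean_corpus()
  specs <- default_family_specs()
  pats <- list(
    fad = compile_pattern("GxGxx[GAN]"),
    nadph = compile_pattern("Gx[GN]xx[GA]"),
    core = compile_pattern("FxGxxxHxxx")
  )
  for (i in seq_len(nrow(corp$truth))) {
    tr <- corp$truth[i, ]
    s <- corp$records$residues[corp$records$id == tr$id]
    expect_true(tr$fad_start %in%
                  find_all(pats$fad, s, c(tr$fad_start, tr$fad_start + 6L))$start)
    expect_true(tr$nadph_start %in%
                  find_all(pats$nadph, s,
                           c(tr$nadph_start, tr$nadph_start + 6L))$start)
    fam <- tr$family
    if (!fam %in% c("NMO", "classG")) {
      expect_true(tr$fmo_start %in%
                    find_all(pats$core, s,
                             c(tr$fmo_start, tr$fmo_start + 10L))$start)
    }
  }
  # strict motif ordering
  ok <- is.na(corp$truth$fmo_start) |
    (corp$truth$fad_start < corp$truth$fmo_start &
       corp$truth$fmo_start < corp$truth$nadph_start)
  expect_true(all(ok))
  expect_true(all(corp$truth$fad_start < corp$truth$nadph_start))
})

test_that("a fixed seed reproduces the corpus byte for byte", {
  c1 <- generate_corpus(sim_config(n_per_family = 5L, seed = 77L,
                                   substitution_rate = 0.03,
                                   motif_rate_multiplier = 0.5))
  c2 <- generate_corpus(sim_config(n_per_family = 5L, seed = 77L,
                                   substitution_rate = 0.03,
                                   motif_rate_multiplier = 0.5))
  expect_identical(c1, c2)
  c3 <- generate_corpus(sim_config(n_per_family = 5L, seed = 78L))
  expect_false(identical(c1$records$residues, c3$records$residues))
})

test_that("diagnostic-residue frequencies obey the binomial sampling bound", {
  corp <- fixture("iib_corpus_200", function() {
    generate_corpus(sim_config(
      n_per_family = 200L, seed = 202L,
      families = default_family_specs()["typeIIb"],
      taxon_assignment = default_taxon_assignment()["typeIIb"]
    ))
  })
  pen <- vapply(seq_len(nrow(corp$truth)), function(i) {
    s <- corp$records$residues[i]
    substring(s, corp$truth$fmo_start[i] + 11L, corp$truth$fmo_start[i] + 11L)
  }, "")
  frac <- mean(pen == "H")
  expect_lt(abs(frac - 0.70), 3 * sqrt(0.70 * 0.30 / 200))
})

test_that("truth labels cover every record", {
  corp <- clean_corpus()
  expect_setequal(corp$records$id, corp$truth$id)
  expect_false(any(is.na(corp$truth$family)))
  expect_setequal(corp$taxonomy$id, corp$records$id)
})

test_that("evolve_on_tree follows the per-branch substitution model", {
  root <- list(id = "r", residues = random_aa_string(60))
  tree <- ape::read.tree(text = "(a:0.15,b:0.15);")
  expect_error(evolve_on_tree(root, tree, rate = 0), "positive")

  # fixed seed reproducibility
  a1 <- evolve_on_tree(root, tree, rate = 1, seed = 31L)
  a2 <- evolve_on_tree(root, tree, rate = 1, seed = 31L)
  expect_identical(a1, a2)

  # saturation curve: p-distance at 10,000 sites vs the 20-state closed form
  root_big <- list(id = "r", residues = random_aa_string(10000))
  aln <- evolve_on_tree(root_big, tree, rate = 1, seed = 32L)
  p <- pairwise_distances(aln, "p")["a", "b"]
  t_total <- 0.3
  expected <- (19 / 20) * (1 - exp(-(20 / 19) * 1 * t_total))
  expect_lt(abs(p - expected), 0.015)

  # motif intervals evolve at the reduced rate
  aln2 <- evolve_on_tree(root_big, tree, rate = 1, seed = 33L,
                         motif_intervals = list(c(0L, 5000L)),
                         motif_rate_multiplier = 0)
  m <- do.call(rbind, lapply(unclass(aln2), function(x) strsplit(x, "")[[1]]))
  expect_true(all(m[1, 1:5000] == m[2, 1:5000]))
  expect_gt(sum(m[1, 5001:10000] != m[2, 5001:10000]), 0)
})

test_that("generator rejects impossible geometry", {
  specs <- default_family_specs()["typeIIb"]
  specs$typeIIb$core_len <- 100L
  expect_error(
    generate_corpus(sim_config(n_per_family = 1L, seed = 1L,
                               families = specs,
                               taxon_assignment =
                                 default_taxon_assignment()["typeIIb"])),
    "too small"
  )
})
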