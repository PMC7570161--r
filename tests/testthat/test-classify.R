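mk_ann <- function(id = "x", fad_start = 10L, fmo_start = 190L,
                   fmo_kind = "FMO", nadph_start = 230L,
                   pen = "Y", las = "K", fad_third = "G",
                   nadph_second = "G", nadph_last = "G",
                   ext = 10L) {
  data.frame(
    id = id, fad_start = fad_start, fmo_start = fmo_start,
    fmo_kind = fmo_kind, nadph_start = nadph_start,
    fmo_penultimate = pen, fmo_last = las, fad_third = fad_third,
    nadph_second = nadph_second, nadph_last = nadph_last,
    nterm_extension_len = ext,
    core_coverage = 0.95, stringsAsFactors = FALSE
  )
}

test_that("diagnostic residues drive the family call", {
  # penultimate H with a non-canonical terminal G and a long extension:
  # the charophyte-like type IIb configuration
  call <- call_family(mk_ann(pen = "H", las = "G", ext = 158L,
                             nadph_second = "N", nadph_last = "A"))
  expect_equal(call$family, "typeIIb")
  expect_equal(call$primary_evidence, "penultimate_H")
  expect_equal(call$confidence, "high")

  call <- call_family(mk_ann(pen = "W", las = "R", nadph_last = "A"))
  expect_equal(call$family, "BVMO")
  expect_equal(call$primary_evidence, "penultimate_W")

  call <- call_family(mk_ann(pen = "Y", las = "K"))
  expect_equal(call$family, "FMO_like_unresolved")
  expect_equal(call$primary_evidence, "YF_KR")
})

test_that("the last-P rule catches type IIb records without penultimate H", {
  # ablation of the penultimate-H route: Y/F penultimate, P last
  for (pen in c("Y", "F")) {
    call <- call_family(mk_ann(pen = pen, las = "P", ext = 160L,
                               nadph_second = "N"))
    expect_equal(call$family, "typeIIb")
    expect_equal(call$primary_evidence, "last_P")
  }
})

test_that("missing Rossmann hits and odd residues give unclassified", {
  expect_equal(call_family(mk_ann(fad_start = NA_integer_))$family,
               "unclassified")
  expect_equal(call_family(mk_ann(nadph_start = NA_integer_))$family,
               "unclassified")
  expect_equal(call_family(mk_ann(pen = "Q", las = "Q"))$family,
               "unclassified")
})

test_that("records without an FMO core split into NMO and class G", {
  nmo <- call_family(mk_ann(fmo_kind = "NMO_H", pen = NA, las = NA,
                            fad_third = "N", nadph_last = "A"))
  expect_equal(nmo$family, "NMO")
  expect_equal(nmo$primary_evidence, "NMO_H_only")
  expect_equal(nmo$confidence, "high")

  # uncorroborated lone H still calls NMO but with demoted confidence
  nmo2 <- call_family(mk_ann(fmo_kind = "NMO_H", pen = NA, las = NA))
  expect_equal(nmo2$family, "NMO")
  expect_false(nmo2$confidence == "high")

  g <- call_family(mk_ann(fmo_kind = NA, fmo_start = NA_integer_,
                          pen = NA, las = NA))
  expect_equal(g$family, "classG")
  expect_equal(g$primary_evidence, "no_FMO_motif")
})

test_that("every annotation yields exactly one family", {
  ann <- clean_annotations()
  calls <- classify_all(ann)
  expect_equal(nrow(calls), nrow(ann))
  expect_true(all(calls$family %in% c(FAMILY_LEVELS, "FMO_like_unresolved",
                                      "unclassified")))
  expect_false(any(is.na(calls$family)))
})

test_that("tree evidence resolves (and outranks) FMO-like motif calls", {
  call <- call_family(mk_ann(pen = "Y", las = "K"))
  ann <- mk_ann(pen = "Y", las = "K")
  expect_equal(resolve_fmo_like(call, ann, "YUCCA")$family, "YUCCA")
  expect_identical(resolve_fmo_like(call, ann, NULL), call)
  expect_error(resolve_fmo_like(call, ann, "weird_clade"), "ten family")
  conflicted <- resolve_fmo_like(call, ann, "NMO")
  expect_equal(conflicted$family, "NMO")
  expect_equal(conflicted$confidence, "low")
})

test_that("scoring against truth measures coarse recall correctly", {
  corp <- clean_corpus()
  calls <- classify_all(clean_annotations())
  sc <- score_against_truth(calls, corp$truth, coarse = TRUE)
  expect_true(all(sc$recall == 1))
  expect_equal(sum(sc$confusion), nrow(calls))

  # permuted truth labels: recall collapses towards chance
  perm <- corp$truth
  set.seed(9)
  perm$family <- sample(perm$family)
  sc_perm <- score_against_truth(calls, perm, coarse = TRUE)
  expect_lt(mean(sc_perm$recall, na.rm = TRUE), 0.5)

  # missing truth ids are a hard error
  expect_error(score_against_truth(calls, corp$truth[-1, ], coarse = TRUE),
               "missing from truth")

  # empty call set gives an all-zero confusion matrix
  empty <- calls[0, ]
  sc0 <- score_against_truth(empty, corp$truth)
  expect_equal(sum(sc0$confusion), 0)
})
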