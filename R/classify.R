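# classify: assignment of annotated sequences to the ten class B
# flavoprotein monooxygenase groups from diagnostic motif residues and
# N-terminal domain architecture.

CALL_LEVELS <- c(FAMILY_LEVELS, "FMO_like_unresolved", "unclassified")

#' Classification thresholds
#'
#' @param extension_min minimum FAD-hit offset (residues) counted as an
#'   N-terminal extension. The extension characteristic of type IIb FMOs is
#'   approximately 160 residues; the default of 100 leaves a noise margin.
#' @export
classify_thresholds <- function(extension_min = 100L) {
  list(extension_min = as.integer(extension_min))
}

secondary_flags <- function(ann, thresholds) {
  flags <- character(0L)
  if (!is.na(ann$nterm_extension_len) &&
      ann$nterm_extension_len >= thresholds$extension_min) {
    flags <- c(flags, "nterm_extension")
  }
  if (!is.na(ann$nadph_second) && ann$nadph_second == "N") {
    flags <- c(flags, "nadph_second_N")
  }
  if (!is.na(ann$fad_third) && ann$fad_third == "A") {
    flags <- c(flags, "fad_third_A")
  }
  if (!is.na(ann$fad_third) && ann$fad_third == "N") {
    flags <- c(flags, "fad_third_N")
  }
  if (!is.na(ann$nadph_last) && ann$nadph_last == "A") {
    flags <- c(flags, "nadph_last_A")
  }
  flags
}

#' Assign a family from one sequence annotation
#'
#' Decision order:
#' 1. no FAD or no NADPH Rossmann hit: `unclassified`;
#' 2. FMO core absent: `NMO` when the relaxed conserved H is present
#'    (confidence is demoted when neither the NMO-type FAD motif, third
#'    position N, nor NADPH motif, last position A, corroborates the call);
#'    otherwise a `classG` candidate;
#' 3. penultimate W: `BVMO`;
#' 4. penultimate H: `typeIIb` (H at this position is near-exclusive to the
#'    family);
#' 5. last P: `typeIIb` (catches the ~30% of type IIb sequences with Y/F at
#'    the penultimate position);
#' 6. penultimate Y/F with last K/R: `FMO_like_unresolved` (the six
#'    motif-indistinguishable FMO-like groups; separation needs tree
#'    evidence, see [resolve_fmo_like()]);
#' 7. anything else: `unclassified`.
#'
#' A terminal residue outside \{P, K, R\} never vetoes a penultimate-H call
#' (type IIb sequences with a terminal G exist). Confidence is `high` when
#' no secondary evidence conflicts with the call, `medium` with one
#' conflict, `low` otherwise.
#'
#' @param annotation one row of [annotate_all()] output.
#' @param thresholds see [classify_thresholds()].
#' @return one-row `data.frame`: `id`, `family`, `primary_evidence`,
#'   `secondary_evidence` (comma-joined flags), `confidence`.
#' @export
call_family <- function(annotation, thresholds = classify_thresholds()) {
  ann <- as.list(annotation[1L, ])
  flags <- secondary_flags(ann, thresholds)
  family <- "unclassified"
  primary <- NA_character_
  conflicts <- 0L

  has_rossmann <- !is.na(ann$fad_start) && !is.na(ann$nadph_start)
  has_core <- !is.na(ann$fmo_kind) && ann$fmo_kind == "FMO"
  has_nmo_h <- !is.na(ann$fmo_kind) && ann$fmo_kind == "NMO_H"

  if (!has_rossmann) {
    family <- "unclassified"
  } else if (!has_core) {
    if (has_nmo_h) {
      family <- "NMO"
      primary <- "NMO_H_only"
      # an NMO call without its characteristic FAD-third-N or NADPH-last-A
      # variant is indistinguishable from a class G record with a chance
      # histidine; record the missing corroboration as a conflict
      if (!any(c("fad_third_N", "nadph_last_A") %in% flags)) {
        conflicts <- conflicts + 1L
      }
    } else {
      family <- "classG"
      primary <- "no_FMO_motif"
    }
  } else {
    pen <- ann$fmo_penultimate
    las <- ann$fmo_last
    if (!is.na(pen) && pen == "W") {
      family <- "BVMO"
      primary <- "penultimate_W"
    } else if (!is.na(pen) && pen == "H") {
      family <- "typeIIb"
      primary <- "penultimate_H"
    } else if (!is.na(las) && las == "P") {
      family <- "typeIIb"
      primary <- "last_P"
    } else if (!is.na(pen) && pen %in% c("Y", "F") &&
               !is.na(las) && las %in% c("K", "R")) {
      family <- "FMO_like_unresolved"
      primary <- "YF_KR"
    } else {
      family <- "unclassified"
    }
  }

  has_ext <- "nterm_extension" %in% flags
  if (family == "typeIIb" && !has_ext) conflicts <- conflicts + 1L
  if (!family %in% c("typeIIb", "unclassified") && has_ext) {
    conflicts <- conflicts + 1L
  }
  if (family == "BVMO" && !("nadph_last_A" %in% flags)) {
    conflicts <- conflicts + 1L
  }
  confidence <- if (family == "unclassified") {
    "low"
  } else if (conflicts == 0L) {
    "high"
  } else if (conflicts == 1L) {
    "medium"
  } else {
    "low"
  }

  data.frame(
    id = ann$id, family = family, primary_evidence = primary,
    secondary_evidence = paste(flags, collapse = ","),
    confidence = confidence, stringsAsFactors = FALSE
  )
}

#' Classify a whole annotation table
#'
#' @param annotations output of [annotate_all()].
#' @param thresholds see [classify_thresholds()].
#' @return `data.frame` of family calls, one row per annotation.
#' @export
classify_all <- function(annotations, thresholds = classify_thresholds()) {
  do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    call_family(annotations[i, ], thresholds)
  }))
}

#' Resolve an FMO-like call with tree evidence
#'
#' Tree evidence outranks motif evidence for the six FMO-like groups: when a
#' clade label is supplied, the family is set from it. A clade label that
#' contradicts the motif evidence (e.g. an NMO clade label for a sequence
#' with a full FMO motif) is accepted but demotes confidence to `low`.
#'
#' @param call one-row family-call `data.frame` with
#'   `family == "FMO_like_unresolved"`.
#' @param annotation the matching [annotate_all()] row.
#' @param group_context optional clade label from the ten-group vocabulary.
#' @export
resolve_fmo_like <- function(call, annotation, group_context = NULL) {
  stopifnot(call$family == "FMO_like_unresolved")
  if (is.null(group_context)) return(call)
  if (!group_context %in% FAMILY_LEVELS) {
    stop2("clade label '", group_context,
          "' is not one of the ten family groups")
  }
  call$family <- group_context
  if (!group_context %in% FMO_LIKE_FAMILIES) {
    # motif evidence said FMO-like; record the conflict
    call$confidence <- "low"
  }
  call
}

#' Score family calls against generator truth
#'
#' @param calls family-call `data.frame` ([classify_all()]).
#' @param truth truth table from [generate_corpus()] (columns `id`,
#'   `family`). Every call id must be present.
#' @param coarse when `TRUE`, an `FMO_like_unresolved` call counts as
#'   correct for any of the six FMO-like truth families.
#' @return list with `confusion` (truth x call matrix), `recall` and
#'   `precision` (named per family), `n` per truth family.
#' @export
score_against_truth <- function(calls, truth, coarse = TRUE) {
  m <- match(calls$id, truth$id)
  if (anyNA(m)) {
    stop2("call id(s) missing from truth: ",
          paste(calls$id[is.na(m)], collapse = ", "))
  }
  tf <- factor(truth$family[m], levels = FAMILY_LEVELS)
  cf <- factor(calls$family, levels = CALL_LEVELS)
  confusion <- table(truth = tf, call = cf)

  correct <- calls$family == truth$family[m]
  if (coarse) {
    correct <- correct | (calls$family == "FMO_like_unresolved" &
                            truth$family[m] %in% FMO_LIKE_FAMILIES)
  }
  recall <- vapply(FAMILY_LEVELS, function(f) {
    idx <- truth$family[m] == f
    if (!any(idx)) return(NA_real_)
    mean(correct[idx])
  }, numeric(1L))
  precision <- vapply(CALL_LEVELS, function(f) {
    idx <- calls$family == f
    if (!any(idx)) return(NA_real_)
    mean(correct[idx])
  }, numeric(1L))
  n <- vapply(FAMILY_LEVELS, function(f) sum(truth$family[m] == f),
              integer(1L))
  list(confusion = confusion, recall = recall, precision = precision, n = n)
}

#' Export family calls as TSV
#' @param calls family-call `data.frame`.
#' @param path output path.
#' @export
write_calls <- function(calls, path) write_table(calls, path)
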