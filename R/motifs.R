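# motifs: detection of the ordered functional motifs of class B flavoprotein
# monooxygenases -- the FAD-binding Rossmann motif near the N terminus, the
# FMO-identifying motif, and the NADPH-binding Rossmann motif -- plus the
# relaxed single-histidine variant carried by NMOs.

#' Compile a motif pattern
#'
#' Dialect: an uppercase amino-acid letter is a literal, `x` is a wildcard
#' matching any residue (including `X`), and `[AB]` is an alternative set.
#' Matching is case-insensitive on the sequence side; an `X` residue in a
#' sequence matches wildcards but never a literal.
#'
#' @param text pattern string, e.g. `"FxGxxxHxxxW"` or `"GxGxx[GA]"`.
#' @return an object of class `fmo_pattern` with fields `text`, `length` and
#'   `elements` (a list with `NULL` for wildcards and a character vector of
#'   allowed residues for constrained positions).
#' @export
compile_pattern <- function(text) {
  chars <- seq_chars(text)
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character(0L)
      closed <- FALSE
      while (j <= length(chars)) {
        if (chars[j] == "]") {
          closed <- TRUE
          break
        }
        if (!chars[j] %in% AA_ALPHABET20) {
          stop2("pattern parse error at offset ", j - 1L,
                ": '", chars[j], "' is not an amino-acid letter")
        }
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (!closed) stop2("pattern parse error at offset ", i - 1L,
                         ": unbalanced '['")
      if (length(set) == 0L) stop2("pattern parse error at offset ", i - 1L,
                                   ": empty alternative set")
      elements[[length(elements) + 1L]] <- unique(set)
      i <- j + 1L
    } else if (ch == "]") {
      stop2("pattern parse error at offset ", i - 1L, ": unbalanced ']'")
    } else if (ch == "x") {
      elements[[length(elements) + 1L]] <- NULL_ELEMENT
      i <- i + 1L
    } else if (ch %in% AA_ALPHABET20) {
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop2("pattern parse error at offset ", i - 1L,
            ": unexpected character '", ch, "'")
    }
  }
  structure(
    list(text = text, length = length(elements), elements = elements),
    class = "fmo_pattern"
  )
}

# sentinel kept distinct from NULL so list() retains wildcard slots
NULL_ELEMENT <- NA_character_

is_wildcard <- function(el) length(el) == 1L && is.na(el[1L])

#' Find all pattern occurrences in a sequence
#'
#' Scans every 0-based offset in `window` (half-open) at which the whole
#' pattern fits inside the sequence, and reports occurrences with at most
#' `max_mismatch` constrained positions violated. Overlapping occurrences are
#' all reported, in ascending offset order.
#'
#' @param pattern an `fmo_pattern` from [compile_pattern()].
#' @param residues sequence string.
#' @param window integer pair `c(lo, hi)`, 0-based half-open; defaults to the
#'   whole sequence. Out-of-bounds windows are a hard error.
#' @param max_mismatch number of constrained positions allowed to mismatch
#'   (0 = exact matching).
#' @return `data.frame` with columns `start` (0-based), `matched`,
#'   `mismatches`.
#' @export
find_all <- function(pattern, residues, window = NULL, max_mismatch = 0L) {
  stopifnot(inherits(pattern, "fmo_pattern"))
  len <- nchar(residues)
  if (is.null(window)) window <- c(0L, len)
  if (window[1L] < 0L || window[2L] > len || window[1L] > window[2L]) {
    stop2("window [", window[1L], ",", window[2L],
          ") out of bounds for sequence of length ", len)
  }
  empty <- data.frame(start = integer(0L), matched = character(0L),
                      mismatches = integer(0L), stringsAsFactors = FALSE)
  plen <- pattern$length
  last_start <- min(window[2L], len) - plen    # 0-based inclusive
  if (plen == 0L || last_start < window[1L]) return(empty)
  chars <- toupper(seq_chars(residues))
  starts <- window[1L]:last_start              # 0-based
  mm <- integer(length(starts))
  for (j in seq_len(plen)) {
    el <- pattern$elements[[j]]
    if (is_wildcard(el)) next
    mm <- mm + as.integer(!(chars[starts + j] %in% el))
  }
  keep <- mm <= max_mismatch
  if (!any(keep)) return(empty)
  st <- starts[keep]
  data.frame(
    start = st,
    matched = substring(paste(chars, collapse = ""), st + 1L, st + plen),
    mismatches = mm[keep],
    stringsAsFactors = FALSE
  )
}

#' Default motif ruleset
#'
#' Patterns, search windows and spacing priors used by [annotate()]:
#' * FAD-binding Rossmann motif `GxGxx[GAN]`, searched in `[0, 250)` so that
#'   the ~160-residue N-terminal extension of type IIb FMOs is accommodated;
#' * FMO-identifying core `FxGxxxHxxx`, extended by two free positions
#'   (penultimate and last of the 12-position motif), searched downstream of
#'   the FAD hit;
#' * NADPH-binding Rossmann motif `Gx[GN]xx[GA]`, searched downstream of the
#'   FMO hit.
#'
#' Spacing priors (FAD start to FMO start 150-220 residues; FMO end to NADPH
#' start 0-40) act as tie-breakers between candidate arrangements, never as
#' hard filters for exact matches. When no exact match exists,
#' single-mismatch fallback hits are considered; the FMO-core fallback is
#' additionally gated on zero spacing deviation and on both trailing
#' positions carrying residues from the known diagnostic repertoire, so that
#' sequences genuinely lacking the motif are not assigned a spurious one.
#' The relaxed NMO histidine is sought near the NADPH Rossmann hit (the FMO
#' motif sits just upstream of the second Rossmann motif), offsets
#' `nmo_window` relative to the NADPH start.
#'
#' @param extension_min minimum FAD-hit offset regarded as an N-terminal
#'   extension by downstream classification (residues).
#' @return a ruleset list, YAML-serialisable.
#' @export
default_ruleset <- function(extension_min = 100L) {
  list(
    fad_pattern = "GxGxx[GAN]",
    fmo_core_pattern = "FxGxxxHxxx",
    fmo_extra_positions = 2L,
    nadph_pattern = "Gx[GN]xx[GA]",
    fad_window = c(0L, 250L),
    spacing_fad_fmo = c(150L, 220L),
    spacing_fmo_nadph = c(0L, 40L),
    spacing_fad_nadph = c(150L, 280L),
    nmo_window = c(-46L, -9L),
    nmo_flank = c(6L, 4L),
    allow_mismatch = TRUE,
    diagnostic_penultimate = c("H", "Y", "F", "W"),
    diagnostic_last = c("P", "K", "R"),
    extension_min = as.integer(extension_min)
  )
}

#' Read / write a motif ruleset as YAML
#' @param path YAML file path.
#' @export
read_ruleset <- function(path) {
  rs <- yaml::read_yaml(path)
  base <- default_ruleset()
  for (nm in names(rs)) base[[nm]] <- rs[[nm]]
  base
}

#' @rdname read_ruleset
#' @param ruleset ruleset list.
#' @export
write_ruleset <- function(ruleset, path) {
  yaml::write_yaml(ruleset, path)
  invisible(path)
}

interval_deviation <- function(x, bounds) {
  max(0L, bounds[1L] - x) + max(0L, x - bounds[2L])
}

motif_hit <- function(kind, start, matched, mismatches = 0L) {
  list(kind = kind, start = as.integer(start), matched = matched,
       mismatches = as.integer(mismatches))
}

#' Annotate one protein sequence with its motif architecture
#'
#' Finds the best ordered arrangement FAD < FMO < NADPH under the scoring:
#' (1) maximise the number of motifs found, (2) prefer the FAD hit with the
#' smallest start, (3) minimise the total deviation from the expected
#' spacings, breaking remaining ties by the smallest FMO then NADPH start.
#' If no FMO core is accepted, the relaxed NMO histidine is attempted and
#' recorded with kind `NMO_H`. The annotation records the diagnostic
#' residues (FMO-motif penultimate/last; FAD-motif third conserved position;
#' NADPH-motif second and last conserved positions), the N-terminal
#' extension length (the FAD-hit offset) and the core coverage
#' `(length - fad_start) / length`. Absent motifs are recorded as absent,
#' never raised as errors.
#'
#' @param record one row of a protein-record `data.frame`, or a list with
#'   `id` and `residues`.
#' @param ruleset see [default_ruleset()].
#' @return a list of class `fmo_annotation`.
#' @export
annotate <- function(record, ruleset = default_ruleset()) {
  id <- record$id[1L]
  residues <- toupper(record$residues[1L])
  len <- nchar(residues)
  pat_fad <- compile_pattern(ruleset$fad_pattern)
  pat_core <- compile_pattern(ruleset$fmo_core_pattern)
  pat_nadph <- compile_pattern(ruleset$nadph_pattern)
  extra <- ruleset$fmo_extra_positions
  fmo_len <- pat_core$length + extra

  ann <- structure(
    list(id = id, fad = NULL, fmo = NULL, nadph = NULL,
         fmo_penultimate = NA_character_, fmo_last = NA_character_,
         fad_third = NA_character_, nadph_second = NA_character_,
         nadph_last = NA_character_,
         nterm_extension_len = NA_integer_, core_coverage = NA_real_),
    class = "fmo_annotation"
  )

  fad_win <- c(ruleset$fad_window[1L], min(ruleset$fad_window[2L], len))
  if (fad_win[2L] <= fad_win[1L]) return(ann)
  fads_exact <- find_all(pat_fad, residues, fad_win)

  chars <- seq_chars(residues)
  best <- NULL   # list(count, fad, fmo, nadph, dev)

  consider <- function(cand) {
    if (is.null(best)) {
      best <<- cand
      return(invisible(NULL))
    }
    b <- best
    better <- FALSE
    if (cand$count != b$count) {
      better <- cand$count > b$count
    } else if (cand$fad$start != b$fad$start) {
      better <- cand$fad$start < b$fad$start
    } else if (cand$dev != b$dev) {
      better <- cand$dev < b$dev
    } else {
      cs <- if (is.null(cand$fmo)) Inf else cand$fmo$start
      bs <- if (is.null(b$fmo)) Inf else b$fmo$start
      if (cs != bs) {
        better <- cs < bs
      } else {
        cn <- if (is.null(cand$nadph)) Inf else cand$nadph$start
        bn <- if (is.null(b$nadph)) Inf else b$nadph$start
        better <- cn < bn
      }
    }
    if (better) best <<- cand
    invisible(NULL)
  }

  evaluate_fads <- function(fads) {
  for (fi in seq_len(nrow(fads))) {
    fad <- motif_hit("FAD", fads$start[fi], fads$matched[fi],
                     fads$mismatches[fi])
    fad_end <- fad$start + pat_fad$length
    if (fad_end >= len) {
      consider(list(count = 1L, fad = fad, fmo = NULL, nadph = NULL, dev = 0L))
      next
    }
    # exact FMO cores with the two trailing diagnostic positions available
    cores <- find_all(pat_core, residues, c(fad_end, len))
    cores <- cores[cores$start + fmo_len <= len, , drop = FALSE]
    core_tier <- rep(0L, nrow(cores))
    if (nrow(cores) == 0L && isTRUE(ruleset$allow_mismatch)) {
      cores <- find_all(pat_core, residues, c(fad_end, len), max_mismatch = 1L)
      cores <- cores[cores$start + fmo_len <= len, , drop = FALSE]
      if (nrow(cores) > 0L) {
        # fallback cores must sit at zero spacing deviation and show
        # diagnostic-repertoire residues at the trailing positions
        pen <- chars[cores$start + fmo_len - 1L]
        las <- chars[cores$start + fmo_len]
        ok <- pen %in% ruleset$diagnostic_penultimate &
          las %in% ruleset$diagnostic_last &
          vapply(cores$start, function(s) {
            interval_deviation(s - fad$start, ruleset$spacing_fad_fmo) == 0L
          }, logical(1L))
        cores <- cores[ok, , drop = FALSE]
        core_tier <- rep(1L, nrow(cores))
      }
    }

    any_triple <- FALSE
    if (nrow(cores) > 0L) {
      for (ci in seq_len(nrow(cores))) {
        fmo <- motif_hit("FMO", cores$start[ci],
                         substring(residues, cores$start[ci] + 1L,
                                   cores$start[ci] + fmo_len),
                         cores$mismatches[ci])
        fmo_end <- fmo$start + fmo_len
        dev_ff <- interval_deviation(fmo$start - fad$start,
                                     ruleset$spacing_fad_fmo)
        nads <- if (fmo_end < len) {
          find_all(pat_nadph, residues, c(fmo_end, len))
        } else {
          NULL
        }
        if (!is.null(nads) && nrow(nads) == 0L &&
            isTRUE(ruleset$allow_mismatch)) {
          nads <- find_all(pat_nadph, residues, c(fmo_end, len),
                           max_mismatch = 1L)
          if (nrow(nads) > 0L) {
            ok <- vapply(nads$start, function(s) {
              interval_deviation(s - fmo_end, ruleset$spacing_fmo_nadph) == 0L
            }, logical(1L))
            nads <- nads[ok, , drop = FALSE]
          }
        }
        if (!is.null(nads) && nrow(nads) > 0L) {
          for (ni in seq_len(nrow(nads))) {
            nad <- motif_hit("NADPH", nads$start[ni], nads$matched[ni],
                             nads$mismatches[ni])
            dev <- dev_ff + interval_deviation(nad$start - fmo_end,
                                               ruleset$spacing_fmo_nadph)
            consider(list(count = 3L, fad = fad, fmo = fmo, nadph = nad,
                          dev = dev))
            any_triple <- TRUE
          }
        } else if (core_tier[ci] == 0L) {
          consider(list(count = 2L, fad = fad, fmo = fmo, nadph = NULL,
                        dev = dev_ff))
        }
      }
    }
    if (!any_triple) {
      # Rossmann pair without an accepted FMO core
      nads <- find_all(pat_nadph, residues, c(fad_end, len))
      if (nrow(nads) == 0L && isTRUE(ruleset$allow_mismatch)) {
        nads <- find_all(pat_nadph, residues, c(fad_end, len),
                         max_mismatch = 1L)
        if (nrow(nads) > 0L) {
          ok <- vapply(nads$start, function(s) {
            interval_deviation(s - fad$start, ruleset$spacing_fad_nadph) == 0L
          }, logical(1L))
          nads <- nads[ok, , drop = FALSE]
        }
      }
      if (nrow(nads) > 0L) {
        devs <- vapply(nads$start, function(s) {
          interval_deviation(s - fad$start, ruleset$spacing_fad_nadph)
        }, integer(1L))
        ni <- order(devs, nads$start)[1L]
        nad <- motif_hit("NADPH", nads$start[ni], nads$matched[ni],
                         nads$mismatches[ni])
        consider(list(count = 2L, fad = fad, fmo = NULL, nadph = nad,
                      dev = devs[ni]))
      } else {
        consider(list(count = 1L, fad = fad, fmo = NULL, nadph = NULL,
                      dev = 0L))
      }
    }
  }
  }

  evaluate_fads(fads_exact)
  # exact FAD candidates may all be decoys (e.g. the NADPH Rossmann motif
  # seen through the FAD window when the true FAD site is degraded): when
  # no full triple emerges, fold in single-mismatch FAD candidates and
  # let the motif-count criterion arbitrate
  if ((is.null(best) || best$count < 3L) && isTRUE(ruleset$allow_mismatch)) {
    best_exact <- best
    fads_fb <- find_all(pat_fad, residues, fad_win, max_mismatch = 1L)
    fads_fb <- fads_fb[!(fads_fb$start %in% fads_exact$start), , drop = FALSE]
    if (nrow(fads_fb) > 0L) {
      best <- NULL
      evaluate_fads(rbind(fads_exact, fads_fb))
      if (!is.null(best_exact) &&
          (is.null(best) || best$count <= best_exact$count)) {
        best <- best_exact
      }
    }
  }
  if (is.null(best)) return(ann)

  fad <- best$fad
  fmo <- best$fmo
  nad <- best$nadph

  # relaxed NMO histidine: only attempted when both Rossmann hits are present
  # and no FMO core was accepted
  if (is.null(fmo) && !is.null(fad) && !is.null(nad)) {
    lo <- max(fad$start + pat_fad$length + ruleset$nmo_flank[1L],
              nad$start + ruleset$nmo_window[1L])
    hi <- min(nad$start - ruleset$nmo_flank[2L] - 1L,
              nad$start + ruleset$nmo_window[2L])
    if (lo <= hi) {
      region <- chars[(lo + 1L):(hi + 1L)]
      hpos <- which(region == "H")
      if (length(hpos) > 0L) {
        p <- lo + hpos[1L] - 1L
        start <- p - ruleset$nmo_flank[1L]
        fmo <- motif_hit(
          "NMO_H", start,
          substring(residues, start + 1L,
                    p + ruleset$nmo_flank[2L] + 1L)
        )
      }
    }
  }

  ann$fad <- fad
  ann$fmo <- fmo
  ann$nadph <- nad
  if (!is.null(fad)) {
    ann$fad_third <- chars[fad$start + pat_fad$length]
    ann$nterm_extension_len <- fad$start
    ann$core_coverage <- (len - fad$start) / len
  }
  if (!is.null(nad)) {
    ann$nadph_second <- chars[nad$start + 3L]
    ann$nadph_last <- chars[nad$start + pat_nadph$length]
  }
  if (!is.null(fmo) && fmo$kind == "FMO") {
    ann$fmo_penultimate <- chars[fmo$start + fmo_len - 1L]
    ann$fmo_last <- chars[fmo$start + fmo_len]
  }
  ann
}

#' Annotate a whole record set
#'
#' @param records protein-record `data.frame`.
#' @param ruleset see [default_ruleset()].
#' @return `data.frame` with one row per record: motif starts (0-based, `NA`
#'   when absent), FMO-motif kind (`FMO`, `NMO_H` or `NA`), diagnostic
#'   residues, extension length and core coverage.
#' @export
annotate_all <- function(records, ruleset = default_ruleset()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    a <- annotate(records[i, ], ruleset)
    data.frame(
      id = a$id,
      fad_start = if (is.null(a$fad)) NA_integer_ else a$fad$start,
      fmo_start = if (is.null(a$fmo)) NA_integer_ else a$fmo$start,
      fmo_kind = if (is.null(a$fmo)) NA_character_ else a$fmo$kind,
      nadph_start = if (is.null(a$nadph)) NA_integer_ else a$nadph$start,
      fmo_penultimate = a$fmo_penultimate,
      fmo_last = a$fmo_last,
      fad_third = a$fad_third,
      nadph_second = a$nadph_second,
      nadph_last = a$nadph_last,
      nterm_extension_len = a$nterm_extension_len,
      core_coverage = a$core_coverage,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export annotations as TSV (1-based display coordinates)
#'
#' @param annotations output of [annotate_all()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  for (col in c("fad_start", "fmo_start", "nadph_start")) {
    out[[col]] <- out[[col]] + 1L
  }
  write_table(out, path)
}
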