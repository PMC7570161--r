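# synth: generation of synthetic class-B-flavoprotein-monooxygenase-like
# corpora with the family-specific three-motif architecture, so that every
# downstream stage (annotation, classification, consensus, search, trees)
# is testable without database access.

#' Default family specifications
#'
#' One specification per group, encoding the family-specific consensus of the
#' three motifs as per-position emission distributions:
#' * FAD-binding Rossmann motif `GxGxxG`; the third conserved glycine is
#'   frequently replaced by alanine in type IIc FMOs and by asparagine in
#'   most NMOs;
#' * FMO-identifying motif `FxGxxxHxxx` plus penultimate/last positions:
#'   Y/F then K/R for the six FMO-like groups, a conserved tryptophan for
#'   BVMOs, and H (70%) or Y/F (30%) followed by an invariant proline for
#'   type IIb FMOs; NMOs carry only a single conserved histidine
#'   (`xxxxxxHxxxx`) and class G proteins no FMO motif at all;
#' * NADPH-binding Rossmann motif `GxGxxG`; type IIb FMOs emit asparagine
#'   instead of the second glycine in 57% of cases; the last glycine is
#'   frequently alanine in YUC-like/IIa/IIb/I FMOs and NMOs and is an
#'   invariant alanine in cyanobacterial FMOs and BVMOs.
#'
#' "Frequently" is rendered as probability 0.8 and "in most cases" as 0.9;
#' the 0.70/0.57 type IIb fractions are the study conditions themselves.
#' Type IIb records additionally carry a 160-residue N-terminal extension;
#' the default core length is 380 residues.
#'
#' @return named list of family specs (class `fmo_family_spec` each).
#' @export
default_family_specs <- function() {
  fad_g <- list(`1` = c(G = 1), `3` = c(G = 1), `6` = c(G = 1))
  fmo_like_fmo <- list(
    `1` = c(F = 1), `3` = c(G = 1), `7` = c(H = 1),
    `11` = c(Y = 0.7, F = 0.3), `12` = c(K = 0.5, R = 0.5)
  )
  nadph_ggg <- list(`1` = c(G = 1), `3` = c(G = 1), `6` = c(G = 1))
  nadph_ga <- list(`1` = c(G = 1), `3` = c(G = 1), `6` = c(A = 0.8, G = 0.2))
  nadph_aa <- list(`1` = c(G = 1), `3` = c(G = 1), `6` = c(A = 1))

  spec <- function(family, fmo, nadph, fad = fad_g,
                   nterm = 0L, fmo_len = 12L) {
    s <- list(
      family = family,
      fad = list(length = 6L, emissions = fad),
      fmo = fmo,            # NULL for classG; fmo$relaxed TRUE for NMO
      nadph = list(length = 6L, emissions = nadph),
      nterm_extension_len = as.integer(nterm),
      core_len = 380L,
      diagnostic_distribution = if (!is.null(fmo) && !isTRUE(fmo$relaxed)) {
        list(penultimate = fmo$emissions[["11"]], last = fmo$emissions[["12"]])
      } else {
        NULL
      }
    )
    class(s) <- "fmo_family_spec"
    validate_family_spec(s)
    s
  }

  list(
    YUCCA = spec("YUCCA",
                 list(length = 12L, emissions = fmo_like_fmo), nadph_ggg),
    YUC_like = spec("YUC_like",
                    list(length = 12L, emissions = fmo_like_fmo), nadph_ga),
    cyanobacterial = spec("cyanobacterial",
                          list(length = 12L, emissions = fmo_like_fmo),
                          nadph_aa),
    typeI = spec("typeI",
                 list(length = 12L, emissions = fmo_like_fmo), nadph_ga),
    typeIIa = spec("typeIIa",
                   list(length = 12L, emissions = fmo_like_fmo), nadph_ga),
    typeIIb = spec(
      "typeIIb",
      list(length = 12L, emissions = list(
        `1` = c(F = 1), `3` = c(G = 1), `7` = c(H = 1),
        `11` = c(H = 0.70, Y = 0.15, F = 0.15), `12` = c(P = 1)
      )),
      list(`1` = c(G = 1), `3` = c(N = 0.57, G = 0.43),
           `6` = c(A = 0.8, G = 0.2)),
      nterm = 160L
    ),
    typeIIc = spec(
      "typeIIc",
      list(length = 12L, emissions = fmo_like_fmo),
      nadph_ggg,
      fad = list(`1` = c(G = 1), `3` = c(G = 1), `6` = c(A = 0.8, G = 0.2))
    ),
    NMO = spec(
      "NMO",
      list(length = 11L, relaxed = TRUE, emissions = list(`7` = c(H = 1))),
      nadph_ga,
      fad = list(`1` = c(G = 1), `3` = c(G = 1), `6` = c(N = 0.9, G = 0.1))
    ),
    BVMO = spec(
      "BVMO",
      list(length = 12L, emissions = list(
        `1` = c(F = 1), `3` = c(G = 1), `7` = c(H = 1),
        `11` = c(W = 1), `12` = c(K = 0.5, R = 0.5)
      )),
      nadph_aa
    ),
    classG = spec("classG", NULL, nadph_ggg)
  )
}

validate_family_spec <- function(s) {
  check_em <- function(em, what) {
    for (pos in names(em)) {
      p <- em[[pos]]
      if (abs(sum(p) - 1) > 1e-9) {
        stop2(s$family, " ", what, " position ", pos,
              ": probabilities sum to ", sum(p), ", not 1")
      }
      if (!all(names(p) %in% AA_ALPHABET20)) {
        stop2(s$family, " ", what, " position ", pos,
              ": residue outside the amino-acid alphabet")
      }
    }
  }
  check_em(s$fad$emissions, "FAD motif")
  if (!is.null(s$fmo)) check_em(s$fmo$emissions, "FMO motif")
  check_em(s$nadph$emissions, "NADPH motif")
  if (s$nterm_extension_len < 0L) stop2("negative N-terminal extension")
  invisible(s)
}

#' Default per-family taxon label distributions
#'
#' Reflects the taxonomic spread reported for each group: YUCCAs are plant
#' proteins, YUC-like FMOs bacterial, type IIb FMOs mostly bacterial with a
#' fungal and a small plant component, BVMOs fungal/bacterial, and so on.
#'
#' @return named list, family -> named probability vector over taxon labels.
#' @export
default_taxon_assignment <- function() {
  list(
    YUCCA = c(plants = 1),
    YUC_like = c(bacteria = 1),
    cyanobacterial = c(bacteria = 1),
    typeI = c(bacteria = 0.4, animals = 0.3, plants = 0.2, protists = 0.1),
    typeIIa = c(bacteria = 1),
    typeIIb = c(bacteria = 0.7, fungi = 0.25, plants = 0.05),
    typeIIc = c(bacteria = 1),
    NMO = c(bacteria = 0.6, fungi = 0.4),
    BVMO = c(fungi = 0.5, bacteria = 0.45, protists = 0.05),
    classG = c(bacteria = 1)
  )
}

#' Simulation configuration
#'
#' @param n_per_family records per family.
#' @param substitution_rate per-site substitution probability in `[0, 1)`
#'   applied to background positions.
#' @param motif_rate_multiplier multiplier in `[0, 1]` for the substitution
#'   probability inside motif spans.
#' @param within_family_divergence per-site divergence of each record from
#'   its family founder sequence (non-motif positions), in `[0, 1)`. The
#'   default 0.25 gives ~56% within-family pairwise identity, so family
#'   members are strong mutual homologs while families stay unrelated.
#' @param seed RNG seed; a fixed seed gives byte-identical corpora.
#' @param families family specs (default [default_family_specs()]).
#' @param taxon_assignment per-family taxon label distributions.
#' @param n_species_per_taxon species pool size per taxon label.
#' @param background residue sampling distribution (default uniform over the
#'   20 amino acids).
#' @return validated config list (class `fmo_sim_config`).
#' @export
sim_config <- function(n_per_family = 200L, substitution_rate = 0,
                       motif_rate_multiplier = 1, seed = 1L,
                       within_family_divergence = 0.25,
                       families = default_family_specs(),
                       taxon_assignment = default_taxon_assignment(),
                       n_species_per_taxon = 30L,
                       background = NULL) {
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop2("substitution_rate must be in [0, 1)")
  }
  if (within_family_divergence < 0 || within_family_divergence >= 1) {
    stop2("within_family_divergence must be in [0, 1)")
  }
  if (motif_rate_multiplier < 0 || motif_rate_multiplier > 1) {
    stop2("motif_rate_multiplier must be in [0, 1]")
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  }
  structure(
    list(n_per_family = as.integer(n_per_family),
         substitution_rate = substitution_rate,
         motif_rate_multiplier = motif_rate_multiplier,
         seed = as.integer(seed),
         within_family_divergence = within_family_divergence,
         families = families,
         taxon_assignment = taxon_assignment,
         n_species_per_taxon = as.integer(n_species_per_taxon),
         background = background),
    class = "fmo_sim_config"
  )
}

sample_bg <- function(n, background) {
  sample(names(background), n, replace = TRUE, prob = background)
}

sample_emission <- function(p) {
  if (length(p) == 1L) return(names(p))
  sample(names(p), 1L, prob = p)
}

# implant one motif at 0-based offset; wildcard positions keep background
implant_motif <- function(chars, offset, emissions) {
  for (pos in names(emissions)) {
    chars[offset + as.integer(pos)] <- sample_emission(emissions[[pos]])
  }
  chars
}

# Remove pattern matches / stray histidines that would make the implanted
# motif offsets ambiguous for a zero-noise sequence. Resamples only
# background positions (never implanted constrained positions), iterating
# until clean. See the methods vignette for why identifiability must be
# guaranteed by construction.
scrub_confounders <- function(chars, protected, rules, background) {
  seqstr <- function() paste(chars, collapse = "")
  for (iter in 1:100) {
    dirty <- FALSE
    for (rule in rules) {
      if (rule$type == "pattern") {
        if (rule$window[2L] <= rule$window[1L]) next
        hits <- find_all(rule$pattern, seqstr(), rule$window,
                         max_mismatch = rule$max_mismatch %||% 0L)
        hits <- hits[!(hits$start %in% rule$keep), , drop = FALSE]
        for (h in hits$start) {
          lits <- h + rule$literal_offsets            # 0-based positions
          lits <- lits[!(lits %in% protected)]
          if (length(lits) == 0L) next
          chars[lits + 1L] <- sample_bg(length(lits), background)
          dirty <- TRUE
        }
      } else if (rule$type == "no_h") {
        if (rule$window[2L] <= rule$window[1L]) next
        idx <- (rule$window[1L]:(rule$window[2L] - 1L)) + 1L
        bad <- idx[chars[idx] == "H" & !((idx - 1L) %in% protected)]
        if (length(bad) > 0L) {
          repl <- sample(setdiff(AA_ALPHABET20, "H"), length(bad),
                         replace = TRUE)
          chars[bad] <- repl
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(chars)
  }
  stop2("confounder scrubbing did not converge")
}

literal_offsets <- function(pattern) {
  which(!vapply(pattern$elements, is_wildcard, logical(1L))) - 1L
}

#' Generate a synthetic corpus
#'
#' Each family is seeded by a founder: an optional N-terminal extension of
#' background residues followed by a core with the three motifs implanted in
#' the strict order FAD < FMO < NADPH at randomized but recorded offsets
#' (FAD at core offset 5-25, FMO 150-220 residues downstream of the FAD
#' start, NADPH 5-40 residues downstream of the FMO end; class G and NMO
#' records keep the same geometry with the FMO slot empty or reduced to the
#' single conserved histidine). Each record is derived from its founder by
#' per-site divergence (`within_family_divergence`) at non-motif positions
#' and fresh emission of the constrained motif positions from the family's
#' per-position distributions, so family members are strong mutual homologs
#' while distinct families are unrelated. Background residues are then
#' rejection-resampled so that, at zero noise, the implanted offsets are the
#' unique motif arrangement the annotator can recover. Finally substitution
#' noise is applied: probability `substitution_rate` per background site and
#' `substitution_rate * motif_rate_multiplier` per motif site, replacing the
#' residue uniformly by one of the other 19.
#'
#' @param config an `fmo_sim_config`, see [sim_config()].
#' @return list with `records` (protein-record `data.frame`), `taxonomy`
#'   (id/species/taxon) and `truth` (id, family, taxon, absolute 0-based
#'   motif offsets, extension length).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "fmo_sim_config"))
  rs <- default_ruleset()
  pat_fad <- compile_pattern(rs$fad_pattern)
  pat_core <- compile_pattern(rs$fmo_core_pattern)
  pat_nadph <- compile_pattern(rs$nadph_pattern)

  with_seed(config$seed, {
    all_records <- list()
    all_truth <- list()
    for (family in names(config$families)) {
      fs <- config$families[[family]]
      taxdist <- config$taxon_assignment[[family]] %||% c(bacteria = 1)
      founder <- family_founder(fs, config)
      for (i in seq_len(config$n_per_family)) {
        rec <- generate_record(fs, founder, config, rs,
                               pat_fad, pat_core, pat_nadph)
        taxon <- sample_emission_chr(taxdist)
        species <- sprintf("%s_sp%02d", taxon,
                           sample.int(config$n_species_per_taxon, 1L))
        id <- sprintf("%s_%04d", family, i)
        all_records[[id]] <- data.frame(
          id = id, residues = rec$residues, taxon = taxon,
          species = species, source = "synthetic", stringsAsFactors = FALSE
        )
        all_truth[[id]] <- data.frame(
          id = id, family = family, taxon = taxon, species = species,
          fad_start = rec$fad_start, fmo_start = rec$fmo_start,
          nadph_start = rec$nadph_start,
          extension_len = fs$nterm_extension_len,
          stringsAsFactors = FALSE
        )
      }
    }
    records <- do.call(rbind, unname(all_records))
    truth <- do.call(rbind, unname(all_truth))
    validate_records(records)
    list(
      records = records,
      taxonomy = data.frame(id = records$id, species = truth$species,
                            taxon = truth$taxon, stringsAsFactors = FALSE),
      truth = truth
    )
  })
}

sample_emission_chr <- function(p) {
  if (length(p) == 1L) names(p) else sample(names(p), 1L, prob = p)
}

# Family founder: background sequence plus motif geometry, shared by all
# records of the family (no indel process, so offsets are family-wide).
family_founder <- function(fs, config) {
  ext <- fs$nterm_extension_len
  core_len <- fs$core_len
  len <- ext + core_len

  fad_core <- sample(5:25, 1L)
  fmo_gap <- sample(150:220, 1L)                 # FAD start -> FMO start
  fmo_len <- if (is.null(fs$fmo)) 11L else fs$fmo$length
  nadph_gap <- sample(5:40, 1L)                  # FMO end -> NADPH start
  fad_start <- ext + fad_core
  fmo_start <- fad_start + fmo_gap
  nadph_start <- fmo_start + fmo_len + nadph_gap
  if (nadph_start + fs$nadph$length > len) {
    stop2("core_len too small for the three motifs plus spacers")
  }
  list(
    chars = sample_bg(len, config$background),
    len = len, fad_start = fad_start, fmo_start = fmo_start,
    fmo_len = fmo_len, nadph_start = nadph_start
  )
}

generate_record <- function(fs, founder, config, rs,
                            pat_fad, pat_core, pat_nadph) {
  len <- founder$len
  fad_start <- founder$fad_start
  fmo_start <- founder$fmo_start
  fmo_len <- founder$fmo_len
  nadph_start <- founder$nadph_start

  # diverge from the founder at non-motif positions
  chars <- founder$chars
  if (config$within_family_divergence > 0) {
    hit <- which(stats::runif(len) < config$within_family_divergence)
    for (p in hit) chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
  }
  chars <- implant_motif(chars, fad_start, fs$fad$emissions)
  if (!is.null(fs$fmo)) {
    chars <- implant_motif(chars, fmo_start, fs$fmo$emissions)
  }
  chars <- implant_motif(chars, nadph_start, fs$nadph$emissions)

  fad_end <- fad_start + 6L
  fmo_end <- fmo_start + fmo_len
  relaxed <- is.null(fs$fmo) || isTRUE(fs$fmo$relaxed)

  protected <- c(
    fad_start + as.integer(names(fs$fad$emissions)) - 1L,
    if (!is.null(fs$fmo)) fmo_start + as.integer(names(fs$fmo$emissions)) - 1L,
    nadph_start + as.integer(names(fs$nadph$emissions)) - 1L
  )

  rules <- list(
    # no FAD-pattern match upstream of the true FAD site
    list(type = "pattern", pattern = pat_fad,
         literal_offsets = literal_offsets(pat_fad),
         window = c(0L, min(fad_start + pat_fad$length - 1L, rs$fad_window[2L])),
         keep = fad_start),
    # no FMO-core match other than the implanted one; records without an
    # implanted core are also cleared of single-mismatch near-matches so
    # the annotator's mismatch-tolerant fallback cannot invent a motif
    list(type = "pattern", pattern = pat_core,
         literal_offsets = literal_offsets(pat_core),
         window = c(fad_end, len),
         max_mismatch = if (relaxed) 1L else 0L,
         keep = if (relaxed) integer(0L) else fmo_start),
    # no NADPH-pattern match between the FMO slot (or, for records without
    # an implanted FMO core, the FAD hit) and the true NADPH site
    list(type = "pattern", pattern = pat_nadph,
         literal_offsets = literal_offsets(pat_nadph),
         window = c(if (relaxed) fad_end else fmo_end,
                    nadph_start + pat_nadph$length - 1L),
         keep = nadph_start)
  )
  if (relaxed) {
    # keep the inter-Rossmann region free of stray histidines so that the
    # presence/absence of the conserved H is the truth label
    rules <- c(rules, list(
      list(type = "no_h", window = c(fad_end, nadph_start))
    ))
  }
  chars <- scrub_confounders(chars, protected, rules, config$background)

  # substitution noise
  if (config$substitution_rate > 0) {
    motif_sites <- unique(c(
      fad_start:(fad_end - 1L),
      if (!is.null(fs$fmo)) fmo_start:(fmo_end - 1L),
      nadph_start:(nadph_start + fs$nadph$length - 1L)
    ))
    rate <- rep(config$substitution_rate, len)
    rate[motif_sites + 1L] <-
      config$substitution_rate * config$motif_rate_multiplier
    hit <- which(stats::runif(len) < rate)
    for (p in hit) {
      chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
    }
  }

  list(
    residues = paste(chars, collapse = ""),
    fad_start = fad_start,
    fmo_start = if (is.null(fs$fmo)) NA_integer_ else fmo_start,
    nadph_start = nadph_start
  )
}

#' Evolve a root sequence along a tree
#'
#' Independent per-site substitutions along each branch with probability
#' `1 - exp(-rate * branch_length)` per site, replacing the residue
#' uniformly by one of the other 19; sites listed in `motif_intervals`
#' evolve at `rate * motif_rate_multiplier`. No indel process: the output
#' rows are aligned by construction.
#'
#' @param root_record list or one-row `data.frame` with `id`, `residues`
#'   (gap-free).
#' @param tree `ape::phylo` with branch lengths.
#' @param rate substitution rate per site per unit branch length (> 0).
#' @param seed RNG seed.
#' @param motif_intervals optional list of 0-based half-open `c(lo, hi)`
#'   intervals held at the reduced rate.
#' @param motif_rate_multiplier multiplier in `[0, 1]`.
#' @return an `fmo_alignment` with one row per leaf.
#' @export
evolve_on_tree <- function(root_record, tree, rate, seed = NULL,
                           motif_intervals = NULL,
                           motif_rate_multiplier = 1) {
  if (rate <= 0) stop2("rate must be positive")
  if (is.null(tree$edge.length)) stop2("tree must have branch lengths")
  residues <- toupper(root_record$residues[1L])
  if (grepl("-", residues, fixed = TRUE)) stop2("root sequence must be gap-free")
  n_sites <- nchar(residues)
  site_mult <- rep(1, n_sites)
  for (iv in motif_intervals %||% list()) {
    site_mult[(iv[1L] + 1L):iv[2L]] <- motif_rate_multiplier
  }

  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- seq_chars(residues)
    # preorder traversal
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1L]
      child <- ord$edge[e, 2L]
      bl <- ord$edge.length[e]
      p_sub <- 1 - exp(-rate * site_mult * bl)
      s <- seqs[[parent]]
      hit <- which(stats::runif(n_sites) < p_sub)
      for (p in hit) s[p] <- sample(setdiff(AA_ALPHABET20, s[p]), 1L)
      seqs[[child]] <- s
    }
    rows <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                   character(1L))
    names(rows) <- tree$tip.label
    as_alignment(rows)
  })
}

#' Default guide tree for clade-structured simulation
#'
#' A rooted topology with one clade per family, YUC-like FMOs sister to the
#' YUCCAs, the type IIb clade well separated from both, and the class G
#' proteins as the outgroup. Used by the clade-recovery tests and the
#' pipeline demo.
#'
#' @param n_per_clade leaves per family clade.
#' @param within within-clade pendant branch length.
#' @param between family-separating branch length.
#' @return an `ape::phylo` tree whose tips are named `family_i`.
#' @export
default_guide_tree <- function(n_per_clade = 3L, within = 0.05,
                               between = 0.3) {
  clade <- function(fam) {
    tips <- paste0(
      sprintf("%s_%d:%g", fam, seq_len(n_per_clade), within),
      collapse = ","
    )
    sprintf("(%s)", tips)
  }
  nwk <- sprintf(
    "(((((%s:%g,%s:%g):%g,%s:%g):%g,((%s:%g,%s:%g):%g,%s:%g):%g):%g,((%s:%g,%s:%g):%g,%s:%g):%g):%g,%s:%g);",
    clade("YUCCA"), between, clade("YUC_like"), between, between,
    clade("cyanobacterial"), between, between,
    clade("typeI"), between, clade("typeIIa"), between, between,
    clade("typeIIc"), between, between, between,
    clade("typeIIb"), between, clade("NMO"), between, between,
    clade("BVMO"), between, between, between,
    clade("classG"), between
  )
  ape::read.tree(text = nwk)
}
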