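# reports: the three table shapes (per-taxon abundance by e-value bin,
# per-taxon homolog counts for two queries, per-species co-occurrence) and
# the end-to-end pipeline driver.

#' Species carrying homologs of both queries
#'
#' One row per species with at least one hit for each of the two hit sets,
#' plus a per-taxon summary of how many species co-carry both.
#'
#' @param hits_A,hits_B search-hit `data.frame`s (need a `subject` column).
#' @param taxonomy taxonomy table; every subject id must be present.
#' @return list (class `fmo_cooccurrence`) with `rows` (species, taxon,
#'   `n_A`, `n_B`) and `summary` (taxon, n_species).
#' @export
cooccurrence <- function(hits_A, hits_B, taxonomy) {
  count_by_species <- function(hits) {
    if (nrow(hits) == 0L) {
      return(stats::setNames(integer(0L), character(0L)))
    }
    m <- match(hits$subject, taxonomy$id)
    if (anyNA(m)) {
      stop2("subject id(s) missing from taxonomy: ",
            paste(unique(hits$subject[is.na(m)]), collapse = ", "))
    }
    sp <- taxonomy$species[m]
    tapply(hits$subject, sp, function(x) length(unique(x)))
  }
  a <- count_by_species(hits_A)
  b <- count_by_species(hits_B)
  both <- sort(intersect(names(a), names(b)))
  taxon_of <- taxonomy$taxon[match(both, taxonomy$species)]
  rows <- data.frame(
    species = both, taxon = taxon_of,
    n_A = as.integer(a[both]), n_B = as.integer(b[both]),
    stringsAsFactors = FALSE
  )
  summary <- if (nrow(rows) == 0L) {
    data.frame(taxon = character(0L), n_species = integer(0L),
               stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(species ~ taxon, data = rows,
                            FUN = function(x) length(unique(x)))
    names(agg)[2L] <- "n_species"
    agg[order(agg$taxon), , drop = FALSE]
  }
  structure(list(rows = rows, summary = summary),
            class = "fmo_cooccurrence")
}

#' Per-taxon homolog counts with the "homologs(species)" rendering
#'
#' @param hits search-hit `data.frame`.
#' @param taxonomy taxonomy table; every subject id must be present.
#' @param taxa optional taxon vocabulary fixing row order; taxa without
#'   hits render as `"-"` (the dash convention of the published per-taxon
#'   tables).
#' @return `data.frame` with `taxon`, `homologs`, `species`, `cell`.
#' @export
per_taxon_counts <- function(hits, taxonomy, taxa = NULL) {
  if (nrow(hits) > 0L) {
    m <- match(hits$subject, taxonomy$id)
    if (anyNA(m)) {
      stop2("subject id(s) missing from taxonomy: ",
            paste(unique(hits$subject[is.na(m)]), collapse = ", "))
    }
    hits$taxon <- taxonomy$taxon[m]
    hits$species <- taxonomy$species[m]
  }
  if (is.null(taxa)) {
    taxa <- sort(unique(if (nrow(hits) > 0L) hits$taxon else character(0L)))
  }
  rows <- lapply(taxa, function(tx) {
    ht <- if (nrow(hits) > 0L) hits[hits$taxon == tx, ] else hits
    h <- if (nrow(ht) > 0L) length(unique(ht$subject)) else 0L
    s <- if (nrow(ht) > 0L) length(unique(ht$species)) else 0L
    data.frame(taxon = tx, homologs = h, species = s,
               cell = format_count_cell(h, s, zero = "-"),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(taxon = character(0L), homologs = integer(0L),
                      species = integer(0L), cell = character(0L),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Render an abundance table with "N(M)" total cells
#'
#' Per-bin rows print bare homolog counts; total rows print
#' `homologs(species)`; zero cells print bare `0`.
#'
#' @param abundance output of [aggregate_abundance()].
#' @return the table with an added `cell` column.
#' @export
render_abundance <- function(abundance) {
  cell <- character(nrow(abundance))
  for (i in seq_len(nrow(abundance))) {
    if (abundance$bin[i] == "total") {
      cell[i] <- format_count_cell(abundance$homologs[i],
                                   abundance$species[i])
    } else {
      cell[i] <- as.character(abundance$homologs[i])
    }
  }
  abundance$cell <- cell
  abundance
}

#' Default pipeline configuration
#'
#' A self-contained synthetic demonstration: simulate a corpus, annotate
#' and classify it, build type IIb consensus statistics, run the
#' pattern-constrained homolog search with the three group patterns,
#' evolve an alignment on the family guide tree, reconstruct and root the
#' NJ tree, test the headline clade relations, and write the abundance /
#' co-occurrence reports.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_per_family corpus size per family.
#' @param substitution_rate,motif_rate_multiplier corpus noise settings.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @export
pipeline_config <- function(out_dir = tempfile("fmofam_run_"), seed = 1L,
                            n_per_family = 30L, substitution_rate = 0.02,
                            motif_rate_multiplier = 0.2,
                            bootstrap_replicates = 100L) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    n_per_family = as.integer(n_per_family),
    substitution_rate = substitution_rate,
    motif_rate_multiplier = motif_rate_multiplier,
    bootstrap_replicates = as.integer(bootstrap_replicates),
    threshold = 1e-5,
    patterns = c(typeIIb = "FxGxxxHxxxH", FMO_like = "FxGxxxHxxx[YF]",
                 BVMO = "FxGxxxHxxxW")
  )
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
  log[[name]] <- "ok"
  list(result = res, log = log)
}

#' Run the whole pipeline
#'
#' Executes simulate, annotate, classify, consensus, search, filter, tree
#' and report stages on a synthetic corpus and writes every artifact plus a
#' manifest (package version, seed, configuration hash, per-stage log,
#' output checksums) under `config$out_dir`. Outputs are byte-identical
#' under an identical configuration and seed. A stage failure aborts the
#' run with the failing stage named.
#'
#' @param config list from [pipeline_config()], or the path of a YAML file
#'   with the same fields.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("pipeline stage 'config' failed: no such file: ", config)
    base <- pipeline_config()
    usr <- yaml::read_yaml(config)
    for (nm in names(usr)) base[[nm]] <- usr[[nm]]
    if (!is.null(usr$patterns)) base$patterns <- unlist(usr$patterns)
    config <- base
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log <- list()

  st <- run_stage("simulate", log, {
    corpus <- generate_corpus(sim_config(
      n_per_family = config$n_per_family,
      substitution_rate = config$substitution_rate,
      motif_rate_multiplier = config$motif_rate_multiplier,
      seed = config$seed
    ))
    write_fasta(corpus$records, out("corpus.fasta"))
    write_table(corpus$taxonomy, out("taxonomy.tsv"))
    write_table(corpus$truth, out("truth.tsv"))
    corpus
  })
  corpus <- st$result; log <- st$log

  st <- run_stage("annotate", log, {
    ann <- annotate_all(corpus$records)
    write_annotations(ann, out("annotations.tsv"))
    ann
  })
  ann <- st$result; log <- st$log

  st <- run_stage("classify", log, {
    calls <- classify_all(ann)
    write_calls(calls, out("calls.tsv"))
    score <- score_against_truth(calls, corpus$truth, coarse = TRUE)
    write_table(
      data.frame(family = names(score$recall), recall = score$recall,
                 n = score$n[names(score$recall)]),
      out("recall.tsv")
    )
    list(calls = calls, score = score)
  })
  calls <- st$result$calls; score <- st$result$score; log <- st$log

  st <- run_stage("consensus", log, {
    iib <- calls$id[calls$family == "typeIIb"]
    pfms <- list(
      build_pfm(ann, corpus$records, iib, "FMO", group = "typeIIb"),
      build_pfm(ann, corpus$records, iib, "NADPH", group = "typeIIb")
    )
    stats <- diagnostic_fractions(pfms)
    write_table(stats, out("diagnostics.tsv"))
    write_pfm(pfms[[1L]], out("pfm_typeIIb_FMO.tsv"))
    stats
  })
  log <- st$log

  st <- run_stage("search", log, {
    pick_query <- function(fam) {
      ids <- corpus$truth$id[corpus$truth$family == fam]
      corpus$records[corpus$records$id == ids[1L], ]
    }
    queries <- rbind(pick_query("typeIIb"), pick_query("YUCCA"),
                     pick_query("BVMO"))
    queries$group <- c("typeIIb", "FMO_like", "BVMO")
    hits <- run_phi_search(queries, config$patterns, corpus$records,
                           corpus$taxonomy, threshold = config$threshold)
    write_table(hits, out("hits.tsv"))
    abundance <- aggregate_abundance(hits, corpus$taxonomy)
    write_table(render_abundance(abundance), out("abundance.tsv"))
    hits
  })
  hits <- st$result; log <- st$log

  st <- run_stage("tree", log, {
    guide <- default_guide_tree()
    root_rec <- list(id = "root",
                     residues = with_seed(config$seed + 1L, paste(
                       sample_bg(500L, stats::setNames(rep(1 / 20, 20),
                                                       AA_ALPHABET20)),
                       collapse = "")))
    aln <- evolve_on_tree(root_rec, guide, rate = 1,
                          seed = config$seed + 2L)
    tr <- bootstrap_support(aln, config$bootstrap_replicates,
                            seed = config$seed + 3L)
    keep <- reject_poorly_aligned(aln, c(0L, alignment_width(aln)), 0.5)
    write_filter_report(keep, out("filter.tsv"))
    rooted <- root_on_outgroup(tr, grep("^classG_", tr$tip.label,
                                        value = TRUE))
    write_newick(rooted, out("tree.nwk"))
    iib_tips <- grep("^typeIIb_", rooted$tip.label, value = TRUE)
    yuc_tips <- grep("^YUCCA_", rooted$tip.label, value = TRUE)
    clades <- data.frame(
      check = c("typeIIb_monophyletic", "yucca_sister_is_yuclike"),
      value = c(
        is_monophyletic(rooted, iib_tips),
        all(grepl("^YUC_like_", sister_group(rooted, yuc_tips)))
      ),
      stringsAsFactors = FALSE
    )
    write_table(clades, out("clade_checks.tsv"))
    clades
  })
  log <- st$log

  st <- run_stage("report", log, {
    co <- cooccurrence(hits[hits$group == "typeIIb", ],
                       hits[hits$group == "FMO_like", ],
                       corpus$taxonomy)
    write_table(co$rows, out("cooccurrence.tsv"))
    write_table(co$summary, out("cooccurrence_summary.tsv"))
    write_table(per_taxon_counts(hits[hits$group == "typeIIb", ],
                                 corpus$taxonomy),
                out("per_taxon_typeIIb.tsv"))
    co
  })
  log <- st$log

  cfg_for_hash <- config[sort(setdiff(names(config), "out_dir"))]
  cfg_yaml <- yaml::as.yaml(cfg_for_hash)
  cfg_file <- out("config.yaml")
  writeLines(cfg_yaml, cfg_file)
  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.yaml"))
  manifest <- list(
    package = "fmofam",
    version = as.character(utils::packageVersion("fmofam")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = log,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, outputs))), outputs
    )),
    coarse_recall_min = min(score$recall, na.rm = TRUE)
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}
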