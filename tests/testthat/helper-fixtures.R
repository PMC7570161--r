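# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small zero-noise corpus covering all ten families
clean_corpus <- function() {
  fixture("clean_corpus", function() {
    generate_corpus(sim_config(n_per_family = 25L, seed = 101L))
  })
}

clean_annotations <- function() {
  fixture("clean_annotations", function() {
    annotate_all(clean_corpus()$records)
  })
}

# pseudo-hit expansion of the published co-occurrence counts: one hit row
# per homolog, so the report functions are exercised through their real
# interface
cooccurrence_fixture <- function() {
  counts <- utils::read.delim(
    system.file("extdata", "cooccurrence_counts.tsv", package = "fmofam"),
    check.names = FALSE
  )
  tax <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n_typeIIb[i] + counts$n_yucca[i]
    data.frame(
      id = paste0("id", i, "_h", seq_len(n)),
      species = counts$species[i], taxon = counts$taxon[i],
      stringsAsFactors = FALSE
    )
  }))
  hits <- function(col, tag) {
    rows <- list()
    for (i in seq_len(nrow(counts))) {
      k <- counts[[col]][i]
      if (k == 0) next
      off <- if (col == "n_yucca") counts$n_typeIIb[i] else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        query = tag, group = tag,
        subject = paste0("id", i, "_h", off + seq_len(k)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  }
  list(counts = counts, taxonomy = tax,
       hits_iib = hits("n_typeIIb", "typeIIb"),
       hits_yucca = hits("n_yucca", "YUCCA"))
}

# build a record with a hand-placed motif architecture; `fmo` may be a full
# 12-residue motif, NULL (none), or "H" to plant a lone histidine at the
# FMO slot
handmade_record <- function(id = "rec", ext = 0L, fad = "GAGLLG",
                            fmo = "FLGAGVHAAAYK", nadph = "GAGLLG",
                            fad_core = 10L, fmo_gap = 180L,
                            nadph_gap = 20L, len = 420L, seed = 500L) {
  set.seed(seed)
  chars <- rep("L", ext + len)  # homopolymer background: no chance motifs
  fad_start <- ext + fad_core
  place <- function(chars, start, s) {
    ss <- strsplit(s, "")[[1]]
    chars[(start + 1):(start + length(ss))] <- ss
    chars
  }
  chars <- place(chars, fad_start, fad)
  fmo_start <- fad_start + fmo_gap
  fmo_len <- 12L
  if (!is.null(fmo)) {
    if (identical(fmo, "H")) {
      chars <- place(chars, fmo_start + 6L, "H")
      fmo_len <- 11L
    } else {
      chars <- place(chars, fmo_start, fmo)
    }
  }
  nadph_start <- fmo_start + fmo_len + nadph_gap
  chars <- place(chars, nadph_start, nadph)
  list(
    record = protein_records(id, paste(chars, collapse = "")),
    fad_start = fad_start, fmo_start = fmo_start,
    nadph_start = nadph_start
  )
}
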