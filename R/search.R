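# search: pattern-constrained homolog search over a sequence corpus --
# pattern filtering, anchored local alignment, Karlin-Altschul bit scores
# and e-values, e-value binning and abundance aggregation.

#' Karlin-Altschul and gap parameters
#'
#' `lambda` and `K` default to the standard gapped BLOSUM62 constants
#' (0.267, 0.041); gap costs default to open 11 / extend 1; a gap of length
#' k costs `open + k * extend`.
#'
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @param gap_open,gap_extend positive gap penalties.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041,
                      gap_open = 11L, gap_extend = 1L) {
  if (lambda <= 0 || K <= 0) stop2("lambda and K must be positive")
  if (gap_open <= 0 || gap_extend <= 0) stop2("gap penalties must be positive")
  list(lambda = lambda, K = K, gap_open = as.integer(gap_open),
       gap_extend = as.integer(gap_extend))
}

#' The BLOSUM62 substitution matrix
#'
#' Retrieved from the matrices shipped with Biostrings.
#'
#' @return symmetric integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Subjects of a corpus carrying a pattern occurrence
#'
#' The pattern-hit-initiated search semantics: only subjects with at least
#' one occurrence of the pattern can become hits, whatever their similarity
#' to the query.
#'
#' @param pattern an `fmo_pattern`.
#' @param corpus protein-record `data.frame`.
#' @return `data.frame` with columns `id`, `start` (0-based occurrence
#'   offsets; one row per occurrence).
#' @export
pattern_filter <- function(pattern, corpus) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    hits <- find_all(pattern, corpus$residues[i])
    if (nrow(hits) == 0L) return(NULL)
    data.frame(id = corpus$id[i], start = hits$start,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    return(data.frame(id = character(0L), start = integer(0L),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Anchored local alignment
#'
#' Best affine-gap local alignment between `query` and `subject` whose
#' subject span covers the 0-based half-open anchor interval
#' `[anchor_offset, anchor_offset + anchor_len)` -- the dynamic-programming
#' stand-in for the extension step of a pattern-hit-initiated search.
#' Ties are broken deterministically (highest score, then smallest end
#' coordinates).
#'
#' @param query,subject sequence strings.
#' @param anchor_offset 0-based offset of the pattern occurrence in
#'   `subject`.
#' @param anchor_len length of the pattern occurrence.
#' @param matrix symmetric integer substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return list with `score` and 0-based half-open `query_span`,
#'   `subject_span`.
#' @export
anchored_align <- function(query, subject, anchor_offset, anchor_len,
                           matrix = blosum62(),
                           gap_open = 11L, gap_extend = 1L) {
  if (gap_open <= 0 || gap_extend <= 0) stop2("gap penalties must be positive")
  qc <- toupper(seq_chars(query))
  sc <- toupper(seq_chars(subject))
  ab <- rownames(matrix)
  qi <- match(qc, ab)
  si <- match(sc, ab)
  if (anyNA(qi) || anyNA(si)) {
    bad <- unique(c(qc[is.na(qi)], sc[is.na(si)]))
    stop2("residue(s) not covered by the substitution matrix: ",
          paste(bad, collapse = ", "))
  }
  a <- as.integer(anchor_offset)
  b <- a + as.integer(anchor_len)
  if (a < 0L || b > length(sc)) stop2("anchor outside subject")
  res <- sw_anchored_cpp(qi - 1L, si - 1L,
                         matrix[ab, ab, drop = FALSE],
                         as.integer(gap_open), as.integer(gap_extend),
                         a, b)
  if (is.na(res[1L])) {
    return(list(score = NA_integer_, query_span = NULL, subject_span = NULL))
  }
  list(
    score = res[1L],
    query_span = c(res[2L], res[3L]),
    subject_span = c(res[4L], res[5L])
  )
}

#' Bit score from a raw alignment score
#'
#' `bit = (lambda * score - ln K) / ln 2`.
#'
#' @param score raw alignment score (substitution-matrix units).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @export
bit_score <- function(score, lambda = 0.267, K = 0.041) {
  if (lambda <= 0 || K <= 0) stop2("lambda and K must be positive")
  (lambda * score - log(K)) / log(2)
}

#' E-value from a bit score
#'
#' `evalue = m * n_db * 2^(-bit)`: linear in the database size, monotone
#' decreasing in the score.
#'
#' @param bit bit score.
#' @param m query length (>= 1).
#' @param n_db database size in residues (>= 1).
#' @export
evalue <- function(bit, m, n_db) {
  if (m < 1 || n_db < 1) stop2("m and n_db must be >= 1")
  m * n_db * 2^(-bit)
}

#' Bin an e-value as in the abundance tables
#'
#' `strong`: \[0, 1e-70); `mid`: \[1e-70, 1e-40); `weak`: \[1e-40,
#' threshold\]. Values above the threshold return `NA`.
#'
#' @param e e-value(s).
#' @param threshold search recognition threshold (default 1e-5).
#' @export
bin_evalue <- function(e, threshold = 1e-5) {
  out <- rep(NA_character_, length(e))
  out[e < 1e-70] <- "strong"
  out[e >= 1e-70 & e < 1e-40] <- "mid"
  out[e >= 1e-40 & e <= threshold] <- "weak"
  out
}

#' Pattern-hit-initiated homolog search
#'
#' For each query: subjects carrying the query group's pattern are aligned
#' (anchored at each occurrence, best occurrence kept), scored, converted to
#' e-values against the corpus size, thresholded and binned.
#'
#' @param queries protein-record `data.frame` with an extra `group` column
#'   naming the query group of each row.
#' @param patterns named character vector, group -> pattern text, e.g.
#'   `c(typeIIb = "FxGxxxHxxxH", FMO_like = "FxGxxxHxxx[YF]",
#'   BVMO = "FxGxxxHxxxW")`.
#' @param corpus protein-record `data.frame` (the database).
#' @param taxonomy optional taxonomy table used to attach subject taxon and
#'   species labels.
#' @param threshold e-value recognition threshold (default 1e-5).
#' @param params see [ka_params()].
#' @return `data.frame` of search hits: `query`, `group`, `subject`,
#'   `pattern_id`, `score`, `bit`, `evalue`, `bin`, plus `taxon`/`species`
#'   when taxonomy is given.
#' @export
run_phi_search <- function(queries, patterns, corpus, taxonomy = NULL,
                           threshold = 1e-5, params = ka_params()) {
  if (!"group" %in% names(queries)) {
    stop2("queries need a 'group' column naming the query group")
  }
  mat <- blosum62()
  n_db <- sum(nchar(corpus$residues))
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    group <- queries$group[i]
    if (!group %in% names(patterns)) {
      stop2("no pattern supplied for query group '", group, "'")
    }
    pat <- compile_pattern(patterns[[group]])
    occ <- pattern_filter(pat, corpus)
    if (nrow(occ) == 0L) next
    for (sid in unique(occ$id)) {
      subject <- corpus$residues[corpus$id == sid][1L]
      starts <- occ$start[occ$id == sid]
      best <- NULL
      for (st in starts) {
        al <- anchored_align(queries$residues[i], subject, st, pat$length,
                             matrix = mat, gap_open = params$gap_open,
                             gap_extend = params$gap_extend)
        if (is.na(al$score)) next
        if (is.null(best) || al$score > best$score) best <- al
      }
      if (is.null(best)) next
      b <- bit_score(best$score, params$lambda, params$K)
      e <- evalue(b, nchar(queries$residues[i]), n_db)
      if (e > threshold) next
      rows[[length(rows) + 1L]] <- data.frame(
        query = queries$id[i], group = group, subject = sid,
        pattern_id = pat$text, score = best$score, bit = b, evalue = e,
        bin = bin_evalue(e, threshold), stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(rows) == 0L) {
    data.frame(query = character(0L), group = character(0L),
               subject = character(0L), pattern_id = character(0L),
               score = integer(0L), bit = numeric(0L), evalue = numeric(0L),
               bin = character(0L), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(taxonomy) && nrow(hits) > 0L) {
    m <- match(hits$subject, taxonomy$id)
    if (anyNA(m)) {
      stop2("subject id(s) missing from taxonomy: ",
            paste(unique(hits$subject[is.na(m)]), collapse = ", "))
    }
    hits$taxon <- taxonomy$taxon[m]
    hits$species <- taxonomy$species[m]
  }
  hits
}

BIN_LEVELS <- c("strong", "mid", "weak")

#' Aggregate search hits into an abundance table
#'
#' Counts homologs (distinct subjects) and species (distinct species
#' labels, exact string match) per (group, taxon, e-value bin), plus a
#' `total` row per (group, taxon) summing the bins -- the "All homologs"
#' convention of the published abundance tables.
#'
#' @param hits search hits from [run_phi_search()].
#' @param taxonomy taxonomy table; every subject id must be present.
#' @return `data.frame` with columns `group`, `taxon`, `bin` (strong / mid /
#'   weak / total), `homologs`, `species`.
#' @export
aggregate_abundance <- function(hits, taxonomy) {
  cols <- c("group", "taxon", "bin", "homologs", "species")
  if (nrow(hits) == 0L) {
    out <- data.frame(group = character(0L), taxon = character(0L),
                      bin = character(0L), homologs = integer(0L),
                      species = integer(0L), stringsAsFactors = FALSE)
    return(out)
  }
  m <- match(hits$subject, taxonomy$id)
  if (anyNA(m)) {
    stop2("subject id(s) missing from taxonomy: ",
          paste(unique(hits$subject[is.na(m)]), collapse = ", "))
  }
  hits$taxon <- taxonomy$taxon[m]
  hits$species <- taxonomy$species[m]
  hits <- hits[!duplicated(hits[, c("group", "subject")]), ]

  rows <- list()
  for (g in unique(hits$group)) {
    hg <- hits[hits$group == g, ]
    for (tx in sort(unique(hg$taxon))) {
      ht <- hg[hg$taxon == tx, ]
      for (b in BIN_LEVELS) {
        hb <- ht[ht$bin == b, ]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, taxon = tx, bin = b,
          homologs = length(unique(hb$subject)),
          species = length(unique(hb$species)),
          stringsAsFactors = FALSE
        )
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, taxon = tx, bin = "total",
        homologs = length(unique(ht$subject)),
        species = length(unique(ht$species)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[, cols]
}

#' Sum per-bin homolog counts into totals
#'
#' Worked-example helper: given per-bin homolog counts for one or more
#' (group, taxon) cells, returns the `total` ("All homologs") count per
#' cell, the sum over the three e-value bins.
#'
#' @param bins `data.frame` with columns `group`, `taxon`, `bin`,
#'   `homologs` (bins `strong`, `mid`, `weak`).
#' @return `data.frame` with `group`, `taxon`, `homologs` totals.
#' @export
sum_bins <- function(bins) {
  stopifnot(all(c("group", "taxon", "bin", "homologs") %in% names(bins)))
  agg <- stats::aggregate(homologs ~ group + taxon,
                          data = bins[bins$bin %in% BIN_LEVELS, ],
                          FUN = sum)
  agg[order(agg$group, agg$taxon), , drop = FALSE]
}
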