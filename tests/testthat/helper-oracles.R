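# Independent oracles used to cross-check the implementation paths.

# Position-by-position brute-force pattern matcher, independent of
# find_all()'s vectorised scan.
oracle_find_all <- function(pattern, residues, window = NULL,
                            max_mismatch = 0L) {
  chars <- toupper(strsplit(residues, "")[[1]])
  len <- length(chars)
  if (is.null(window)) window <- c(0L, len)
  starts <- integer(0)
  plen <- pattern$length
  last <- min(window[2], len) - plen
  if (plen == 0L || last < window[1]) return(starts)
  for (st in seq(window[1], last, by = 1L)) {
    mm <- 0L
    for (j in seq_len(plen)) {
      el <- pattern$elements[[j]]
      if (length(el) == 1L && is.na(el[1])) next
      if (!chars[st + j] %in% el) mm <- mm + 1L
    }
    if (mm <= max_mismatch) starts <- c(starts, st)
  }
  starts
}

# Plain-R anchored affine Smith-Waterman (score only): alignment must start
# at a subject column <= a and end at a column >= b (0-based half-open
# anchor [a, b)). Same gap convention as the package: gap length k costs
# open + k * ext.
oracle_sw_anchored <- function(q, s, mat, open, ext, a, b) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e15
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- NEG
  for (i in 1:m) {
    for (j in 1:n) {
      sub <- mat[qc[i], sc[j]]
      start_ok <- if (j - 1 <= a) 0 else NEG
      M[i + 1, j + 1] <- sub + max(start_ok, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      if (j >= b && M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  if (best <= NEG / 2) NA_integer_ else as.integer(best)
}

# Exhaustive anchored-local-alignment oracle for tiny strings: maximise the
# global affine alignment score over all substring pairs whose subject span
# covers [a, b).
oracle_sw_exhaustive <- function(q, s, mat, open, ext, a, b) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  nw <- function(qs, ss) {
    m <- length(qs); n <- length(ss)
    NEG <- -1e15
    M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
    M[1, 1] <- 0
    for (i in seq_len(m)) X[i + 1, 1] <- -open - ext * i
    for (j in seq_len(n)) Y[1, j + 1] <- -open - ext * j
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        M[i + 1, j + 1] <- mat[qs[i], ss[j]] + max(M[i, j], X[i, j], Y[i, j])
        X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
        Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      }
    }
    max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
  }
  best <- -Inf
  for (q1 in seq_along(qc)) for (q2 in q1:length(qc)) {
    for (s1 in seq_len(a + 1)) for (s2 in b:length(sc)) {
      if (s2 < s1) next
      best <- max(best, nw(qc[q1:q2], sc[s1:s2]))
    }
  }
  as.integer(best)
}

# Bipartition enumeration by direct edge traversal (independent of
# ape::prop.part): returns a list of tip-label sets, one side per edge.
oracle_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  nodes <- unique(tree$edge[, 2])
  lapply(nodes, desc)
}

random_aa_string <- function(len) {
  paste(sample(fmofam::AA_ALPHABET20, len, replace = TRUE), collapse = "")
}
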