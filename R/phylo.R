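# phylo: distance-based tree reconstruction with bootstrap, monophyly and
# sister-clade tests. Trees are ape "phylo" objects throughout; unrooted
# trees carry the conventional basal trifurcation.

#' Pairwise distances from a protein alignment
#'
#' p-distance over the columns where both rows are non-gap (pairwise
#' deletion), optionally Poisson-corrected (`d = -ln(1 - p)`). A pair with
#' no comparable columns, or a saturated pair (`p >= 1`) under the Poisson
#' correction, is a hard error naming the pair.
#'
#' @param alignment an `fmo_alignment`.
#' @param correction `"p"` or `"poisson"`.
#' @return symmetric distance matrix with row/column names.
#' @export
pairwise_distances <- function(alignment, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  if (length(alignment) == 0L) stop2("empty alignment")
  ids <- names(alignment)
  mat <- do.call(rbind, lapply(unclass(alignment), seq_chars))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1L) return(d)
  gap <- mat == "-"
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        stop2("no comparable columns for pair (", ids[i], ", ", ids[j], ")")
      }
      p <- sum(mat[i, comp] != mat[j, comp]) / nc
      if (correction == "poisson") {
        if (p >= 1) {
          stop2("saturated pair (", ids[i], ", ", ids[j], "): p = ", p)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

fmt_bl <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' The standard agglomerative algorithm: at each step the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` is joined; ties are broken by the
#' lexicographically smallest label pair (clusters are represented by their
#' smallest leaf label), so the result is reproducible under input
#' permutation. Negative branch lengths are clamped to zero with the
#' deficit transferred to the adjacent branch. Exact on additive matrices.
#'
#' @param dm symmetric distance matrix with unique dimnames (>= 3 labels).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  labels <- rownames(dm)
  if (is.null(labels) || length(labels) < 3L) {
    stop2("neighbor joining needs at least 3 labelled taxa")
  }
  if (max(abs(dm - t(dm))) > 1e-12) stop2("distance matrix not symmetric")
  d <- dm
  # newick fragment and representative (smallest) leaf label per cluster
  frag <- labels
  rep_lab <- labels
  names(frag) <- names(rep_lab) <- labels

  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keyz <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keyz)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- d[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { lj <- dij; li <- 0 }
    if (lj < 0) { li <- dij; lj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(li),
                        frag[j], fmt_bl(lj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- (d[i, ] + d[j, ] - dij) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, new = du), new = c(du, 0))
    frag <- c(frag[-c(i, j)], new_frag)
    rep_lab <- c(rep_lab[-c(i, j)], new_rep)
  }

  # closing trifurcation: three-point formulas
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1L], fmt_bl(la), frag[2L], fmt_bl(lb),
                 frag[3L], fmt_bl(lc))
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_replicates` times;
#' the support of each internal edge of the full-data tree is the
#' percentage of replicate trees containing the same bipartition.
#' Replicates whose distance matrix is degenerate (saturated or
#' incomparable pairs) are skipped, counted and reported with a warning.
#' Deterministic under a fixed seed.
#'
#' @param alignment an `fmo_alignment`.
#' @param n_replicates number of bootstrap replicates (>= 1, default 100).
#' @param seed RNG seed.
#' @param correction distance correction, see [pairwise_distances()].
#' @return the full-data NJ tree with integer percentage supports in
#'   `node.label` and attributes `n_replicates_used`, `n_skipped`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = NULL,
                              correction = "poisson") {
  if (n_replicates < 1L) stop2("n_replicates must be >= 1")
  full <- neighbor_joining(pairwise_distances(alignment, correction))
  width <- alignment_width(alignment)
  mat <- do.call(rbind, lapply(unclass(alignment), seq_chars))
  boot_trees <- list()
  skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(width, width, replace = TRUE)
      rows <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(rows) <- names(alignment)
      tr <- tryCatch(
        neighbor_joining(pairwise_distances(as_alignment(rows), correction)),
        error = function(e) NULL
      )
      if (is.null(tr)) skipped <- skipped + 1L else {
        boot_trees[[length(boot_trees) + 1L]] <- tr
      }
    }
  })
  used <- n_replicates - skipped
  if (skipped > 0L) {
    warning(skipped, " bootstrap replicate(s) skipped (degenerate distances)")
  }
  counts <- ape::prop.clades(full, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.character(as.integer(round(100 * counts / used)))
  attr(full, "n_replicates_used") <- used
  attr(full, "n_skipped") <- skipped
  full
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Test whether a label set is monophyletic
#'
#' TRUE iff the labels equal the complete leaf set of one side of some
#' bipartition of the tree (so the test is rooting-invariant).
#'
#' @param tree an `ape::phylo` tree.
#' @param labels leaf labels (subset of the tree's tips).
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(labels %in% tips)) {
    stop2("label(s) not in tree: ",
          paste(setdiff(labels, tips), collapse = ", "))
  }
  idx <- sort(match(unique(labels), tips))
  # single tips, full leaf sets and complements of a single tip are always
  # one side of a (possibly pendant) edge
  if (length(idx) <= 1L || length(idx) >= length(tips) - 1L) return(TRUE)
  all_idx <- seq_along(tips)
  for (clade in ape::prop.part(tree)) {
    side <- sort(clade)
    if (identical(side, idx)) return(TRUE)
    if (identical(sort(setdiff(all_idx, side)), idx)) return(TRUE)
  }
  FALSE
}

#' Sister group of a monophyletic label set
#'
#' For a rooted tree, returns the leaf set of the sibling subtree of the
#' labels' most recent common ancestor. Non-monophyletic labels, or labels
#' whose clade is a child of nothing (the root), are hard errors.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param labels leaf labels forming a clade.
#' @return character vector of sister leaf labels.
#' @export
sister_group <- function(tree, labels) {
  if (!ape::is.rooted(tree)) stop2("sister_group needs a rooted tree")
  if (!is_monophyletic(tree, labels)) {
    stop2("labels are not monophyletic: ", paste(labels, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  node <- if (length(unique(labels)) == 1L) {
    match(labels[1L], tree$tip.label)
  } else {
    ape::getMRCA(tree, unique(labels))
  }
  # the MRCA must subtend exactly the labels (monophyly already checked,
  # but a rooted clade check guards against the root-spanning case)
  if (!setequal(tips_under(tree, node), unique(labels))) {
    stop2("labels do not form a rooted clade (they span the root)")
  }
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(parent) == 0L) stop2("labels subtend the root; no sister group")
  sibs <- tree$edge[tree$edge[, 1L] == parent & tree$edge[, 2L] != node, 2L]
  sort(unique(unlist(lapply(sibs, tips_under, tree = tree))))
}

#' Root a tree on an outgroup
#'
#' The outgroup must form a clade in the unrooted tree (checked; violation
#' is a hard error). The root is placed at the midpoint of the edge
#' subtending the outgroup, so all pairwise leaf path lengths are
#' preserved.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup_labels leaf labels of the outgroup.
#' @return a rooted `ape::phylo` tree.
#' @export
root_on_outgroup <- function(tree, outgroup_labels) {
  tips <- tree$tip.label
  if (!all(outgroup_labels %in% tips)) {
    stop2("outgroup label(s) not in tree: ",
          paste(setdiff(outgroup_labels, tips), collapse = ", "))
  }
  if (length(unique(outgroup_labels)) >= length(tips)) {
    stop2("outgroup cannot contain every leaf")
  }
  if (!is_monophyletic(tree, outgroup_labels)) {
    stop2("outgroup is not a clade: ",
          paste(outgroup_labels, collapse = ", "))
  }
  rooted <- ape::root(tree, outgroup = unique(outgroup_labels),
                      resolve.root = TRUE)
  # split the subtending edge at its midpoint
  ntip <- length(rooted$tip.label)
  root_node <- ntip + 1L
  root_edges <- which(rooted$edge[, 1L] == root_node)
  if (length(root_edges) == 2L) {
    total <- sum(rooted$edge.length[root_edges])
    rooted$edge.length[root_edges] <- total / 2
  }
  rooted
}
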