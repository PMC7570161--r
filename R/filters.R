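# filters: sample-construction rules -- rejection of poorly aligned rows
# and clade-aware redundancy reduction.

filter_report <- function(kept, dropped_ids, reasons) {
  structure(
    list(
      kept = kept,
      dropped = data.frame(id = dropped_ids, reason = reasons,
                           stringsAsFactors = FALSE),
      fraction_dropped = length(dropped_ids) /
        max(1L, length(kept) + length(dropped_ids))
    ),
    class = "fmo_filter_report"
  )
}

#' Reject rows poorly aligned over the core region
#'
#' A row is dropped when its gap fraction within the core column interval
#' exceeds `max_gap_fraction`; gap-free rows are never dropped.
#'
#' @param alignment an `fmo_alignment`.
#' @param core_interval 0-based half-open column interval `c(lo, hi)` (the
#'   conserved-core region of the alignment).
#' @param max_gap_fraction tolerated gap fraction in `(0, 1]` (default 0.5).
#' @return filter report: `kept` ids, `dropped` (id, reason),
#'   `fraction_dropped`.
#' @export
reject_poorly_aligned <- function(alignment, core_interval,
                                  max_gap_fraction = 0.5) {
  width <- alignment_width(alignment)
  if (core_interval[1L] < 0L || core_interval[2L] > width ||
      core_interval[1L] >= core_interval[2L]) {
    stop2("core interval [", core_interval[1L], ",", core_interval[2L],
          ") outside alignment width ", width)
  }
  if (max_gap_fraction <= 0 || max_gap_fraction > 1) {
    stop2("max_gap_fraction must be in (0, 1]")
  }
  cols <- (core_interval[1L] + 1L):core_interval[2L]
  gapfrac <- vapply(unclass(alignment), function(row) {
    chars <- seq_chars(row)[cols]
    mean(chars == "-")
  }, numeric(1L))
  drop <- gapfrac > max_gap_fraction
  filter_report(names(alignment)[!drop], names(alignment)[drop],
                rep("poorly_aligned", sum(drop)))
}

#' Clade-aware redundancy reduction
#'
#' Within each designated clade, whitelisted species are kept first, then
#' leaves are added greedily so as to maximise the minimum pairwise path
#' distance among the kept set, until `max_per_clade` is reached or the
#' best remaining leaf would sit closer than `min_dist` to the kept set.
#' Ties are broken by id order, so the procedure is deterministic. Leaves
#' outside every designated clade are always kept.
#'
#' @param tree `ape::phylo`; its leaves must all be record ids.
#' @param records protein-record `data.frame` (supplies the species of each
#'   leaf).
#' @param clades named list of leaf-id vectors, one per clade to reduce.
#' @param keep_rules list with `whitelist` (species names always retained;
#'   a whitelisted species absent from a clade raises a warning, not an
#'   error), `max_per_clade` (integer) and `min_dist` (default 0).
#' @return filter report with dropped reason `"redundant"`.
#' @export
reduce_redundancy <- function(tree, records, clades,
                              keep_rules = list(whitelist = character(0L),
                                                max_per_clade = 5L,
                                                min_dist = 0)) {
  leaves <- tree$tip.label
  if (!all(leaves %in% records$id)) {
    stop2("tree leaves missing from records: ",
          paste(setdiff(leaves, records$id), collapse = ", "))
  }
  whitelist <- keep_rules$whitelist %||% character(0L)
  max_per <- keep_rules$max_per_clade %||% 5L
  min_dist <- keep_rules$min_dist %||% 0
  dmat <- ape::cophenetic.phylo(tree)
  species_of <- stats::setNames(records$species, records$id)

  kept <- setdiff(leaves, unlist(clades))
  dropped <- character(0L)
  for (cl in names(clades)) {
    ids <- sort(intersect(clades[[cl]], leaves))
    if (length(ids) == 0L) next
    wl_ids <- ids[!is.na(species_of[ids]) & species_of[ids] %in% whitelist]
    missing_sp <- setdiff(whitelist, species_of[ids])
    if (length(whitelist) > 0L && length(missing_sp) > 0L) {
      warning("clade '", cl, "': whitelisted species absent: ",
              paste(missing_sp, collapse = ", "))
    }
    sel <- wl_ids
    pool <- setdiff(ids, sel)
    if (length(sel) == 0L && length(pool) > 0L && max_per >= 1L) {
      if (length(pool) == 1L || max_per == 1L) {
        sel <- pool[1L]
      } else {
        # seed with the farthest pair (ties by id order)
        sub <- dmat[pool, pool, drop = FALSE]
        far <- which(sub == max(sub), arr.ind = TRUE)
        far <- far[far[, 1L] < far[, 2L], , drop = FALSE]
        keyz <- apply(far, 1L, function(ij) {
          paste(sort(pool[ij]), collapse = "\r")
        })
        pick <- far[order(keyz)[1L], ]
        sel <- sort(pool[pick])
      }
      pool <- setdiff(pool, sel)
    }
    while (length(sel) < max_per && length(pool) > 0L) {
      mind <- vapply(pool, function(x) min(dmat[x, sel]), numeric(1L))
      best <- max(mind)
      if (best < min_dist) break
      cand <- sort(pool[mind == best])[1L]
      sel <- c(sel, cand)
      pool <- setdiff(pool, cand)
    }
    if (length(sel) > max_per) sel <- sel[seq_len(max_per)]
    kept <- c(kept, sel)
    dropped <- c(dropped, setdiff(ids, sel))
  }
  filter_report(sort(kept), sort(dropped),
                rep("redundant", length(dropped)))
}

#' Export a filter report as TSV
#' @param report an `fmo_filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  kept <- data.frame(id = report$kept,
                     status = rep("kept", length(report$kept)),
                     reason = rep("", length(report$kept)),
                     stringsAsFactors = FALSE)
  dropped <- data.frame(id = report$dropped$id,
                        status = rep("dropped", nrow(report$dropped)),
                        reason = report$dropped$reason,
                        stringsAsFactors = FALSE)
  write_table(rbind(kept, dropped), path)
}
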