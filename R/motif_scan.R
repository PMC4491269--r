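# The putative STP cystine-motif grammar.
#
# An STP motif is six cysteines C1..C6 whose disulfides pair sequentially
# (C1-C4, C2-C5, C3-C6). The grammar works entirely on the "cysteine loops"
# dC(i,i+1): the number of residues strictly between consecutive cysteines.
# Rules, applied in order:
#   1. fewer than six cysteines in the chain       -> invalid
#   2. global minimum loop over the whole chain > 3 -> invalid
#   3. a six-cysteine window is anchored so the global-minimum pair sits at
#      C3-C4; with fewer than two cysteines downstream of the pair its role
#      shifts up to C4-C5 (one downstream) or C5-C6 (none), drawing more
#      upstream cysteines; chains with exactly six cysteines ARE the window.
#      Missing upstream cysteines make the chain unanchorable.
#   4. if the anchored window's own minimum loop lies between C1-C2 or
#      C2-C3 the motif is discarded: short N-terminal CXXC-type spacings
#      are the signature of ferredoxin/rubredoxin-like electron-transport
#      folds, not of tri-disulfide toxins.
# Ties for the minimum loop always resolve to the most N-terminal pair.

#' Positions of all cysteines in a sequence
#'
#' @param seq A single residue string (validated, uppercase).
#' @return Strictly increasing integer vector of 1-based positions of `C`.
#' @export
cysteine_positions <- function(seq) {
  stopifnot(length(seq) == 1L)
  hits <- gregexpr("C", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

#' Loop lengths between consecutive cysteines
#'
#' Loop i counts the residues strictly between cysteines i and i+1, so
#' adjacent cysteines have loop 0.
#'
#' @param positions Strictly increasing integer positions.
#' @return Integer vector of length `length(positions) - 1` (empty when
#'   fewer than two positions).
#' @export
loop_lengths <- function(positions) {
  if (length(positions) < 2L) return(integer(0))
  stopifnot(all(diff(positions) > 0))
  as.integer(diff(positions) - 1L)
}

.new_motif <- function(positions, loops, valid, reject_reason,
                       min_loop_index = NA_integer_, n_cys = length(positions)) {
  structure(list(positions = as.integer(positions),
                 loops = as.integer(loops),
                 min_loop_index = as.integer(min_loop_index),
                 valid = valid,
                 reject_reason = reject_reason,
                 n_cys = as.integer(n_cys)),
            class = "stp_motif")
}

#' Anchor the six-cysteine STP window
#'
#' Applies the full rule cascade to the cysteine positions of one chain and
#' returns the anchored motif. Invalidity is a value (`valid = FALSE` with a
#' `reject_reason`), never an error. Reject reasons:
#' `fewer_than_six_cysteines`, `min_loop_gt_three` (global minimum loop
#' exceeds 3), `cannot_anchor` (too few upstream cysteines to complete the
#' window), `min_loop_in_first_two` (the anchored window's minimum loop sits
#' at C1-C2 or C2-C3, the ferredoxin/rubredoxin exclusion) or `none`.
#'
#' For valid motifs `positions` holds the six window cysteines, `loops` the
#' five window loops and `min_loop_index` the window pair (i, i+1) carrying
#' the minimum; for unanchored chains `positions`/`loops` fall back to the
#' whole-chain values.
#'
#' @param positions Integer positions of every cysteine in the chain.
#' @return An `stp_motif` object.
#' @export
anchor_motif <- function(positions) {
  positions <- as.integer(positions)
  n <- length(positions)
  chain_loops <- loop_lengths(positions)
  if (n < 6L)
    return(.new_motif(positions, chain_loops, FALSE, "fewer_than_six_cysteines"))
  k <- which.min(chain_loops)            # leftmost minimum
  if (chain_loops[k] > 3L)
    return(.new_motif(positions, chain_loops, FALSE, "min_loop_gt_three"))
  if (n == 6L) {
    start <- 1L
  } else {
    downstream <- n - (k + 1L)
    role <- if (downstream >= 2L) 3L else if (downstream == 1L) 4L else 5L
    start <- k - (role - 1L)
    if (start < 1L)
      return(.new_motif(positions, chain_loops, FALSE, "cannot_anchor"))
  }
  win <- positions[start:(start + 5L)]
  wloops <- loop_lengths(win)
  m <- which.min(wloops)
  if (m <= 2L)
    return(.new_motif(win, wloops, FALSE, "min_loop_in_first_two",
                      min_loop_index = m, n_cys = n))
  .new_motif(win, wloops, TRUE, "none", min_loop_index = m, n_cys = n)
}

#' Scan one sequence for the STP cystine motif
#'
#' @param seq A single residue string.
#' @return An `stp_motif` object (see [anchor_motif()]).
#' @export
scan_motif <- function(seq) {
  anchor_motif(cysteine_positions(seq))
}

#' @export
print.stp_motif <- function(x, ...) {
  cat("STP cystine motif (", x$n_cys, " cysteines in chain)\n", sep = "")
  cat("  window positions:", paste(x$positions, collapse = ","), "\n")
  cat("  loops dC(i,i+1): ", paste(x$loops, collapse = ","), "\n")
  if (!is.na(x$min_loop_index))
    cat("  min loop at pair C", x$min_loop_index, "-C", x$min_loop_index + 1L,
        "\n", sep = "")
  cat("  valid:", x$valid,
      if (!identical(x$reject_reason, "none")) paste0("(", x$reject_reason, ")"),
      "\n")
  invisible(x)
}

#' Scan many sequences, returning an annotation table
#'
#' @param seqs Named character vector of sequences.
#' @return A data.frame with columns `id`, `n_cys`, `positions` and `loops`
#'   (comma-joined), `valid` and `reject_reason`, one row per sequence.
#' @export
scan_motifs <- function(seqs) {
  seqs <- validate_peptides(seqs)
  motifs <- lapply(seqs, scan_motif)
  data.frame(
    id = names(seqs),
    n_cys = vapply(motifs, `[[`, integer(1), "n_cys"),
    positions = vapply(motifs, function(m) paste(m$positions, collapse = ","),
                       character(1)),
    loops = vapply(motifs, function(m) paste(m$loops, collapse = ","),
                   character(1)),
    valid = vapply(motifs, `[[`, logical(1), "valid"),
    reject_reason = vapply(motifs, `[[`, character(1), "reject_reason"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
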