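# Seeded synthetic-sequence generator.
#
# The generator emulates the cysteine geometry of the training conditions
# the classifier was designed around: a positive class of 144 chains of
# 23-143 residues (length ~ Normal(42.2, 15.7), clipped) each carrying a
# valid six-cysteine STP motif, and a negative class of 393 chains of 9-160
# residues (length ~ Normal(63.2, 25.9), clipped) that fail the motif
# grammar in structured ways: random cysteine placement, ferredoxin-like
# N-terminal CXXC decoys, and six-cysteine chains with uniformly long
# loops. Background residues are drawn uniformly from the 19 non-cysteine
# standard residues so cysteine geometry stays fully controlled; real
# peptide composition is NOT emulated beyond that.

.NONCYS <- setdiff(c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L", "K",
                     "M", "F", "P", "S", "T", "W", "Y", "V", "C"), "C")

.rand_flank <- function(n) {
  if (n <= 0) return("")
  paste(sample(.NONCYS, n, replace = TRUE), collapse = "")
}

# assemble a chain from cysteine loop lengths + N/C flanks of random length
# so the total hits `len` (stretched if the cysteine core alone exceeds it)
.chain_from_loops <- function(loops, len) {
  core <- 6L + sum(loops)
  len <- max(len, core)
  nflank <- sample(0:(len - core), 1L)
  segs <- vapply(loops, .rand_flank, character(1))
  paste0(.rand_flank(nflank),
         "C", segs[1], "C", segs[2], "C", segs[3], "C", segs[4], "C",
         segs[5], "C",
         .rand_flank(len - core - nflank))
}

.draw_length <- function(mean, sd, range) {
  min(max(round(stats::rnorm(1, mean, sd)), range[1]), range[2])
}

#' Generate motif-positive synthetic peptides
#'
#' Every emitted chain carries exactly six cysteines whose loops satisfy
#' the STP grammar: the minimum loop (0-3 residues) sits between C3 and C4,
#' every other loop is strictly longer, and both C-terminal loops contain
#' at least one residue. Deterministic for a fixed seed.
#'
#' @param n Number of sequences.
#' @param seed Integer seed (default 1).
#' @param length_range Total-length bounds, default `c(23, 143)`; lengths
#'   are drawn from Normal(42.2, 15.7) and clipped to this range.
#' @return Named character vector (`pos1`, `pos2`, ...).
#' @export
simulate_positives <- function(n, seed = 1L, length_range = c(23L, 143L)) {
  stopifnot(n >= 0, length_range[1] >= 8, length_range[2] >= length_range[1])
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    min_loop <- sample(0:3, 1L)
    others <- min_loop + sample(1:7, 4L, replace = TRUE)
    loops <- c(others[1:2], min_loop, others[3:4])
    out[i] <- .chain_from_loops(loops,
                                .draw_length(42.2, 15.7, length_range))
  }
  names(out) <- if (n > 0) paste0("pos", seq_len(n)) else character(0)
  out
}

#' Generate structured motif-negative synthetic peptides
#'
#' A mixture of three failure modes: (a) random peptides with 0-6
#' unconstrained cysteines, re-drawn in the rare case they satisfy the
#' grammar by chance; (b) ferredoxin-like decoys whose shortest loop sits
#' among the first two cysteine pairs near the N-terminus, triggering the
#' positional discard rule; (c) six-cysteine chains whose loops are all
#' longer than 3, triggering the minimum-loop rule. In `hard` mode the
#' negatives instead all PASS the motif grammar but with outsized loops,
#' so only the proximity-length features separate them from positives.
#'
#' @param n Number of sequences.
#' @param seed Integer seed (default 1).
#' @param length_range Total-length bounds, default `c(9, 160)`; lengths
#'   drawn from Normal(63.2, 25.9) and clipped.
#' @param decoy_fraction Fraction of ferredoxin-like decoys (default 0.3);
#'   long-loop chains take a further 0.3, random peptides the rest.
#' @param hard Generate grammar-passing hard negatives instead.
#' @return Named character vector (`neg1`, `neg2`, ...).
#' @export
simulate_negatives <- function(n, seed = 1L, length_range = c(9L, 160L),
                               decoy_fraction = 0.3, hard = FALSE) {
  stopifnot(n >= 0, decoy_fraction >= 0, decoy_fraction <= 1)
  set.seed(seed + 1L)
  rest <- 1 - decoy_fraction
  kinds <- if (hard) rep("hard", n) else
    sample(c("decoy", "longloop", "random"), n, replace = TRUE,
           prob = c(decoy_fraction, 0.4 * rest, 0.6 * rest))
  out <- character(n)
  for (i in seq_len(n)) {
    len <- .draw_length(63.2, 25.9, length_range)
    out[i] <- switch(kinds[i],
      decoy = {
        # shortest loop among the first pairs, near the N-terminus
        short <- sample(0:2, 1L)
        loops <- c(short, short + sample(2:8, 4L, replace = TRUE))
        s <- .chain_from_loops(loops, len)
        # trim N flank so the CXXC sits near the N-terminus
        first_c <- regexpr("C", s, fixed = TRUE)
        keep <- sample(0:3, 1L)
        substr(s, max(1L, first_c - keep), nchar(s))
      },
      longloop = {
        loops <- sample(4:12, 5L, replace = TRUE)
        .chain_from_loops(loops, len)
      },
      hard = {
        min_loop <- sample(0:3, 1L)
        others <- min_loop + sample(8:20, 4L, replace = TRUE)
        loops <- c(others[1:2], min_loop, others[3:4])
        .chain_from_loops(loops, max(len, 6L + sum(loops)))
      },
      random = {
        repeat {
          ncys <- sample(0:6, 1L)
          chars <- sample(.NONCYS, len, replace = TRUE)
          if (ncys > 0) chars[sample(len, min(ncys, len))] <- "C"
          s <- paste(chars, collapse = "")
          if (!scan_motif(s)$valid) break
        }
        s
      })
    if (!hard && scan_motif(out[i])$valid)   # safety net, deterministic redraw
      out[i] <- {
        loops <- sample(4:12, 5L, replace = TRUE)
        .chain_from_loops(loops, len)
      }
  }
  names(out) <- if (n > 0) paste0("neg", seq_len(n)) else character(0)
  out
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `pos.fasta`, `neg.fasta` and `manifest.json` (seed, sizes,
#' options, package version) into `dir`. Re-running with the manifest's
#' settings reproduces the files byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param n_pos,n_neg Class sizes; the defaults 144/393 mirror the training
#'   conditions the classifier family was developed under.
#' @param seed Integer seed.
#' @param decoy_fraction,hard Passed to [simulate_negatives()].
#' @return Invisibly, `list(pos, neg, manifest)`.
#' @export
simulate_dataset <- function(dir, n_pos = 144L, n_neg = 393L, seed = 1L,
                             decoy_fraction = 0.3, hard = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- simulate_positives(n_pos, seed = seed)
  neg <- simulate_negatives(n_neg, seed = seed, decoy_fraction = decoy_fraction,
                            hard = hard)
  write_fasta(pos, file.path(dir, "pos.fasta"))
  write_fasta(neg, file.path(dir, "neg.fasta"))
  manifest <- list(seed = seed, n_pos = n_pos, n_neg = n_neg,
                   decoy_fraction = decoy_fraction, hard = hard,
                   pos_length_range = c(23L, 143L),
                   neg_length_range = c(9L, 160L),
                   package = "stpsvm",
                   version = as.character(utils::packageVersion("stpsvm")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pos = pos, neg = neg, manifest = manifest))
}
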