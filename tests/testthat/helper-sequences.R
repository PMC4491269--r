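# Shared fixture builders. All sequences are constructed in code; the
# flank filler is alanine unless randomness is requested.

# build a six-cysteine chain from its five loop lengths
seq_from_loops <- function(loops, nflank = 3L, cflank = 3L, fill = "A") {
  stopifnot(length(loops) == 5L)
  segs <- vapply(loops, function(k) strrep(fill, k), character(1))
  paste0(strrep(fill, nflank),
         "C", segs[1], "C", segs[2], "C", segs[3], "C", segs[4], "C",
         segs[5], "C", strrep(fill, cflank))
}

# cysteine positions implied by loops + flank (for expectations)
positions_from_loops <- function(loops, nflank = 3L) {
  cumsum(c(nflank + 1L, loops + 1L))
}

# random peptide of given length with cysteines at `ncys` random positions
random_peptide <- function(len, ncys) {
  noncys <- c("A","R","N","D","Q","E","G","H","I","L","K","M","F","P","S",
              "T","W","Y","V")
  chars <- sample(noncys, len, replace = TRUE)
  if (ncys > 0) chars[sample.int(len, min(ncys, len))] <- "C"
  paste(chars, collapse = "")
}
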