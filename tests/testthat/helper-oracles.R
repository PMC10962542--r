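# independent brute-force oracles used across tests

# all maximal runs of >= min_run index-consecutive residues passing the
# threshold, found by exhaustive candidate enumeration (O(n^2))
brute_force_segments <- function(idx, vals, min_run = 4, thr = 0.1) {
  ok <- function(i) {
    k <- match(i, idx)
    !is.na(k) && !is.na(vals[k]) && vals[k] > thr
  }
  segs <- list()
  for (s in idx) for (e in idx[idx >= s]) {
    if (e - s + 1 < min_run) next
    if (!all(vapply(s:e, ok, TRUE))) next
    if (ok(s - 1) || ok(e + 1)) next  # not maximal
    segs <- c(segs, list(c(s, e)))
  }
  if (!length(segs))
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = vapply(segs, `[`, 1, 1), end = vapply(segs, `[`, 1, 2))
}

# exhaustive i,i+spacing pair enumeration with the same filters as the
# design operation, written directly from the filter definitions
brute_force_cys_pairs <- function(p, rs, re, hotspots, spacing = 4) {
  seq_chars <- p$residues
  off <- p$numbering_offset
  pairs <- list()
  for (i in rs:re) {
    j <- i + spacing
    if (j > re) next
    if (i %in% hotspots || j %in% hotspots) next
    if (seq_chars[i - off + 1] == "C" || seq_chars[j - off + 1] == "C") next
    pairs <- c(pairs, list(c(i, j)))
  }
  pairs
}
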