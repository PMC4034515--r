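# Brute-force direct-summation oracles, independent of the cumulative-sum
# implementation in the package.

naive_reflect <- function(i, L) {
  if (L == 1L) return(1L)
  repeat {
    if (i < 1L) i <- 2L - i
    else if (i > L) i <- 2L * L - i
    else return(i)
  }
}

naive_box <- function(x, h, edge = "truncate") {
  L <- length(x)
  out <- numeric(L)
  if (edge == "truncate") {
    for (k in seq_len(L)) {
      lo <- max(1L, k - h)
      hi <- min(L, k + h)
      out[k] <- sum(x[lo:hi]) / (hi - lo + 1L)
    }
  } else {
    for (k in seq_len(L)) {
      idx <- vapply((k - h):(k + h), naive_reflect, integer(1), L = L)
      out[k] <- sum(x[idx]) / length(idx)
    }
  }
  out
}

naive_cascade <- function(x, n_max, edge = "truncate") {
  f <- x
  out <- vector("list", n_max)
  for (n in seq_len(n_max)) {
    f <- naive_box(f, n, edge)
    out[[n]] <- f
  }
  out
}

# segments covered positions as a plain integer set
covered_positions <- function(segments) {
  if (!nrow(segments)) return(integer(0))
  unlist(Map(seq.int, segments$start, segments$end), use.names = FALSE)
}

make_reference <- function(id, starts, ends, sp = NULL) {
  reference_annotation(id, data.frame(start = starts, end = ends),
                       signal_peptide = sp)
}

make_segments <- function(starts, ends, kind = "tmd") {
  data.frame(start = as.integer(starts), end = as.integer(ends),
             kind = kind, source = "detected", stringsAsFactors = FALSE)
}
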