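#' Centred moving (box) average of a numeric series
#'
#' Element k of the result is the arithmetic mean of the input over
#' positions k - half_width .. k + half_width.  Under the `truncate`
#' edge rule, positions outside 1..L are dropped and the divisor is the
#' number of in-range positions; under `mirror`, the series is reflected
#' about its ends before averaging.  Either way the output has the same
#' length as the input and a constant series is preserved exactly.
#'
#' @param series Numeric vector, length >= 1.
#' @param half_width Positive integer half-window; full width is
#'   `2 * half_width + 1`.
#' @param edge_rule `"truncate"` (default) or `"mirror"`.
#' @return Numeric vector of the same length as `series`.
#' @export
box_average <- function(series, half_width, edge_rule = c("truncate", "mirror")) {
  edge_rule <- match.arg(edge_rule)
  if (!is.numeric(series) || length(series) < 1L) {
    stop("series must be a nonempty numeric vector", call. = FALSE)
  }
  if (length(half_width) != 1L || is.na(half_width) || half_width < 1 ||
      half_width != as.integer(half_width)) {
    stop("half_width must be a positive integer", call. = FALSE)
  }
  h <- as.integer(half_width)
  L <- length(series)
  # work relative to the first element: running sums of a constant series
  # are then exactly zero, so constants are preserved bit-exactly
  ref <- series[1]
  series <- series - ref
  if (edge_rule == "mirror") {
    # reflect about the end elements (end element not duplicated);
    # shorter series than the pad are reflected repeatedly
    idx <- seq_len(L + 2L * h) - h
    idx <- vapply(idx, reflect_index, integer(1), L = L)
    padded <- series[idx]
    s <- cumsum(padded)
    hi <- seq_len(L) + 2L * h
    lo <- seq_len(L)
    sums <- s[hi] - c(0, s)[lo]
    return(sums / (2 * h + 1) + ref)
  }
  s <- cumsum(series)
  k <- seq_len(L)
  hi <- pmin(L, k + h)
  lo <- pmax(1L, k - h)
  sums <- s[hi] - c(0, s)[lo]
  sums / (hi - lo + 1) + ref
}

# fold an out-of-range index back into 1..L by repeated reflection
reflect_index <- function(i, L) {
  if (L == 1L) return(1L)
  period <- 2L * (L - 1L)
  i <- (i - 1L) %% period
  if (i >= L) i <- period - i
  i + 1L
}

#' Cascade averaging of a hydrophobicity series
#'
#' Pass n smooths the output of pass n-1 with a centred box filter of
#' width 2n + 1: the first pass averages over 3 elements, the second
#' over 5, and so on.  Four to five passes (a final window of 9-11
#' residues) give the best separation of transmembrane domains in
#' practice.
#'
#' @param series Raw hydrophobicity series f0 (from [encode_sequence()]).
#' @param n_max Cascade depth (number of passes), a positive integer,
#'   typically 4 or 5.
#' @param edge_rule Passed to [box_average()].
#' @return A list of `n_max` numeric vectors: element n is the series
#'   f_n after pass n.  All intermediate passes are retained.
#' @export
cascade_average <- function(series, n_max, edge_rule = c("truncate", "mirror")) {
  edge_rule <- match.arg(edge_rule)
  if (!is.numeric(series) || length(series) < 1L) {
    stop("series must be a nonempty numeric vector", call. = FALSE)
  }
  if (length(n_max) != 1L || is.na(n_max) || n_max < 1 ||
      n_max != as.integer(n_max)) {
    stop("n_max must be a positive integer", call. = FALSE)
  }
  if (2 * n_max + 1 > length(series)) {
    warning("final window width ", 2 * n_max + 1,
            " exceeds series length ", length(series), call. = FALSE)
  }
  out <- vector("list", n_max)
  f <- series
  for (n in seq_len(n_max)) {
    f <- box_average(f, n, edge_rule)
    out[[n]] <- f
  }
  names(out) <- paste0("f", seq_len(n_max))
  out
}

#' Whole-chain mean level of the raw hydrophobicity series
#'
#' The threshold u = <f(k)> = (1/L) sum_k f(k), computed over the entire
#' length of the ORIGINAL unsmoothed series f0.  Crossings of the
#' smoothed profile through this level delimit hydrophobic segments.
#'
#' @param series Raw hydrophobicity series f0.
#' @return Scalar mean level u.
#' @export
mean_level <- function(series) {
  if (!is.numeric(series) || length(series) < 1L) {
    stop("series must be a nonempty numeric vector", call. = FALSE)
  }
  mean(series)
}

#' Build a smoothed hydropathy profile for one protein
#'
#' Convenience composition of [encode_sequence()], [cascade_average()]
#' and [mean_level()].
#'
#' @inheritParams encode_sequence
#' @param n Cascade depth.
#' @param level Threshold level u; `NULL` (default) uses the whole-chain
#'   mean of f0.
#' @param edge_rule Passed to [box_average()].
#' @return An object of class `hydro_profile`: list with `protein_id`,
#'   `scale_name`, `n`, `edge_rule`, `f0`, `passes` (list f1..fn),
#'   `series` (the final pass f_n), `u`, and `residues`.
#' @export
hydro_profile <- function(seq, scale, n = 4, level = NULL,
                          edge_rule = c("truncate", "mirror"),
                          unknown = c("zero", "error")) {
  edge_rule <- match.arg(edge_rule)
  seq <- as_protein_sequence(seq)
  if (is.character(scale)) scale <- get_scale(scale)
  f0 <- encode_sequence(seq, scale, unknown = match.arg(unknown))
  passes <- cascade_average(f0, n, edge_rule)
  u <- if (is.null(level)) mean_level(f0) else {
    stopifnot(is.numeric(level), length(level) == 1L, !is.na(level))
    as.numeric(level)
  }
  structure(list(protein_id = seq$id, scale_name = scale$name,
                 n = as.integer(n), edge_rule = edge_rule,
                 f0 = f0, passes = passes,
                 series = passes[[length(passes)]],
                 u = u,
                 residues = strsplit(seq$residues, "", fixed = TRUE)[[1]]),
            class = "hydro_profile")
}

#' @export
print.hydro_profile <- function(x, ...) {
  cat(sprintf("<hydro_profile> %s: scale %s, n = %d, L = %d, u = %.3f\n",
              x$protein_id, x$scale_name, x$n, length(x$f0), x$u))
  invisible(x)
}

#' Per-residue profile table
#'
#' @param profile A `hydro_profile`.
#' @return A data frame with columns `position`, `residue`, `f0`,
#'   `f1`..`fn` and `u`, one row per residue.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "hydro_profile"))
  out <- data.frame(position = seq_along(profile$f0),
                    residue = profile$residues,
                    f0 = profile$f0,
                    stringsAsFactors = FALSE)
  for (nm in names(profile$passes)) out[[nm]] <- profile$passes[[nm]]
  out$u <- profile$u
  out
}
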