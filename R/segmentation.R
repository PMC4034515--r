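#' Segmentation parameters
#'
#' @param min_tmd_length Minimum segment length (residues) to call a
#'   transmembrane domain; shorter hydrophobic runs outside the
#'   signal-peptide window are reported as `hydrophobic_region`.
#'   Default 12, just below the 15-30 aa range typical of membrane-
#'   spanning helices, so genuine domains blurred a few residues short
#'   are kept while narrow spikes are not.
#' @param sp_window Length (residues) of the N-terminal span within
#'   which a hydrophobic segment lying entirely inside it is flagged as
#'   a signal-peptide region.  Default 30.
#' @param L_avg Assumed average domain length used when splitting a
#'   merged double domain from its outer boundaries.  Default 20.
#' @param split_enabled Apply the merged-domain split automatically to
#'   any tmd segment wide enough (width >= 2 * L_avg + 2)?  Default
#'   `FALSE`: splitting is an explicit, opt-in correction.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_tmd_length = 12, sp_window = 30,
                                L_avg = 20, split_enabled = FALSE) {
  stopifnot(min_tmd_length >= 1, L_avg >= 1, sp_window >= 0)
  structure(list(min_tmd_length = as.integer(min_tmd_length),
                 sp_window = as.integer(sp_window),
                 L_avg = as.integer(L_avg),
                 split_enabled = isTRUE(split_enabled)),
            class = "segmentation_params")
}

new_segments <- function(start = integer(), end = integer(),
                         kind = character(), source = character()) {
  data.frame(start = as.integer(start), end = as.integer(end),
             kind = as.character(kind), source = as.character(source),
             stringsAsFactors = FALSE)
}

#' Detect hydrophobic segments as runs above the threshold level
#'
#' Returns the maximal runs of consecutive positions k with
#' f_n(k) > u (strict: a value exactly equal to u counts as below).
#' Each run becomes one 1-based inclusive segment.
#'
#' @param profile A `hydro_profile`, or a numeric vector taken as the
#'   smoothed series f_n.
#' @param u Threshold level; defaults to the profile's own level.
#' @return A data frame of segments (`start`, `end`, `kind` =
#'   `"hydrophobic_region"`, `source` = `"detected"`), sorted and
#'   disjoint.
#' @export
detect_segments <- function(profile, u = NULL) {
  if (inherits(profile, "hydro_profile")) {
    series <- profile$series
    if (is.null(u)) u <- profile$u
  } else {
    series <- profile
    if (is.null(u)) stop("u must be supplied with a bare series", call. = FALSE)
  }
  if (!is.numeric(series) || length(series) < 1L) {
    stop("profile series must be nonempty", call. = FALSE)
  }
  above <- series > u
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  new_segments(starts[keep], ends[keep],
               rep("hydrophobic_region", sum(keep)),
               rep("detected", sum(keep)))
}

check_disjoint_sorted <- function(segments) {
  if (nrow(segments) > 1L) {
    if (is.unsorted(segments$start, strictly = TRUE) ||
        any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
      stop("segments must be sorted and pairwise disjoint", call. = FALSE)
    }
  }
  invisible(segments)
}

#' Classify hydrophobic segments
#'
#' A segment lying entirely within the first `sp_window` residues is a
#' signal-peptide region; otherwise it is a tmd if at least
#' `min_tmd_length` residues long, else a short hydrophobic region.
#' Only the `kind` column is changed.
#'
#' @param segments Segment data frame from [detect_segments()].
#' @param seq_length Protein length L (for bounds checking).
#' @param params A [segmentation_params()] list.
#' @return The segment data frame with `kind` assigned.
#' @export
classify_segments <- function(segments, seq_length, params = segmentation_params()) {
  check_disjoint_sorted(segments)
  if (nrow(segments) && (min(segments$start) < 1L ||
                         max(segments$end) > seq_length)) {
    stop("segments out of range 1..", seq_length, call. = FALSE)
  }
  len <- segments$end - segments$start + 1L
  kind <- ifelse(segments$end <= params$sp_window, "signal_peptide",
                 ifelse(len >= params$min_tmd_length, "tmd",
                        "hydrophobic_region"))
  segments$kind <- kind
  segments
}

#' Split a merged double domain from its outer boundaries
#'
#' When two adjacent membrane helices merge into one long segment, the
#' two domains are recovered by adding to the left boundary and
#' subtracting from the right boundary the assumed average domain
#' length: segment (a, b) becomes (a, a + L_avg) and (b - L_avg, b).
#'
#' @param segment One-row segment data frame, or a length-2 numeric
#'   `c(start, end)`.
#' @param L_avg Assumed average domain length (residues), default 20.
#' @return A two-row segment data frame, both rows kind `"tmd"` and
#'   source `"split"`.
#' @examples
#' split_merged_segment(c(89, 151))   # (89,109) and (131,151)
#' @export
split_merged_segment <- function(segment, L_avg = 20) {
  if (is.numeric(segment) && length(segment) == 2L) {
    a <- as.integer(segment[1]); b <- as.integer(segment[2])
  } else if (is.data.frame(segment) && nrow(segment) == 1L) {
    a <- as.integer(segment$start); b <- as.integer(segment$end)
  } else {
    stop("segment must be c(start, end) or a one-row segment data frame",
         call. = FALSE)
  }
  L_avg <- as.integer(L_avg)
  if (b - a < 2L * L_avg + 2L) {
    stop("segment (", a, ", ", b, ") too narrow to split: width ",
         b - a, " < ", 2L * L_avg + 2L, call. = FALSE)
  }
  new_segments(c(a, b - L_avg), c(a + L_avg, b),
               c("tmd", "tmd"), c("split", "split"))
}

#' Split every over-wide tmd segment in a set
#'
#' Applies [split_merged_segment()] to each segment of kind `"tmd"`
#' (or to every segment, if there is no `kind` column) whose width
#' `end - start` is at least `2 * L_avg + 2`; other segments pass
#' through unchanged.
#'
#' @param segments Segment data frame with columns `start`, `end` and
#'   optionally `kind`, `source`.
#' @param L_avg Assumed average domain length, default 20.
#' @return The segment data frame with wide segments replaced by their
#'   two split halves (source `"split"`).
#' @export
split_wide_segments <- function(segments, L_avg = 20) {
  if (is.null(segments$kind)) segments$kind <- "tmd"
  if (is.null(segments$source)) segments$source <- "detected"
  apply_splitting(segments, as.integer(L_avg))
}

apply_splitting <- function(segments, L_avg) {
  wide <- segments$kind == "tmd" &
    (segments$end - segments$start) >= 2L * L_avg + 2L
  if (!any(wide)) return(segments)
  pieces <- lapply(seq_len(nrow(segments)), function(i) {
    if (wide[i]) split_merged_segment(segments[i, ], L_avg) else segments[i, ]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Predict the transmembrane topography of a protein
#'
#' End-to-end prediction: encode the sequence on a hydropathy scale,
#' smooth by cascade averaging, threshold at the level u (by default
#' the whole-chain mean of the raw series), report the maximal runs
#' above the level, classify them, and optionally split over-wide
#' merged domains.
#'
#' @inheritParams hydro_profile
#' @param params A [segmentation_params()] list.
#' @return An object of class `tm_prediction`: list with `protein_id`,
#'   `scale_name`, `n`, `u`, `profile` (the `hydro_profile`), and
#'   `segments` (data frame `start`, `end`, `kind`, `source`).
#' @examples
#' p <- generate_block_protein(block_architecture(
#'   c("loop", "tmd", "loop"), c(25, 21, 25), seed = 1))
#' predict_topography(p$sequence, "H3", n = 4)
#' @export
predict_topography <- function(seq, scale, n = 4, level = NULL,
                               params = segmentation_params(),
                               edge_rule = c("truncate", "mirror"),
                               unknown = c("zero", "error")) {
  prof <- hydro_profile(seq, scale, n = n, level = level,
                        edge_rule = match.arg(edge_rule),
                        unknown = match.arg(unknown))
  segs <- detect_segments(prof)
  segs <- classify_segments(segs, length(prof$f0), params)
  if (params$split_enabled) segs <- apply_splitting(segs, params$L_avg)
  structure(list(protein_id = prof$protein_id, scale_name = prof$scale_name,
                 n = prof$n, u = prof$u, profile = prof, segments = segs,
                 params = params),
            class = "tm_prediction")
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat(sprintf("<tm_prediction> %s: scale %s, n = %d, u = %.3f\n",
              x$protein_id, x$scale_name, x$n, x$u))
  counts <- table(factor(x$segments$kind,
                         c("tmd", "signal_peptide", "hydrophobic_region")))
  cat(sprintf("  %d tmd, %d signal_peptide, %d hydrophobic_region\n",
              counts[["tmd"]], counts[["signal_peptide"]],
              counts[["hydrophobic_region"]]))
  print(x$segments)
  invisible(x)
}
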