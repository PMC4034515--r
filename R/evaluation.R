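#' Construct a reference annotation
#'
#' @param protein_id Identifier matching the prediction to be scored.
#' @param tmds Data frame (or matrix) with columns `start`, `end`:
#'   reference transmembrane intervals, 1-based inclusive, sorted,
#'   pairwise disjoint.
#' @param signal_peptide Optional length-2 numeric `c(start, end)`.
#' @param source Free-text provenance.
#' @return An object of class `reference_annotation`.
#' @export
reference_annotation <- function(protein_id, tmds, signal_peptide = NULL,
                                 source = "") {
  tmds <- as.data.frame(tmds)
  stopifnot(all(c("start", "end") %in% names(tmds)))
  tmds <- data.frame(start = as.integer(tmds$start),
                     end = as.integer(tmds$end))
  if (nrow(tmds)) {
    stopifnot(all(tmds$start >= 1), all(tmds$end >= tmds$start))
    check_disjoint_sorted(tmds)
  }
  structure(list(protein_id = as.character(protein_id), tmds = tmds,
                 signal_peptide = signal_peptide,
                 source = as.character(source)),
            class = "reference_annotation")
}

overlap_len <- function(a1, a2, b1, b2) {
  pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
}

#' Score predicted transmembrane domains against a reference annotation
#'
#' Each reference TMD is assigned the predicted segment with maximal
#' residue overlap (at least one residue).  A reference TMD is
#' *resolved* iff it has an assigned segment and that segment is not
#' also the maximal-overlap assignee of another reference TMD: a single
#' prediction spanning two reference domains (a merged double domain)
#' resolves neither under this strict one-to-one rule, but is counted
#' once in the lenient `n_revealed` tally (two domains merged into one
#' detected region lose exactly one domain).  For each resolved TMD the
#' two boundaries count as in agreement iff the absolute deviation
#' between predicted and reference position is at most `tolerance`
#' residues; boundaries of unresolved TMDs count as failures.
#'
#' @param predicted A `tm_prediction`, or a segment data frame; only
#'   rows of kind `"tmd"` (or rows without a `kind` column) participate.
#' @param reference A `reference_annotation`.
#' @param tolerance Boundary agreement tolerance in residues,
#'   default 6 (about half the final smoothing window at n = 4..5).
#' @return An object of class `tm_evaluation`: counts `n_ref_tmds`,
#'   `n_resolved`, `n_revealed`, `n_boundaries`, `n_boundaries_ok`,
#'   the `tolerance`, and a `per_domain` data frame with the matched
#'   predicted interval and both boundary deviations per reference TMD.
#' @export
match_domains <- function(predicted, reference, tolerance = 6) {
  stopifnot(inherits(reference, "reference_annotation"))
  if (inherits(predicted, "tm_prediction")) {
    if (!identical(predicted$protein_id, reference$protein_id)) {
      stop("protein id mismatch: prediction '", predicted$protein_id,
           "' vs reference '", reference$protein_id, "'", call. = FALSE)
    }
    segs <- predicted$segments
  } else {
    segs <- as.data.frame(predicted)
  }
  if (!is.null(segs$kind)) segs <- segs[segs$kind == "tmd", , drop = FALSE]
  check_disjoint_sorted(segs)
  ref <- reference$tmds
  m <- nrow(ref)

  assignee <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (!nrow(segs)) break
    ov <- overlap_len(ref$start[i], ref$end[i], segs$start, segs$end)
    if (any(ov > 0L)) assignee[i] <- which.max(ov)
  }
  claimed <- table(assignee[!is.na(assignee)])
  multi <- as.integer(names(claimed)[claimed > 1L])
  resolved <- !is.na(assignee) & !(assignee %in% multi)
  n_revealed <- sum(resolved) + length(multi)

  dev_l <- dev_r <- rep(NA_integer_, m)
  ok_l <- ok_r <- rep(FALSE, m)
  ps <- pe <- rep(NA_integer_, m)
  has <- !is.na(assignee)
  ps[has] <- segs$start[assignee[has]]
  pe[has] <- segs$end[assignee[has]]
  dev_l[has] <- abs(ps[has] - ref$start[has])
  dev_r[has] <- abs(pe[has] - ref$end[has])
  ok_l[resolved] <- dev_l[resolved] <= tolerance
  ok_r[resolved] <- dev_r[resolved] <= tolerance

  per_domain <- data.frame(
    ref_start = ref$start, ref_end = ref$end,
    pred_start = ps, pred_end = pe,
    resolved = resolved, dev_left = dev_l, dev_right = dev_r,
    ok_left = ok_l, ok_right = ok_r)

  structure(list(protein_id = reference$protein_id,
                 n_ref_tmds = m,
                 n_resolved = sum(resolved),
                 n_revealed = n_revealed,
                 n_boundaries = 2L * m,
                 n_boundaries_ok = sum(ok_l) + sum(ok_r),
                 tolerance = tolerance,
                 per_domain = per_domain),
            class = "tm_evaluation")
}

#' @export
print.tm_evaluation <- function(x, ...) {
  cat(sprintf("<tm_evaluation> %s: %d/%d resolved (%d revealed), %d/%d boundaries within %d aa\n",
              x$protein_id, x$n_resolved, x$n_ref_tmds, x$n_revealed,
              x$n_boundaries_ok, x$n_boundaries, as.integer(x$tolerance)))
  print(x$per_domain)
  invisible(x)
}

#' Aggregate per-protein evaluation reports
#'
#' Sums the counts over proteins and derives the two headline
#' percentages: fraction of reference TMDs resolved (also the lenient
#' revealed fraction) and fraction of boundary positions in agreement.
#'
#' @param reports A list of `tm_evaluation` objects sharing one
#'   tolerance.
#' @return A list of class `tm_evaluation_summary` with total counts and
#'   percentages (`pct_resolved`, `pct_revealed` to 1 decimal;
#'   `pct_boundaries_ok` rounded to integer in printing, full value
#'   kept).
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "tm_evaluation")))
  tol <- unique(vapply(reports, `[[`, numeric(1), "tolerance"))
  if (length(tol) != 1L) {
    stop("reports use different tolerances: ",
         paste(tol, collapse = ", "), call. = FALSE)
  }
  tot <- function(field) sum(vapply(reports, `[[`, numeric(1), field))
  n_ref <- tot("n_ref_tmds")
  n_res <- tot("n_resolved")
  n_rev <- tot("n_revealed")
  n_b <- tot("n_boundaries")
  n_ok <- tot("n_boundaries_ok")
  structure(list(n_proteins = length(reports), tolerance = tol,
                 n_ref_tmds = n_ref, n_resolved = n_res, n_revealed = n_rev,
                 n_boundaries = n_b, n_boundaries_ok = n_ok,
                 pct_resolved = round(100 * n_res / n_ref, 1),
                 pct_revealed = round(100 * n_rev / n_ref, 1),
                 pct_boundaries_ok = round(100 * n_ok / n_b, 1)),
            class = "tm_evaluation_summary")
}

#' @export
print.tm_evaluation_summary <- function(x, ...) {
  cat(sprintf("%d proteins, tolerance %d aa\n", x$n_proteins,
              as.integer(x$tolerance)))
  cat(sprintf("  resolved: %d/%d (%.1f%%); revealed: %d/%d (%.1f%%)\n",
              x$n_resolved, x$n_ref_tmds, x$pct_resolved,
              x$n_revealed, x$n_ref_tmds, x$pct_revealed))
  cat(sprintf("  boundaries within tolerance: %d/%d (%.0f%%)\n",
              x$n_boundaries_ok, x$n_boundaries,
              100 * x$n_boundaries_ok / x$n_boundaries))
  invisible(x)
}

#' Write a per-domain evaluation report as TSV
#'
#' One row per reference TMD followed by a `# summary:` comment block.
#'
#' @param evaluations A list of `tm_evaluation` objects (or one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(evaluations, path) {
  if (inherits(evaluations, "tm_evaluation")) evaluations <- list(evaluations)
  rows <- do.call(rbind, lapply(evaluations, function(ev) {
    cbind(protein_id = ev$protein_id, index = seq_len(ev$n_ref_tmds),
          ev$per_domain)
  }))
  s <- aggregate_reports(evaluations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("evaluate",
                           c(tolerance = s$tolerance,
                             proteins = s$n_proteins)), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# summary: resolved %d/%d (%.1f%%), revealed %d/%d (%.1f%%), boundaries_ok %d/%d (%.1f%%)",
                     s$n_resolved, s$n_ref_tmds, s$pct_resolved,
                     s$n_revealed, s$n_ref_tmds, s$pct_revealed,
                     s$n_boundaries_ok, s$n_boundaries,
                     s$pct_boundaries_ok), con)
  invisible(path)
}
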