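pkg_version <- function() {
  as.character(utils::packageVersion("hydrocascade"))
}

# "# hydrocascade vX.Y.Z <command> key=value ..." comment header embedded in
# every output file so a result is reproducible from the file alone
output_header <- function(command, params = c()) {
  kv <- if (length(params)) {
    paste(paste0(names(params), "=", unname(params)), collapse = " ")
  } else ""
  trimws(paste("# hydrocascade", pkg_version(), command, kv))
}

#' Read protein sequences from a FASTA file
#'
#' Light structural validation (with line numbers in error messages) is
#' performed first, then the records are parsed with
#' `Biostrings::readAAStringSet`.  Sequences are upper-cased; the part
#' of the header line after the first whitespace is kept as the
#' description.
#'
#' @param path FASTA file path.
#' @return A list of `protein_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA (", path, " line ", first,
         "): sequence data before first header", call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  empty_rec <- hdr[-length(hdr)] & (hdr[-1L] | trimws(lines[-1L]) == "")
  if (hdr[length(hdr)] || any(empty_rec)) {
    bad <- if (hdr[length(hdr)]) length(lines) else which(empty_rec)[1L]
    stop("malformed FASTA (", path, " line ", bad,
         "): header with no sequence", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    full <- names(set)[i]
    id <- sub("\\s.*$", "", full)
    desc <- if (grepl("\\s", full)) sub("^\\S+\\s+", "", full) else ""
    protein_sequence(as.character(set[[i]]), id = id, description = desc)
  })
}

#' Write protein sequences as FASTA
#'
#' @param seqs A `protein_sequence` or list of them.
#' @param path Output path.
#' @param width Line-wrap width, default 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, character(1), "residues"))
  nm <- vapply(seqs, `[[`, character(1), "id")
  desc <- vapply(seqs, `[[`, character(1), "description")
  names(set) <- ifelse(nzchar(desc), paste(nm, desc), nm)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

prediction_rows <- function(predictions) {
  if (inherits(predictions, "tm_prediction")) predictions <- list(predictions)
  do.call(rbind, lapply(predictions, function(p) {
    if (!nrow(p$segments)) return(NULL)
    cbind(protein = p$protein_id, p$segments,
          scale = p$scale_name, n = p$n, u = round(p$u, 3))
  }))
}

#' Write predictions as a tab-separated table
#'
#' Columns: protein, start, end, kind, source, scale, n, u.
#' Coordinates are 1-based inclusive.  The level u is printed rounded
#' to 3 decimals.
#'
#' @param predictions A `tm_prediction` or list of them.
#' @param path Output path ("" for standard output).
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(predictions, path = "") {
  rows <- prediction_rows(predictions)
  hdr <- output_header("predict", c(format = "tsv"))
  if (identical(path, "")) {
    cat(hdr, "\n", sep = "")
    utils::write.table(rows, "", sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write predictions in BED format
#'
#' Internal 1-based inclusive intervals \[start, end\] are converted at
#' write time to BED's 0-based half-open convention
#' (`chromStart = start - 1`, `chromEnd = end`); reading them back with
#' `start = chromStart + 1`, `end = chromEnd` round-trips exactly.
#' The name field carries the segment kind.
#'
#' @inheritParams write_segments_tsv
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(predictions, path = "") {
  rows <- prediction_rows(predictions)
  bed <- data.frame(chrom = rows$protein,
                    chromStart = rows$start - 1L,
                    chromEnd = rows$end,
                    name = rows$kind,
                    score = 0L,
                    strand = ".")
  lines <- c(output_header("predict", c(format = "bed")),
             apply(bed, 1L, paste, collapse = "\t"))
  writeLines(lines, if (identical(path, "")) stdout() else path)
  invisible(path)
}

#' Write predictions in GFF3 format
#'
#' Feature types are `Transmembrane_helix`, `Signal_peptide` and
#' `Hydrophobic_region`; coordinates stay 1-based inclusive per GFF3.
#'
#' @inheritParams write_segments_tsv
#' @return `path`, invisibly.
#' @export
write_segments_gff3 <- function(predictions, path = "") {
  rows <- prediction_rows(predictions)
  type <- c(tmd = "Transmembrane_helix",
            signal_peptide = "Signal_peptide",
            hydrophobic_region = "Hydrophobic_region")[rows$kind]
  attr <- sprintf("ID=%s.%d;scale=%s;n=%d;u=%s;source_rule=%s",
                  rows$protein, seq_len(nrow(rows)), rows$scale,
                  rows$n, rows$u, rows$source)
  gff <- paste(rows$protein, "hydrocascade", type, rows$start, rows$end,
               ".", ".", ".", attr, sep = "\t")
  lines <- c("##gff-version 3",
             output_header("predict", c(format = "gff3")),
             gff)
  writeLines(lines, if (identical(path, "")) stdout() else path)
  invisible(path)
}

#' Read reference TMD annotations from a tab-separated file
#'
#' Expected columns (header required): `protein_id`, `index`, `start`,
#' `end`; extra columns are carried along but ignored.  `index` is the
#' ordinal of the TMD within the protein, or the literal `SP` for a
#' signal-peptide row.  Lines starting with `#` are comments.
#'
#' @param path TSV file path.
#' @return A named list of `reference_annotation` objects, one per
#'   protein, in file order.
#' @export
read_reference_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "index", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("reference file ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ids <- unique(tab$protein_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$protein_id == id, , drop = FALSE]
    is_sp <- toupper(as.character(sub$index)) == "SP"
    sp <- if (any(is_sp)) c(sub$start[is_sp][1L], sub$end[is_sp][1L])
    tmds <- sub[!is_sp, , drop = FALSE]
    tmds <- tmds[order(tmds$start), , drop = FALSE]
    reference_annotation(id, tmds[, c("start", "end")],
                         signal_peptide = sp, source = path)
  })
  stats::setNames(out, ids)
}

#' Write reference annotations in the tab-separated exchange format
#'
#' @param annotations A list of `reference_annotation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_tsv <- function(annotations, path) {
  if (inherits(annotations, "reference_annotation")) {
    annotations <- list(annotations)
  }
  rows <- do.call(rbind, lapply(annotations, function(a) {
    r <- data.frame(protein_id = a$protein_id,
                    index = as.character(seq_len(nrow(a$tmds))),
                    start = a$tmds$start, end = a$tmds$end)
    if (!is.null(a$signal_peptide)) {
      r <- rbind(data.frame(protein_id = a$protein_id, index = "SP",
                            start = a$signal_peptide[1],
                            end = a$signal_peptide[2]), r)
    }
    r
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("reference"), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-residue profile table as TSV
#'
#' @param profile A `hydro_profile`.
#' @param path Output path ("" for standard output).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path = "") {
  tab <- profile_table(profile)
  hdr <- output_header("profile",
                       c(protein = profile$protein_id,
                         scale = profile$scale_name, n = profile$n,
                         u = round(profile$u, 3),
                         edge = profile$edge_rule))
  if (identical(path, "")) {
    cat(hdr, "\n", sep = "")
    utils::write.table(tab, "", sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
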