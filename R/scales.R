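#' Bundled hydrophobicity scales
#'
#' Seven per-residue hydropathy scales spanning the common families of
#' hydrophobicity measures: free-energy based scales (H1, H6), crude
#' class-indicator scales (H2: hydrophobic = 1, rest = 0; H3: hydrophobic
#' = +1, hydrophilic = -1, neutral A/H/Y = 0), a buried-fraction scale
#' derived from solvent-accessible surface areas (H4, values in (0, 1)),
#' and consensus/statistical scales (H5, H7).  The hydrophobic class is
#' C, F, I, L, M, V, W; the hydrophilic class is D, E, G, K, N, P, Q, R,
#' S, T; A, H and Y are neutral.
#'
#' @format A data frame with 20 rows (one per standard amino acid) and
#'   columns `code` (one-letter code), `name` (full amino-acid name) and
#'   `H1`..`H7` (numeric scale values).
#' @seealso [get_scale()], [encode_sequence()], [write_scales_tsv()]
#' @export
hydro_scales <- local({
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code name          H1   H2 H3 H4   H5    H6    H7
A    Alanine       1.8  0  0  0.74 0.62  1.60  -0.17
C    Cysteine      2.5  1  1  0.91 0.29  2.00  0.24
D    Aspartic.acid -3.5 0  -1 0.62 -0.90 -9.20 -1.23
E    Glutamic.acid -3.5 0  -1 0.62 -0.74 -8.20 -2.02
F    Phenylalanine 2.8  1  1  0.88 1.19  3.70  1.13
G    Glycine       -0.4 0  -1 0.72 0.48  1.00  -0.01
H    Histidine     -3.2 0  0  0.78 -0.40 -3.00 -0.96
I    Isoleucine    4.5  1  1  0.88 1.38  3.10  0.31
K    Lysine        -3.9 0  -1 0.52 -1.50 -8.80 -0.99
L    Leucine       3.8  1  1  0.85 1.06  2.80  0.56
M    Methionine    1.9  1  1  0.85 0.64  3.40  0.23
N    Asparagine    -3.5 0  -1 0.63 -0.78 -4.80 -1.23
P    Proline       -1.6 0  -1 0.64 0.12  -0.20 -0.45
Q    Glutamine     -3.5 0  -1 0.62 -0.85 -4.10 -0.58
R    Arginine      -4.5 0  -1 0.64 -2.53 -12.3 -0.81
S    Serine        -0.8 0  -1 0.66 -0.18 0.60  -0.13
T    Threonine     -0.7 0  -1 0.70 -0.05 1.20  -0.14
V    Valine        4.2  1  1  0.86 1.08  2.60  -0.07
W    Tryptophan    -0.9 1  1  0.85 0.81  1.90  1.85
Y    Tyrosine      -1.3 0  0  0.76 0.26  -0.70 0.94
")
  tab$name <- gsub(".", " ", tab$name, fixed = TRUE)
  tab[paste0("H", 1:7)] <- lapply(tab[paste0("H", 1:7)], as.numeric)
  tab
})

#' @rdname amino_acid_classes
#' @name amino_acid_classes
#' @title Amino-acid hydrophobicity classes
#' @description Character vectors of one-letter codes for the hydrophobic
#'   (7 residues), hydrophilic (10 residues) and neutral (3 residues)
#'   classes underlying the crude scales H2 and H3.
#' @export
hydrophobic_residues <- c("C", "F", "I", "L", "M", "V", "W")

#' @rdname amino_acid_classes
#' @export
hydrophilic_residues <- c("D", "E", "G", "K", "N", "P", "Q", "R", "S", "T")

#' @rdname amino_acid_classes
#' @export
neutral_residues <- c("A", "H", "Y")

scale_names <- function() paste0("H", 1:7)

#' Retrieve one hydrophobicity scale
#'
#' @param name Scale identifier, one of `"H1"`..`"H7"`.
#' @return An object of class `hydro_scale`: a list with elements `name`,
#'   `values` (named numeric vector of length 20, names are one-letter
#'   amino-acid codes) and `citation`.
#' @examples
#' h1 <- get_scale("H1")
#' h1$values[["A"]]  # 1.8
#' @export
get_scale <- function(name) {
  if (length(name) != 1L || !is.character(name) || !name %in% scale_names()) {
    stop("unknown scale '", paste(name, collapse = ","),
         "'; valid scales are ", paste(scale_names(), collapse = ", "),
         call. = FALSE)
  }
  values <- stats::setNames(hydro_scales[[name]], hydro_scales$code)
  citations <- c(
    H1 = "Kyte-Doolittle free-energy hydropathy",
    H2 = "crude indicator: hydrophobic class = 1, others = 0",
    H3 = "crude three-class: hydrophobic +1, hydrophilic -1, neutral 0",
    H4 = "buried fraction 1 - <A>/A0 from solvent-accessible surface areas",
    H5 = "Eisenberg consensus hydrophobicity",
    H6 = "free energy of transfer to water",
    H7 = "statistical hydrophobicity"
  )
  structure(list(name = name, values = values,
                 citation = unname(citations[name])),
            class = "hydro_scale")
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("Hydrophobicity scale", x$name, "-", x$citation, "\n")
  print(x$values)
  invisible(x)
}

#' Construct a protein sequence record
#'
#' @param residues Character scalar of one-letter amino-acid codes
#'   (lower case accepted; normalised to upper case).
#' @param id Identifier for the protein.
#' @param description Optional free-text description.
#' @return An object of class `protein_sequence` with elements `id`,
#'   `residues`, `length` and `description`.
#' @export
protein_sequence <- function(residues, id = "protein", description = "") {
  if (length(residues) != 1L || !is.character(residues) || is.na(residues)) {
    stop("residues must be a single character string", call. = FALSE)
  }
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) stop("empty protein sequence", call. = FALSE)
  structure(list(id = as.character(id), residues = residues,
                 length = nchar(residues),
                 description = as.character(description)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, x$length))
  invisible(x)
}

as_protein_sequence <- function(x, id = "protein") {
  if (inherits(x, "protein_sequence")) return(x)
  protein_sequence(as.character(x), id = id)
}

#' Encode a protein sequence as a hydrophobicity series
#'
#' Maps each residue at position k = 1..L to its scale value, giving the
#' raw hydropathy series f0(k) from which smoothed profiles are built.
#'
#' @param seq A `protein_sequence`, or a character scalar of one-letter
#'   codes.
#' @param scale A `hydro_scale` (from [get_scale()]) or a scale name.
#' @param unknown Policy for non-standard codes (X, B, Z, U, O, ...):
#'   `"zero"` maps them to 0 with a warning, `"error"` aborts naming the
#'   position and offending code.
#' @return Numeric vector of length `L`.
#' @examples
#' encode_sequence("ACD", "H1")  # 1.8 2.5 -3.5
#' @export
encode_sequence <- function(seq, scale, unknown = c("zero", "error")) {
  unknown <- match.arg(unknown)
  seq <- as_protein_sequence(seq)
  if (is.character(scale)) scale <- get_scale(scale)
  stopifnot(inherits(scale, "hydro_scale"))
  codes <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  vals <- unname(scale$values[codes])
  bad <- which(is.na(vals))
  if (length(bad)) {
    what <- paste0(codes[bad], "@", bad, collapse = ", ")
    if (unknown == "error") {
      stop("non-standard residue code(s) in '", seq$id, "': ", what,
           call. = FALSE)
    }
    warning("non-standard residue code(s) in '", seq$id,
            "' mapped to 0: ", what, call. = FALSE)
    vals[bad] <- 0
  }
  vals
}

#' Write the bundled scales as a tab-separated table
#'
#' One row per amino acid, columns `code`, `name`, `H1`..`H7`.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scales_tsv <- function(path) {
  utils::write.table(hydro_scales, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
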