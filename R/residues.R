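#' Build a residue set
#'
#' A residue set is a tibble of amino-acid building blocks, one row per
#' residue, with a unique short `code`, a human-readable `name`, a `natural`
#' flag, and optionally one column per physicochemical descriptor. Codes are
#' free tokens (not restricted to one-letter IUPAC symbols) because most
#' building blocks of interest for anchor substitution are unnatural.
#'
#' @param code character vector of unique residue codes.
#' @param name character vector of residue names (recycled from `code` if
#'   missing).
#' @param natural logical vector flagging proteinogenic residues.
#' @param descriptors optional data frame / matrix of numeric descriptor
#'   values, one row per residue.
#' @return A tibble with class `residue_set`.
#' @export
#' @examples
#' residue_set(c("Ile", "Hle"), natural = c(TRUE, FALSE))
residue_set <- function(code, name = code, natural = TRUE,
                        descriptors = NULL) {
  code <- as.character(code)
  if (anyDuplicated(code)) {
    stop("residue codes must be unique; duplicated: ",
         paste(unique(code[duplicated(code)]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    code = code,
    name = rep_len(as.character(name), length(code)),
    natural = rep_len(as.logical(natural), length(code))
  )
  if (!is.null(descriptors)) {
    descriptors <- as.data.frame(descriptors)
    stopifnot(nrow(descriptors) == length(code))
    if (!all(vapply(descriptors, is.numeric, logical(1)))) {
      stop("descriptor columns must be numeric", call. = FALSE)
    }
    out <- dplyr::bind_cols(out, tibble::as_tibble(descriptors))
  }
  class(out) <- c("residue_set", class(out))
  out
}

#' Read a residue set from a delimited file
#'
#' Expects columns `code` and `name`; an optional logical `natural` column;
#' any remaining numeric columns are treated as descriptors.
#'
#' @param path file path (TSV by default).
#' @param delim field delimiter.
#' @return A `residue_set` tibble.
#' @export
read_residue_set <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#")
  if (!all(c("code", "name") %in% names(raw))) {
    stop("residue file must have 'code' and 'name' columns", call. = FALSE)
  }
  natural <- if ("natural" %in% names(raw)) as.logical(raw$natural) else TRUE
  desc_cols <- setdiff(names(raw), c("code", "name", "natural"))
  desc <- if (length(desc_cols)) raw[desc_cols] else NULL
  residue_set(raw$code, raw$name, natural, desc)
}

#' Descriptor matrix of a residue set
#'
#' @param residues a `residue_set`.
#' @return Numeric matrix with residue codes as row names, or an error if the
#'   set carries no descriptors.
#' @export
residue_descriptors <- function(residues) {
  desc_cols <- setdiff(names(residues), c("code", "name", "natural"))
  if (!length(desc_cols)) {
    stop("residue set carries no descriptor columns", call. = FALSE)
  }
  m <- as.matrix(residues[desc_cols])
  rownames(m) <- residues$code
  m
}

#' Anchor residue sets of the designed glycopeptide library
#'
#' The seven building blocks retained for each of the two varied anchor
#' positions of the CII259-273 glycopeptide after consensus scoring and
#' principal-property selection: position p260 (the residue anchored in the
#' A(q) P1 pocket) and position p263 (the A(q) P4 / DR4 P1 anchor).
#'
#' @param position `"p260"` or `"p263"`.
#' @return A `residue_set` tibble with 7 rows.
#' @export
#' @examples
#' anchor_residues("p260")$code
anchor_residues <- function(position = c("p260", "p263")) {
  position <- match.arg(position)
  path <- system.file("extdata", paste0("residues_", position, ".tsv"),
                      package = "pepsmd", mustWork = TRUE)
  read_residue_set(path)
}
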