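#' Enumerate a two-position factorial peptide library
#'
#' Builds every combination of the candidate residues at the two varied
#' anchor positions of a fixed template sequence. The template octapeptide
#' used throughout (`Ac-Ile260-Ala-Gly-Phe263-Lys-Gly-Glu-Gln267-NH2`) keeps
#' all other positions invariant, so a library is fully described by the
#' (p260, p263) pair of each member.
#'
#' @param p260_set,p263_set character vectors of residue codes (or
#'   `residue_set` tibbles) for the two varied positions.
#' @param template character vector of codes for the invariant positions;
#'   stored as an attribute, not expanded per row.
#' @return A tibble with one row per peptide: `id` (`"<p260>_<p263>"`),
#'   `p260`, `p263`, in p260-major order.
#' @export
#' @examples
#' nrow(enumerate_library(c("A", "B"), c("X", "Y", "Z")))  # 6
enumerate_library <- function(p260_set, p263_set,
                              template = c("Ala", "Gly", "Lys", "Gly",
                                           "Glu", "Gln")) {
  p260_set <- library_codes(p260_set, "p260")
  p263_set <- library_codes(p263_set, "p263")
  out <- tidyr::expand_grid(p260 = p260_set, p263 = p263_set)
  out <- dplyr::mutate(out, id = paste(.data$p260, .data$p263, sep = "_"),
                       .before = 1)
  attr(out, "template") <- as.character(template)
  out
}

library_codes <- function(x, what) {
  codes <- if (is.data.frame(x)) as.character(x$code) else as.character(x)
  if (!length(codes)) stop(what, " set is empty", call. = FALSE)
  if (anyDuplicated(codes)) {
    stop("duplicate codes in ", what, " set: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  codes
}

#' Encode peptides as position/residue indicator variables
#'
#' Each peptide is described by the presence (1) or absence (0) of each
#' candidate residue at each varied position: one binary column per
#' (position, residue) level, position-major with residue codes in
#' lexicographic order. With seven residues per position this yields the
#' 14-variable qualitative description used for indicator-variable PLS.
#'
#' @param peptides tibble with columns `id`, `p260`, `p263` (as returned by
#'   [enumerate_library()]).
#' @param p260_levels,p263_levels residue codes defining the columns;
#'   default: the sorted codes observed in `peptides`.
#' @return Numeric 0/1 matrix, rows named by peptide id, columns
#'   `p260.<code>` then `p263.<code>`; every row sums to 2.
#' @export
encode_indicators <- function(peptides,
                              p260_levels = sort(unique(peptides$p260)),
                              p263_levels = sort(unique(peptides$p263))) {
  stopifnot(all(c("id", "p260", "p263") %in% names(peptides)))
  p260_levels <- sort(library_codes(p260_levels, "p260 levels"))
  p263_levels <- sort(library_codes(p263_levels, "p263 levels"))
  bad <- peptides$id[!(peptides$p260 %in% p260_levels) |
                       !(peptides$p263 %in% p263_levels)]
  if (length(bad)) {
    stop("peptide(s) with anchor residue outside the level lists: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  block <- function(values, levels, position) {
    m <- outer(values, levels, `==`) * 1
    colnames(m) <- paste(position, levels, sep = ".")
    m
  }
  x <- cbind(block(peptides$p260, p260_levels, "p260"),
             block(peptides$p263, p263_levels, "p263"))
  rownames(x) <- peptides$id
  x
}

#' Decode an indicator matrix back to anchor pairs
#'
#' Inverse of [encode_indicators()]: recovers the (p260, p263) residue pair
#' of each row.
#'
#' @param x indicator matrix with `p260.`/`p263.`-prefixed column names.
#' @return Tibble with columns `id`, `p260`, `p263`.
#' @export
decode_indicators <- function(x) {
  decode_pos <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), colnames(x), value = TRUE)
    sub_x <- x[, cols, drop = FALSE]
    if (any(rowSums(sub_x) != 1)) {
      stop("each row must have exactly one 1 among ", prefix, " columns",
           call. = FALSE)
    }
    sub("^[^.]+\\.", "", cols[max.col(sub_x)])
  }
  tibble::tibble(
    id = rownames(x) %||% as.character(seq_len(nrow(x))),
    p260 = decode_pos("p260"),
    p263 = decode_pos("p263")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
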