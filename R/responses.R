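tcell_alphabet <- c("-" = NA_real_, "+" = 150, "++" = 30, "+++" = 6.0,
                    "++++" = 1.2, "+++++" = 0.24, "++++++" = 0.0064)

#' Load the glycopeptide biological response panel
#'
#' The transcribed competitive MHC-binding and T-cell hybridoma response
#' tables for the reference glycopeptide (peptide 1) and the 20 designed
#' anchor-modified glycopeptides (2-21): % inhibition against A(q) and DR4
#' at two competitor concentrations each, ordinal response categories for
#' six A(q)-restricted and two DR4-restricted hybridomas, and the anchor
#' residue assignment of each peptide.
#'
#' @param anchors join the per-peptide (p260, p263) assignment (default
#'   TRUE).
#' @return Tibble with one row per peptide.
#' @export
#' @examples
#' panel <- response_panel()
#' panel[panel$peptide == "1", "aq_inhib_100"]  # 90
response_panel <- function(anchors = TRUE) {
  path <- system.file("extdata", "tables1_2.tsv", package = "pepsmd",
                      mustWork = TRUE)
  panel <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(peptide = "c"))
  if (anchors) {
    map_path <- system.file("extdata", "glycopeptides.tsv",
                            package = "pepsmd", mustWork = TRUE)
    map <- readr::read_tsv(map_path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(peptide = "c"))
    panel <- dplyr::left_join(panel, map, by = "peptide")
  }
  panel
}

#' Encode ordinal T-cell response categories as numeric strengths
#'
#' The hybridoma panels grade responses by the antigen concentration (uM)
#' required to reach 10% of the maximal IL-2 response; more plus signs mean
#' a lower concentration, i.e. a stronger response. The encoding maps each
#' category to its threshold concentration and returns
#' `-log10(concentration)`, so strength increases strictly with category.
#' No-response (`"-"`) is assigned a floor concentration of ten times the
#' highest tested dose (1500 uM by default, one log-unit below the weakest
#' category); `"n.d."` becomes `NA`.
#'
#' @param symbol character vector of category symbols.
#' @param floor_conc concentration (uM) standing in for no response.
#' @return Numeric vector of response strengths.
#' @export
#' @examples
#' encode_tcell(c("+++", "-", "++++++"))
encode_tcell <- function(symbol, floor_conc = 1500) {
  symbol <- trimws(as.character(symbol))
  symbol[symbol == "−"] <- "-"  # tolerate typographic minus
  out <- rep(NA_real_, length(symbol))
  nd <- symbol %in% c("n.d.", "nd", "NA") | is.na(symbol)
  known <- symbol %in% names(tcell_alphabet)
  if (any(!known & !nd)) {
    stop("unknown response symbol(s): ",
         paste(unique(symbol[!known & !nd]), collapse = ", "),
         call. = FALSE)
  }
  conc <- tcell_alphabet[symbol[known & !nd]]
  conc[is.na(conc)] <- floor_conc
  out[known & !nd] <- -log10(conc)
  out
}

#' Aggregate statistics of the response panel
#'
#' Counts and ranges used to sanity-check the transcribed tables: the
#' number of designed peptides with measured A(q) inhibition (the actives),
#' the min/max inhibition per protein and concentration among the designed
#' peptides, and the reference peptide's values.
#'
#' @param panel a [response_panel()] tibble.
#' @return Named list of scalars.
#' @export
table_aggregates <- function(panel) {
  if (!nrow(panel)) stop("empty response panel", call. = FALSE)
  stopifnot("designed" %in% names(panel))
  des <- dplyr::filter(panel, .data$designed)
  ref <- dplyr::filter(panel, !.data$designed)
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(min = NA_real_, max = NA_real_) else range(v)
  }
  aq100 <- rng(des$aq_inhib_100); aq500 <- rng(des$aq_inhib_500)
  d100 <- rng(des$dr4_inhib_100); d500 <- rng(des$dr4_inhib_500)
  list(
    n_designed = nrow(des),
    n_aq_active = sum(des$aq_active),
    aq_100_min = aq100[1], aq_100_max = aq100[2],
    aq_500_min = aq500[1], aq_500_max = aq500[2],
    dr4_100_min = d100[1], dr4_100_max = d100[2],
    dr4_500_min = d500[1], dr4_500_max = d500[2],
    ref_aq_100 = ref$aq_inhib_100[1],
    ref_dr4_500 = ref$dr4_inhib_500[1]
  )
}

#' Numeric response matrix for pattern analysis
#'
#' Encodes the panel as a peptide x response matrix: the four binding
#' variables (% inhibition) plus one strength per hybridoma (see
#' [encode_tcell()]). Cells without a measurement are handled according to
#' `missing`: `"floor"` (default) treats the A(q) inhibition of peptides
#' classified inactive as 0% and untested (`n.d.`) hybridomas as
#' no-response - these peptides were not carried forward precisely because
#' they did not bind, so the floor is the informative value; `"mean"`
#' leaves them `NA` for mean imputation after scaling inside
#' [response_pca()].
#'
#' @param panel a [response_panel()] tibble.
#' @param missing `"floor"` or `"mean"`.
#' @param floor_conc passed to [encode_tcell()].
#' @return Numeric matrix, rows named by peptide.
#' @export
encode_panel <- function(panel, missing = c("floor", "mean"),
                         floor_conc = 1500) {
  missing <- match.arg(missing)
  bind_cols <- c("aq_inhib_100", "aq_inhib_500",
                 "dr4_inhib_100", "dr4_inhib_500")
  tc_cols <- grep("^tc_", names(panel), value = TRUE)
  x <- as.matrix(panel[bind_cols])
  tc <- sapply(panel[tc_cols], encode_tcell, floor_conc = floor_conc)
  if (missing == "floor") {
    x[is.na(x)] <- 0
    tc[is.na(tc)] <- -log10(floor_conc)
  }
  out <- cbind(x, tc)
  rownames(out) <- panel$peptide
  out
}

#' PCA of the combined biological responses
#'
#' Groups peptides by their full activity fingerprint: a PCA on the encoded
#' response matrix (binding to both proteins at both concentrations plus
#' all hybridoma response strengths), followed by hierarchical clustering of
#' the leading component scores. Peptides close together in score space
#' share a response pattern - e.g. strong binders of both proteins versus
#' peptides binding neither.
#'
#' @param panel a [response_panel()] tibble.
#' @param n_components components to extract (default 3).
#' @param n_groups clusters cut from the score-space dendrogram (default 4).
#' @param missing,floor_conc passed to [encode_panel()].
#' @return List: `pca` ([fit_pca()] model), `scores` tibble with `peptide`,
#'   component scores and `group`, and `matrix` (the encoded input).
#' @export
response_pca <- function(panel, n_components = 3, n_groups = 4,
                         missing = c("floor", "mean"), floor_conc = 1500) {
  missing <- match.arg(missing)
  x <- encode_panel(panel, missing = missing, floor_conc = floor_conc)
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warning("excluding peptide(s) with no responses: ",
            paste(rownames(x)[all_missing], collapse = ", "), call. = FALSE)
    x <- x[!all_missing, , drop = FALSE]
  }
  x_fit <- x
  if (anyNA(x_fit)) {
    # mean imputation after scaling: scaled column mean is 0 by construction
    xp <- mv_preprocess(x_fit)
    xp[is.na(xp)] <- 0
    x_fit <- sweep(sweep(xp, 2, attr(xp, "scale"), `*`), 2,
                   attr(xp, "center"), `+`)
  }
  pca <- fit_pca(x_fit, n_components = n_components, cv_groups = 7)
  sc <- pca$scores
  groups <- stats::cutree(
    stats::hclust(stats::dist(sc), method = "complete"), k = n_groups)
  scores <- dplyr::bind_cols(
    tibble::tibble(peptide = rownames(x_fit)),
    tibble::as_tibble(sc),
    tibble::tibble(group = unname(groups))
  )
  list(pca = pca, scores = scores, matrix = x)
}
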