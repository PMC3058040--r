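#' Orient scoring functions so that lower is better
#'
#' Docking scoring functions disagree on sign conventions; functions whose
#' raw values increase with predicted affinity (e.g. Goldscore) are
#' multiplied by -1 so that, across all columns, a large negative value
#' corresponds to a high rank. Applying the same flip twice restores the
#' original table.
#'
#' @param scores tibble with a `peptide_id` column and one numeric column
#'   per scoring function.
#' @param flip character vector of scoring-function columns to negate.
#' @return The score table with the named columns negated.
#' @export
#' @examples
#' tb <- tibble::tibble(peptide_id = "a", Goldscore = 50)
#' orient_scores(tb, "Goldscore")$Goldscore  # -50
orient_scores <- function(scores, flip = "Goldscore") {
  unknown <- setdiff(flip, names(scores))
  if (length(unknown)) {
    stop("unknown scoring function(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(scores, dplyr::across(dplyr::all_of(flip), ~ -.x))
}

#' Per-position consensus statistics of residue scores
#'
#' Collapses peptide-level rescoring values into statistics for each
#' residue observed at one varied position: the frequency (number of
#' surviving peptides carrying the residue) and, per scoring function, the
#' best (minimum, scores oriented so lower is better), mean, and sample
#' standard deviation of the scores. With seven scoring functions each
#' residue is described by 22 parameters (1 frequency + 3 x 7). The SD of a
#' residue seen once is recorded as 0 so the summary matrix stays complete.
#'
#' @param scores oriented score table (see [orient_scores()]) with
#'   `peptide_id` plus one column per function; every peptide must appear in
#'   `peptides`.
#' @param peptides tibble mapping `id` to `p260`, `p263`.
#' @param position `"p260"` or `"p263"`.
#' @return Tibble: `residue`, `frequency`, then `<fn>_best`, `<fn>_mean`,
#'   `<fn>_sd` for each scoring function.
#' @export
summarize_position <- function(scores, peptides, position = c("p260", "p263")) {
  position <- match.arg(position)
  if (!nrow(scores)) stop("empty score table", call. = FALSE)
  fn_cols <- setdiff(names(scores), "peptide_id")
  unmapped <- setdiff(scores$peptide_id, peptides$id)
  if (length(unmapped)) {
    stop("score rows without a peptide mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    scores, dplyr::select(peptides, peptide_id = "id",
                          residue = dplyr::all_of(position)),
    by = "peptide_id"
  )
  long <- tidyr::pivot_longer(joined, dplyr::all_of(fn_cols),
                              names_to = "fn", values_to = "score")
  stats_tb <- long |>
    dplyr::summarise(
      best = min(.data$score),
      mean = mean(.data$score),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$score), 0),
      .by = c("residue", "fn")
    ) |>
    tidyr::pivot_wider(names_from = "fn",
                       values_from = c("best", "mean", "sd"),
                       names_glue = "{fn}_{.value}")
  freq <- dplyr::count(joined, .data$residue, name = "frequency")
  out <- dplyr::left_join(freq, stats_tb, by = "residue")
  # column order: frequency, then per function best/mean/sd
  ordered <- c("residue", "frequency",
               as.vector(t(outer(fn_cols, c("best", "mean", "sd"),
                                 paste, sep = "_"))))
  dplyr::arrange(out[ordered], .data$residue)
}

#' Select candidate residues from a consensus summary by PCA
#'
#' Fits a PCA on the preprocessed consensus parameter matrix and selects
#' residues whose first-component score lies on the favourable side:
#' PC1 is sign-oriented from its loadings so that the positive direction
#' corresponds to high frequency, good (low) scores, and low standard
#' deviations, and residues with an oriented PC1 score above `threshold`
#' are returned. This makes explicit, and reproducible, the visual
#' score-plot selection used in practice.
#'
#' @param summary a [summarize_position()] tibble.
#' @param n_components PCA components to extract (default 2).
#' @param threshold selection cutoff on the oriented PC1 score (default 0).
#' @return List with `selected` (residue codes), `scores` (tibble of
#'   residue, oriented PC scores, selected flag) and `pca` (the
#'   [fit_pca()] model).
#' @export
consensus_select <- function(summary, n_components = 2, threshold = 0) {
  if (nrow(summary) < 3) {
    stop("consensus selection needs at least 3 residues", call. = FALSE)
  }
  x <- as.matrix(summary[setdiff(names(summary), "residue")])
  rownames(x) <- summary$residue
  pca <- fit_pca(x, n_components = n_components, cv_groups = 0)
  load1 <- pca$loadings[, 1]
  fav <- ifelse(grepl("^frequency$", names(load1)), 1, -1)
  orient <- sign(sum(load1 * fav))
  if (orient == 0) orient <- 1
  pc1 <- pca$scores[, 1] * orient
  scores_tb <- tibble::tibble(
    residue = summary$residue,
    pc1 = unname(pc1),
    selected = unname(pc1 > threshold)
  )
  if (pca$n_components >= 2) scores_tb$pc2 <- unname(pca$scores[, 2])
  list(selected = scores_tb$residue[scores_tb$selected],
       scores = scores_tb, pca = pca, orientation = orient)
}
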