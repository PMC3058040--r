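#' Principal-property space for a residue set
#'
#' Compresses a physicochemical descriptor table into principal properties:
#' a PCA (on the mean-centered, unit-variance-scaled descriptors) whose
#' first few score vectors summarize the main variation in size,
#' hydrophobicity, flexibility etc. among the building blocks. The score
#' vectors are the coordinates later used for D-optimal selection.
#'
#' @param descriptors numeric matrix with residue codes as row names, or a
#'   `residue_set` carrying descriptor columns.
#' @param n_components number of principal properties to extract.
#' @param cv_groups passed to [fit_pca()] (0 skips cross-validation).
#' @return An object of class `pp_space`: the `pep_pca` model plus a
#'   `scores` tibble (`residue`, `PC1`, ..., `PCk`).
#' @export
build_pp_space <- function(descriptors, n_components = 4, cv_groups = 7) {
  if (inherits(descriptors, "residue_set")) {
    descriptors <- residue_descriptors(descriptors)
  }
  descriptors <- as.matrix(descriptors)
  if (is.null(rownames(descriptors))) {
    stop("descriptor matrix needs residue codes as row names", call. = FALSE)
  }
  if (anyNA(descriptors)) {
    bad <- rownames(descriptors)[apply(is.na(descriptors), 1, any)]
    stop("residue(s) with missing descriptors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_components <- min(n_components,
                      min(nrow(descriptors) - 1, ncol(descriptors)))
  pca <- fit_pca(descriptors, n_components = n_components,
                 cv_groups = cv_groups)
  scores <- tibble::as_tibble(pca$scores, rownames = "residue")
  structure(list(pca = pca, scores = scores,
                 n_components = n_components), class = "pp_space")
}

pp_lookup <- function(space, codes, k) {
  if (k > space$n_components) {
    stop("k (", k, ") exceeds the ", space$n_components,
         " fitted principal properties", call. = FALSE)
  }
  m <- as.matrix(space$scores[paste0("PC", seq_len(k))])
  rownames(m) <- space$scores$residue
  missing <- setdiff(codes, rownames(m))
  if (length(missing)) {
    stop("residue(s) absent from property space: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m[codes, , drop = FALSE]
}

#' Candidate model matrix for D-optimal peptide selection
#'
#' Enumerates the full factorial of the chosen residues at the two anchor
#' positions and builds the design model matrix: each candidate row is the
#' intercept followed by the first `k` principal-property scores of its
#' p260 residue and of its p263 residue (main effects only), giving 2k+1
#' columns.
#'
#' @param space_p260,space_p263 [build_pp_space()] objects for the two
#'   positions.
#' @param p260_set,p263_set residue codes to combine (default: every
#'   residue in the respective space).
#' @param k principal properties used per position (default 4).
#' @return An object of class `candidate_design`: `candidates` tibble
#'   (`id`, `p260`, `p263`), numeric `model_matrix` (rows named by id), and
#'   `k`.
#' @export
build_candidate_matrix <- function(space_p260, space_p263,
                                   p260_set = space_p260$scores$residue,
                                   p263_set = space_p263$scores$residue,
                                   k = 4) {
  candidates <- enumerate_library(p260_set, p263_set)
  s260 <- pp_lookup(space_p260, candidates$p260, k)
  s263 <- pp_lookup(space_p263, candidates$p263, k)
  x <- cbind(intercept = 1, s260, s263)
  colnames(x) <- c("intercept",
                   paste0("p260_PC", seq_len(k)),
                   paste0("p263_PC", seq_len(k)))
  rownames(x) <- candidates$id
  structure(list(candidates = candidates, model_matrix = x, k = k),
            class = "candidate_design")
}

logdet_info <- function(x, ridge) {
  m <- crossprod(x) + diag(ridge, ncol(x))
  as.numeric(determinant(m, logarithm = TRUE)$modulus)
}

#' D-optimal subset selection by Fedorov exchange
#'
#' Selects `n_select` candidate rows maximizing the determinant of the
#' information matrix X'X (plus a small ridge for numerical safety), so
#' that the chosen subset spans the property space as thoroughly as
#' possible. Classic single-point exchange: starting from a random subset,
#' the (remove, add) swap that most increases the log-determinant is applied
#' until no swap improves; the best of `n_starts` seeded random starts is
#' returned. Exchange ties are broken by candidate index, and the
#' determinant never decreases along the iteration trace.
#'
#' @param design a [build_candidate_matrix()] object (or any list with a
#'   numeric `model_matrix` and a `candidates` tibble).
#' @param n_select subset size; must be at least the number of model-matrix
#'   columns unless a larger `ridge` is supplied.
#' @param n_starts random restarts (default 20).
#' @param seed integer seed (mandatory).
#' @param ridge diagonal loading of X'X (default 1e-8).
#' @return The design with added elements: `selected` (candidate ids),
#'   `selected_idx`, `log_det`, and `trace` (per-iteration log-det of the
#'   winning start).
#' @export
fedorov_select <- function(design, n_select, n_starts = 20, seed,
                           ridge = 1e-8) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  x <- design$model_matrix
  n <- nrow(x)
  if (n_select > n) {
    stop("n_select (", n_select, ") exceeds the ", n, " candidates",
         call. = FALSE)
  }
  if (n_select < ncol(x) && ridge <= 1e-8) {
    stop("n_select below the number of model columns (", ncol(x),
         "); supply a larger ridge for a singular design", call. = FALSE)
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    sel <- sort(sample.int(n, n_select))
    ld <- logdet_info(x[sel, , drop = FALSE], ridge)
    trace <- ld
    repeat {
      out_pool <- setdiff(seq_len(n), sel)
      best_swap <- NULL
      best_ld <- ld
      for (i in sel) {
        for (j in out_pool) {
          cand <- c(setdiff(sel, i), j)
          ld_new <- logdet_info(x[cand, , drop = FALSE], ridge)
          # strict improvement beyond tolerance; ties resolved by the
          # (i, j) loop order, i.e. candidate index
          if (ld_new > best_ld + 1e-9) {
            best_ld <- ld_new
            best_swap <- c(i, j)
          }
        }
      }
      if (is.null(best_swap)) break
      sel <- sort(c(setdiff(sel, best_swap[1]), best_swap[2]))
      ld <- best_ld
      trace <- c(trace, ld)
    }
    if (is.null(best) || ld > best$log_det + 1e-12) {
      best <- list(sel = sel, log_det = ld, trace = trace)
    }
  }
  design$selected_idx <- best$sel
  design$selected <- design$candidates$id[best$sel]
  design$log_det <- best$log_det
  design$trace <- best$trace
  design$ridge <- ridge
  design
}

#' Level coverage of a selected peptide subset
#'
#' Checks that every candidate residue at each position occurs in at least
#' `min_count` of the selected peptides, the balance needed to estimate
#' per-residue effects in the downstream indicator-variable SAR model.
#'
#' @param selection tibble with `p260` and `p263` columns (e.g.
#'   `design$candidates[design$selected_idx, ]`).
#' @param p260_levels,p263_levels residue codes that must be covered.
#' @param min_count required occurrences per level (default 2).
#' @return List: `counts` tibble (`position`, `residue`, `count`, `ok`),
#'   `pass` (all levels covered), `failing` (labels of uncovered levels).
#' @export
coverage_check <- function(selection, p260_levels, p263_levels,
                           min_count = 2) {
  if (!nrow(selection)) stop("empty selection", call. = FALSE)
  n <- nrow(selection)
  for (lv in list(p260 = p260_levels, p263 = p263_levels)) {
    if (n < length(lv) * min_count) {
      stop("coverage infeasible: ", n, " peptides cannot contain ",
           length(lv), " levels ", min_count, " times each", call. = FALSE)
    }
  }
  count_pos <- function(values, levels, position) {
    tibble::tibble(
      position = position,
      residue = levels,
      count = vapply(levels, function(l) sum(values == l), integer(1))
    )
  }
  counts <- dplyr::bind_rows(
    count_pos(selection$p260, p260_levels, "p260"),
    count_pos(selection$p263, p263_levels, "p263")
  )
  counts$ok <- counts$count >= min_count
  list(counts = counts, pass = all(counts$ok),
       failing = paste(counts$position[!counts$ok],
                       counts$residue[!counts$ok], sep = "."))
}

#' Repair level coverage of a D-optimal selection
#'
#' Greedy post-pass (off by default in the pipeline; the original workflow
#' achieved balance without it): while some residue level occurs fewer than
#' `min_count` times, swap out a peptide from an over-represented
#' combination for an unselected candidate carrying a deficient level,
#' choosing at each step the swap that loses the least log-determinant
#' without pushing any covered level below `min_count`.
#'
#' @param design a [fedorov_select()] result.
#' @param p260_levels,p263_levels levels that must be covered.
#' @param min_count required occurrences per level.
#' @param max_iter safety bound on repair swaps.
#' @return The design with updated `selected`, `selected_idx`, `log_det`;
#'   element `repaired` counts the swaps applied.
#' @export
coverage_repair <- function(design, p260_levels, p263_levels,
                            min_count = 2, max_iter = 50) {
  x <- design$model_matrix
  cand <- design$candidates
  sel <- design$selected_idx
  ridge <- design$ridge %||% 1e-8
  n_swaps <- 0
  deficiency <- function(sel_idx) {
    cov <- coverage_check(cand[sel_idx, ], p260_levels, p263_levels,
                          min_count = min_count)
    sum(pmax(min_count - cov$counts$count, 0))
  }
  for (iter in seq_len(max_iter)) {
    cur_def <- deficiency(sel)
    if (cur_def == 0) break
    best <- NULL
    for (j in setdiff(seq_len(nrow(cand)), sel)) {
      for (i in sel) {
        new_sel <- sort(c(setdiff(sel, i), j))
        new_def <- deficiency(new_sel)
        if (new_def >= cur_def) next  # only strictly deficiency-reducing swaps
        ld <- logdet_info(x[new_sel, , drop = FALSE], ridge)
        if (is.null(best) || new_def < best$def ||
            (new_def == best$def && ld > best$ld + 1e-12)) {
          best <- list(sel = new_sel, ld = ld, def = new_def)
        }
      }
    }
    if (is.null(best)) {
      warning("coverage repair stalled; returning partially repaired design",
              call. = FALSE)
      break
    }
    sel <- best$sel
    n_swaps <- n_swaps + 1
  }
  design$selected_idx <- sel
  design$selected <- cand$id[sel]
  design$log_det <- logdet_info(x[sel, , drop = FALSE], ridge)
  design$repaired <- n_swaps
  design
}
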