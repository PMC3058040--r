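#' Build a pose record
#'
#' A pose is a tidy atom table: one row per atom with the residue index it
#' belongs to, the atom role (`"N"`, `"CA"`, `"C"`, `"O"`, or any side-chain
#' label), and Cartesian coordinates in Angstrom. Docked and energy-minimized
#' poses are distinguished by the `stage` attribute.
#'
#' @param resi integer residue indices.
#' @param role character atom roles.
#' @param x,y,z numeric coordinates (Angstrom).
#' @param peptide_id optional peptide identifier attached to every atom.
#' @param stage `"docked"` or `"minimized"`.
#' @return A tibble with class `pose`.
#' @export
pose <- function(resi, role, x, y, z, peptide_id = NA_character_,
                 stage = c("docked", "minimized")) {
  stage <- match.arg(stage)
  out <- tibble::tibble(
    peptide_id = rep_len(as.character(peptide_id), length(resi)),
    resi = as.integer(resi), role = as.character(role),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("pose coordinates must be finite", call. = FALSE)
  }
  attr(out, "stage") <- stage
  class(out) <- c("pose", class(out))
  out
}

as_pose <- function(df, stage = attr(df, "stage") %||% "docked") {
  pose(df$resi, df$role, df$x, df$y, df$z,
       peptide_id = df$peptide_id %||% NA_character_, stage = stage)
}

#' Truncate a pose to a residue range
#'
#' Docked peptides often vary most in backbone conformation at the
#' unmodified terminus; truncating to the varied fragment (residues 260-263
#' in the glycopeptide library) focuses RMSD filtering and rescoring on the
#' region that differs between library members.
#'
#' @param p a [pose()].
#' @param first,last closed residue-index interval to keep.
#' @return The pose restricted to residues in `[first, last]`.
#' @export
truncate_fragment <- function(p, first, last) {
  stopifnot(first <= last)
  rng <- range(p$resi)
  if (first < rng[1] || last > rng[2]) {
    stop("truncation interval [", first, ",", last,
         "] outside pose residue range [", rng[1], ",", rng[2], "]",
         call. = FALSE)
  }
  out <- dplyr::filter(p, .data$resi >= first, .data$resi <= last)
  if (!nrow(out)) stop("truncation left no atoms", call. = FALSE)
  as_pose(out)
}

#' Backbone RMSD between two poses
#'
#' Root-mean-square deviation over matched (residue index, atom role) pairs.
#' By default no superposition is applied: poses docked into one fixed
#' receptor frame are compared in place, so a rigid offset contributes fully
#' to the RMSD. With `superpose = TRUE` an optimal rigid-body (Kabsch)
#' superposition is applied first.
#'
#' @param p,reference poses sharing atoms for the requested roles.
#' @param roles atom roles entering the RMSD; default backbone `N`, `CA`,
#'   `C`.
#' @param superpose apply optimal rigid superposition before measuring.
#' @return RMSD in Angstrom (single non-negative number).
#' @export
#' @examples
#' ref <- pose(1:3, "CA", 0:2, 0, 0)
#' backbone_rmsd(ref, ref)                      # 0
backbone_rmsd <- function(p, reference, roles = c("N", "CA", "C"),
                          superpose = FALSE) {
  a <- match_backbone(p, roles)
  b <- match_backbone(reference, roles)
  key_a <- paste(a$resi, a$role)
  key_b <- paste(b$resi, b$role)
  missing_in_p <- setdiff(key_b, key_a)
  missing_in_ref <- setdiff(key_a, key_b)
  if (length(missing_in_p) || length(missing_in_ref)) {
    stop("atom mismatch between poses; missing in pose: [",
         paste(missing_in_p, collapse = "; "), "], missing in reference: [",
         paste(missing_in_ref, collapse = "; "), "]", call. = FALSE)
  }
  xa <- as.matrix(a[c("x", "y", "z")])[order(a$resi, a$role), , drop = FALSE]
  xb <- as.matrix(b[c("x", "y", "z")])[order(b$resi, b$role), , drop = FALSE]
  if (superpose) xa <- kabsch_fit(xa, xb)
  sqrt(mean(rowSums((xa - xb)^2)))
}

match_backbone <- function(p, roles) {
  out <- dplyr::filter(p, .data$role %in% roles)
  if (!nrow(out)) stop("pose has no atoms with the requested roles",
                       call. = FALSE)
  if (anyDuplicated(paste(out$resi, out$role))) {
    stop("duplicated (residue, role) atoms in pose", call. = FALSE)
  }
  out
}

# Kabsch: rotate+translate `moving` onto `target` (least-squares).
kabsch_fit <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  a <- sweep(moving, 2, cm); b <- sweep(target, 2, ct)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(a %*% t(rot), 2, ct, `+`)
}

#' Two-stage geometric culling of docked poses
#'
#' Stage 1 keeps peptides whose docked pose lies within `pre_threshold` of
#' the reference backbone; those survivors are expected to have been
#' energy-minimized externally, and stage 2 keeps peptides whose minimized
#' pose lies within `post_threshold`. Both comparisons are strict
#' (`RMSD < threshold`): poses exactly at a threshold are culled.
#'
#' @param docked named list of docked poses (names = peptide ids).
#' @param minimized named list of minimized poses for stage-1 survivors. May
#'   be `NULL` when `reuse_docked = TRUE`, in which case docked coordinates
#'   are reused for stage 2.
#' @param reference the reference [pose()].
#' @param pre_threshold,post_threshold stage cutoffs in Angstrom.
#' @param roles,superpose passed to [backbone_rmsd()].
#' @param reuse_docked fall back to the docked pose when a stage-1 survivor
#'   has no minimized pose (default `FALSE`: that situation is an error).
#' @return A tibble with one row per input peptide: `peptide_id`,
#'   `rmsd_docked`, `rmsd_minimized` (NA for peptides culled at stage 1),
#'   `stage1`, `stage2` (logical), `survives`.
#' @export
two_stage_filter <- function(docked, minimized = NULL, reference,
                             pre_threshold = 3.0, post_threshold = 1.5,
                             roles = c("N", "CA", "C"), superpose = FALSE,
                             reuse_docked = FALSE) {
  stopifnot(is.list(docked), !is.null(names(docked)))
  rmsd1 <- vapply(docked, backbone_rmsd, numeric(1), reference = reference,
                  roles = roles, superpose = superpose)
  stage1 <- rmsd1 < pre_threshold
  rmsd2 <- rep(NA_real_, length(docked))
  names(rmsd2) <- names(docked)
  for (id in names(docked)[stage1]) {
    min_pose <- minimized[[id]]
    if (is.null(min_pose)) {
      if (!reuse_docked) {
        stop("stage-1 survivor '", id, "' has no minimized pose ",
             "(set reuse_docked = TRUE to fall back to docked coordinates)",
             call. = FALSE)
      }
      min_pose <- docked[[id]]
    }
    rmsd2[id] <- backbone_rmsd(min_pose, reference, roles = roles,
                               superpose = superpose)
  }
  stage2 <- !is.na(rmsd2) & rmsd2 < post_threshold
  tibble::tibble(
    peptide_id = names(docked),
    rmsd_docked = unname(rmsd1),
    rmsd_minimized = unname(rmsd2),
    stage1 = unname(stage1),
    stage2 = unname(stage2),
    survives = unname(stage1 & stage2)
  )
}

#' Read peptide poses from a PDB file
#'
#' One pose per MODEL record (or a single pose for single-model files).
#' Requires the suggested \pkg{bio3d} package.
#'
#' @param path PDB file path.
#' @param stage stage tag attached to each pose.
#' @return A named list of [pose()] objects (`model_1`, `model_2`, ...).
#' @export
read_pdb_poses <- function(path, stage = "docked") {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB poses requires the 'bio3d' package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  poses <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    pose(at$resno, at$elety, xyz[, 1], xyz[, 2], xyz[, 3], stage = stage)
  })
  names(poses) <- paste0("model_", seq_len(n_models))
  poses
}
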