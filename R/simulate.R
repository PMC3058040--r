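#' Reference backbone pose for simulations
#'
#' An idealized extended backbone (N, CA, C atoms per residue at roughly
#' peptide-like spacing along x) used as the reference frame for simulated
#' docking poses.
#'
#' @param n_res number of residues.
#' @param first_resi index of the first residue (default 260, matching the
#'   glycopeptide numbering).
#' @return A [pose()].
#' @export
reference_pose <- function(n_res = 8, first_resi = 260) {
  resi <- rep(first_resi + seq_len(n_res) - 1, each = 3)
  role <- rep(c("N", "CA", "C"), n_res)
  i <- rep(seq_len(n_res) - 1, each = 3)
  dx <- rep(c(-1.2, 0, 1.2), n_res)
  dy <- rep(c(0.5, 0, 0.5), n_res) * rep_len(c(1, -1), n_res)[i + 1]
  pose(resi, role, 3.8 * i + dx, dy, 0)
}

#' Simulate a multi-function docking score table
#'
#' Each peptide's score under every scoring function is the sum of latent
#' per-residue affinity contributions of its two anchors plus
#' function-correlated Gaussian noise: the noise of observation i under
#' function f is `sqrt(rho) * common_i + sqrt(1-rho) * eps_if`, giving an
#' inter-function correlation of `rho`. Scores are oriented so lower is
#' better. The drawn latent contributions are returned as ground truth for
#' recovery tests.
#'
#' @param p260_set,p263_set residue codes.
#' @param n_functions number of scoring functions (default 7).
#' @param latent_sd SD of the per-residue latent contributions.
#' @param noise_sd SD of the per-function scoring noise.
#' @param rho inter-function noise correlation, in `[0, 1)`.
#' @param planted named numeric vectors `list(p260 =, p263 =)` of latent
#'   offsets added to specific residues (negative = advantage).
#' @param seed integer seed (mandatory).
#' @return List: `scores` tibble (`peptide_id` + one column per function),
#'   `peptides` ([enumerate_library()] tibble), `latent` tibble
#'   (`position`, `residue`, `latent`).
#' @export
gen_score_table <- function(p260_set, p263_set, n_functions = 7,
                            latent_sd = 1, noise_sd = 0.5, rho = 0.5,
                            planted = list(), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(rho >= 0, rho < 1, noise_sd >= 0, latent_sd >= 0)
  set.seed(seed)
  draw_latent <- function(codes, position) {
    lat <- stats::rnorm(length(codes), sd = latent_sd)
    names(lat) <- codes
    extra <- planted[[position]]
    if (!is.null(extra)) lat[names(extra)] <- lat[names(extra)] + extra
    lat
  }
  lat260 <- draw_latent(p260_set, "p260")
  lat263 <- draw_latent(p263_set, "p263")
  peptides <- enumerate_library(p260_set, p263_set)
  n <- nrow(peptides)
  base <- lat260[peptides$p260] + lat263[peptides$p263]
  common <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * n_functions), n, n_functions)
  noise <- noise_sd * (sqrt(rho) * common + sqrt(1 - rho) * eps)
  scores <- base + noise
  colnames(scores) <- paste0("fn", seq_len(n_functions))
  list(
    scores = dplyr::bind_cols(tibble::tibble(peptide_id = peptides$id),
                              tibble::as_tibble(scores)),
    peptides = peptides,
    latent = dplyr::bind_rows(
      tibble::tibble(position = "p260", residue = names(lat260),
                     latent = unname(lat260)),
      tibble::tibble(position = "p263", residue = names(lat263),
                     latent = unname(lat263))
    )
  )
}

#' Simulate a low-rank molecular descriptor table
#'
#' Descriptors follow a latent factor model `X = L W' + noise`: each
#' residue has `latent_rank` latent property values, each descriptor loads
#' on them, and independent Gaussian noise is added. The latent rank is
#' recoverable by PCA when the noise is small.
#'
#' @param n_residues,n_descriptors table dimensions.
#' @param latent_rank number of latent factors (must not exceed
#'   `n_descriptors`).
#' @param noise_sd SD of the added noise.
#' @param scale SD of the latent factor scores.
#' @param seed integer seed (mandatory).
#' @return Numeric matrix with rows `R1..Rn` and columns `D1..Dk`.
#' @export
gen_descriptor_table <- function(n_residues, n_descriptors, latent_rank,
                                 noise_sd = 0.1, scale = 1, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(latent_rank <= n_descriptors)
  set.seed(seed)
  l <- matrix(stats::rnorm(n_residues * latent_rank, sd = scale),
              n_residues, latent_rank)
  w <- matrix(stats::rnorm(n_descriptors * latent_rank),
              n_descriptors, latent_rank)
  x <- l %*% t(w) +
    matrix(stats::rnorm(n_residues * n_descriptors, sd = noise_sd),
           n_residues, n_descriptors)
  dimnames(x) <- list(paste0("R", seq_len(n_residues)),
                      paste0("D", seq_len(n_descriptors)))
  x
}

#' Simulate docked poses around a reference
#'
#' Perturbs every atom of the reference independently by Gaussian noise of
#' the given per-coordinate SD (expected RMSD approaches `sd * sqrt(3)` for
#' many atoms), or applies a fixed rigid translation. The exact RMSD of
#' each generated pose to the reference is returned.
#'
#' @param reference a [pose()].
#' @param n number of poses.
#' @param perturbation_sd per-coordinate Gaussian SD (Angstrom); recycled
#'   over poses, so a vector gives each pose its own perturbation level.
#' @param translation optional length-3 vector; when given, pose i is the
#'   reference translated by `i * translation` and no noise is added.
#' @param seed integer seed (mandatory unless `translation` is given).
#' @param stage stage tag for the generated poses.
#' @return List: `poses` (named list `pose_1..pose_n`), `rmsd` tibble
#'   (`peptide_id`, `rmsd`).
#' @export
gen_poses <- function(reference, n, perturbation_sd = 0.5,
                      translation = NULL, seed, stage = "docked") {
  stopifnot(all(perturbation_sd >= 0))
  if (is.null(translation)) {
    if (missing(seed)) stop("a seed is required", call. = FALSE)
    set.seed(seed)
  }
  sds <- rep_len(perturbation_sd, n)
  m <- nrow(reference)
  poses <- lapply(seq_len(n), function(i) {
    if (!is.null(translation)) {
      shift <- matrix(rep(i * translation, each = m), m, 3)
    } else {
      shift <- matrix(stats::rnorm(3 * m, sd = sds[i]), m, 3)
    }
    pose(reference$resi, reference$role,
         reference$x + shift[, 1], reference$y + shift[, 2],
         reference$z + shift[, 3],
         peptide_id = paste0("pose_", i), stage = stage)
  })
  names(poses) <- paste0("pose_", seq_len(n))
  rmsd <- vapply(poses, backbone_rmsd, numeric(1), reference = reference,
                 roles = unique(reference$role))
  list(poses = poses,
       rmsd = tibble::tibble(peptide_id = names(poses),
                             rmsd = unname(rmsd)))
}

#' Simulate binding responses from an indicator design
#'
#' Generates `y = intercept + X beta + eps` with Gaussian noise, clipped to
#' the percent-inhibition range `[0, 100]` (the clipping is a deliberate
#' deviation from pure linearity, mirroring the bounded assay readout).
#'
#' @param x indicator (or any numeric) design matrix.
#' @param beta coefficient vector, one entry per column of `x`.
#' @param noise_sd response noise SD.
#' @param intercept baseline response (default 50, mid-range).
#' @param clip clip range; `NULL` disables clipping.
#' @param seed integer seed (mandatory).
#' @return List: `y` numeric response vector, `beta` the ground truth.
#' @export
gen_binding_responses <- function(x, beta, noise_sd = 5, intercept = 50,
                                  clip = c(0, 100), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  x <- as.matrix(x)
  stopifnot(length(beta) == ncol(x))
  set.seed(seed)
  y <- intercept + as.numeric(x %*% beta) +
    stats::rnorm(nrow(x), sd = noise_sd)
  if (!is.null(clip)) y <- pmin(pmax(y, clip[1]), clip[2])
  list(y = y, beta = beta)
}
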