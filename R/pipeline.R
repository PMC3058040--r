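#' Default pipeline configuration
#'
#' Collects every tunable of the design pipeline with its default: the
#' two-stage RMSD thresholds (3.0 / 1.5 Angstrom, strict), the number of
#' principal properties per position used in the D-optimal model matrix
#' (k = 4), the selection size (20 peptides), Fedorov restarts, the number
#' of permutations for PLS validation (100), and the synthetic-data sizes
#' used when no external docking output is supplied.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param ... overrides of any default element.
#' @return A named list with class `pepsmd_config`.
#' @export
pipeline_config <- function(seed, ...) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    pre_threshold = 3.0, post_threshold = 1.5,
    rmsd_roles = c("N", "CA", "C"),
    n_residues_per_position = 12,
    n_functions = 7,
    latent_sd = 1, score_noise_sd = 0.5, score_rho = 0.5,
    n_descriptors = 20, descriptor_rank = 4, descriptor_noise_sd = 0.3,
    pp_k = 4, n_select = 20, n_starts = 20, ridge = 1e-8,
    min_count = 2,
    response_noise_sd = 5, n_perm = 100,
    pose_sd = 1.0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("pepsmd_config", "list"))
}

#' Run the design pipeline end-to-end on synthetic inputs
#'
#' Exercises every stage with internally generated data: simulated docked
#' poses are culled by the two-stage RMSD filter; simulated score tables
#' are collapsed to per-position consensus summaries and residues selected
#' by PCA; principal-property spaces are built from simulated descriptors
#' and a D-optimal subset chosen by Fedorov exchange; simulated binding
#' responses for the selected peptides are modelled by indicator-variable
#' PLS with permutation validation; and the response panel fixture is
#' analysed by combined-response PCA. Each stage's output is returned, and
#' a rerun with the same config is reproducible.
#'
#' @param config a [pipeline_config()].
#' @return Named list of stage outputs (`filter`, `consensus_p260`,
#'   `consensus_p263`, `design`, `coverage`, `pls`, `permutation`,
#'   `response`), plus `config`.
#' @export
run_pipeline <- function(config = pipeline_config(seed = 1)) {
  seed <- config$seed
  n_res <- config$n_residues_per_position
  p260_set <- paste0("a", seq_len(n_res))
  p263_set <- paste0("b", seq_len(n_res))

  # stage 2 data first: the score table defines the peptide cohort
  sim_scores <- gen_score_table(
    p260_set, p263_set, n_functions = config$n_functions,
    latent_sd = config$latent_sd, noise_sd = config$score_noise_sd,
    rho = config$score_rho, seed = seed + 1)
  peptides <- sim_scores$peptides

  # stage 1: one docked pose per peptide, perturbation level varying
  # across peptides so the geometric cull separates the cohort
  ref <- reference_pose()
  set.seed(seed)
  pose_sds <- stats::runif(nrow(peptides), 0, config$pose_sd * 2)
  sim_poses <- gen_poses(ref, n = nrow(peptides),
                         perturbation_sd = pose_sds, seed = seed)
  names(sim_poses$poses) <- peptides$id
  filter_report <- two_stage_filter(
    sim_poses$poses, minimized = sim_poses$poses, reference = ref,
    pre_threshold = config$pre_threshold,
    post_threshold = config$post_threshold, roles = config$rmsd_roles)

  # stage 2: consensus scoring of the geometric survivors
  surviving <- filter_report$peptide_id[filter_report$survives]
  culled_scores <- dplyr::filter(sim_scores$scores,
                                 .data$peptide_id %in% surviving)
  consensus <- lapply(c(p260 = "p260", p263 = "p263"), function(pos) {
    sm <- summarize_position(culled_scores, peptides, pos)
    consensus_select(sm)
  })
  top7 <- function(cs) {
    ord <- dplyr::arrange(cs$scores, dplyr::desc(.data$pc1))
    utils::head(ord$residue, 7)
  }
  sel260 <- top7(consensus$p260)
  sel263 <- top7(consensus$p263)

  # stage 3: principal properties + D-optimal selection
  desc260 <- gen_descriptor_table(length(sel260), config$n_descriptors,
                                  config$descriptor_rank,
                                  config$descriptor_noise_sd,
                                  seed = seed + 2)
  desc263 <- gen_descriptor_table(length(sel263), config$n_descriptors,
                                  config$descriptor_rank,
                                  config$descriptor_noise_sd,
                                  seed = seed + 3)
  rownames(desc260) <- sel260
  rownames(desc263) <- sel263
  space260 <- build_pp_space(desc260, n_components = config$pp_k)
  space263 <- build_pp_space(desc263, n_components = config$pp_k)
  design <- build_candidate_matrix(space260, space263, k = config$pp_k)
  design <- fedorov_select(design, n_select = config$n_select,
                           n_starts = config$n_starts, seed = seed + 4,
                           ridge = config$ridge)
  selection <- design$candidates[design$selected_idx, ]
  coverage <- coverage_check(selection, sel260, sel263,
                             min_count = config$min_count)

  # stage 4: indicator PLS SAR on simulated responses
  x <- encode_indicators(selection)
  beta <- stats::rnorm(ncol(x), sd = 10)
  resp <- gen_binding_responses(x, beta,
                                noise_sd = config$response_noise_sd,
                                seed = seed + 5)
  pls <- fit_pls(x, resp$y, n_lv = 2)
  permutation <- permutation_test(x, resp$y, n_lv = 2,
                                  n_perm = config$n_perm, seed = seed + 6)

  # stage 5: combined-response PCA on the shipped panel
  response <- response_pca(response_panel())

  list(filter = filter_report,
       consensus_p260 = consensus$p260, consensus_p263 = consensus$p263,
       design = design, coverage = coverage,
       pls = pls, permutation = permutation,
       response = response, config = config)
}

#' Write a stage table with a provenance header
#'
#' TSV writer used for pipeline outputs: prepends comment lines recording
#' the package version, the seed, and a hash of the resolved configuration,
#' so any output file identifies the run that produced it.
#'
#' @param x data frame to write.
#' @param path output file.
#' @param config the run's [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, config) {
  header <- c(
    paste0("# pepsmd ", as.character(utils::packageVersion("pepsmd"))),
    paste0("# seed: ", config$seed),
    paste0("# config_hash: ", rlang::hash(unclass(config)))
  )
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a stage table written by [write_stage_tsv()]
#'
#' @param path file path.
#' @return Tibble (header comment lines are skipped).
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
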