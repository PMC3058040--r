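test_that("score orientation negates named columns and is an involution", {
  tb <- tibble::tibble(peptide_id = c("a", "b"), Goldscore = c(50, 30),
                       Chemscore = c(-1, -2))
  flipped <- orient_scores(tb, "Goldscore")
  expect_equal(flipped$Goldscore, c(-50, -30))
  expect_equal(flipped$Chemscore, tb$Chemscore)
  expect_equal(orient_scores(flipped, "Goldscore"), tb)
  expect_equal(orient_scores(tb, character(0)), tb)
  expect_error(orient_scores(tb, "Nope"), "unknown scoring function")
})

test_that("position summary reproduces the worked three-peptide example", {
  peptides <- tibble::tibble(id = c("A_X", "A_Y", "B_X"),
                             p260 = c("A", "A", "B"),
                             p263 = c("X", "Y", "X"))
  scores <- tibble::tibble(peptide_id = peptides$id, fn1 = c(1, 3, 2))
  sm <- summarize_position(scores, peptides, "p260")
  expect_equal(sm$residue, c("A", "B"))
  expect_equal(sm$frequency, c(2L, 1L))
  expect_equal(sm$fn1_best, c(1, 2))
  expect_equal(sm$fn1_mean, c(2, 2))
  expect_equal(sm$fn1_sd, c(sqrt(2), 0), tolerance = 1e-12)

  single <- summarize_position(scores[1, ], peptides, "p263")
  expect_equal(single$frequency, 1L)
  expect_equal(single$fn1_best, single$fn1_mean)
  expect_equal(single$fn1_sd, 0)
})

test_that("with 7 functions the summary carries 22 parameters per residue", {
  sim <- gen_score_table(paste0("a", 1:4), paste0("b", 1:4),
                         n_functions = 7, seed = 1)
  sm <- summarize_position(sim$scores, sim$peptides, "p260")
  expect_equal(ncol(sm) - 1, 22)  # residue code column + 22 parameters
  expect_equal(sum(sm$frequency), nrow(sim$scores))
})

test_that("summary statistics match a brute-force group-by oracle", {
  set.seed(99)
  for (rep in 1:3) {
    n260 <- sample(5:12, 1); n263 <- sample(5:12, 1)
    sim <- gen_score_table(paste0("a", 1:n260), paste0("b", 1:n263),
                           n_functions = 3, seed = rep)
    keep <- sample(nrow(sim$scores), min(400, nrow(sim$scores)))
    culled <- sim$scores[keep, ]
    for (pos in c("p260", "p263")) {
      sm <- summarize_position(culled, sim$peptides, pos)
      oracle <- brute_position_summary(as.data.frame(culled),
                                       as.data.frame(sim$peptides), pos)
      expect_equal(as.data.frame(sm), oracle, tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(sum(sm$frequency), nrow(culled))
    }
  }
})

test_that("empty or unmapped score tables error", {
  peptides <- tibble::tibble(id = "A_X", p260 = "A", p263 = "X")
  expect_error(summarize_position(tibble::tibble(peptide_id = character(0),
                                                 fn1 = numeric(0)),
                                  peptides, "p260"), "empty")
  expect_error(summarize_position(tibble::tibble(peptide_id = "zzz", fn1 = 1),
                                  peptides, "p260"), "without a peptide")
})

test_that("a residue dominating all parameters is selected", {
  set.seed(4)
  n_res <- 8
  sm <- tibble::tibble(residue = paste0("r", seq_len(n_res)))
  for (f in paste0("fn", 1:7)) {
    base <- rnorm(n_res, 0, 0.3)
    sm[[paste0(f, "_best")]] <- base - c(3, rep(0, n_res - 1))
    sm[[paste0(f, "_mean")]] <- base - c(3, rep(0, n_res - 1)) + 0.5
    sm[[paste0(f, "_sd")]] <- abs(rnorm(n_res, 1, 0.2)) +
      c(-0.5, rep(0, n_res - 1))
  }
  sm <- dplyr::mutate(sm, frequency = c(30, sample(5:15, n_res - 1,
                                                   replace = TRUE)),
                      .after = "residue")
  sel <- consensus_select(sm)
  expect_true("r1" %in% sel$selected)
  expect_equal(sel$scores$residue[which.max(sel$scores$pc1)], "r1")
})

test_that("degenerate consensus inputs error", {
  sm <- tibble::tibble(residue = c("a", "b", "c"), frequency = 2,
                       fn1_best = 1, fn1_mean = 1.5, fn1_sd = 0.1)
  expect_error(suppressWarnings(consensus_select(sm)), "constant")
  expect_error(consensus_select(sm[1:2, ]), "at least 3")
})

test_that("planted latent advantage is recovered by consensus selection", {
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    sim <- gen_score_table(paste0("a", 1:8), paste0("b", 1:8),
                           n_functions = 7, latent_sd = 0.25,
                           noise_sd = 0.5, rho = 0.5,
                           planted = list(p260 = c(a1 = -1.0)),
                           seed = 1000 + r)
    sm <- suppressWarnings(
      summarize_position(sim$scores, sim$peptides, "p260"))
    sel <- suppressWarnings(consensus_select(sm))
    if ("a1" %in% sel$selected) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
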