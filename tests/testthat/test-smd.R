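test_that("principal-property space attaches score vectors per residue", {
  d <- gen_descriptor_table(10, 8, 3, seed = 2)
  sp <- build_pp_space(d, n_components = 4)
  expect_equal(sp$scores$residue, rownames(d))
  expect_equal(ncol(sp$scores) - 1, 4)

  # rank bound: 3 residues x 2 descriptors -> at most 2 components
  small <- build_pp_space(matrix(rnorm(6), 3, 2,
                                 dimnames = list(c("a", "b", "c"), NULL)),
                          n_components = 4, cv_groups = 0)
  expect_equal(small$n_components, 2)

  dd <- d
  dd[2, 3] <- NA
  expect_error(build_pp_space(dd, 2), "missing descriptors")
})

test_that("duplicated descriptor columns leave the pp space unchanged", {
  d <- gen_descriptor_table(9, 5, 2, seed = 6)
  sp1 <- build_pp_space(d, 2, cv_groups = 0)
  sp2 <- build_pp_space(cbind(d, d), 2, cv_groups = 0)
  # same directions up to component sign (scores scale with column count)
  for (pc in c("PC1", "PC2")) {
    expect_equal(abs(cor(sp1$scores[[pc]], sp2$scores[[pc]])), 1,
                 tolerance = 1e-10)
  }
})

test_that("candidate matrix concatenates intercept and per-anchor scores", {
  d260 <- gen_descriptor_table(7, 10, 3, seed = 3)
  d263 <- gen_descriptor_table(7, 10, 3, seed = 4)
  sp260 <- build_pp_space(d260, 4, cv_groups = 0)
  sp263 <- build_pp_space(d263, 4, cv_groups = 0)
  cd <- build_candidate_matrix(sp260, sp263, k = 4)
  expect_equal(dim(cd$model_matrix), c(49, 9))
  expect_true(all(cd$model_matrix[, 1] == 1))

  # element-wise lookup oracle on a random candidate row
  i <- 17
  p260 <- cd$candidates$p260[i]; p263 <- cd$candidates$p263[i]
  s260 <- as.matrix(sp260$scores[sp260$scores$residue == p260, -1])
  s263 <- as.matrix(sp263$scores[sp263$scores$residue == p263, -1])
  expect_equal(unname(cd$model_matrix[i, -1]), c(s260, s263))

  cd2 <- build_candidate_matrix(sp260, sp263,
                                p260_set = rownames(d260)[1:2],
                                p263_set = rownames(d263)[1:2], k = 1)
  expect_equal(dim(cd2$model_matrix), c(4, 3))
  expect_error(build_candidate_matrix(sp260, sp263, k = 5), "exceeds")
})

test_that("selecting all candidates returns the full-matrix determinant", {
  d <- gen_descriptor_table(4, 6, 2, seed = 5)
  sp <- build_pp_space(d, 2, cv_groups = 0)
  cd <- build_candidate_matrix(sp, sp, k = 2)
  sel <- fedorov_select(cd, n_select = nrow(cd$candidates), n_starts = 2,
                        seed = 1)
  expect_setequal(sel$selected, cd$candidates$id)
  full_ld <- as.numeric(determinant(crossprod(cd$model_matrix) +
                                      diag(1e-8,
                                           ncol(cd$model_matrix)))$modulus)
  expect_equal(sel$log_det, full_ld, tolerance = 1e-10)
})

test_that("fedorov exchange matches exhaustive search on small instances", {
  set.seed(17)
  for (rep in 1:10) {
    n_cand <- sample(6:10, 1)
    p <- sample(2:3, 1)
    x <- cbind(1, matrix(rnorm(n_cand * p), n_cand, p))
    rownames(x) <- paste0("c", seq_len(n_cand))
    design <- list(model_matrix = x,
                   candidates = tibble::tibble(id = rownames(x)))
    n_sel <- sample((p + 1):5, 1)
    got <- fedorov_select(design, n_sel, n_starts = 10, seed = rep)
    oracle <- brute_doptimal(x, n_sel)
    expect_equal(got$log_det, oracle$log_det, tolerance = 1e-8)
  }
})

test_that("exchange trace is monotone and runs are seed-reproducible", {
  d <- gen_descriptor_table(7, 10, 4, seed = 9)
  sp <- build_pp_space(d, 4, cv_groups = 0)
  cd <- build_candidate_matrix(sp, sp, k = 4)
  s1 <- fedorov_select(cd, 20, n_starts = 5, seed = 42)
  s2 <- fedorov_select(cd, 20, n_starts = 5, seed = 42)
  expect_true(all(diff(s1$trace) >= 0))
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$log_det, s2$log_det)

  # determinant is invariant under candidate reordering
  perm <- sample(nrow(cd$model_matrix))
  cd_perm <- cd
  cd_perm$model_matrix <- cd$model_matrix[perm, ]
  cd_perm$candidates <- cd$candidates[perm, ]
  s3 <- fedorov_select(cd_perm, 20, n_starts = 5, seed = 42)
  expect_equal(s3$log_det, s1$log_det, tolerance = 1e-6)

  expect_error(fedorov_select(cd, 100, seed = 1), "exceeds")
  expect_error(fedorov_select(cd, 5, seed = 1), "ridge")
})

test_that("coverage is counted per level and infeasibility errors", {
  sel <- tibble::tibble(p260 = c("A", "A", "B", "B", "C"),
                        p263 = c("X", "Y", "X", "Y", "X"))
  cc <- coverage_check(sel, c("A", "B"), c("X", "Y"))
  expect_true(cc$pass)
  sel6 <- dplyr::bind_rows(sel, tibble::tibble(p260 = "A", p263 = "Y"))
  cc2 <- coverage_check(sel6, c("A", "B", "C"), c("X", "Y"))
  expect_false(cc2$pass)
  expect_equal(cc2$failing, "p260.C")
  expect_error(coverage_check(sel, c("A", "B", "C"), c("X", "Y")),
               "infeasible")
})

test_that("design-scale coverage (20 over 7+7, min 2) is feasible", {
  lib <- enumerate_library(paste0("a", 1:7), paste0("b", 1:7))
  expect_no_error(coverage_check(lib[1:20, ], paste0("a", 1:7),
                                 paste0("b", 1:7), min_count = 2))
})

test_that("coverage repair fills deficient levels with little log-det loss", {
  d260 <- gen_descriptor_table(7, 10, 4, seed = 13)
  d263 <- gen_descriptor_table(7, 10, 4, seed = 14)
  sp260 <- build_pp_space(d260, 4, cv_groups = 0)
  sp263 <- build_pp_space(d263, 4, cv_groups = 0)
  cd <- build_candidate_matrix(sp260, sp263, k = 4)
  sel <- fedorov_select(cd, 20, n_starts = 10, seed = 3)
  rep <- coverage_repair(sel, rownames(d260), rownames(d263), min_count = 2)
  cc <- coverage_check(rep$candidates[rep$selected_idx, ],
                       rownames(d260), rownames(d263), min_count = 2)
  expect_true(cc$pass)
  expect_lte(rep$log_det, sel$log_det + 1e-9)
})
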