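# Independent brute-force oracles used across test files.

# RMSD by direct per-atom arithmetic over explicitly paired coordinates.
brute_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  total <- 0
  for (i in seq_len(nrow(a))) {
    total <- total + (a$x[i] - b$x[i])^2 + (a$y[i] - b$y[i])^2 +
      (a$z[i] - b$z[i])^2
  }
  sqrt(total / nrow(a))
}

# Group-by summary via split() + loops, independent of the dplyr path.
brute_position_summary <- function(scores, peptides, position) {
  fn_cols <- setdiff(names(scores), "peptide_id")
  res <- peptides[[position]][match(scores$peptide_id, peptides$id)]
  out <- list()
  for (r in sort(unique(res))) {
    rows <- scores[res == r, fn_cols, drop = FALSE]
    rec <- list(residue = r, frequency = nrow(rows))
    for (f in fn_cols) {
      v <- rows[[f]]
      rec[[paste0(f, "_best")]] <- min(v)
      rec[[paste0(f, "_mean")]] <- mean(v)
      rec[[paste0(f, "_sd")]] <- if (length(v) > 1) stats::sd(v) else 0
    }
    out[[r]] <- as.data.frame(rec)
  }
  do.call(rbind, out)
}

# Exhaustive D-optimal search over all subsets.
brute_doptimal <- function(x, n_select, ridge = 1e-8) {
  combos <- utils::combn(nrow(x), n_select)
  lds <- apply(combos, 2, function(idx) {
    as.numeric(determinant(crossprod(x[idx, , drop = FALSE]) +
                             diag(ridge, ncol(x)),
                           logarithm = TRUE)$modulus)
  })
  list(log_det = max(lds), idx = sort(combos[, which.max(lds)]))
}

# Tiny toy pose pair with hand-listed coordinates.
toy_pose_pair <- function() {
  a <- pose(resi = c(1, 1, 2, 2), role = c("N", "CA", "N", "CA"),
            x = c(0, 1, 2, 3), y = c(0, 0, 1, 1), z = c(0, 0, 0, 0))
  b <- pose(resi = c(1, 1, 2, 2), role = c("N", "CA", "N", "CA"),
            x = c(0, 1, 2, 4), y = c(0, 1, 1, 1), z = c(0, 0, 2, 0))
  list(a = a, b = b)
}
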