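# Shared fixture builders; all data is generated in code.

# Balanced +1/-1 genotype matrix on a widely spaced map (markers are
# effectively unlinked unless spacing is made small).
toy_genotypes <- function(n = 40, p = 6, spacing = 200, seed = 1, chr = 1L) {
  set.seed(seed)
  codes <- matrix(sample(c(-1L, 1L), n * p, replace = TRUE), n, p)
  mk <- tibble::tibble(
    marker = sprintf("M%02d", seq_len(p)),
    chr = chr,
    pos_cM = (seq_len(p) - 1) * spacing,
    allele_high = "A", allele_low = "B"
  )
  genotype_matrix(codes, mk)
}

# Long-format phenotypes from a linear signal plus noise.
toy_phenotypes <- function(G, beta = NULL, H = 2, sd = 1, seed = 2, mu = 10,
                           env_effects = NULL) {
  set.seed(seed)
  n <- nrow(G)
  if (is.null(beta)) beta <- rep(0, ncol(G))
  if (is.null(env_effects)) env_effects <- seq_len(H) - mean(seq_len(H))
  g <- as.numeric(unclass(G) %*% beta)
  tibble::tibble(
    line = rep(line_ids(G), times = H),
    env = rep(seq_len(H), each = n),
    value = mu + rep(env_effects, each = n) + rep(g, times = H) +
      rnorm(n * H, 0, sd)
  )
}

# The fold assignment gmdr_screen() derives from a seed.
screen_folds <- function(n, k_folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k_folds), n))
}

# Independent straight-loop implementation of the cross-validated
# balanced-accuracy evaluation, used as the brute-force oracle for the
# GMDR search.
oracle_combo_accuracy <- function(G, scores, folds, combo) {
  g <- unclass(G)[, combo, drop = FALSE]
  cell <- apply(g, 1, paste, collapse = "/")
  k <- max(folds)
  accs <- c()
  for (f in seq_len(k)) {
    tr <- folds != f
    sums <- tapply(scores[tr], cell[tr], sum)
    tp <- fn <- tn <- fp <- 0
    for (i in which(!tr)) {
      s <- sums[cell[i]]
      if (is.na(s) || abs(s) <= 1e-12) next
      pred_high <- s > 0
      pos <- scores[i] > 0
      if (pos && pred_high) tp <- tp + 1
      if (pos && !pred_high) fn <- fn + 1
      if (!pos && !pred_high) tn <- tn + 1
      if (!pos && pred_high) fp <- fp + 1
    }
    parts <- c(
      if (tp + fn > 0) tp / (tp + fn),
      if (tn + fp > 0) tn / (tn + fp)
    )
    if (length(parts)) accs <- c(accs, mean(parts))
  }
  if (length(accs)) mean(accs) else NA_real_
}
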