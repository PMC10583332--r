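# Shared fixtures: small cohort configurations used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A CU-only normative cohort (single A-T- cell) of size n.
normative_only_config <- function(n, seed = 1L, ...) {
  npg <- matrix(0L, 3, 4, dimnames = list(c("CU", "MCI", "AD"), at_levels()))
  npg["CU", "A-T-"] <- as.integer(n)
  cohort_config(n_per_group = npg, seed = seed, ...)
}

# A small mixed cohort exercising all diagnosis and A/T cells.
small_mixed_config <- function(seed = 1L, ...) {
  npg <- matrix(
    c(60L, 8L, 8L, 0L,
      0L, 1L, 3L, 0L,
      0L, 1L, 2L, 0L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("CU", "MCI", "AD"), at_levels())
  )
  cohort_config(n_per_group = npg, seed = seed, ...)
}

# Independent brute-force oracle for Cliff's delta (pair enumeration).
brute_cliffs_delta <- function(x, y) {
  wins <- 0L
  losses <- 0L
  for (a in x) for (b in y) {
    if (a > b) wins <- wins + 1L else if (a < b) losses <- losses + 1L
  }
  (wins - losses) / (length(x) * length(y))
}

# Independent pair-enumeration oracle for the AUC (ties count one half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Step-up BH definition applied literally: min over the tail of p * m / rank.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(sorted)))
  pmin(adj, 1)
}
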