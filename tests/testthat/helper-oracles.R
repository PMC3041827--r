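# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# the F-score equation evaluated term by term
brute_fscore <- function(pos, neg) {
  xbar <- sum(c(pos, neg)) / (length(pos) + length(neg))
  xbar_p <- sum(pos) / length(pos)
  xbar_n <- sum(neg) / length(neg)
  num <- (xbar_p - xbar)^2 + (xbar_n - xbar)^2
  den_p <- 0
  for (x in pos) den_p <- den_p + (x - xbar_p)^2
  den_n <- 0
  for (x in neg) den_n <- den_n + (x - xbar_n)^2
  den <- den_p / (length(pos) - 1) + den_n / (length(neg) - 1)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

# all-pairs Mann-Whitney count, ties scoring one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# small labeled matrix with an optional planted mean shift in given columns
make_labeled_matrix <- function(n_pos, n_neg, n_feat, shift_cols = integer(0),
                                shift = 0) {
  X <- matrix(rnorm((n_pos + n_neg) * n_feat), n_pos + n_neg, n_feat)
  X[seq_len(n_pos), shift_cols] <- X[seq_len(n_pos), shift_cols] + shift
  list(X = X, y = rep(c(1L, -1L), c(n_pos, n_neg)))
}

# reduced but non-trivial grids keep pipeline tests inside the time budget
fast_config <- function(seed, repeats = 3L) {
  training_config(C_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1),
                  repeats = repeats, seed = seed)
}
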