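# Small in-code fixtures shared across test files.

# a deterministic 6x6 categorical map (codes 1..3)
toy_map <- function(vals = NULL, ps = 10) {
  if (is.null(vals)) {
    vals <- matrix(c(1, 1, 2, 2, 3, 2,
                     1, 1, 2, 2, 2, 2,
                     2, 2, 2, 2, 2, 2,
                     2, 2, 1, 1, 2, 2,
                     3, 2, 1, 1, 2, 2,
                     3, 3, 2, 2, 2, 2), 6, 6, byrow = TRUE)
  }
  grid(vals, ps, origin = c(0, nrow(vals) * ps), kind = "categorical")
}

# the worked 3-class matrix used in the hand-arithmetic examples
hand_matrix <- function(duration = 1) {
  transition_matrix(matrix(c(50, 5, 0,
                             10, 30, 5,
                             0, 5, 10), 3, 3, byrow = TRUE),
                    duration = duration)
}

# brute-force intensity quantities straight from a pair of maps
brute_intensity <- function(map_t, map_t1, duration, scheme = class_scheme()) {
  a <- as.vector(map_t$values); b <- as.vector(map_t1$values)
  ha <- cell_area_ha(map_t)
  A <- sum(!is.na(a) & !is.na(b)) * ha
  change <- sum(a != b, na.rm = TRUE) * ha
  S <- change / (duration * A) * 100
  G <- L <- numeric(scheme$J)
  for (k in seq_len(scheme$J)) {
    cd <- scheme$codes[k]
    gain <- sum(b == cd & a != cd, na.rm = TRUE) * ha
    loss <- sum(a == cd & b != cd, na.rm = TRUE) * ha
    G[k] <- gain / duration / (sum(b == cd, na.rm = TRUE) * ha) * 100
    L[k] <- loss / duration / (sum(a == cd, na.rm = TRUE) * ha) * 100
  }
  list(S = S, G = G, L = L, change = change, A = A)
}

# rank-sum AUC of scores against binary labels
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
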