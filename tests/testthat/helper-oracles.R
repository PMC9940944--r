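# Independent oracles used to cross-check the implementation.

# brute-force ordinal AUC: expand the contingency counts to individual
# records and count case>control pairs with half credit for ties
bruteForceAUC <- function(cases, controls) {
  cs <- rep(seq_along(cases), cases)
  ct <- rep(seq_along(controls), controls)
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# independent Fleiss kappa: observed agreement counted by brute force over
# all rater pairs per subject, chance agreement from category marginals
pairwiseKappaOracle <- function(ratings) {
  ratings <- as.matrix(ratings)
  r <- ncol(ratings)
  pairs <- utils::combn(r, 2)
  pObs <- apply(ratings, 1, function(row)
    mean(apply(pairs, 2, function(p) row[p[1]] == row[p[2]])))
  pBar <- mean(pObs)
  cats <- sort(unique(as.vector(ratings)))
  pj <- vapply(cats, function(cg) mean(ratings == cg), numeric(1))
  pe <- sum(pj^2)
  (pBar - pe) / (1 - pe)
}

# published 14-rater, 10-subject, 5-category worked example; the printed
# kappa is 0.210 (Pbar 0.378, Pe 0.213)
fleissPublishedRatings <- function() {
  counts <- matrix(c(
    0, 0, 0, 0, 14,
    0, 2, 6, 4, 2,
    0, 0, 3, 5, 6,
    0, 3, 9, 2, 0,
    2, 2, 8, 1, 1,
    7, 7, 0, 0, 0,
    3, 2, 6, 3, 0,
    2, 5, 3, 2, 2,
    6, 5, 2, 1, 0,
    0, 2, 2, 3, 7), ncol = 5, byrow = TRUE)
  t(apply(counts, 1, function(r) rep(1:5, r)))
}

# random contingency table with bounded subject count
randomTable <- function(maxN = 200, maxK = 5) {
  k <- sample(2:maxK, 1)
  repeat {
    cases <- stats::rpois(k, sample(1:20, 1))
    controls <- stats::rpois(k, sample(1:20, 1))
    if (sum(cases) >= 1 && sum(controls) >= 1 &&
        sum(cases) + sum(controls) <= maxN) break
  }
  list(cases = cases, controls = controls)
}
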