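# Independent brute-force oracles used to pin down the production code.
# These deliberately avoid the package's own computation paths.

# random binary mask
random_mask <- function(dims, p = 0.5) {
  array(runif(prod(dims)) < p, dims)
}

# integer-arithmetic overlap/volume oracles
oracle_dice <- function(a, b) {
  inter <- sum(a == TRUE & b == TRUE)
  2 * inter / (sum(a == TRUE) + sum(b == TRUE))
}

oracle_vs <- function(a, b) {
  na <- sum(a == TRUE)
  nb <- sum(b == TRUE)
  1 - abs(na - nb) / (na + nb)
}

# border voxels by explicit 6-neighbour enumeration
oracle_border <- function(mask) {
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow = 0, ncol = 3)
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    is_border <- FALSE
    for (k in 1:3) for (s in c(-1, 1)) {
      nb <- v
      nb[k] <- nb[k] + s
      if (nb[k] < 1 || nb[k] > d[k] || !mask[nb[1], nb[2], nb[3]]) {
        is_border <- TRUE
      }
    }
    if (is_border) out <- rbind(out, v)
  }
  out
}

# all pairwise border distances, then a type-7 percentile per direction
oracle_hd <- function(a, b, spacing, percentile = 95) {
  pa <- oracle_border(a)
  pb <- oracle_border(b)
  pa_mm <- sweep(pa, 2, spacing, `*`)
  pb_mm <- sweep(pb, 2, spacing, `*`)
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j) {
    sqrt((pa_mm[i, 1] - pb_mm[j, 1])^2 +
         (pa_mm[i, 2] - pb_mm[j, 2])^2 +
         (pa_mm[i, 3] - pb_mm[j, 3])^2)
  })
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  max(quantile(d_ab, percentile / 100, type = 7, names = FALSE),
      quantile(d_ba, percentile / 100, type = 7, names = FALSE))
}

# mean of tied positions, by enumeration (rank-convention oracle)
oracle_fractional_ranks <- function(values_best_first) {
  ord <- order(values_best_first)
  out <- numeric(length(values_best_first))
  pos <- seq_along(values_best_first)
  for (v in unique(values_best_first)) {
    idx <- which(values_best_first == v)
    out[idx] <- mean(pos[ord %in% idx])
  }
  out
}

# tiny score-table builder for ranking tests: one row per
# (team, case, label) with the given metric columns
make_score_table <- function(teams, cases, labels, fill) {
  grid <- expand.grid(team = teams, case_id = cases, label_code = labels,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  defaults <- list(dsc = 0.5, hd95 = 1, vs = 0.5, bne0 = 0L, bne1 = 0L,
                   bne2 = 0L, missing = FALSE, both_empty = FALSE)
  for (col in names(defaults)) grid[[col]] <- rep(defaults[[col]], n)
  if (!missing(fill)) grid <- fill(grid)
  grid
}
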