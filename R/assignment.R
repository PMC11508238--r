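# Linear assignment via the Hungarian algorithm with potentials (O(n^3)).
# Minimizes total cost over complete one-to-one assignments of a square
# matrix. Verified in the test suite against exhaustive permutation search.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  if (ncol(cost) != n) abort("hungarian_assign() needs a square matrix.")
  if (any(!is.finite(cost))) abort("Assignment costs must be finite.")
  # columns are stored at index j + 1; index 1 is the virtual start column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- cost[i0, free] - u[i0] - v[free + 1]
      better <- cur < minv[free]
      if (any(better)) {
        minv[free[better]] <- cur[better]
        way[free[better] + 1] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Bipartite matching between trajectories and detections
#'
#' Solves the maximum-total-similarity one-to-one assignment between the rows
#' and columns of a similarity matrix (Hungarian algorithm on negated
#' similarities), then removes assigned pairs whose similarity falls below
#' `min_similarity` and reports them as unmatched. With unequal set sizes the
#' assignment covers the smaller side; the surplus is unmatched.
#'
#' @param similarity Numeric matrix; entry `(k, j)` scores trajectory `k`
#'   against detection `j` (e.g. cosine similarity or IoU).
#' @param min_similarity Pairs with similarity below this are discarded after
#'   the optimal assignment is computed, not before.
#' @return A list with `pairs` (tibble: `row`, `col`, `similarity`),
#'   `unmatched_rows` and `unmatched_cols` (integer indices).
#' @export
#' @examples
#' match_bipartite(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2), min_similarity = 0)
match_bipartite <- function(similarity, min_similarity = 0) {
  similarity <- as.matrix(similarity)
  k <- nrow(similarity)
  m <- ncol(similarity)
  empty <- list(
    pairs = tibble(row = integer(0), col = integer(0), similarity = numeric(0)),
    unmatched_rows = seq_len(k),
    unmatched_cols = seq_len(m)
  )
  if (k == 0 || m == 0) return(empty)
  if (any(!is.finite(similarity))) abort("Similarity matrix must be finite.")
  n <- max(k, m)
  cost <- matrix(0, n, n) # constant padding leaves the real assignment intact
  cost[seq_len(k), seq_len(m)] <- -similarity
  assign_col <- hungarian_assign(cost)
  rows <- seq_len(k)
  cols <- assign_col[rows]
  keep <- cols <= m
  rows <- rows[keep]
  cols <- cols[keep]
  sims <- similarity[cbind(rows, cols)]
  ok <- sims >= min_similarity
  pairs <- tibble(row = rows[ok], col = cols[ok], similarity = sims[ok])
  list(
    pairs = pairs,
    unmatched_rows = setdiff(seq_len(k), pairs$row),
    unmatched_cols = setdiff(seq_len(m), pairs$col)
  )
}
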