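#' Solve the linear sum assignment problem
#'
#' Minimum-total-cost one-to-one assignment over a rectangular cost matrix,
#' by the shortest-augmenting-path algorithm with dual potentials
#' (Jonker-Volkgenant style, O(n^2 m)). Every row (or column, whichever side
#' is smaller) is assigned; the larger side keeps `min(n, m)` assignments.
#' Ties between equally cheap assignments resolve deterministically by
#' processing rows in increasing index order.
#'
#' @param cost Numeric matrix of finite costs.
#' @return List with `pairs` (two-column matrix `row`, `col`, ordered by
#'   row), `total` (total assigned cost), `unassigned_rows`,
#'   `unassigned_cols`.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost))
  if (length(cost) == 0)
    return(list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("row", "col"))),
                total = 0,
                unassigned_rows = seq_len(nrow(cost)),
                unassigned_cols = seq_len(ncol(cost))))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  transposed <- nrow(cost) > ncol(cost)
  m <- if (transposed) t(cost) else cost
  n_rows <- nrow(m); n_cols <- ncol(m)
  u <- numeric(n_rows); v <- numeric(n_cols)
  col4row <- rep(NA_integer_, n_rows)
  row4col <- rep(NA_integer_, n_cols)
  for (cur in seq_len(n_rows)) {
    shortest <- rep(Inf, n_cols)
    path <- rep(NA_integer_, n_cols)
    visited <- logical(n_cols)
    rows_seen <- integer(0)
    min_val <- 0; i <- cur; sink <- NA_integer_
    while (is.na(sink)) {
      rows_seen <- c(rows_seen, i)
      idx <- which(!visited)
      red <- min_val + m[i, idx] - u[i] - v[idx]
      upd <- red < shortest[idx]
      if (any(upd)) {
        shortest[idx[upd]] <- red[upd]
        path[idx[upd]] <- i
      }
      j <- idx[which.min(shortest[idx])]
      min_val <- shortest[j]
      visited[j] <- TRUE
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
    }
    u[cur] <- u[cur] + min_val
    for (ii in rows_seen[rows_seen != cur])
      u[ii] <- u[ii] + min_val - shortest[col4row[ii]]
    vis <- which(visited)
    v[vis] <- v[vis] - (min_val - shortest[vis])
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      nxt <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- nxt
    }
  }
  if (transposed) {
    pairs <- cbind(row = col4row, col = seq_len(n_rows))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  } else {
    pairs <- cbind(row = seq_len(n_rows), col = col4row)
  }
  total <- sum(cost[pairs])
  list(pairs = pairs, total = total,
       unassigned_rows = setdiff(seq_len(nrow(cost)), pairs[, 1]),
       unassigned_cols = setdiff(seq_len(ncol(cost)), pairs[, 2]))
}
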