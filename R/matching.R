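#' Intersection over union of two cell masks
#'
#' @param mask_a,mask_b `cell_mask`s in the same coordinate frame.
#' @return `|A ∩ B| / |A ∪ B|` in \[0, 1\]; 0 when disjoint.
#' @export
iou <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "cell_mask"), inherits(mask_b, "cell_mask"))
  if (nrow(mask_a$pixels) == 0 || nrow(mask_b$pixels) == 0)
    stop("empty mask")
  ka <- paste(mask_a$pixels[, 1], mask_a$pixels[, 2])
  kb <- paste(mask_b$pixels[, 1], mask_b$pixels[, 2])
  inter <- sum(ka %in% kb)
  inter / (length(ka) + length(kb) - inter)
}

#' Build the cross-session assignment cost matrix
#'
#' Cost is `1 - IoU` between mask pairs (so the assignment minimizes
#' overlap loss and a kept match with cost below 0.8 has IoU above 0.2),
#' with pairs whose centroids are farther apart than `gate_dist_px` set to
#' exactly 1.
#'
#' @param masks_a,masks_b Lists of `cell_mask`s in a common frame.
#' @param gate_dist_px Centroid distance gate in pixels.
#' @return Object of class `cost_matrix`: `values` (`length(masks_a)` x
#'   `length(masks_b)`), `gate_dist_px`, and the centroid `distances`.
#' @export
build_cost_matrix <- function(masks_a, masks_b, gate_dist_px = 10) {
  na <- length(masks_a); nb <- length(masks_b)
  values <- matrix(1, na, nb)
  distances <- matrix(NA_real_, na, nb)
  if (na && nb) {
    ca <- t(vapply(masks_a, `[[`, numeric(2), "centroid_px"))
    cb <- t(vapply(masks_b, `[[`, numeric(2), "centroid_px"))
    for (i in seq_len(na)) {
      d <- sqrt((ca[i, 1] - cb[, 1])^2 + (ca[i, 2] - cb[, 2])^2)
      distances[i, ] <- d
      for (j in which(d <= gate_dist_px))
        values[i, j] <- 1 - iou(masks_a[[i]], masks_b[[j]])
    }
  }
  structure(list(values = values, gate_dist_px = gate_dist_px,
                 distances = distances),
            class = "cost_matrix")
}

#' Match cells across two sessions
#'
#' Maps session A's masks into session B's coordinate frame with a shift
#' field (from [piecewise_rigid_map()]), builds the gated `1 - IoU` cost
#' matrix, solves the linear sum assignment problem, and keeps only pairs
#' with cost strictly below `threshold`. Everything else lands in the
#' unmatched sets.
#'
#' @param masks_a,masks_b Lists of `cell_mask`s from the two sessions.
#' @param shift_field Optional `shift_field` mapping A onto B's frame
#'   (`NULL` for already-aligned masks).
#' @param threshold Cost cutoff: pairs with cost `>= threshold` are dropped.
#' @param gate_dist_px Centroid distance gate (pixels).
#' @return Object of class `match_result`: `pairs` (data frame `i`, `j`,
#'   `cost`, `iou`, `dist_px`), `unmatched_a`, `unmatched_b`, `threshold`,
#'   `gate_dist_px`.
#' @export
match_cells <- function(masks_a, masks_b, shift_field = NULL,
                        threshold = 0.8, gate_dist_px = 10) {
  mapped <- if (is.null(shift_field)) masks_a
            else apply_shift_field(masks_a, shift_field)
  nonempty <- vapply(mapped, function(m) nrow(m$pixels) > 0, logical(1))
  cm <- build_cost_matrix(mapped[nonempty], masks_b, gate_dist_px)
  sol <- solve_assignment(cm$values)
  idx_a <- which(nonempty)
  keep <- sol$pairs[, 1][cm$values[sol$pairs] < threshold]
  pairs <- data.frame(i = integer(0), j = integer(0), cost = numeric(0),
                      iou = numeric(0), dist_px = numeric(0))
  if (length(keep)) {
    kp <- sol$pairs[sol$pairs[, 1] %in% keep, , drop = FALSE]
    pairs <- data.frame(
      i = idx_a[kp[, 1]], j = kp[, 2],
      cost = cm$values[kp],
      iou = 1 - cm$values[kp],
      dist_px = cm$distances[kp])
  }
  structure(list(
    pairs = pairs,
    unmatched_a = setdiff(seq_along(masks_a), pairs$i),
    unmatched_b = setdiff(seq_along(masks_b), pairs$j),
    threshold = threshold, gate_dist_px = gate_dist_px
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (cost < %g), %d unmatched in A, %d in B\n",
              nrow(x$pairs), x$threshold, length(x$unmatched_a),
              length(x$unmatched_b)))
  invisible(x)
}

#' Split cells into matched and session-unique groups
#'
#' @param match A `match_result`.
#' @param cells_a,cells_b Indexable collections (or counts) of the cells in
#'   each session; only their lengths are used.
#' @return List with `matched` (data frame `i`, `j`), `unique_a`,
#'   `unique_b`; the three groups are disjoint and cover all cells.
#' @export
split_matched_unique <- function(match, cells_a, cells_b) {
  stopifnot(inherits(match, "match_result"))
  na <- if (is.numeric(cells_a) && length(cells_a) == 1L) cells_a else length(cells_a)
  nb <- if (is.numeric(cells_b) && length(cells_b) == 1L) cells_b else length(cells_b)
  list(matched = match$pairs[, c("i", "j")],
       unique_a = setdiff(seq_len(na), match$pairs$i),
       unique_b = setdiff(seq_len(nb), match$pairs$j))
}
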