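# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Circularly roll a matrix: content moves down by `dy` rows and right by
# `dx` columns (negative values move up/left).
roll_matrix <- function(m, dy = 0L, dx = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  dy <- ((dy %% nr) + nr) %% nr
  dx <- ((dx %% nc) + nc) %% nc
  if (dy != 0L) m <- m[c((nr - dy + 1L):nr, seq_len(nr - dy)), , drop = FALSE]
  if (dx != 0L) m <- m[, c((nc - dx + 1L):nc, seq_len(nc - dx)), drop = FALSE]
  m
}

# Translate a matrix by a possibly fractional shift (dx along columns, dy
# along rows) using bilinear interpolation between the four neighbouring
# circular integer rolls.  Consistent with the periodic correlation model.
shift_image <- function(m, dx = 0, dy = 0) {
  fy <- floor(dy); fx <- floor(dx)
  ry <- dy - fy;   rx <- dx - fx
  if (ry == 0 && rx == 0) return(roll_matrix(m, fy, fx))
  m00 <- roll_matrix(m, fy,      fx)
  m10 <- roll_matrix(m, fy + 1L, fx)
  m01 <- roll_matrix(m, fy,      fx + 1L)
  m11 <- roll_matrix(m, fy + 1L, fx + 1L)
  (1 - ry) * (1 - rx) * m00 + ry * (1 - rx) * m10 +
    (1 - ry) * rx * m01 + ry * rx * m11
}

# Sample a matrix at fractional (row, col) positions by bilinear
# interpolation; positions outside the matrix return NA.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  ok <- r >= 1 & c >= 1 & r <= nr & c <= nc
  r0p <- pmin(pmax(r0, 1L), nr); r1p <- pmin(r0p + 1L, nr)
  c0p <- pmin(pmax(c0, 1L), nc); c1p <- pmin(c0p + 1L, nc)
  v <- (1 - fr) * (1 - fc) * m[cbind(r0p, c0p)] +
    fr * (1 - fc) * m[cbind(r1p, c0p)] +
    (1 - fr) * fc * m[cbind(r0p, c1p)] +
    fr * fc * m[cbind(r1p, c1p)]
  v[!ok] <- NA_real_
  v
}

# Robust noise scale of a trace from lag-1 differences (transients are
# sparse, so successive differences are noise-dominated).
robust_noise_sd <- function(x) {
  if (length(x) < 3L) return(stats::sd(x))
  stats::mad(diff(x)) / sqrt(2)
}

as_plain_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}
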