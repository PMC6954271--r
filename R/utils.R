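# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Separable box (moving-average) blur with edge replication; k is the
# half-width, window = 2k + 1.
box_blur <- function(m, k) {
  if (k < 1) return(m)
  blur1 <- function(x, k) {
    n <- length(x)
    xp <- c(rep(x[1], k), x, rep(x[n], k))
    cs <- cumsum(xp)
    (cs[(2 * k + 1):(n + 2 * k)] - c(0, cs[1:(n - 1)])) / (2 * k + 1)
  }
  m <- apply(m, 2L, blur1, k = k)
  t(apply(m, 1L, blur1, k = k))
}

# Pearson normalized cross-correlation of two equal-length pixel sets.
ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# Extract the image matrix from panel/sectioned/raw inputs.
as_image <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && is.matrix(x$image)) return(x$image)
  stop("cannot interpret input as an image")
}

# Round half away from zero (printed-table convention).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shift a matrix by (dy, dx) pixels, filling vacated cells with `fill`.
shift_fill <- function(m, dy = 0L, dx = 0L, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  sr <- max(1L, 1L - dy):min(nrow(m), nrow(m) - dy)
  sc <- max(1L, 1L - dx):min(ncol(m), ncol(m) - dx)
  if (length(sr) && length(sc)) out[sr + dy, sc + dx] <- m[sr, sc]
  out
}
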