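# Internal helpers: classed error conditions, RNG scoping, bilinear sampling.

stop_hq <- function(msg, class, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "hookquant_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

abort_validation <- function(msg) stop_hq(msg, "hookquant_validation_error")
abort_degenerate <- function(msg) stop_hq(msg, "hookquant_degenerate_error")
abort_no_tissue <- function(msg) stop_hq(msg, "hookquant_no_tissue_error")
abort_oob <- function(msg) stop_hq(msg, "hookquant_out_of_bounds_error")
abort_missing_cell <- function(msg) stop_hq(msg, "hookquant_missing_cell_error")

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state so
# package functions never disturb the global stream. seed = NULL leaves the
# current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_validation("seed must be a single finite number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("%s must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    abort_validation(sprintf("%s must be > %g (got %g)", name, min, x))
  }
  if (!strict_min && x < min) {
    abort_validation(sprintf("%s must be >= %g (got %g)", name, min, x))
  }
  if (x > max) {
    abort_validation(sprintf("%s must be <= %g (got %g)", name, max, x))
  }
  invisible(x)
}

as_point <- function(p, name) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p))) {
    abort_validation(sprintf("%s must be a finite (row, col) pair", name))
  }
  p
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) {
    abort_degenerate("cannot normalize a (near-)zero direction vector")
  }
  v / n
}

# Bilinear interpolation on a matrix at 0-based (row, col) coordinates.
# Points must lie within [0, nrow-1] x [0, ncol-1].
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img)
  nc <- ncol(img)
  if (any(r < 0 | r > nr - 1 | c < 0 | c > nc - 1)) {
    abort_oob("sample coordinates fall outside the image")
  }
  r0 <- pmin(floor(r), nr - 2L)
  c0 <- pmin(floor(c), nc - 2L)
  r0 <- pmax(r0, 0)
  c0 <- pmax(c0, 0)
  fr <- r - r0
  fc <- c - c0
  i00 <- cbind(r0 + 1L, c0 + 1L)
  i01 <- cbind(r0 + 1L, c0 + 2L)
  i10 <- cbind(r0 + 2L, c0 + 1L)
  i11 <- cbind(r0 + 2L, c0 + 2L)
  img[i00] * (1 - fr) * (1 - fc) + img[i01] * (1 - fr) * fc +
    img[i10] * fr * (1 - fc) + img[i11] * fr * fc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
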