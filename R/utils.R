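#' Derive a deterministic sub-seed from a master seed and a stage tag
#'
#' All randomness in the package flows through one integer master seed;
#' each stage (tree generation, point clouds, reflectance noise, CV folds,
#' ...) draws from its own sub-seed derived deterministically from the
#' master seed and a character tag, so stages can be re-run in isolation
#' and in any order without perturbing one another.
#'
#' @param seed Integer master seed.
#' @param tag Character stage tag (e.g. `"trees"`, `"cv"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  # small multiplicative string hash, kept well inside 32-bit integer range
  h <- as.double(seed %% 2147483647)
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded from (seed, tag);
# restores the caller's RNG state afterwards.
with_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, tag))
  expr
}

# Smoothed standardized Gaussian random field on an nr x nc grid.
# Repeated separable box-filter passes approximate a Gaussian kernel with
# spatial range ~ `range_cells`; the result is standardized to mean 0, sd 1.
smooth_field <- function(nr, nc, range_cells = 6, passes = 3) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  w <- max(1L, as.integer(round(range_cells / sqrt(passes))))
  k <- 2L * w + 1L
  pad_smooth <- function(m) {
    # mirror-pad then running mean along rows and columns
    run <- function(v) {
      n <- length(v)
      vp <- c(rev(v[seq_len(min(w, n))]), v, rev(v[seq.int(max(1L, n - w + 1L), n)]))
      cs <- cumsum(vp)
      (cs[seq.int(k, length(vp))] - c(0, cs[seq_len(length(vp) - k)]))[seq_len(n)] / k
    }
    m <- apply(m, 2L, run)
    t(apply(m, 1L, run))
  }
  for (i in seq_len(passes)) z <- pad_smooth(z)
  (z - mean(z)) / stats::sd(z)
}

# Assign integer classes to a matrix field by empirical quantiles so the
# class proportions match `fractions` exactly (up to integer rounding).
classify_by_quantile <- function(field, fractions, codes = seq_along(fractions) - 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n <- length(field)
  ord <- order(field)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  cls <- rep(codes, times = counts)
  out <- field
  out[ord] <- cls
  matrix(as.integer(out), nrow(field), ncol(field))
}

# Pearson (non-excess) kurtosis and standardized skewness; population moments.
moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}
moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

# Safe coefficient of variation (0 for zero mean).
safe_cv <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(0)
  stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
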