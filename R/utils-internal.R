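# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a child seed,
#' so that independent pipeline stages consume independent, reproducible
#' RNG streams. The result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Sample skewness (biased, moment-based); returns 0 for constant input.
skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# Min-max scale a numeric vector to [0, 1]; degenerate input maps to 0
# with a warning (a single observation carries no relative scale).
minmax_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("degenerate min-max scaling: all values equal; returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

# Physical voxel volume from a spacing triple (dx, dy, dz).
voxel_volume <- function(spacing) prod(spacing)

# Voxel-center physical coordinates (um) for array indices along each axis.
axis_coords <- function(n, step) (seq_len(n) - 0.5) * step

is_binary_array <- function(x) {
  is.array(x) && length(dim(x)) == 3 && all(x %in% c(0, 1, TRUE, FALSE))
}
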