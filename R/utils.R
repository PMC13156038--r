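# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state
# afterwards, so every generator is a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single value in [0, 1]", call. = FALSE)
  }
  as.double(x)
}

# Column-standardize and drop the scaling attributes scale() attaches.
scale_cols <- function(m) {
  s <- scale(m)
  attributes(s) <- attributes(s)[c("dim", "dimnames")]
  s
}

# Largest inter-centroid distance; the natural length scale of an atlas.
atlas_diameter <- function(atlas) {
  max(pairwise_distances(atlas))
}
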