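# Shared fixtures built in code.

tiny_atlas <- function(n = 3) {
  region_atlas(data.frame(
    region_id = seq_len(n),
    name = paste0("r", seq_len(n)),
    structure = rep_len(c("cortex", "subcortex", "hypothalamus"), n),
    stratum = rep_len(c("visual", "thalamus", "hypothalamus"), n),
    hemisphere = rep_len(c("L", "R", "M"), n),
    x = seq_len(n), y = 0, z = 0))
}

# Regions on a circle; with k = 2 every region's neighbours are its two
# ring neighbours.
ring_atlas <- function(n = 10, radius = 10) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  region_atlas(data.frame(
    region_id = seq_len(n), name = paste0("r", seq_len(n)),
    structure = "cortex", stratum = "visual",
    hemisphere = "M",
    x = radius * cos(th), y = radius * sin(th), z = 0))
}

unit_vec <- function(n, seed) {
  set.seed(seed)
  w <- rnorm(n)
  w / sqrt(sum(w^2))
}

# All permutations of 1..n (small n), for exhaustive checks.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}
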