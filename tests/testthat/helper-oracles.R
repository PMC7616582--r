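# independent flood-fill oracle used to cross-check grow_to_clinical: for
# every component, walk outward collecting voxels whose path from the
# component passes only through intensities >= frac * component max
# (membership in the current mask is irrelevant to traversability),
# iterating to a fixed point
grow_oracle <- function(mask, pet, frac = 0.4, connectivity = 26L) {
  off <- vqheal:::neighbor_offsets(connectivity)
  dims <- dim(mask)
  nbrs <- function(i) {
    co <- arrayInd(i, dims)
    out <- integer(0)
    for (r in seq_len(nrow(off))) {
      cc <- co + off[r, ]
      if (all(cc >= 1) && all(cc <= dims))
        out <- c(out, cc[1] + dims[1] * ((cc[2] - 1) + dims[2] * (cc[3] - 1)))
    }
    out
  }
  repeat {
    lab <- label_components(mask, connectivity)
    new <- mask
    for (k in seq_len(max(lab))) {
      comp <- which(lab == k)
      thr <- frac * max(pet[comp])
      visited <- array(FALSE, dims)
      visited[comp] <- TRUE
      q <- comp
      while (length(q)) {
        i <- q[1]; q <- q[-1]
        for (j in nbrs(i)) {
          if (!visited[j] && pet[j] >= thr) {
            visited[j] <- TRUE
            new[j] <- TRUE
            q <- c(q, j)
          }
        }
      }
    }
    if (identical(new, mask)) return(mask)
    mask <- new
  }
}

rand_grow_case <- function(seed) {
  set.seed(seed)
  dims <- c(7, 7, 5)
  pet <- array(runif(prod(dims), 0, 1), dims)
  mask <- array(runif(prod(dims)) < 0.04, dims)
  list(mask = mask, pet = pet)
}
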