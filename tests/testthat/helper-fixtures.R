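# Small shared fixtures, built in code at test time.

tiny_phantom <- function(N = 16L, seed = 7L, kind = "blobs", n_blobs = 3L) {
  make_phantom(phantom_spec(kind, n_blobs = n_blobs, seed = seed),
               N = N, voxel = 1e-9)
}

tiny_geometry <- function(n_pixels = 32L, voxel = 1e-9) {
  spi_geometry(voxel = voxel, n_pixels = n_pixels)
}

# Noise-free, unit-fluence stack at given orientations.
clean_stack <- function(model, geom, orientations, nufft_tol = 1e-8) {
  simulate_patterns(model, geom, orientations,
                    noise = noise_spec(poisson = FALSE, fluence_jitter_cv = 0),
                    nufft_tol = nufft_tol)
}

# Oriented merge samples (points in the particle frame, values = counts).
merge_samples <- function(stack, orientations = stack$true_orientation) {
  qg <- pixel_to_q(stack$geom)
  npix <- nrow(qg$q)
  D <- length(orientations)
  pts <- matrix(0, npix * D, 3)
  for (i in seq_len(D))
    pts[(i - 1) * npix + seq_len(npix), ] <- qg$q %*% quat_to_matrix(orientations[[i]])
  list(points = pts, values = as.vector(stack$images))
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Independently coded brute-force matcher (triple loop): the oracle for
# match_orientations.
brute_force_match <- function(I, W, refs, known = NULL) {
  D <- ncol(I)
  out <- data.frame(orientation = integer(D), conformation = integer(D),
                    distance = numeric(D), scale = numeric(D))
  for (i in seq_len(D)) {
    best <- Inf; bo <- NA; bc <- NA; bs <- NA
    for (ci in seq_along(refs)) {
      S <- refs[[ci]]$slices
      for (j in seq_len(ncol(S))) {
        r <- S[, j]; w <- W[, i]
        s <- if (is.null(known)) sum(w * I[, i] * r) / sum(w * r^2) else known[i]
        dd <- sum(w * (I[, i] - s * r)^2)
        if (dd < best * (1 - 1e-12)) { best <- dd; bo <- j; bc <- ci; bs <- s }
      }
    }
    out[i, ] <- list(bo, bc, best, bs)
  }
  out
}

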