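# Shared fixtures and small independent oracles used across test files.

# atom tibble shorthand
atoms_tbl <- function(element, x, y, z) {
  tibble::tibble(element = element, x = x, y = y, z = z)
}

# a bent 3-atom "water-like" fixture with hand-placed coordinates
fixture_bent_molecule <- function() {
  atoms_tbl(c("O", "H", "H"),
            x = c(0, 0.9572, -0.2399),
            y = c(0, 0, 0.9266),
            z = c(0, 0, 0))
}

# a small mixed-element conformer for invariance checks
fixture_mixed_conformer <- function() {
  atoms_tbl(c("C", "C", "O", "N", "H", "H", "H"),
            x = c(0, 1.54, 2.2, -0.8, 0.3, 1.2, -1.5),
            y = c(0, 0, 1.1, -0.9, 1.0, -1.0, 0.2),
            z = c(0, 0, -0.4, 0.6, -0.8, 0.9, -0.3))
}

# random rigid rotation matrix (proper, det = +1), deterministic given seed
random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

transform_atoms <- function(atoms, rotation = diag(3), shift = c(0, 0, 0)) {
  m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  tibble::tibble(element = atoms$element,
                 x = m[, 1] + shift[1],
                 y = m[, 2] + shift[2],
                 z = m[, 3] + shift[3])
}

# an ensemble of n randomly perturbed copies of a base conformer
random_ensemble <- function(n, seed = 1, base = fixture_mixed_conformer()) {
  set.seed(seed)
  atoms <- lapply(seq_len(n), function(i) {
    tibble::tibble(element = base$element,
                   x = base$x + rnorm(nrow(base), sd = 0.3),
                   y = base$y + rnorm(nrow(base), sd = 0.3),
                   z = base$z + rnorm(nrow(base), sd = 0.3))
  })
  conformer_ensemble(atoms, species_name = "random_fixture")
}

# analytic solvent-accessible area of two intersecting spheres with expanded
# radii R1, R2 at center distance d: each sphere loses a spherical cap
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- (R2^2 - (d - R1)^2) / (2 * d)  # cap height on sphere 1
  h2 <- (R1^2 - (d - R2)^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

# independent RMSD oracle: coarse search over Euler angles followed by
# Nelder-Mead refinement, never touching the SVD route under test
rmsd_rotation_oracle <- function(a, b) {
  P <- as.matrix(a[, c("x", "y", "z")])
  Q <- as.matrix(b[, c("x", "y", "z")])
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(euler(ang)) - Q)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- NULL; best_val <- Inf
  for (az in grid) for (ay in seq(0, pi, length.out = 7)) for (ax in grid) {
    v <- obj(c(az, ay, ax))
    if (v < best_val) { best_val <- v; best <- c(az, ay, ax) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
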