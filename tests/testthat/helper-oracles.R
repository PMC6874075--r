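# Independent, brute-force reference implementations used as oracles.
# These deliberately avoid the package's fast kernels.

# exact squared Euclidean distance to the nearest background voxel
edt_sq_oracle <- function(mask) {
  d <- dim(mask)
  co <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                              z = seq_len(d[3])))
  fg <- which(mask != 0)
  bg <- which(mask == 0)
  out <- array(0, d)
  if (!length(fg) || !length(bg)) return(out)
  bgc <- co[bg, , drop = FALSE]
  for (i in fg) {
    dx <- bgc[, 1] - co[i, 1]
    dy <- bgc[, 2] - co[i, 2]
    dz <- bgc[, 3] - co[i, 3]
    out[i] <- min(dx * dx + dy * dy + dz * dz)
  }
  out
}

# maximal-sphere local thickness by exhaustive sphere painting (no ridge
# shortcut): thickness(v) = max over foreground u covering v of 2*dt(u) - 1,
# where u covers v iff |v - u|^2 <= dt(u)^2.
local_thickness_oracle <- function(mask) {
  d <- dim(mask)
  dt <- sqrt(edt_sq_oracle(mask))
  co <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                              z = seq_len(d[3])))
  fg <- which(mask != 0)
  th <- array(0, d)
  fgc <- co[fg, , drop = FALSE]
  for (u in fg) {
    du <- dt[u]
    diam <- 2 * du - 1
    dx <- fgc[, 1] - co[u, 1]
    dy <- fgc[, 2] - co[u, 2]
    dz <- fgc[, 3] - co[u, 3]
    covered <- (dx * dx + dy * dy + dz * dz) <= du * du
    sel <- fg[covered]
    th[sel] <- pmax(th[sel], diam)
  }
  th[fg] <- pmax(th[fg], 1)
  th
}

# digital sphere mask of diameter d voxels centred in an n^3 image
digital_sphere <- function(d, n = d + 6) {
  cc <- (n + 1) / 2
  m <- array(0L, c(n, n, n))
  co <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  inside <- rowSums(sweep(co, 2, cc)^2) <= (d / 2)^2
  m[co[inside, , drop = FALSE]] <- 1L
  m
}

# random blobby test mask: union of a few random balls, guaranteed background
random_blob_mask <- function(n, seed, n_balls = 4) {
  set.seed(seed)
  m <- array(0L, c(n, n, n))
  co <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 4, n - 3)
    r <- runif(1, 2, n / 3)
    inside <- (co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2 +
      (co[, 3] - c0[3])^2 <= r^2
    m[co[inside, , drop = FALSE]] <- 1L
  }
  # keep a shell of background so every foreground voxel has a finite EDT
  m[c(1, n), , ] <- 0L; m[, c(1, n), ] <- 0L; m[, , c(1, n)] <- 0L
  m
}

# slow Gauss-quadrature oracle for the 8-node hexahedral stiffness matrix
element_stiffness_oracle <- function(E, nu, edge_mm, n_gauss = 3) {
  gp <- switch(as.character(n_gauss),
               "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
               "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                          w = c(5, 8, 5) / 9))
  # element-local node order must match the package convention
  signs <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                 c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  J <- edge_mm / 2 # isoparametric scale, cube element
  Ke <- matrix(0, 24, 24)
  for (a in seq_len(n_gauss)) for (b in seq_len(n_gauss))
    for (c in seq_len(n_gauss)) {
      xi <- gp$x[a]; eta <- gp$x[b]; zeta <- gp$x[c]
      B <- matrix(0, 6, 24)
      for (k in 1:8) {
        sx <- signs[k, 1]; sy <- signs[k, 2]; sz <- signs[k, 3]
        dNx <- sx * (1 + sy * eta) * (1 + sz * zeta) / 8 / J
        dNy <- sy * (1 + sx * xi) * (1 + sz * zeta) / 8 / J
        dNz <- sz * (1 + sx * xi) * (1 + sy * eta) / 8 / J
        col <- 3 * (k - 1)
        B[1, col + 1] <- dNx
        B[2, col + 2] <- dNy
        B[3, col + 3] <- dNz
        B[4, col + 1] <- dNy; B[4, col + 2] <- dNx
        B[5, col + 2] <- dNz; B[5, col + 3] <- dNy
        B[6, col + 1] <- dNz; B[6, col + 3] <- dNx
      }
      wgt <- gp$w[a] * gp$w[b] * gp$w[c] * J^3
      Ke <- Ke + wgt * t(B) %*% D %*% B
    }
  Ke
}

# random tube-like mask + matching TMD image for conservation properties
random_tube <- function(seed, d = c(24, 24, 40)) {
  set.seed(seed)
  m <- array(0L, d)
  co <- as.matrix(expand.grid(1:d[1], 1:d[2]))
  for (k in seq_len(d[3])) {
    cx <- d[1] / 2 + sin(k / 7 + seed) * 3
    cy <- d[2] / 2 + cos(k / 5) * 3
    rr <- 6 + 2 * sin(k / 9)
    ri <- rr - 2.5
    rho <- sqrt((co[, 1] - cx)^2 + (co[, 2] - cy)^2)
    sl <- matrix(0L, d[1], d[2])
    sl[co[rho <= rr & rho > ri, , drop = FALSE]] <- 1L
    m[, , k] <- sl
  }
  tmdv <- array(stats::runif(prod(d), 400, 1200), d)
  list(mask = bone_mask(m, 10.4),
       tmd = voxel_image(tmdv, 10.4, value_kind = "tmd"))
}

# seeded notched prism used by the strength-criterion oracle tests
notched_prism <- function(seed, nx = 12, ny = 12, nz = 28) {
  set.seed(seed)
  m <- array(1L, c(nx, ny, nz))
  depth <- sample(3:(nx - 4), 1)
  width <- sample(2:4, 1)
  z0 <- sample(10:(nz - 12), 1)
  m[seq_len(depth), seq_len(ny %/% 2), z0:(z0 + width)] <- 0L
  m
}
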