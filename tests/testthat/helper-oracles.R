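# Independent Mie oracle built on base Bessel functions: Riccati-Bessel
# functions from half-integer besselJ/besselY, Qsca/g recomputed both by the
# partial-wave sums and by Simpson quadrature of the amplitude functions
# |S1|^2 + |S2|^2 over [0, pi]. Shares no code with the package's
# recurrence-based implementation.
oracle_psi <- function(n, x) sqrt(pi * x / 2) * besselJ(x, n + 0.5)
oracle_chi <- function(n, x) -sqrt(pi * x / 2) * besselY(x, n + 0.5)

mie_oracle <- function(x, m, nq = 4001) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  n <- 1:nmax
  psx <- oracle_psi(n, x); psx1 <- oracle_psi(n - 1, x)
  psm <- oracle_psi(n, m * x); psm1 <- oracle_psi(n - 1, m * x)
  chx <- oracle_chi(n, x); chx1 <- oracle_chi(n - 1, x)
  xix <- complex(real = psx, imaginary = -chx)
  xix1 <- complex(real = psx1, imaginary = -chx1)
  dpsx <- psx1 - n * psx / x
  dpsm <- psm1 - n * psm / (m * x)
  dxix <- xix1 - n * xix / x
  a <- (m * psm * dpsx - psx * dpsm) / (m * psm * dxix - xix * dpsm)
  b <- (psm * dpsx - m * psx * dpsm) / (psm * dxix - m * xix * dpsm)
  Qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  Qext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  th <- seq(0, pi, length.out = nq)
  mu <- cos(th)
  S1 <- complex(nq); S2 <- complex(nq)
  pim1 <- rep(0, nq); pik <- rep(1, nq)
  for (k in 1:nmax) {
    tauk <- k * mu * pik - (k + 1) * pim1
    f <- (2 * k + 1) / (k * (k + 1))
    S1 <- S1 + f * (a[k] * pik + b[k] * tauk)
    S2 <- S2 + f * (a[k] * tauk + b[k] * pik)
    pin <- ((2 * k + 1) * mu * pik - (k + 1) * pim1) / k
    pim1 <- pik; pik <- pin
  }
  ii <- Mod(S1)^2 + Mod(S2)^2
  h <- pi / (nq - 1)
  w <- rep(c(4, 2), length.out = nq - 2)
  simp <- function(y) h / 3 * (y[1] + y[nq] + sum(w * y[2:(nq - 1)]))
  list(Qsca = Qsca, Qext = Qext,
       Qsca_quad = simp(ii * sin(th)) / x^2,
       g_quad = simp(ii * sin(th) * mu) / simp(ii * sin(th)),
       intensity = ii, theta = th)
}

# Simpson integral on a uniform grid (odd number of points).
simpson <- function(y, h) {
  nq <- length(y)
  w <- rep(c(4, 2), length.out = nq - 2)
  h / 3 * (y[1] + y[nq] + sum(w * y[2:(nq - 1)]))
}

# Small digitized-ball label volume for painter tests.
ball_labels <- function(radius_vox = 10, pad = 3, voxel = 0.2) {
  n <- 2 * (radius_vox + pad) + 1
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  labeled_volume(array(as.integer(r2 <= radius_vox^2), c(n, n, n)), voxel)
}

# Circular shift of a matrix (for translation-invariance checks).
roll_matrix <- function(m, s) {
  s <- s %% dim(m)
  if (s[1]) m <- rbind(m[(s[1] + 1):nrow(m), , drop = FALSE],
                       m[1:s[1], , drop = FALSE])
  if (s[2]) m <- cbind(m[, (s[2] + 1):ncol(m), drop = FALSE],
                       m[, 1:s[2], drop = FALSE])
  m
}
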