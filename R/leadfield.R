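# Three-shell spherical forward model and depth-weighted minimum-norm inverse
# used by the current-density-norm feature.
#
# The head is modelled as three concentric spherical shells (brain, skull,
# scalp) of radii 0.87 / 0.92 / 1.0 and conductivities 0.33 / 0.0042 / 0.33
# S/m. Dipoles sit on a fixed quasi-uniform grid of 642 points at radius 0.84
# with three Cartesian orientations each. Scalp potentials are computed from
# the classical Legendre series solution for a dipole in concentric spheres.

.lf_cache <- new.env(parent = emptyenv())

# Fibonacci lattice: n quasi-uniform directions on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Radial transfer factors for the concentric three-shell model.
# For each harmonic degree n, solves the 5x5 boundary-value system for a
# source term b^{-(n+1)} in the innermost shell and returns the scalp-surface
# potential per unit source coefficient.
shell_transfer <- function(nmax, radii = c(0.87, 0.92, 1.0),
                           cond = c(0.33, 0.0042, 0.33)) {
  r1 <- radii[1]; r2 <- radii[2]; R <- radii[3]
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  vn <- numeric(nmax)
  for (n in seq_len(nmax)) {
    # unknowns: A1, A2, B2, A3, B3
    A <- rbind(
      c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0),
      c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
        s2 * (n + 1) * r1^(-(n + 2)), 0, 0),
      c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1))),
      c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-(n + 2)),
        -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-(n + 2))),
      c(0, 0, 0, n * R^(n - 1), -(n + 1) * R^(-(n + 2)))
    )
    rhs <- c(-r1^(-(n + 1)), s1 * (n + 1) * r1^(-(n + 2)), 0, 0, 0)
    sol <- solve(A, rhs)
    vn[n] <- sol[4] * R^n + sol[5] * R^(-(n + 1))
  }
  vn
}

# Lead field: electrodes x (dipoles * 3 orientations), plus grid geometry.
# Dipole at b * dhat with moment q gives scalp potential
#   V = sum_n vn * b^{n-1} / (4 pi s1) * [ n (q.dhat) P_n(cosg)
#                                          + (q.u) P_n'(cosg) ]
# with u = ehat - cosg * dhat (the P_n^1 / sing factor is absorbed into u).
compute_leadfield <- function(montage, n_dipoles = 642, dipole_radius = 0.84,
                              nmax = 40) {
  E <- montage$positions                       # ne x 3
  D <- fibonacci_sphere(n_dipoles)             # nd x 3
  ne <- nrow(E); nd <- nrow(D)
  vn <- shell_transfer(nmax)
  b <- dipole_radius
  s1 <- 0.33

  cosg <- D %*% t(E)                           # nd x ne
  cosg[cosg > 1] <- 1; cosg[cosg < -1] <- -1

  # Legendre P_n and P_n' by recurrence, accumulated into radial/tangential
  # kernels.
  Pm1 <- matrix(1, nd, ne)        # P_0
  P <- cosg                        # P_1
  dPm1 <- matrix(0, nd, ne)       # P_0'
  dP <- matrix(1, nd, ne)         # P_1'
  Krad <- matrix(0, nd, ne)
  Ktan <- matrix(0, nd, ne)
  for (n in seq_len(nmax)) {
    cf <- vn[n] * b^(n - 1) / (4 * pi * s1)
    Krad <- Krad + cf * n * P
    Ktan <- Ktan + cf * dP
    # advance recurrences to degree n+1
    Pn1 <- ((2 * n + 1) * cosg * P - n * Pm1) / (n + 1)
    dPn1 <- dP * cosg + (n + 1) * P      # P_{n+1}' = x P_n' + (n+1) P_n
    Pm1 <- P; P <- Pn1
    dPm1 <- dP; dP <- dPn1
  }

  L <- matrix(0, ne, nd * 3L)
  for (k in 1:3) {
    # radial part: (q_k = e_k) . dhat ; tangential: e_k . u = E_k - cosg D_k
    rad <- Krad * D[, k]                           # nd x ne
    tanp <- Ktan * (matrix(E[, k], nd, ne, byrow = TRUE) - cosg * D[, k])
    L[, seq(k, nd * 3L, by = 3L)] <- t(rad + tanp)
  }
  # average-reference the lead field (EEG potentials are reference-free up to
  # a constant; ICA patterns from referenced data live in the same space)
  L <- sweep(L, 2, colMeans(L))
  list(L = L, dipoles = D * dipole_radius, vn = vn)
}

# Depth-weighted minimum-norm inverse operator with GCV-frozen Tikhonov
# regularisation: J = W L' (L W L' + lambda I)^-1 p, W = column-norm weights.
# lambda is selected once per montage by minimising the mean GCV score over
# the normalised lead-field columns and cached.
minimum_norm_operator <- function(montage) {
  key <- paste(montage$names, collapse = "|")
  if (!is.null(.lf_cache[[key]])) return(.lf_cache[[key]])
  lf <- compute_leadfield(montage)
  L <- lf$L
  cn <- sqrt(colSums(L^2))
  cn[cn < .Machine$double.eps] <- 1
  Lw <- sweep(L, 2, cn, "/")           # depth-weighted lead field
  G <- tcrossprod(Lw)                  # ne x ne
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scl <- mean(ev)
  # GCV over the normalised lead-field columns as canonical test patterns
  idx <- seq(1, ncol(Lw), length.out = min(64, ncol(Lw)))
  Pats <- Lw[, round(idx), drop = FALSE]
  Pats <- sweep(Pats, 2, pmax(sqrt(colSums(Pats^2)), 1e-12), "/")
  Pv <- crossprod(eg$vectors, Pats)    # ne x npat, in eigenbasis
  lambdas <- scl * 10^seq(-8, 0, by = 0.5)
  gcv <- vapply(lambdas, function(lam) {
    shr <- lam / (ev + lam)            # I - H in eigenbasis
    num <- colSums((shr * Pv)^2)
    mean(num) / (mean(shr))^2
  }, numeric(1))
  lambda <- lambdas[which.min(gcv)]
  op <- list(
    Lw = Lw, weights = cn, lambda = lambda,
    solve_mat = eg$vectors %*% (t(eg$vectors) / (eg$values + lambda))
  )
  .lf_cache[[key]] <- op
  op
}

# Current-density estimate for a scalp pattern: returns the dipole-space
# coefficient vector (weighted-space norm is what the feature uses).
current_density_estimate <- function(pattern, montage) {
  op <- minimum_norm_operator(montage)
  if (length(pattern) != nrow(op$Lw))
    abort("pattern length does not match montage size",
          "icaclean_dimension_error")
  p <- pattern - mean(pattern)
  as.numeric(crossprod(op$Lw, op$solve_mat %*% p))
}
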