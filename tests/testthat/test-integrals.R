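# Integral engine: closed forms, literature values, quadrature oracles,
# erf attenuation, symmetries, and the London-orbital complex variants.

test_that("overlap matches Gaussian-product closed form and normalization", {
  # two normalized s Gaussians, equal exponent a, separation R:
  # S = exp(-a R^2 / 2)
  a <- 0.8; R <- 1.7
  atoms <- data.frame(element = c("H", "H"), Z = c(1, 1), x = c(0, 0),
                      y = c(0, 0), z = c(0, R), ghost = FALSE)
  b <- structure(list(
    shells = list(list(center = c(0, 0, 0), l = 0L, exps = a, coefs = 1,
                       atom = 1L),
                  list(center = c(0, 0, R), l = 0L, exps = a, coefs = 1,
                       atom = 2L)),
    atoms = atoms, nao = 2L, ao_atom = 1:2, ao_monomer = NULL),
    class = "efm_ao_basis")
  S <- one_electron_integrals(b)$S
  expect_equal(S[1, 2], exp(-a * R^2 / 2), tolerance = 1e-13)
  expect_equal(diag(S), c(1, 1), tolerance = 1e-13)
})

test_that("H2/STO-3G integrals reproduce published reference values", {
  # Szabo & Ostlund's classic minimal-basis H2 at R = 1.4 bohr
  cl <- cluster(list(h2_monomer()))
  b <- monomer_basis(cl, 1)
  i <- one_electron_integrals(b)
  g <- eri_tensor(b)
  expect_equal(i$S[1, 2], 0.6593, tolerance = 2e-4)
  expect_equal(i$T[1, 1], 0.7600, tolerance = 2e-4)
  expect_equal(i$T[1, 2], 0.2365, tolerance = 2e-4)
  expect_equal(i$V[1, 1], -1.8804, tolerance = 2e-4)
  expect_equal(i$V[1, 2], -1.1948, tolerance = 2e-4)
  expect_equal(g[1, 1, 1, 1], 0.7746, tolerance = 2e-4)
  expect_equal(g[2, 1, 1, 1], 0.4441, tolerance = 2e-4)
  expect_equal(g[2, 2, 1, 1], 0.5697, tolerance = 2e-4)
  expect_equal(g[2, 1, 2, 1], 0.2970, tolerance = 2e-4)
})

test_that("point-charge attraction matches the erf closed form", {
  # normalized s Gaussian (exponent a): <s| 1/|r-C| |s> = erf(sqrt(2a) R)/R
  A <- c(0.3, -0.2, 0.5); Cq <- c(0.9, -0.8, 0.2); a <- 1.1
  b <- toy_basis(A = A)
  R <- sqrt(sum((A - Cq)^2))
  # isolate the s AO against a single charge: use ghost atoms so no nuclei
  b$atoms$ghost <- TRUE
  q <- point_charges(1.5, matrix(Cq, 1))
  V <- one_electron_integrals(b, charges = q)$V
  expect_equal(V[1, 1], -1.5 * erf_ref(sqrt(2 * a) * R) / R,
               tolerance = 1e-10)
  # erf-attenuated variant: scale the argument by s = mu^2/(p + mu^2)
  for (mu in c(0.45, 2)) {
    s <- mu^2 / (2 * a + mu^2)
    Va <- one_electron_integrals(b, point_charges(1.5, matrix(Cq, 1),
                                                  mu = mu))$V
    expect_equal(Va[1, 1], -1.5 * erf_ref(sqrt(2 * a * s) * R) / R,
                 tolerance = 1e-10)
    # attenuation only ever weakens the attraction
    expect_lt(abs(Va[1, 1]), abs(V[1, 1]))
  }
  # mu -> infinity restores the bare Coulomb kernel
  Vinf <- one_electron_integrals(b, point_charges(1.5, matrix(Cq, 1),
                                                  mu = 1e6))$V
  expect_equal(Vinf, V, tolerance = 1e-10)
})

test_that("attenuated point-charge potential is bounded by the bare one", {
  # pointwise kernel inequality |q erf(mu r)/r| <= |q / r| on a grid
  site <- list(center = c(0, 0, 0), mu_vec = c(0, 0, 0.7), d = 0.01)
  ch_b <- site_point_charges(site, mu = Inf)
  ch_a <- site_point_charges(site, mu = 0.45)
  pot <- function(ch, r) {
    sum(vapply(seq_len(nrow(ch)), function(k) {
      d <- sqrt(sum((r - c(ch$x[k], ch$y[k], ch$z[k]))^2))
      f <- if (is.finite(ch$mu[k])) erf_ref(ch$mu[k] * d) else 1
      ch$q[k] * f / d
    }, 0))
  }
  set.seed(4)
  for (k in 1:40) {
    r <- stats::rnorm(3) * 2
    expect_lte(abs(pot(ch_a, r)), abs(pot(ch_b, r)) + 1e-14)
  }
})

test_that("ERI tensor has 8-fold symmetry and classical long-range limit", {
  cl <- cluster(list(water_monomer()))
  b <- monomer_basis(cl, 1)
  g <- eri_tensor(b)
  set.seed(2)
  for (k in 1:20) {
    i <- sample(7, 4, replace = TRUE)
    v <- g[i[1], i[2], i[3], i[4]]
    expect_equal(g[i[2], i[1], i[3], i[4]], v, tolerance = 1e-12)
    expect_equal(g[i[1], i[2], i[4], i[3]], v, tolerance = 1e-12)
    expect_equal(g[i[3], i[4], i[1], i[2]], v, tolerance = 1e-12)
  }
  # positive semidefinite as a matrix over charge-density pairs
  M <- matrix(g, 49, 49)
  expect_gt(min(eigen((M + t(M)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-10)
  # two unit s densities far apart: Coulomb integral -> 1/R
  a <- 0.9; R <- 60
  atoms <- data.frame(element = c("H", "H"), Z = c(1, 1), x = c(0, 0),
                      y = c(0, 0), z = c(0, R), ghost = FALSE)
  b2 <- structure(list(
    shells = list(list(center = c(0, 0, 0), l = 0L, exps = a, coefs = 1,
                       atom = 1L),
                  list(center = c(0, 0, R), l = 0L, exps = a, coefs = 1,
                       atom = 2L)),
    atoms = atoms, nao = 2L, ao_atom = 1:2, ao_monomer = NULL),
    class = "efm_ao_basis")
  g2 <- eri_tensor(b2)
  expect_equal(g2[1, 1, 2, 2], 1 / R, tolerance = 1e-10)
  # in-core guard
  expect_error(eri_tensor(b, max_ao = 3), "guard")
})

test_that("integrals are invariant under rigid translation", {
  cl1 <- water_dimer()
  shift <- c(11.3, -7.2, 4.9)
  cl2 <- cluster(lapply(cl1$monomers, function(m)
    monomer(m$element, m$xyz + matrix(rep(shift, each = nrow(m$xyz)),
                                      nrow(m$xyz)))))
  b1 <- full_basis(cl1); b2 <- full_basis(cl2)
  q1 <- point_charges(c(0.3, -0.3), rbind(c(8, 0, 0), c(8.01, 0, 0)))
  q2 <- point_charges(c(0.3, -0.3), rbind(c(8, 0, 0) + shift,
                                          c(8.01, 0, 0) + shift))
  i1 <- one_electron_integrals(b1, q1)
  i2 <- one_electron_integrals(b2, q2)
  for (nm in c("S", "T", "V")) {
    expect_lt(max(abs(i1[[nm]] - i2[[nm]])), 1e-10)
  }
  expect_lt(max(abs(eri_tensor(b1) - eri_tensor(b2))), 1e-10)
})

test_that("complex Boys function agrees with direct quadrature", {
  for (Tre in c(0, 0.5, 3, 11, 27)) {
    for (Tim in c(-6, -0.7, 0, 1.3, 8)) {
      F <- cpp_boys_cplx(5, Tre, Tim)
      for (m in c(0, 2, 5)) {
        expect_equal(F[m + 1], boys_quadrature(m, Tre, Tim),
                     tolerance = 1e-10)
      }
    }
  }
  # real path consistency
  Fr <- cpp_boys_real(4, 7.3)
  Fc <- cpp_boys_cplx(4, 7.3, 0)
  expect_equal(Fr, Re(Fc), tolerance = 1e-13)
  # large-argument branch
  expect_equal(cpp_boys_real(0, 60)[1], 0.5 * sqrt(pi / 60),
               tolerance = 1e-12)
})

test_that("London one-electron matrices match a numerical oracle", {
  # brute-force quadrature of S, (1/2)<pi w|pi w> and V for an s + p toy
  # basis in a skewed field; validates phases, Zeeman and diamagnetic
  # terms and their factors in one shot
  b <- toy_basis()
  B <- c(0.13, -0.21, 0.17)
  ints <- lao_integrals(b, B)
  h <- 0.2; L <- 6.4
  x <- seq(-L, L, by = h)
  gp <- as.matrix(expand.grid(x, x, x)); dv <- h^3
  A <- b$shells[[1]]$center; Cc <- b$shells[[2]]$center
  als <- c(1.1, 0.7, 0.7, 0.7); comps <- c(0, 1, 2, 3)
  centers <- list(A, Cc, Cc, Cc)
  crossv <- function(a, v) c(a[2] * v[3] - a[3] * v[2],
                             a[3] * v[1] - a[1] * v[3],
                             a[1] * v[2] - a[2] * v[1])
  aoval <- function(ctr, al, comp) {
    d <- sweep(gp, 2, ctr); r2 <- rowSums(d^2)
    nrm <- (2 * al / pi)^0.75 * if (comp == 0) 1 else sqrt(4 * al)
    g <- exp(-al * r2)
    if (comp == 0) nrm * g else nrm * d[, comp] * g
  }
  aograd <- function(ctr, al, comp) {
    d <- sweep(gp, 2, ctr); r2 <- rowSums(d^2)
    nrm <- (2 * al / pi)^0.75 * if (comp == 0) 1 else sqrt(4 * al)
    g <- exp(-al * r2)
    if (comp == 0) return(-2 * al * nrm * g * d)
    out <- -2 * al * nrm * d[, comp] * g * d
    out[, comp] <- out[, comp] + nrm * g
    out
  }
  phase <- function(ctr) exp(-1i * 0.5 * (gp %*% crossv(B, ctr)))
  w <- lapply(1:4, function(i)
    as.vector(phase(centers[[i]])) * aoval(centers[[i]], als[i], comps[i]))
  piw <- lapply(1:4, function(i) {
    val <- aoval(centers[[i]], als[i], comps[i])
    grd <- aograd(centers[[i]], als[i], comps[i])
    bx <- t(apply(sweep(gp, 2, centers[[i]]), 1,
                  function(r) crossv(B, r)))
    (-1i * grd + 0.5 * bx * val) * as.vector(phase(centers[[i]]))
  })
  Sq <- matrix(0 + 0i, 4, 4); Tq <- matrix(0 + 0i, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    Sq[i, j] <- sum(Conj(w[[i]]) * w[[j]]) * dv
    Tq[i, j] <- 0.5 * sum(Conj(piw[[i]]) * piw[[j]]) * dv
  }
  expect_lt(max(abs(ints$S - Sq)), 1e-10)
  expect_lt(max(abs(ints$TM - Tq)), 1e-10)
  expect_hermitian(ints$S)
  expect_hermitian(ints$TM)
  expect_hermitian(ints$V)
})

test_that("London integrals reduce to real integrals in the right limits", {
  cl <- cluster(list(water_monomer()))
  b <- monomer_basis(cl, 1)
  # B = 0: phases vanish entirely
  i0 <- lao_integrals(b, c(0, 0, 0))
  ir <- one_electron_integrals(b)
  expect_lt(max(abs(i0$S - ir$S)), 1e-12)
  expect_lt(max(abs(i0$TM - ir$T)), 1e-12)
  expect_lt(max(abs(i0$V - ir$V)), 1e-12)
  g0 <- eri_tensor(b, B = c(0, 0, 0), lao = TRUE)
  expect_lt(max(abs(g0 - eri_tensor(b))), 1e-12)
  # all shells at a common centre: pair phases vanish for any B, so the
  # overlap equals the real overlap (field terms still act in TM)
  atoms <- data.frame(element = "O", Z = 8, x = 0.4, y = -0.3, z = 0.9,
                      ghost = FALSE)
  bs <- load_basis("sto-3g")$O
  b1 <- structure(list(
    shells = lapply(bs, function(s) list(center = c(0.4, -0.3, 0.9),
                                         l = s$l, exps = s$exps,
                                         coefs = s$coefs, atom = 1L)),
    atoms = atoms, nao = 5L, ao_atom = rep(1L, 5), ao_monomer = NULL),
    class = "efm_ao_basis")
  iB <- lao_integrals(b1, c(0, 0, 0.3))
  expect_lt(max(abs(iB$S - one_electron_integrals(b1)$S)), 1e-12)
})

test_that("LAO two-electron tensor: hermiticity and reduced symmetry", {
  cl <- cluster(list(water_monomer()))
  b <- monomer_basis(cl, 1)
  B <- c(0, 0, 0.2)
  g <- eri_tensor(b, B = B, lao = TRUE)
  set.seed(3)
  for (k in 1:20) {
    i <- sample(7, 4, replace = TRUE)
    v <- g[i[1], i[2], i[3], i[4]]
    # 4-fold complex symmetry: hermitian pair swap and particle exchange
    expect_equal(g[i[2], i[1], i[4], i[3]], Conj(v), tolerance = 1e-12)
    expect_equal(g[i[3], i[4], i[1], i[2]], v, tolerance = 1e-12)
  }
  # the full 8-fold (real) symmetry is genuinely broken at B != 0
  expect_gt(max(abs(g - Conj(g))), 1e-6)
})

test_that("CGO field matrices assemble consistently with the pi^2 route", {
  # two independent code paths: angular-momentum + second-moment matrices
  # versus the direct (1/2)<pi|pi> kernel with common phase centre
  cl <- cluster(list(water_monomer()))
  b <- monomer_basis(cl, 1)
  B <- c(0.11, 0.07, -0.19)
  O <- c(0.5, -0.2, 0.3)
  f <- field_one_electron(b, B, O)
  ir <- one_electron_integrals(b)
  r <- cpp_int1e(b$shells, matrix(0, 0, 5), B, O, c(0, 0, 0), FALSE)
  expect_lt(max(abs((ir$T + f$zeeman + f$dia) - r$TM)), 1e-11)
  # s-only functions centred at the gauge origin carry no angular momentum
  b1 <- toy_basis(A = O, C = O)
  b1$shells <- b1$shells[1]
  b1$nao <- 1L
  f1 <- field_one_electron(b1, c(0, 0, 1), O)
  expect_lt(max(abs(f1$L[[3]])), 1e-12)
  # diamagnetic matrix is positive semidefinite
  ev <- eigen(f$dia, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12)
})

test_that("one-electron energy grows quadratically for small fields", {
  # single electron in an s basis: E(B) - E(0) = -B/2 (spin) + c B^2,
  # c > 0; fit the orbital part by finite differences
  mh <- monomer("H", matrix(c(0, 0, 0), 1))
  cl <- cluster(list(mh))
  b <- monomer_basis(cl, 1)
  en <- vapply(c(0, 0.1, 0.2), function(Bz) {
    scf_solve(b, nelec = 1, B = c(0, 0, Bz), treatment = "lao")$energy +
      Bz / 2  # remove the linear spin-Zeeman part
  }, 0)
  c1 <- (en[2] - en[1]) / 0.01   # both estimate the curvature coefficient
  c2 <- (en[3] - en[2]) / 0.03
  expect_gt(c1, 0)
  expect_equal(c2 / c1, 1, tolerance = 0.25)
})
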