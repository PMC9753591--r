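# Shared fixtures: small water geometries (bohr) and convenience builders.
# All fixtures are built in code; nothing is read from disk except the
# bundled basis files.

water_monomer <- function(shift = c(0, 0, 0)) {
  monomer(c("O", "H", "H"),
          rbind(c(-0.009, 0, 0.117),
                c(-0.060, 1.435, -0.931),
                c(-0.060, -1.435, -0.931)) +
            matrix(rep(shift, each = 3), 3))
}

# hydrogen-bonded partner: donor H pointing at the acceptor oxygen
water_partner <- function() {
  monomer(c("O", "H", "H"),
          rbind(c(5.67, 0, 0.0), c(3.9, 0, 0.1), c(6.3, 0, 1.7)))
}

water_dimer <- function(B = c(0, 0, 0)) {
  cluster(list(water_monomer(), water_partner()), B = B)
}

# compact hydrogen-bonded-ish trimer (synthetic; near-equilibrium O-O)
water_trimer <- function(B = c(0, 0, 0)) {
  cluster(list(water_monomer(), water_partner(),
               monomer(c("O", "H", "H"),
                       rbind(c(2.8, 4.9, 0), c(1.6, 3.6, 0.3),
                             c(4.0, 4.2, -1.0)))),
          B = B)
}

h2_monomer <- function(shift = c(0, 0, 0), R = 1.4) {
  monomer(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, R)) +
            matrix(rep(shift, each = 2), 2))
}

monomer_basis <- function(cl, i, basis = "sto-3g") {
  build_basis(subsystem_atoms(cl, i), basis)
}

full_basis <- function(cl, basis = "sto-3g") {
  build_basis(subsystem_atoms(cl, seq_along(cl$monomers)), basis)
}

# uncontracted two-shell toy basis (s at A, p at C) used by quadrature
# oracles
toy_basis <- function(A = c(0.3, -0.2, 0.5), C = c(-0.4, 0.6, -0.1),
                      a_s = 1.1, a_p = 0.7) {
  atoms <- data.frame(element = c("H", "H"), Z = c(1, 1),
                      x = c(A[1], C[1]), y = c(A[2], C[2]),
                      z = c(A[3], C[3]), monomer = c(1L, 2L),
                      ghost = FALSE)
  structure(list(
    shells = list(list(center = A, l = 0L, exps = a_s, coefs = 1, atom = 1L),
                  list(center = C, l = 1L, exps = a_p, coefs = 1, atom = 2L)),
    atoms = atoms, nao = 4L, ao_atom = c(1L, 2L, 2L, 2L),
    ao_monomer = NULL), class = "efm_ao_basis")
}

# complex-argument Boys oracle: direct quadrature of
# F_m(T) = int_0^1 t^(2m) exp(-T t^2) dt, real and imaginary parts
boys_quadrature <- function(m, Tre, Tim) {
  re <- stats::integrate(function(t) t^(2 * m) * exp(-Tre * t^2) *
                           cos(Tim * t^2), 0, 1, rel.tol = 1e-12)$value
  im <- stats::integrate(function(t) -t^(2 * m) * exp(-Tre * t^2) *
                           sin(Tim * t^2), 0, 1, rel.tol = 1e-12)$value
  complex(real = re, imaginary = im)
}

expect_hermitian <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - Conj(t(M)))), tol)
}

erf_ref <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
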