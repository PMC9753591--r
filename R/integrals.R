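# R-level interface to the McMurchie-Davidson integral engine.
#
# Point charges are passed around as data frames with columns q, x, y, z
# (bohr) and mu -- the erf(mu*r) short-range attenuation scale; mu = Inf
# means no attenuation.  Ghost atoms never enter the charge lists.

.empty_charges <- function() {
  data.frame(q = numeric(0), x = numeric(0), y = numeric(0),
             z = numeric(0), mu = numeric(0))
}

#' Point-charge table helper
#'
#' @param q charges (a.u.); positive values attract electrons.
#' @param pos matrix (n x 3) of positions in bohr.
#' @param mu erf attenuation parameter (1/bohr); `Inf` disables attenuation.
#' @return Charge data frame used by the integral and SCF routines.
#' @export
point_charges <- function(q, pos, mu = Inf) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  data.frame(q = as.numeric(q), x = pos[, 1], y = pos[, 2], z = pos[, 3],
             mu = rep_len(as.numeric(mu), length(q)))
}

# charges of the real nuclei of a basis (for electron-nuclear attraction)
.nuclear_charges <- function(basis) {
  at <- basis$atoms[!basis$atoms$ghost, , drop = FALSE]
  point_charges(at$Z, as.matrix(at[, c("x", "y", "z")]), mu = Inf)
}

.charges_matrix <- function(charges) {
  if (is.null(charges) || nrow(charges) == 0) {
    return(matrix(0, 0, 5))
  }
  mu <- ifelse(is.finite(charges$mu) & charges$mu > 0, charges$mu, -1)
  cbind(charges$q, charges$x, charges$y, charges$z, mu)
}

.as_real <- function(m, tol = 1e-12) {
  if (is.complex(m) && max(abs(Im(m))) < tol) Re(m) else m
}

#' One-electron integrals (real, zero-field)
#'
#' Overlap, kinetic energy, nuclear/point-charge attraction and dipole
#' matrices over the Cartesian Gaussian AOs of `basis`.  The attraction
#' matrix includes the real (non-ghost) nuclei plus any supplied embedding
#' point charges, each with its own erf attenuation.
#'
#' @param basis an `efm_ao_basis`.
#' @param charges optional [point_charges()] data frame of embedding
#'   charges.
#' @param dipole_origin origin for the dipole matrices (bohr).
#' @return List with S, T, V, Dx, Dy, Dz (real matrices).
#' @export
one_electron_integrals <- function(basis, charges = NULL,
                                   dipole_origin = c(0, 0, 0)) {
  ch <- rbind(.nuclear_charges(basis),
              if (!is.null(charges)) charges else .empty_charges())
  r <- cpp_int1e(basis$shells, .charges_matrix(ch), c(0, 0, 0), c(0, 0, 0),
                 as.numeric(dipole_origin), FALSE)
  list(S = .as_real(r$S), T = .as_real(r$TM), V = .as_real(r$V),
       Dx = .as_real(r$Dx), Dy = .as_real(r$Dy), Dz = .as_real(r$Dz))
}

#' Magnetic-field one-electron matrices (common gauge origin)
#'
#' Orbital-Zeeman matrix (1/2) B . L_O (purely imaginary, antisymmetric
#' real part zero) and the diamagnetic matrix (1/8) (B x r_O)^2 (real,
#' symmetric, positive semidefinite) over real Gaussian AOs, both about
#' the supplied gauge origin.  The spin-Zeeman term B . S is handled at
#' the SCF level.
#'
#' @param basis an `efm_ao_basis`.
#' @param B field vector in units of B0.
#' @param gauge_origin gauge origin (bohr).
#' @return List with `zeeman` (complex), `dia` (real), and the raw
#'   angular-momentum component matrices `L` (list of 3 complex matrices).
#' @export
field_one_electron <- function(basis, B, gauge_origin) {
  a <- cpp_angmom(basis$shells, as.numeric(gauge_origin))
  L <- list(-1i * a$Mx, -1i * a$My, -1i * a$Mz)
  zeeman <- 0.5 * (B[1] * L[[1]] + B[2] * L[[2]] + B[3] * L[[3]])
  B2 <- sum(B^2)
  dia <- (B2 * (a$Qxx + a$Qyy + a$Qzz) -
            (B[1]^2 * a$Qxx + B[2]^2 * a$Qyy + B[3]^2 * a$Qzz +
               2 * B[1] * B[2] * a$Qxy + 2 * B[1] * B[3] * a$Qxz +
               2 * B[2] * B[3] * a$Qyz)) / 8
  list(zeeman = zeeman, dia = dia, L = L)
}

#' London-orbital (complex) one-electron integrals
#'
#' Every AO carries the field- and centre-dependent London phase; matrix
#' elements then acquire a plane-wave factor handled exactly by a complex
#' shift of the Gaussian product centre.  `TM` is the full orbital part of
#' the field Hamiltonian, (1/2) <pi w_mu | pi w_nu> with pi = -i grad + A:
#' at B = 0 it reduces to the kinetic matrix.  All matrices are
#' independent of the gauge origin by construction.
#'
#' @inheritParams one_electron_integrals
#' @param B field vector in units of B0.
#' @return List with complex S, TM, V, Dx, Dy, Dz.
#' @export
lao_integrals <- function(basis, B, charges = NULL,
                          dipole_origin = c(0, 0, 0)) {
  ch <- rbind(.nuclear_charges(basis),
              if (!is.null(charges)) charges else .empty_charges())
  r <- cpp_int1e(basis$shells, .charges_matrix(ch), as.numeric(B),
                 c(0, 0, 0), as.numeric(dipole_origin), TRUE)
  list(S = r$S, TM = r$TM, V = r$V, Dx = r$Dx, Dy = r$Dy, Dz = r$Dz)
}

#' Two-electron repulsion tensor
#'
#' Dense in-core (mu nu | la si) tensor in chemist notation.  The real
#' tensor has full 8-fold permutational symmetry; with London orbitals at
#' nonzero field only the 4-fold complex symmetry survives.
#'
#' @param basis an `efm_ao_basis`.
#' @param B field vector (units of B0); nonzero values require
#'   `lao = TRUE`.
#' @param lao use London-orbital phases (complex tensor).
#' @param max_ao guard against accidental huge dense allocations.
#' @return 4-dimensional array, real or complex.
#' @export
eri_tensor <- function(basis, B = c(0, 0, 0), lao = FALSE, max_ao = 400) {
  if (basis$nao > max_ao) {
    stop("dense ERI tensor requested for ", basis$nao, " AOs exceeds the ",
         "in-core guard (", max_ao, "); raise max_ao explicitly if intended")
  }
  if (lao && any(B != 0)) {
    cpp_eri_lao(basis$shells, as.numeric(B))
  } else {
    cpp_eri_real(basis$shells)
  }
}

#' Values of the real Cartesian AOs on points
#' @param basis an `efm_ao_basis`.
#' @param points matrix (n x 3) of positions (bohr).
#' @return Matrix (n x nao).
#' @export
ao_values <- function(basis, points) {
  cpp_ao_values(basis$shells, matrix(as.numeric(points), ncol = 3))
}

#' Nuclear repulsion energy of the real atoms of a basis
#' @param basis an `efm_ao_basis`.
#' @return Energy in hartree; ghost atoms contribute nothing.
#' @export
nuclear_repulsion <- function(basis) {
  at <- basis$atoms[!basis$atoms$ghost, , drop = FALSE]
  n <- nrow(at)
  if (n < 2) return(0)
  e <- 0
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    e <- e + sum(at$Z[i] * at$Z[(i + 1):n] / d)
  }
  e
}

#' Nucleus/point-charge interaction energy
#'
#' Interaction of the real nuclei of a basis with external point charges;
#' each charge's erf attenuation applies here too, so the attenuated
#' embedding potential is felt consistently by electrons and nuclei.
#' Charge-charge terms are excluded everywhere by convention.
#'
#' @param basis an `efm_ao_basis`.
#' @param charges [point_charges()] data frame.
#' @return Energy in hartree.
#' @export
nuclear_charge_energy <- function(basis, charges) {
  if (is.null(charges) || nrow(charges) == 0) return(0)
  at <- basis$atoms[!basis$atoms$ghost, , drop = FALSE]
  if (nrow(at) == 0) return(0)
  e <- 0
  for (i in seq_len(nrow(at))) {
    d <- sqrt((charges$x - at$x[i])^2 + (charges$y - at$y[i])^2 +
                (charges$z - at$z[i])^2)
    f <- ifelse(is.finite(charges$mu), erf_clamped(charges$mu * d), 1)
    e <- e + sum(at$Z[i] * charges$q * f / d)
  }
  e
}

# erf via pnorm; safe for large arguments
erf_clamped <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
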