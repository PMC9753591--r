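# Self-consistent field solutions: real restricted Hartree-Fock at zero
# field and complex general Hartree-Fock (GHF) with either a common gauge
# origin (CGO) or London atomic orbitals (LAO) for uniform magnetic
# fields; DIIS acceleration, superposition guesses, and MP2.
#
# Spinor AO ordering for GHF: [alpha AOs (1..n), beta AOs (n+1..2n)].
# Embedding point charges polarize the subsystem (electron and nuclear
# terms) but never interact with each other.

#' SCF settings
#'
#' Defaults are tighter than typical single-molecule practice because the
#' many-body expansion sums many subsystem energies, so per-subsystem
#' errors accumulate.
#'
#' @param max_iter maximum SCF iterations.
#' @param tol_energy convergence threshold on the energy change (hartree).
#' @param tol_density convergence threshold on the RMS density change.
#' @param diis_size DIIS subspace size.
#' @param level_shift virtual-orbital level shift (hartree) applied in the
#'   orthonormal basis; 0 disables.
#' @param damping optional density mixing factor in (0, 1]; 1 = no damping.
#'   Used as fallback when DIIS breaks down.
#' @param lindep_tol smallest tolerated overlap eigenvalue.
#' @param nalpha,nbeta optional constrained spin occupations for GHF when
#'   the Fock matrix is spin-block-diagonal (field along z); `NULL` fills
#'   by aufbau over all spinors.
#' @return List of class `efm_scf_settings`.
#' @export
scf_settings <- function(max_iter = 200L, tol_energy = 1e-9,
                         tol_density = 1e-7, diis_size = 8L,
                         level_shift = 0, damping = 1, lindep_tol = 1e-8,
                         nalpha = NULL, nbeta = NULL) {
  stopifnot(tol_energy > 0, tol_density > 0, max_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), tol_energy = tol_energy,
                 tol_density = tol_density, diis_size = as.integer(diis_size),
                 level_shift = level_shift, damping = damping,
                 lindep_tol = lindep_tol, nalpha = nalpha, nbeta = nbeta),
            class = "efm_scf_settings")
}

# tr(A %*% B) without forming the product
.trAB <- function(A, B) sum(A * t(B))

.hermitize <- function(A) (A + Conj(t(A))) / 2

# symmetric/Hermitian orthogonalizer S^(-1/2); errors on linear dependence
.orthogonalizer <- function(S, lindep_tol) {
  e <- eigen(.hermitize(S), symmetric = TRUE)
  if (min(e$values) < lindep_tol) {
    stop(sprintf(paste0("basis is linearly dependent: smallest overlap ",
                        "eigenvalue %.3e below tolerance %.1e"),
                 min(e$values), lindep_tol))
  }
  e$vectors %*% (t(Conj(e$vectors)) / sqrt(e$values))
}

# Dense ERI contraction closures.  J_{mu nu} = sum (mu nu|la si) D_{si la};
# K_{mu si} = sum (mu nu|la si) D_{nu la}.
.eri_ops <- function(eri, n) {
  Jm <- matrix(eri, n * n, n * n)
  Km <- matrix(aperm(eri, c(1, 4, 2, 3)), n * n, n * n)
  list(
    J = function(D) matrix(Jm %*% as.vector(t(D)), n, n),
    K = function(D) matrix(Km %*% as.vector(D), n, n)
  )
}

.diis_extrapolate <- function(focks, errs) {
  m <- length(focks)
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) B[i, j] <- Re(sum(Conj(errs[[i]]) * errs[[j]]))
  }
  B[m + 1, seq_len(m)] <- -1
  B[seq_len(m), m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  c <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(c) || any(!is.finite(c))) return(NULL)
  F <- focks[[1]] * c[1]
  if (m > 1) for (i in 2:m) F <- F + focks[[i]] * c[i]
  F
}

# occupied-orbital selection; constrained per-spin filling classifies each
# spinor by its dominant spin when requested (valid when the Fock matrix is
# spin-block-diagonal, i.e. field along z)
.occupy <- function(C, eps, nocc, n, nalpha = NULL, nbeta = NULL) {
  if (is.null(nalpha)) return(seq_len(nocc))
  wa <- colSums(abs(C[seq_len(n), , drop = FALSE])^2)
  wb <- colSums(abs(C[n + seq_len(n), , drop = FALSE])^2)
  is_a <- wa >= wb
  c(which(is_a)[seq_len(nalpha)], which(!is_a)[seq_len(nbeta)])
}

#' Solve the (embedded) SCF equations for a subsystem
#'
#' Variational Hartree-Fock solution of the subsystem in the field of the
#' supplied embedding point charges and, optionally, a uniform magnetic
#' field.  The total energy includes nuclear repulsion of the real atoms
#' and the nucleus/point-charge interaction; point-charge mutual
#' interaction is excluded.
#'
#' @param basis an `efm_ao_basis` (ghost atoms allowed).
#' @param nelec electron count; default from the real atoms (neutral).
#' @param charges embedding [point_charges()]; they must not belong to the
#'   subsystem's own monomers (caller contract).
#' @param B uniform field vector in units of B0.
#' @param treatment `"auto"` (RHF at zero field, LAO otherwise), `"rhf"`,
#'   `"cgo"` or `"lao"`.
#' @param settings an [scf_settings()] object.
#' @param guess_density optional starting density matrix (spatial for RHF,
#'   spinor for GHF).
#' @param gauge_origin gauge origin for `"cgo"` (bohr); LAO energies are
#'   gauge-origin invariant and ignore it.
#' @param eri optional precomputed ERI tensor matching the treatment.
#' @return Object of class `efm_scf`: total `energy` (hartree), orbital
#'   coefficients `C`, orbital energies `eps`, density matrix `D`,
#'   convergence flag and iteration count, `sz` expectation, plus the
#'   matrices needed downstream (S, H1, overlap maps).
#' @export
scf_solve <- function(basis, nelec = NULL, charges = NULL, B = c(0, 0, 0),
                      treatment = c("auto", "rhf", "cgo", "lao"),
                      settings = scf_settings(), guess_density = NULL,
                      gauge_origin = c(0, 0, 0), eri = NULL) {
  treatment <- match.arg(treatment)
  if (treatment == "auto") treatment <- if (all(B == 0)) "rhf" else "lao"
  if (is.null(nelec)) nelec <- basis_electrons(basis)
  n <- basis$nao
  if (treatment == "rhf") {
    if (any(B != 0)) stop("RHF requires zero field; use cgo or lao")
    if (nelec %% 2 != 0) stop("RHF requires an even electron count")
  }

  enuc <- nuclear_repulsion(basis)
  enq <- nuclear_charge_energy(basis, charges)

  if (treatment == "lao") {
    ints <- lao_integrals(basis, B, charges)
    S1 <- ints$S
    H1sp <- ints$TM + ints$V
    if (is.null(eri)) eri <- eri_tensor(basis, B = B, lao = TRUE)
  } else {
    ints <- one_electron_integrals(basis, charges)
    S1 <- ints$S
    H1sp <- ints$T + ints$V
    if (treatment == "cgo") {
      f <- field_one_electron(basis, B, gauge_origin)
      H1sp <- H1sp + f$zeeman + f$dia
    }
    if (is.null(eri)) eri <- eri_tensor(basis)
  }
  ops <- .eri_ops(eri, n)

  ghf <- treatment != "rhf"
  if (ghf) {
    zero <- matrix(0, n, n)
    S <- rbind(cbind(S1, zero), cbind(zero, S1))
    H1 <- rbind(cbind(H1sp + 0.5 * B[3] * S1, 0.5 * (B[1] - 1i * B[2]) * S1),
                cbind(0.5 * (B[1] + 1i * B[2]) * S1,
                      H1sp - 0.5 * B[3] * S1))
    H1 <- H1 * (1 + 0i)
    fock <- function(D) {
      ia <- seq_len(n); ib <- n + ia
      Daa <- D[ia, ia]; Dbb <- D[ib, ib]
      Dab <- D[ia, ib]; Dba <- D[ib, ia]
      Jsp <- ops$J(Daa + Dbb)
      rbind(cbind(Jsp - ops$K(Daa), -ops$K(Dab)),
            cbind(-ops$K(Dba), Jsp - ops$K(Dbb))) + H1
    }
    nocc <- nelec
    dim_tot <- 2 * n
    density <- function(Cocc) tcrossprod(Cocc, Conj(Cocc))
  } else {
    S <- S1
    H1 <- H1sp
    fock <- function(D) H1 + ops$J(D) - 0.5 * ops$K(D)
    nocc <- nelec / 2
    dim_tot <- n
    density <- function(Cocc) 2 * tcrossprod(Cocc, Conj(Cocc))
  }

  X <- .orthogonalizer(S, settings$lindep_tol)
  solve_fock <- function(F) {
    Fo <- .hermitize(t(Conj(X)) %*% F %*% X)
    e <- eigen(Fo, symmetric = TRUE)
    ord <- order(e$values)  # eigen() sorts decreasing; aufbau needs ascending
    list(C = X %*% e$vectors[, ord, drop = FALSE], eps = e$values[ord])
  }

  if (!is.null(guess_density)) {
    D <- guess_density
    stopifnot(nrow(D) == dim_tot)
  } else {
    s0 <- solve_fock(H1)
    occ <- seq_len(nocc)
    D <- density(s0$C[, occ, drop = FALSE])
  }

  Eold <- Inf
  converged <- FALSE
  focks <- list(); errs <- list()
  C <- NULL; eps <- NULL
  niter <- 0L
  ehist <- numeric(0)
  for (it in seq_len(settings$max_iter)) {
    niter <- it
    F <- fock(D)
    E <- Re(0.5 * (.trAB(D, H1 + F))) + enuc + enq
    err <- F %*% D %*% S - S %*% D %*% F
    erro <- t(Conj(X)) %*% err %*% X
    rmserr <- sqrt(mean(abs(erro)^2))
    # DIIS bookkeeping
    focks <- c(focks, list(F)); errs <- c(errs, list(erro))
    if (length(focks) > settings$diis_size) {
      focks <- focks[-1]; errs <- errs[-1]
    }
    Fuse <- F
    if (length(focks) >= 2) {
      Fx <- .diis_extrapolate(focks, errs)
      if (!is.null(Fx)) Fuse <- Fx
    }
    if (settings$level_shift > 0) {
      # shift virtual space in the orthonormal basis
      Do <- t(Conj(X)) %*% S %*% D %*% S %*% X / if (ghf) 1 else 2
      Fuse <- Fuse + settings$level_shift *
        (S %*% X %*% (diag(dim_tot) - Do) %*% t(Conj(X)) %*% S)
    }
    sol <- solve_fock(Fuse)
    occ <- .occupy(sol$C, sol$eps, nocc, n,
                   if (ghf) settings$nalpha else NULL, settings$nbeta)
    Dnew <- density(sol$C[, occ, drop = FALSE])
    if (settings$damping < 1) {
      Dnew <- settings$damping * Dnew + (1 - settings$damping) * D
    }
    rmsd <- sqrt(mean(abs(Dnew - D)^2))
    dE <- E - Eold
    ehist <- c(ehist, E)
    D <- Dnew; C <- sol$C; eps <- sol$eps; Eold <- E
    if (abs(dE) < settings$tol_energy && rmsd < settings$tol_density) {
      converged <- TRUE
      break
    }
  }
  # final energy at the converged density
  F <- fock(D)
  E <- Re(0.5 * (.trAB(D, H1 + F))) + enuc + enq
  sz <- if (ghf) {
    ia <- seq_len(n); ib <- n + ia
    0.5 * Re(.trAB(D[ia, ia], S1) - .trAB(D[ib, ib], S1))
  } else 0
  structure(list(energy = E, C = C, eps = eps, D = D, S = S, S1 = S1,
                 H1 = H1, F = F, converged = converged, niter = niter,
                 nelec = nelec, nocc = nocc, occ = occ, sz = sz,
                 treatment = treatment, ghf = ghf, B = as.numeric(B),
                 enuc = enuc, enq = enq, nao = n, ehist = ehist,
                 basis = basis, charges = charges),
            class = "efm_scf")
}

#' @export
print.efm_scf <- function(x, ...) {
  cat(sprintf("<efm_scf %s%s> E = %.10f hartree, %s in %d iterations\n",
              toupper(x$treatment),
              if (any(x$B != 0)) sprintf(" |B|=%.3g", sqrt(sum(x$B^2))) else "",
              x$energy,
              if (x$converged) "converged" else "NOT CONVERGED", x$niter))
  invisible(x)
}

#' Superpose two monomer densities as a dimer SCF guess
#'
#' Embeds the converged monomer density matrices block-diagonally into the
#' dimer AO (or spinor) indexing.  The small trace deviation induced by
#' inter-monomer overlap is corrected by the first SCF iteration.
#'
#' @param res_i,res_j converged `efm_scf` results for the two monomers.
#' @param map_i,map_j integer vectors giving, for each AO of the monomer,
#'   its position in the dimer AO list.
#' @param n_dimer number of (spatial) AOs of the dimer basis.
#' @return Density matrix in dimer indexing (spinor if the inputs are GHF).
#' @export
dimer_superposition_guess <- function(res_i, res_j, map_i, map_j, n_dimer) {
  ghf <- res_i$ghf
  if (ghf != res_j$ghf) stop("monomer results mix RHF and GHF")
  dim_tot <- if (ghf) 2 * n_dimer else n_dimer
  D <- matrix(if (ghf) 0 + 0i else 0, dim_tot, dim_tot)
  place <- function(D, res, map) {
    n <- res$nao
    if (ghf) {
      idx <- c(map, n_dimer + map)
      src <- c(seq_len(n), n + seq_len(n))
      D[idx, idx] <- D[idx, idx] + res$D[src, src]
    } else {
      D[map, map] <- D[map, map] + res$D
    }
    D
  }
  D <- place(D, res_i, map_i)
  place(D, res_j, map_j)
}

# generic MO transformation of a chemist-notation AO tensor:
# (pq|rs) = sum Conj(C1)[mu,p] C2[nu,q] Conj(C3)[la,r] C4[si,s] g[mu,nu,la,si]
.transform_eri <- function(g, C1, C2, C3, C4) {
  n <- dim(g)[1]
  step <- function(g, C, conjugate) {
    m <- matrix(g, n, length(g) / n)
    Cm <- if (conjugate) Conj(C) else C
    out <- crossprod(Cm, m)  # (p x rest)
    aperm(array(out, c(ncol(C), dim(g)[2], dim(g)[3], dim(g)[4])),
          c(2, 3, 4, 1))
  }
  g <- step(g, C1, TRUE)
  g <- step(g, C2, FALSE)
  g <- step(g, C3, TRUE)
  step(g, C4, FALSE)
}

#' MP2 correlation energy
#'
#' Second-order Moller-Plesset correlation energy on top of a converged
#' SCF result: closed-shell spatial-orbital formula for RHF, complex
#' spin-orbital formula with antisymmetrized integrals for GHF (CGO or
#' LAO).  The result is real and non-positive for a bound ground-state
#' reference.
#'
#' @param scf converged `efm_scf`.
#' @param eri AO two-electron tensor matching the SCF treatment (real for
#'   RHF/CGO, complex LAO tensor for LAO at nonzero field).
#' @param gap_warn warn when the HOMO-LUMO gap falls below this value
#'   (hartree).
#' @return MP2 correlation energy in hartree.
#' @export
mp2_energy <- function(scf, eri, gap_warn = 1e-6) {
  if (!scf$converged) stop("MP2 requires a converged SCF reference")
  occ <- scf$occ
  if (is.null(occ)) occ <- seq_len(scf$nocc)
  if (!scf$ghf) {
    C <- scf$C
    virt <- setdiff(seq_len(ncol(C)), occ)
    eo <- scf$eps[occ]; ev <- scf$eps[virt]
    if (length(virt) == 0) return(0)
    if (min(ev) - max(eo) < gap_warn) {
      warning("near-degenerate occupied/virtual gap; MP2 may be unreliable")
    }
    g <- .transform_eri(eri, C[, occ, drop = FALSE], C[, virt, drop = FALSE],
                        C[, occ, drop = FALSE], C[, virt, drop = FALSE])
    no <- length(occ); nv <- length(virt)
    den <- outer(eo, ev, "-")  # [i, a] = ei - ea
    # D[i,a,j,b] = ei + ej - ea - eb
    Dfull <- outer(den, den, "+")
    gperm <- aperm(g, c(1, 4, 3, 2))  # (ib|ja)
    e2 <- sum(g * (2 * g - gperm) / Dfull)
    return(Re(e2))
  }
  # GHF spin-orbital path
  n <- scf$nao
  C <- scf$C
  Ca <- C[seq_len(n), , drop = FALSE]
  Cb <- C[n + seq_len(n), , drop = FALSE]
  virt <- setdiff(seq_len(ncol(C)), occ)
  eo <- scf$eps[occ]; ev <- scf$eps[virt]
  if (length(virt) == 0) return(0)
  if (min(ev) - max(eo) < gap_warn) {
    warning("near-degenerate occupied/virtual gap; MP2 may be unreliable")
  }
  no <- length(occ); nv <- length(virt)
  # B[(i,a),(mu,nu)] with a fast: spin-summed half-transform
  Bov <- kronecker(t(Conj(Ca[, occ, drop = FALSE])),
                   t(Ca[, virt, drop = FALSE])) +
         kronecker(t(Conj(Cb[, occ, drop = FALSE])),
                   t(Cb[, virt, drop = FALSE]))
  M <- matrix(eri, n * n, n * n)
  G <- Bov %*% M %*% t(Bov)  # [(i,a),(j,b)] = (ia|jb), a fast
  G4 <- array(G, c(nv, no, nv, no))  # [a,i,b,j]
  A <- G4 - aperm(G4, c(3, 2, 1, 4))  # <ij||ab>
  den <- outer(-ev, eo, "+")  # [a,i] = ei - ea
  Dfull <- outer(den, den, "+")  # [a,i,b,j]
  Re(0.25 * sum(abs(A)^2 / Dfull))
}
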