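# Self-consistent dipole embedding: each monomer is represented by a pair
# of point charges (+e, -e) a fixed distance d apart, centred at the
# monomer's nuclear-charge centre and oriented along its dipole moment.
# The charges are iterated until e*d matches the monomer dipole computed
# in the field of all other monomers' sites.  Optional erf(mu r)
# short-range attenuation tames the unphysical behaviour of the bare
# dipole potential when monomers approach closely.

#' Embedding settings
#'
#' @param d dipole length in bohr separating the two point charges
#'   (default 0.01, small enough that the pair reproduces the ideal dipole
#'   potential at all relevant distances).
#' @param threshold self-consistency threshold on max |delta e_j| (a.u.).
#' @param mu erf attenuation parameter (1/bohr); `Inf` disables
#'   attenuation (the Hartree-Fock/MP2 default).
#' @param mixing under-relaxation factor in (0, 1] applied to the dipole
#'   update (1 = plain iteration; 0.5 tames oscillatory mutual
#'   polarization).
#' @param max_iter maximum outer iterations.
#' @return List of class `efm_embed_settings`.
#' @export
embedding_settings <- function(d = 0.01, threshold = 1e-4, mu = Inf,
                               mixing = 0.5, max_iter = 50L) {
  stopifnot(d > 0, threshold > 0, mixing > 0, mixing <= 1)
  structure(list(d = d, threshold = threshold, mu = mu, mixing = mixing,
                 max_iter = as.integer(max_iter)),
            class = "efm_embed_settings")
}

#' Electric dipole moment of a monomer from an SCF density
#'
#' Nuclear dipole minus the electronic dipole (trace of the density with
#' the dipole integrals), about `origin`.  Real-valued even for complex
#' (field) densities.
#'
#' @param scf converged `efm_scf` for the monomer.
#' @param basis the monomer's `efm_ao_basis`.
#' @param origin reference point (bohr); for neutral monomers the dipole
#'   is origin-independent.
#' @return Length-3 dipole vector (a.u.).
#' @export
monomer_dipole <- function(scf, basis, origin = c(0, 0, 0)) {
  if (!scf$converged) stop("monomer_dipole requires a converged SCF result")
  at <- basis$atoms[!basis$atoms$ghost, , drop = FALSE]
  nuc <- c(sum(at$Z * (at$x - origin[1])), sum(at$Z * (at$y - origin[2])),
           sum(at$Z * (at$z - origin[3])))
  Dsp <- spatial_density(scf)
  if (scf$treatment == "lao" && any(scf$B != 0)) {
    ints <- lao_integrals(basis, scf$B, scf$charges, dipole_origin = origin)
  } else {
    ints <- one_electron_integrals(basis, scf$charges,
                                   dipole_origin = origin)
  }
  el <- c(Re(.trAB(Dsp, ints$Dx)), Re(.trAB(Dsp, ints$Dy)),
          Re(.trAB(Dsp, ints$Dz)))
  nuc - el
}

#' Spatial (spin-traced) density matrix of an SCF result
#' @param scf an `efm_scf`.
#' @return n x n (possibly complex) density matrix.
#' @export
spatial_density <- function(scf) {
  if (!scf$ghf) return(scf$D)
  n <- scf$nao
  scf$D[seq_len(n), seq_len(n)] + scf$D[n + seq_len(n), n + seq_len(n)]
}

#' Point-charge pair realizing a dipole site
#'
#' Charges +e and -e at R +/- (d/2) u with u the unit dipole direction
#' (+e on the side the dipole points toward), each tagged with the
#' attenuation parameter.  A zero dipole yields a legal zero-charge pair.
#'
#' @param site a dipole site (list with `center`, `mu_vec`, `d`).
#' @param mu attenuation parameter (1/bohr), `Inf` for none.
#' @return [point_charges()] data frame with two rows.
#' @export
site_point_charges <- function(site, mu = Inf) {
  mag <- sqrt(sum(site$mu_vec^2))
  if (mag == 0) {
    u <- c(0, 0, 1)
    e <- 0
  } else {
    u <- site$mu_vec / mag
    e <- mag / site$d
  }
  pos <- rbind(site$center + 0.5 * site$d * u,
               site$center - 0.5 * site$d * u)
  point_charges(c(e, -e), pos, mu = mu)
}

.make_site <- function(j, center, mu_vec, d) {
  list(monomer = j, center = center, mu_vec = mu_vec,
       e = sqrt(sum(mu_vec^2)) / d, d = d)
}

#' Converge the self-consistent dipole embedding field
#'
#' Outer fixed-point iteration: every monomer's SCF is solved in the
#' point-charge field of all other monomers' sites (Jacobi update: all
#' sites refreshed simultaneously), its dipole about the nuclear-charge
#' centre is recomputed, and the site charges are updated with
#' under-relaxation until no site charge moves by more than the threshold.
#' Iteration 0 uses isolated-monomer dipoles.  Dipoles are computed in the
#' external magnetic field when one is present (magnetic-induction
#' contributions to the embedding potential itself are neglected).
#'
#' @param cl an `efm_cluster` (neutral monomers).
#' @param basis_def basis set (name or `efm_basis_def`).
#' @param embed an [embedding_settings()] object.
#' @param scf an [scf_settings()] object for the monomer SCFs.
#' @param treatment SCF field treatment passed to [scf_solve()].
#' @param workers parallel workers for the independent monomer SCFs.
#' @return Object of class `efm_embedding`: per-monomer sites, attenuation,
#'   convergence history of max |delta e_j|, and the final monomer SCF
#'   results (solved in the penultimate field).
#' @export
converge_embedding <- function(cl, basis_def, embed = embedding_settings(),
                               scf = scf_settings(),
                               treatment = "auto", workers = 1L) {
  basis_def <- load_basis(basis_def)
  N <- length(cl$monomers)
  bases <- lapply(seq_len(N), function(i)
    build_basis(subsystem_atoms(cl, i), basis_def))
  gauge <- cluster_gauge_origin(cl)
  solve_monomer <- function(i, charges) {
    scf_solve(bases[[i]], charges = charges, B = cl$B,
              treatment = treatment, settings = scf,
              gauge_origin = gauge)
  }
  centers <- lapply(cl$monomers, nuclear_charge_center)
  run_all <- function(fn) {
    if (workers > 1L) {
      parallel::mclapply(seq_len(N), fn, mc.cores = workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(seq_len(N), fn)
    }
  }
  # iteration 0: isolated monomers
  results <- run_all(function(i) solve_monomer(i, NULL))
  for (r in results) {
    if (!r$converged) stop("isolated monomer SCF failed to converge")
  }
  sites <- lapply(seq_len(N), function(i) {
    .make_site(i, centers[[i]],
               monomer_dipole(results[[i]], bases[[i]], centers[[i]]),
               embed$d)
  })
  history <- numeric(0)
  converged <- N == 1  # no external field to iterate for a single monomer
  if (!converged) {
    for (it in seq_len(embed$max_iter)) {
      charges_for <- function(i) {
        do.call(rbind, lapply(sites[-i], site_point_charges, mu = embed$mu))
      }
      results <- run_all(function(i) solve_monomer(i, charges_for(i)))
      bad <- which(!vapply(results, function(r) r$converged, TRUE))
      if (length(bad) > 0) {
        stop("embedding SCF did not converge for monomer(s) ",
             paste(bad, collapse = ", "),
             "; consider damping (mixing < 1) or attenuation (finite mu)")
      }
      new_sites <- lapply(seq_len(N), function(i) {
        mu_new <- monomer_dipole(results[[i]], bases[[i]], centers[[i]])
        mu_mix <- embed$mixing * mu_new +
          (1 - embed$mixing) * sites[[i]]$mu_vec
        .make_site(i, centers[[i]], mu_mix, embed$d)
      })
      delta <- max(vapply(seq_len(N), function(i)
        abs(new_sites[[i]]$e - sites[[i]]$e), 0))
      history <- c(history, delta)
      sites <- new_sites
      if (delta < embed$threshold) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      stop(sprintf(paste0("embedding field not converged after %d outer ",
                          "iterations (max |delta e_j| = %.3e); consider ",
                          "stronger damping or erf attenuation"),
                   embed$max_iter, tail(history, 1)))
    }
  }
  structure(list(sites = sites, mu = embed$mu, d = embed$d,
                 history = history, converged = converged,
                 monomer_results = results, bases = bases,
                 settings = embed),
            class = "efm_embedding")
}

#' @export
print.efm_embedding <- function(x, ...) {
  cat(sprintf("<efm_embedding> %d site(s), d = %g bohr, %s, %d outer iter\n",
              length(x$sites), x$d,
              if (is.finite(x$mu)) sprintf("mu = %g", x$mu) else "unattenuated",
              length(x$history)))
  invisible(x)
}

#' Embedding charges felt by a subsystem
#'
#' Charges of all sites whose monomer is not in the excluded set.  For
#' subsystem energies the excluded set is the subsystem itself; the
#' embedded counterpoise correction passes a different exclusion.
#'
#' @param field converged `efm_embedding`.
#' @param exclude monomer indices whose sites are omitted.
#' @return [point_charges()] data frame (possibly zero rows).
#' @export
field_for_subsystem <- function(field, exclude) {
  keep <- Filter(function(s) !(s$monomer %in% exclude), field$sites)
  if (length(keep) == 0) return(.empty_charges())
  do.call(rbind, lapply(keep, site_point_charges, mu = field$mu))
}

#' Exact Coulomb embedding operator (validation reference)
#'
#' One-electron matrix, over the target basis, of the full Coulomb
#' potential of a set of external monomers: their nuclei as point charges
#' plus the Coulomb potential of their converged electron densities
#' (contracted against cross two-electron integrals over the combined
#' basis).  This is the full-potential embedding of the fragment
#' molecular-orbital method; the dipole sites approximate its long-range
#' behaviour, and tests use this operator to bound that approximation.
#'
#' @param target_basis `efm_ao_basis` of the embedded subsystem.
#' @param ext list of external monomers, each a list with `basis`
#'   (`efm_ao_basis`) and `scf` (converged `efm_scf`).
#' @param max_ao dense-ERI guard for the combined basis.
#' @return Real matrix (nao_target x nao_target).
#' @export
coulomb_embedding_reference <- function(target_basis, ext, max_ao = 400) {
  n <- target_basis$nao
  V <- matrix(0, n, n)
  for (e in ext) {
    # nuclear part: external nuclei attract the target electrons
    at <- e$basis$atoms[!e$basis$atoms$ghost, , drop = FALSE]
    if (nrow(at) > 0) {
      ch <- point_charges(at$Z, as.matrix(at[, c("x", "y", "z")]))
      r <- cpp_int1e(target_basis$shells, .charges_matrix(ch), c(0, 0, 0),
                     c(0, 0, 0), c(0, 0, 0), FALSE)
      V <- V + .as_real(r$V)
    }
    # electronic part: Coulomb of the external density over cross ERIs
    comb <- list(shells = c(target_basis$shells, e$basis$shells),
                 nao = n + e$basis$nao)
    if (comb$nao > max_ao) stop("combined basis exceeds reference guard")
    g <- cpp_eri_real(comb$shells)
    Dj <- Re(spatial_density(e$scf))
    idx_t <- seq_len(n)
    idx_e <- n + seq_len(e$basis$nao)
    cross <- g[idx_t, idx_t, idx_e, idx_e, drop = FALSE]
    m <- matrix(cross, n * n, length(idx_e)^2)
    V <- V + matrix(m %*% as.vector(t(Dj)), n, n)
  }
  V
}
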