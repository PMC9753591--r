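# Many-body expansion assembly: embedded second-order energies (the
# embedded fragment method proper), the exact full-order expansion used as
# an internal oracle, the embedded counterpoise correction, and interaction
# / mean interaction energies.

# compensated (Kahan) summation so totals are independent of job order
.ksum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

.resolve_treatment <- function(treatment, B) {
  if (treatment == "auto") {
    if (all(B == 0)) "rhf" else "lao"
  } else treatment
}

# solve one subsystem: basis built from an atom table, optional embedding
# charges, optional superposition guess; returns SCF result + correlation
.solve_subsystem <- function(atoms, basis_def, charges, B, treatment,
                             settings, gauge, mp2, guess_density = NULL) {
  basis <- build_basis(atoms, basis_def)
  eri <- eri_tensor(basis, B = B, lao = (treatment == "lao"))
  res <- scf_solve(basis, charges = charges, B = B, treatment = treatment,
                   settings = settings, gauge_origin = gauge, eri = eri,
                   guess_density = guess_density)
  ecorr <- if (mp2 && res$converged) mp2_energy(res, eri) else 0
  list(scf = res, basis = basis, ecorr = ecorr,
       energy = res$energy + ecorr)
}

#' Embedded fragment method energy (second-order MBE)
#'
#' Monomer energies plus pairwise corrections, every subsystem solved in
#' the converged dipole-embedding field of all other monomers (or
#' unembedded when `field` is `NULL`).  With `counterpoise = TRUE`, each
#' pair correction additionally evaluates the monomers in the dimer
#' (ghost-augmented) basis and in the embedding field excluding the dimer,
#' removing the basis-set superposition error.  All subsystem jobs are
#' independent and can run in parallel; totals use compensated summation
#' over sorted subsystem keys so results are identical for any worker
#' count.
#'
#' @param cl an `efm_cluster`.
#' @param basis_def basis (name or `efm_basis_def`).
#' @param field converged [converge_embedding()] result, or `NULL` for
#'   the unembedded expansion.
#' @param method `"hf"` or `"hf+mp2"`.
#' @param treatment `"auto"`, `"rhf"`, `"cgo"` or `"lao"`.
#' @param counterpoise include the embedded counterpoise correction.
#' @param scf [scf_settings()].
#' @param dimer_cutoff skip dimers whose nuclear-charge-centre distance
#'   (bohr) exceeds this; default `Inf` (no cutoff).
#' @param workers parallel workers (forked; 1 = serial).
#' @param include_isolated also compute isolated-monomer energies (needed
#'   for interaction and mean interaction energies).
#' @param store_results keep the per-subsystem SCF objects (needed for
#'   density assembly).
#' @return Object of class `efm_mbe`; see fields in the implementation and
#'   [mean_interaction_energy()].
#' @export
efm_energy <- function(cl, basis_def, field = NULL,
                       method = c("hf", "hf+mp2"),
                       treatment = "auto", counterpoise = FALSE,
                       scf = scf_settings(), dimer_cutoff = Inf,
                       workers = 1L, include_isolated = TRUE,
                       store_results = TRUE) {
  method <- match.arg(method)
  mp2 <- method == "hf+mp2"
  basis_def <- load_basis(basis_def)
  N <- length(cl$monomers)
  B <- cl$B
  treatment <- .resolve_treatment(treatment, B)
  gauge <- cluster_gauge_origin(cl)
  charges_for <- function(exclude) {
    if (is.null(field)) NULL else field_for_subsystem(field, exclude)
  }
  run <- function(xs, fn) {
    if (workers > 1L) {
      parallel::mclapply(xs, fn, mc.cores = workers, mc.preschedule = TRUE)
    } else lapply(xs, fn)
  }

  # stage 1: embedded monomers (guesses for the dimer stage)
  mono <- run(seq_len(N), function(i) {
    .solve_subsystem(subsystem_atoms(cl, i), basis_def, charges_for(i), B,
                     treatment, scf, gauge, mp2)
  })
  bad <- which(!vapply(mono, function(r) r$scf$converged, TRUE))
  if (length(bad) > 0) {
    stop("monomer SCF failed to converge for monomer(s): ",
         paste(bad, collapse = ", "))
  }
  E_i <- vapply(mono, function(r) r$energy, 0)

  # dimer list under the optional radial cutoff
  centers <- lapply(cl$monomers, nuclear_charge_center)
  pairs <- if (N >= 2) utils::combn(N, 2, simplify = FALSE) else list()
  pairs <- Filter(function(p) {
    sqrt(sum((centers[[p[1]]] - centers[[p[2]]])^2)) <= dimer_cutoff
  }, pairs)

  # stage 2: dimers, counterpoise terms, isolated monomers -- independent
  jobs <- list()
  for (p in pairs) {
    jobs[[length(jobs) + 1]] <- list(type = "dimer", idx = p)
    if (counterpoise) {
      jobs[[length(jobs) + 1]] <- list(type = "cp", idx = p, mono = p[1])
      jobs[[length(jobs) + 1]] <- list(type = "cp", idx = p, mono = p[2])
    }
  }
  if (include_isolated) {
    for (i in seq_len(N)) {
      jobs[[length(jobs) + 1]] <- list(type = "iso", idx = i)
    }
  }
  done <- run(jobs, function(jb) {
    if (jb$type == "dimer") {
      i <- jb$idx[1]; j <- jb$idx[2]
      atoms <- subsystem_atoms(cl, jb$idx)
      bd <- build_basis(atoms, basis_def)
      guess <- dimer_superposition_guess(
        mono[[i]]$scf, mono[[j]]$scf,
        which(bd$ao_monomer == i), which(bd$ao_monomer == j), bd$nao)
      .solve_subsystem(atoms, basis_def, charges_for(jb$idx), B, treatment,
                       scf, gauge, mp2, guess_density = guess)
    } else if (jb$type == "cp") {
      atoms <- subsystem_atoms(cl, real = jb$mono,
                               ghost = setdiff(jb$idx, jb$mono))
      .solve_subsystem(atoms, basis_def, charges_for(jb$idx), B, treatment,
                       scf, gauge, mp2)
    } else {
      .solve_subsystem(subsystem_atoms(cl, jb$idx), basis_def, NULL, B,
                       treatment, scf, gauge, mp2)
    }
  })
  for (k in seq_along(jobs)) {
    if (!done[[k]]$scf$converged) {
      stop("subsystem SCF failed to converge: ", jobs[[k]]$type, " ",
           paste(jobs[[k]]$idx, collapse = "-"))
    }
  }
  key_of <- function(jb) paste0(jb$type, ":", paste(jb$idx, collapse = "-"),
                                if (!is.null(jb$mono)) paste0("#", jb$mono))
  names(done) <- vapply(jobs, key_of, "")

  E_ij <- setNames(numeric(0), character(0))
  dimer_res <- list()
  cp_terms <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "-")
    d <- done[[paste0("dimer:", key)]]
    E_ij[key] <- d$energy
    dimer_res[[key]] <- d
    if (counterpoise) {
      cp_terms[[key]] <- c(done[[paste0("cp:", key, "#", p[1])]]$energy,
                           done[[paste0("cp:", key, "#", p[2])]]$energy)
    }
  }
  delta <- vapply(pairs, function(p) {
    E_ij[paste(p, collapse = "-")] - E_i[p[1]] - E_i[p[2]]
  }, 0)
  keys <- vapply(pairs, function(p) paste(p, collapse = "-"), "")
  ord <- order(keys)
  total <- .ksum(c(E_i, delta[ord]))
  cp_total <- NA_real_
  if (counterpoise) {
    delta_cp <- vapply(seq_along(pairs), function(k) {
      key <- keys[k]
      E_ij[key] - sum(cp_terms[[key]])
    }, 0)
    cp_total <- .ksum(c(E_i, delta_cp[ord]))
  }
  E_iso <- if (include_isolated) {
    vapply(seq_len(N), function(i) done[[paste0("iso:", i)]]$energy, 0)
  } else NULL

  structure(list(
    E_monomer = E_i, E_dimer = E_ij, delta = setNames(delta, keys),
    total = total, cp_total = cp_total, cp_terms = cp_terms,
    E_iso = E_iso, B = B, method = method, treatment = treatment,
    counterpoise = counterpoise, n_monomer = N, pairs = pairs,
    cluster = cl, basis_def = basis_def,
    monomer_results = if (store_results) mono else NULL,
    dimer_results = if (store_results) dimer_res else NULL,
    iso_results = if (store_results && include_isolated) {
      lapply(seq_len(N), function(i) done[[paste0("iso:", i)]])
    } else NULL
  ), class = "efm_mbe")
}

#' @export
print.efm_mbe <- function(x, ...) {
  cat(sprintf("<efm_mbe %s/%s> %d monomers, %d pairs\n", x$method,
              toupper(x$treatment), x$n_monomer, length(x$pairs)))
  cat(sprintf("  E^EFM        = %16.10f hartree\n", x$total))
  if (!is.na(x$cp_total)) {
    cat(sprintf("  E^EFM (CP)   = %16.10f hartree\n", x$cp_total))
  }
  if (!is.null(x$E_iso)) {
    eint <- (x$total - sum(x$E_iso)) * kcal_per_hartree
    cat(sprintf("  E_int        = %12.4f kcal/mol\n", eint))
    cat(sprintf("  MIE          = %12.4f kcal/mol\n", eint / x$n_monomer))
  }
  invisible(x)
}

#' Conventional (whole-cluster) energy
#'
#' Single supersystem SCF (+ MP2) on the entire cluster: the reference the
#' fragment expansion is measured against.
#'
#' @inheritParams efm_energy
#' @return List with `energy` (total, hartree), `scf`, `ecorr`, `basis`.
#' @export
conventional_energy <- function(cl, basis_def, method = c("hf", "hf+mp2"),
                                treatment = "auto", scf = scf_settings()) {
  method <- match.arg(method)
  basis_def <- load_basis(basis_def)
  treatment <- .resolve_treatment(treatment, cl$B)
  atoms <- subsystem_atoms(cl, seq_along(cl$monomers))
  .solve_subsystem(atoms, basis_def, NULL, cl$B, treatment, scf,
                   cluster_gauge_origin(cl), method == "hf+mp2")
}

#' Full many-body expansion to a given order (unembedded)
#'
#' Inclusion-exclusion assembly of all subsystem energies up to size `k`:
#' the k = N result equals the conventional supersystem energy to SCF
#' tolerance, which serves as the master correctness oracle of the
#' expansion machinery.  Cost grows combinatorially; meant for small N.
#'
#' @inheritParams efm_energy
#' @param k expansion order (1 <= k <= number of monomers).
#' @return List with `energy`, per-order increments `by_order`, and the
#'   per-subset energy table.
#' @export
mbe_full_order <- function(cl, basis_def, k, method = c("hf", "hf+mp2"),
                           treatment = "auto", scf = scf_settings()) {
  method <- match.arg(method)
  basis_def <- load_basis(basis_def)
  N <- length(cl$monomers)
  if (k > N) stop("expansion order k = ", k, " exceeds monomer count ", N)
  treatment <- .resolve_treatment(treatment, cl$B)
  gauge <- cluster_gauge_origin(cl)
  mp2 <- method == "hf+mp2"
  Esub <- list()
  for (m in seq_len(k)) {
    for (s in utils::combn(N, m, simplify = FALSE)) {
      key <- paste(s, collapse = "-")
      Esub[[key]] <- .solve_subsystem(subsystem_atoms(cl, s), basis_def,
                                      NULL, cl$B, treatment, scf, gauge,
                                      mp2)$energy
    }
  }
  dE <- list()
  by_order <- numeric(k)
  for (m in seq_len(k)) {
    for (s in utils::combn(N, m, simplify = FALSE)) {
      key <- paste(s, collapse = "-")
      v <- Esub[[key]]
      if (m > 1) {
        for (m2 in seq_len(m - 1)) {
          for (t in utils::combn(s, m2, simplify = FALSE)) {
            v <- v - dE[[paste(t, collapse = "-")]]
          }
        }
      }
      dE[[key]] <- v
      by_order[m] <- by_order[m] + v
    }
  }
  list(energy = .ksum(unlist(dE[order(names(dE))])), by_order = by_order,
       subsystem_energies = Esub)
}

#' Interaction energy of a cluster
#'
#' Difference between the (embedded fragment or conventional) total energy
#' and the sum of isolated-monomer energies at the same method and field.
#'
#' @param result an `efm_mbe` with isolated energies.
#' @param counterpoise use the counterpoise-corrected total.
#' @return Energy in kcal/mol.
#' @export
interaction_energy <- function(result, counterpoise = FALSE) {
  if (is.null(result$E_iso)) {
    stop("isolated monomer energies missing: rerun with include_isolated")
  }
  tot <- if (counterpoise) {
    if (is.na(result$cp_total)) stop("no counterpoise total in result")
    result$cp_total
  } else result$total
  (tot - sum(result$E_iso)) * kcal_per_hartree
}

#' Mean interaction energy per monomer
#'
#' (E_total - sum of isolated monomer energies) / n, in kcal/mol; the
#' per-molecule binding measure used to track the field response of
#' large clusters.
#'
#' @inheritParams interaction_energy
#' @return Energy per monomer in kcal/mol.
#' @export
mean_interaction_energy <- function(result, counterpoise = FALSE) {
  interaction_energy(result, counterpoise) / result$n_monomer
}
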