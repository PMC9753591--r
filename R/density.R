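# Many-body assembled electron densities: cluster-AO density matrix with
# inclusion-exclusion weights, real-space evaluation (with London phases
# at nonzero field) and Gaussian cube output.

#' Assemble the second-order MBE density matrix
#'
#' Embeds each dimer density into cluster AO indexing and combines with
#' monomer densities using the second-order inclusion-exclusion weights
#' D = sum_ij D^ij - (N - 2) sum_i D^i, which conserves the electron
#' count exactly.  Densities are spin-traced (spatial).
#'
#' @param result an `efm_mbe` computed with `store_results = TRUE` and no
#'   dimer cutoff.
#' @return Object of class `efm_density`: cluster basis, density matrix
#'   `D`, overlap `S`, electron count, field vector.
#' @export
assemble_density <- function(result) {
  if (is.null(result$monomer_results)) {
    stop("per-subsystem results missing: rerun efm_energy with store_results")
  }
  cl <- result$cluster
  N <- result$n_monomer
  basis <- build_basis(subsystem_atoms(cl, seq_len(N)), result$basis_def)
  n <- basis$nao
  cplx <- result$treatment == "lao" && any(result$B != 0)
  D <- matrix(if (cplx) 0 + 0i else 0, n, n)
  embed <- function(D, Dsub, map) {
    D[map, map] <- D[map, map] + Dsub
    D
  }
  if (N == 1) {
    D <- spatial_density(result$monomer_results[[1]]$scf)
  } else {
    for (key in names(result$dimer_results)) {
      p <- as.integer(strsplit(key, "-")[[1]])
      map <- which(basis$ao_monomer %in% p)
      D <- embed(D, spatial_density(result$dimer_results[[key]]$scf), map)
    }
    if (length(result$pairs) != choose(N, 2)) {
      stop("density assembly requires all dimers (no cutoff)")
    }
    for (i in seq_len(N)) {
      map <- which(basis$ao_monomer == i)
      D <- embed(D, -(N - 2) * spatial_density(result$monomer_results[[i]]$scf),
                 map)
    }
  }
  S <- if (cplx) lao_integrals(basis, result$B)$S else
    one_electron_integrals(basis)$S
  nelec <- sum(vapply(cl$monomers, monomer_electrons, 1L))
  structure(list(basis = basis, D = D, S = S, nelec = nelec, B = result$B,
                 cluster = cl),
            class = "efm_density")
}

#' Electron count of an assembled density (trace with overlap)
#' @param assembly an `efm_density`.
#' @return Re tr(D S).
#' @export
density_electron_count <- function(assembly) {
  Re(.trAB(assembly$D, assembly$S))
}

#' Regular grid covering a cluster
#'
#' @param cl an `efm_cluster`.
#' @param spacing grid step (bohr).
#' @param margin padding beyond the atomic extent (bohr).
#' @return Grid spec: origin, step, and point counts per axis.
#' @export
density_grid <- function(cl, spacing = 0.4, margin = 4) {
  at <- cluster_atoms(cl)
  lo <- c(min(at$x), min(at$y), min(at$z)) - margin
  hi <- c(max(at$x), max(at$y), max(at$z)) + margin
  npt <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, step = rep(spacing, 3), n = npt)
}

.grid_points <- function(grid) {
  ax <- lapply(1:3, function(d) grid$origin[d] + grid$step[d] *
                 (seq_len(grid$n[d]) - 1))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

# evaluate rho(r) = Re sum_{mu nu} D_{mu nu} w_mu(r) conj(w_nu(r)) for a
# density matrix over (possibly London-phased) AOs, chunked over points
.density_values <- function(basis, D, B, points, chunk = 20000L) {
  n <- basis$nao
  centers <- t(vapply(basis$shells, function(s) s$center, numeric(3)))
  ncart <- vapply(basis$shells, function(s)
    as.integer((s$l + 1) * (s$l + 2) / 2), 1L)
  ao_center <- centers[rep(seq_along(basis$shells), ncart), , drop = FALSE]
  haveB <- any(B != 0)
  # per-AO London wave vector (1/2) B x C_mu; pairwise phases are gauge-free
  kao <- if (haveB) {
    cbind(0.5 * (B[2] * ao_center[, 3] - B[3] * ao_center[, 2]),
          0.5 * (B[3] * ao_center[, 1] - B[1] * ao_center[, 3]),
          0.5 * (B[1] * ao_center[, 2] - B[2] * ao_center[, 1]))
  } else NULL
  np <- nrow(points)
  out <- numeric(np)
  for (start in seq(1, np, by = chunk)) {
    idx <- start:min(start + chunk - 1, np)
    V <- ao_values(basis, points[idx, , drop = FALSE])
    if (haveB) {
      V <- V * exp(-1i * tcrossprod(points[idx, , drop = FALSE], kao))
    }
    out[idx] <- Re(rowSums((V %*% D) * Conj(V)))
  }
  out
}

#' Evaluate an assembled density on a regular grid
#'
#' @param assembly an `efm_density` (or any list with `basis`, `D`, `B`).
#' @param grid a [density_grid()] spec.
#' @return List of class `efm_density_field`: grid, values (3-d array),
#'   and the numerically integrated electron count.
#' @export
density_on_grid <- function(assembly, grid) {
  pts <- .grid_points(grid)
  rho <- .density_values(assembly$basis, assembly$D, assembly$B, pts)
  arr <- array(rho, grid$n)
  dv <- prod(grid$step)
  structure(list(grid = grid, values = arr,
                 integral = sum(rho) * dv,
                 cluster = assembly$cluster),
            class = "efm_density_field")
}

#' Difference of two density fields on the same grid
#' @param a,b `efm_density_field` objects on identical grids.
#' @return `efm_density_field` of a - b.
#' @export
density_difference <- function(a, b) {
  stopifnot(identical(a$grid$n, b$grid$n))
  structure(list(grid = a$grid, values = a$values - b$values,
                 integral = a$integral - b$integral, cluster = a$cluster),
            class = "efm_density_field")
}

#' Superposition-of-isolated-monomers density field
#'
#' Reference field for difference-density plots: the sum of the isolated
#' monomer densities evaluated on the same grid.
#'
#' @param result an `efm_mbe` with stored isolated results.
#' @param grid a [density_grid()] spec.
#' @return `efm_density_field`.
#' @export
isolated_density_field <- function(result, grid) {
  if (is.null(result$iso_results)) {
    stop("isolated results missing: rerun with include_isolated and ",
         "store_results")
  }
  pts <- .grid_points(grid)
  rho <- numeric(nrow(pts))
  for (r in result$iso_results) {
    rho <- rho + .density_values(r$basis, spatial_density(r$scf),
                                 result$B, pts)
  }
  arr <- array(rho, grid$n)
  structure(list(grid = grid, values = arr,
                 integral = sum(rho) * prod(grid$step),
                 cluster = result$cluster),
            class = "efm_density_field")
}

#' Write a density field as a Gaussian cube file
#'
#' @param field an `efm_density_field`.
#' @param path output path.
#' @param comment two comment lines (character vector length <= 2).
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, path, comment = c("electron density",
                                                "generated by efmr")) {
  g <- field$grid
  at <- cluster_atoms(field$cluster)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "")[1:2], con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(at), g$origin[1],
                     g$origin[2], g$origin[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$n[1], g$step[1], 0, 0),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$n[2], 0, g$step[2], 0),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$n[3], 0, 0, g$step[3]),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", at$Z, at$Z, at$x,
                     at$y, at$z), con)
  v <- field$values
  for (i in seq_len(g$n[1])) {
    for (j in seq_len(g$n[2])) {
      row <- v[i, j, ]
      for (s in seq(1, length(row), by = 6)) {
        writeLines(paste(sprintf("%13.5e", row[s:min(s + 5, length(row))]),
                         collapse = " "), con)
      }
    }
  }
  invisible(path)
}
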