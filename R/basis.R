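# Gaussian basis sets: Gaussian94 text input, bundled minimal sets, and
# construction of (ghost-capable) basis objects for cluster subsystems.

#' Read a Gaussian94-format basis set file
#'
#' Parses the plain-text shell blocks (`S`, `P`, `D`, ..., and combined
#' `SP`) separated by `****` markers.  `SP` blocks are split into an S and
#' a P shell sharing exponents.
#'
#' @param path file path.
#' @return Named list (by element symbol); each entry a list of shells,
#'   each shell a list with `l`, `exps`, `coefs`.  Class `efm_basis_def`.
#' @export
read_basis_g94 <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1; next }
    hd <- strsplit(lines[i], "\\s+")[[1]]
    el <- hd[1]
    i <- i + 1
    shells <- list()
    while (i <= length(lines) && lines[i] != "****") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1])
      nprim <- as.integer(sh[2])
      if (is.na(nprim)) stop("malformed basis file at line: ", lines[i])
      prim <- matrix(0, nprim, if (type == "SP") 3 else 2)
      for (k in seq_len(nprim)) {
        v <- as.numeric(gsub("[dD]", "e", strsplit(lines[i + k], "\\s+")[[1]]))
        prim[k, ] <- v
      }
      i <- i + nprim + 1
      if (type == "SP") {
        shells <- c(shells,
                    list(list(l = 0L, exps = prim[, 1], coefs = prim[, 2]),
                         list(l = 1L, exps = prim[, 1], coefs = prim[, 3])))
      } else {
        l <- lmap[type]
        if (is.na(l)) stop("unsupported shell type: ", type)
        shells <- c(shells, list(list(l = unname(l), exps = prim[, 1],
                                      coefs = prim[, 2])))
      }
    }
    out[[el]] <- shells
  }
  structure(out, class = "efm_basis_def")
}

#' Load a bundled basis set by name
#'
#' `"sto-3g"` and `"6-31g"` are shipped with the package (H and O, the
#' elements of the bundled water workflows); any other name is treated as
#' a path to a user-supplied Gaussian94 file.
#'
#' @param name basis name or file path.
#' @return An `efm_basis_def` (see [read_basis_g94()]).
#' @export
load_basis <- function(name) {
  if (inherits(name, "efm_basis_def")) return(name)
  lname <- tolower(name)
  pkgfile <- system.file("extdata", "basis", paste0(lname, ".gbs"),
                         package = "efmr")
  path <- if (nzchar(pkgfile)) pkgfile else name
  if (!file.exists(path)) {
    stop("basis set '", name, "' is not bundled and no such file exists")
  }
  read_basis_g94(path)
}

#' Build a basis for a set of atoms
#'
#' @param atoms data frame with columns element, Z, x, y, z (bohr) and
#'   logical `ghost`; ghost atoms carry basis functions but no nuclear
#'   charge.  A `monomer` column, when present, is propagated to the AO
#'   map so densities can be partitioned by monomer.
#' @param basis_def an `efm_basis_def` or a name accepted by
#'   [load_basis()].
#' @return An `efm_ao_basis`: shells with owning-atom index, the atom
#'   table, AO count and per-AO atom/monomer maps.  AO order is
#'   deterministic: atoms in input order, shells in basis-file order,
#'   Cartesian components lx >= ly >= lz lexicographic.
#' @export
build_basis <- function(atoms, basis_def) {
  basis_def <- load_basis(basis_def)
  if (is.null(atoms$ghost)) atoms$ghost <- FALSE
  shells <- list()
  ao_atom <- integer(0)
  for (ia in seq_len(nrow(atoms))) {
    el <- atoms$element[ia]
    def <- basis_def[[el]]
    if (is.null(def)) stop("basis set has no entry for element ", el)
    for (sh in def) {
      shells[[length(shells) + 1]] <- list(
        center = as.numeric(atoms[ia, c("x", "y", "z")]),
        l = sh$l, exps = sh$exps, coefs = sh$coefs, atom = ia)
      ncart <- (sh$l + 1) * (sh$l + 2) / 2
      ao_atom <- c(ao_atom, rep(ia, ncart))
    }
  }
  ao_monomer <- if (!is.null(atoms$monomer)) atoms$monomer[ao_atom] else NULL
  structure(list(shells = shells, atoms = atoms, nao = length(ao_atom),
                 ao_atom = ao_atom, ao_monomer = ao_monomer),
            class = "efm_ao_basis")
}

#' @export
print.efm_ao_basis <- function(x, ...) {
  cat(sprintf("<efm_ao_basis> %d shells, %d AOs, %d atoms (%d ghost)\n",
              length(x$shells), x$nao, nrow(x$atoms), sum(x$atoms$ghost)))
  invisible(x)
}

#' Atom table for a cluster subsystem, optionally ghost-augmented
#'
#' Real atoms come from the monomers in `real`; monomers listed in `ghost`
#' contribute basis functions only (counterpoise partners).
#'
#' @param cl an `efm_cluster`.
#' @param real monomer indices whose atoms are physical.
#' @param ghost monomer indices whose atoms are ghosts (disjoint from
#'   `real`).
#' @return Atom data frame suitable for [build_basis()].
#' @export
subsystem_atoms <- function(cl, real, ghost = integer(0)) {
  if (length(intersect(real, ghost)) > 0) {
    stop("a monomer cannot be both real and ghost")
  }
  pick <- function(idx, is_ghost) {
    do.call(rbind, lapply(idx, function(i) {
      m <- cl$monomers[[i]]
      data.frame(element = m$element, Z = m$Z, x = m$xyz[, 1],
                 y = m$xyz[, 2], z = m$xyz[, 3], monomer = i,
                 ghost = is_ghost, stringsAsFactors = FALSE)
    }))
  }
  at <- rbind(pick(sort(real), FALSE),
              if (length(ghost) > 0) pick(sort(ghost), TRUE))
  rownames(at) <- NULL
  at
}

#' Ghost-augmented basis for a monomer inside a larger subsystem
#'
#' The basis functions of every atom of `sub` are present; atoms outside
#' `mono` are ghosts (no nuclear charge, no nuclear repulsion).  Used by
#' the embedded counterpoise correction, where monomer energies are
#' re-evaluated in the basis of the dimer they belong to.
#'
#' @param cl an `efm_cluster`.
#' @param sub monomer indices of the enclosing subsystem.
#' @param mono the monomer (single index) whose electrons/nuclei are real;
#'   must be contained in `sub`.
#' @return An `efm_ao_basis`... see [build_basis()].
#' @export
build_ghost_basis <- function(cl, sub, mono, basis_def) {
  if (!(mono %in% sub)) stop("monomer ", mono, " is not part of subsystem")
  build_basis(subsystem_atoms(cl, real = mono, ghost = setdiff(sub, mono)),
              basis_def)
}

# Electrons carried by the real (non-ghost) atoms of a basis.
basis_electrons <- function(basis) {
  as.integer(sum(basis$atoms$Z[!basis$atoms$ghost]))
}
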