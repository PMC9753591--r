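# Geometry and fragment data model: monomers, clusters, XYZ input/output,
# covalent-radius fragment detection and the synthetic water-cluster
# generator.  Coordinates are bohr internally; XYZ files are angstrom.

#' Create a monomer
#'
#' A monomer is one covalently bound molecule of a cluster: element symbols,
#' nuclear charges and positions.  Only neutral monomers are accepted: the
#' dipole embedding drops the monopole term of the multipole expansion,
#' which is only exact when every monomer carries zero net charge.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of positions in bohr.
#' @param charge net charge; must be 0.
#' @return An object of class `efm_monomer`.
#' @export
monomer <- function(element, xyz, charge = 0L) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(element) == nrow(xyz))
  if (!all(is.finite(xyz))) stop("monomer positions must be finite")
  if (charge != 0L) {
    stop("charged monomers are not supported: the dipole embedding ",
         "potential assumes neutral monomers (vanishing monopole term)")
  }
  Z <- element_number(element)
  structure(list(element = as.character(element), Z = Z, xyz = xyz,
                 charge = 0L),
            class = "efm_monomer")
}

#' Number of electrons in a monomer
#' @param m an `efm_monomer`.
#' @return Integer electron count (sum of nuclear charges minus net charge).
#' @export
monomer_electrons <- function(m) {
  as.integer(sum(m$Z) - m$charge)
}

#' Create a cluster
#'
#' @param monomers list of [monomer()] objects with pairwise disjoint atoms.
#' @param B uniform external magnetic field vector, in units of B0
#'   (2.3505e5 T).
#' @param gauge_origin gauge origin in bohr for the common-gauge-origin
#'   field treatment; default (`NULL`) is the nuclear-charge centroid of
#'   the whole cluster.
#' @param title free-form metadata string.
#' @return An object of class `efm_cluster`.
#' @export
cluster <- function(monomers, B = c(0, 0, 0), gauge_origin = NULL,
                    title = "") {
  stopifnot(length(monomers) >= 1)
  lapply(monomers, function(m) stopifnot(inherits(m, "efm_monomer")))
  stopifnot(length(B) == 3, all(is.finite(B)))
  structure(list(monomers = monomers, B = as.numeric(B),
                 gauge_origin = gauge_origin, title = title),
            class = "efm_cluster")
}

#' @export
print.efm_cluster <- function(x, ...) {
  nat <- sum(vapply(x$monomers, function(m) nrow(m$xyz), 1L))
  cat(sprintf("<efm_cluster> %d monomer(s), %d atoms", length(x$monomers),
              nat))
  if (any(x$B != 0)) cat(sprintf(", |B| = %.4g B0", sqrt(sum(x$B^2))))
  if (nzchar(x$title)) cat(" -- ", x$title, sep = "")
  cat("\n")
  invisible(x)
}

#' All atoms of a cluster as a data frame
#'
#' @param cl an `efm_cluster`.
#' @return data frame with element, Z, x, y, z (bohr) and monomer index
#'   (1-based).
#' @export
cluster_atoms <- function(cl) {
  do.call(rbind, lapply(seq_along(cl$monomers), function(i) {
    m <- cl$monomers[[i]]
    data.frame(element = m$element, Z = m$Z, x = m$xyz[, 1], y = m$xyz[, 2],
               z = m$xyz[, 3], monomer = i, stringsAsFactors = FALSE)
  }))
}

#' Nuclear charge center of a monomer
#'
#' The charge-weighted centroid \eqn{R_j = \sum_J Z_J R_J / \sum_J Z_J},
#' the point about which the nuclear dipole moment of the monomer vanishes;
#' the embedding dipole site of each monomer is placed here.
#'
#' @param m an `efm_monomer`.
#' @return Length-3 position in bohr.
#' @export
nuclear_charge_center <- function(m) {
  as.numeric(crossprod(m$xyz, m$Z) / sum(m$Z))
}

#' Default gauge origin of a cluster (nuclear-charge centroid)
#' @param cl an `efm_cluster`.
#' @return Length-3 position in bohr.
#' @export
cluster_gauge_origin <- function(cl) {
  if (!is.null(cl$gauge_origin)) return(as.numeric(cl$gauge_origin))
  at <- cluster_atoms(cl)
  as.numeric(c(sum(at$Z * at$x), sum(at$Z * at$y), sum(at$Z * at$z)) /
               sum(at$Z))
}

#' Partition atoms into molecules by covalent-radius bond graph
#'
#' Two atoms are bonded when their distance does not exceed `bond_scale`
#' times the sum of their covalent radii; monomers are the connected
#' components of the resulting graph, returned in order of their lowest
#' atom index.
#'
#' @param atoms data frame with columns element, x, y, z (bohr).
#' @param bond_scale multiplier on the covalent-radius sum (default 1.2).
#' @return Integer vector assigning each atom a 1-based component index.
#' @export
detect_fragments <- function(atoms, bond_scale = 1.2) {
  n <- nrow(atoms)
  stopifnot(n >= 1)
  rad <- .covalent_radius[atoms$element] / angstrom_per_bohr
  if (anyNA(rad)) stop("no covalent radius for element(s): ",
                       paste(unique(atoms$element[is.na(rad)]),
                             collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  # union-find over bonded pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
      cut <- bond_scale * (rad[i] + rad[(i + 1):n])
      for (j in which(d <= cut)) {
        a <- find(i); b <- find(i + j)
        if (a != b) parent[b] <- a
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Read a cluster from an XYZ file
#'
#' Standard XYZ (angstrom) or extended XYZ where fragments are separated by
#' blank lines within the atom block.  The comment line may carry a field
#' tag `B= bx by bz` (units of B0).
#'
#' @param path file path.
#' @param fragmentation `"blank"` uses blank-line-delimited fragment
#'   blocks (a file without blank lines is a single fragment); `"auto"`
#'   partitions atoms by the covalent-radius bond graph of
#'   [detect_fragments()].
#' @param bond_scale passed to [detect_fragments()] for `"auto"`.
#' @return An `efm_cluster`.
#' @export
read_cluster_xyz <- function(path, fragmentation = c("blank", "auto"),
                             bond_scale = 1.2) {
  fragmentation <- match.arg(fragmentation)
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ (", path, "): fewer than 2 lines")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("malformed XYZ (", path, ") line 1: expected atom count")
  comment <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[-(1:2)]
  atoms <- list()
  frag_of <- integer(0)
  frag <- 1L
  ln <- 2L
  for (l in body) {
    ln <- ln + 1L
    if (!nzchar(trimws(l))) {
      if (length(atoms) > 0 && length(frag_of) > 0 &&
          frag_of[length(frag_of)] == frag) frag <- frag + 1L
      next
    }
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 4) stop("malformed XYZ (", path, ") line ", ln,
                              ": expected 'El x y z'")
    pos <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(pos)) stop("malformed XYZ (", path, ") line ", ln,
                         ": non-numeric coordinate")
    atoms[[length(atoms) + 1]] <- list(el = tok[1], pos = pos)
    frag_of <- c(frag_of, frag)
    if (length(atoms) == nat) break
  }
  if (length(atoms) != nat) {
    stop("malformed XYZ (", path, "): expected ", nat, " atoms, found ",
         length(atoms))
  }
  df <- data.frame(element = vapply(atoms, function(a) a$el, ""),
                   x = vapply(atoms, function(a) a$pos[1], 0) / angstrom_per_bohr,
                   y = vapply(atoms, function(a) a$pos[2], 0) / angstrom_per_bohr,
                   z = vapply(atoms, function(a) a$pos[3], 0) / angstrom_per_bohr,
                   stringsAsFactors = FALSE)
  part <- if (fragmentation == "auto") {
    detect_fragments(df, bond_scale)
  } else {
    match(frag_of, unique(frag_of))
  }
  B <- c(0, 0, 0)
  bpat <- "B=\\s*(-?[0-9.eE+-]+)\\s+(-?[0-9.eE+-]+)\\s+(-?[0-9.eE+-]+)"
  bm <- regmatches(comment, regexec(bpat, comment))[[1]]
  if (length(bm) == 4) {
    B <- as.numeric(bm[2:4])
    comment <- sub(bpat, "", comment)  # tag is re-added on write
  }
  mons <- lapply(sort(unique(part)), function(k) {
    idx <- which(part == k)
    monomer(df$element[idx], as.matrix(df[idx, c("x", "y", "z")]))
  })
  cluster(mons, B = B, title = trimws(comment))
}

#' Write a cluster to an (extended) XYZ file
#'
#' Fragments are separated by blank lines; coordinates in angstrom.  A
#' nonzero field vector is recorded as a `B=` tag on the comment line.
#'
#' @param cl an `efm_cluster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_xyz <- function(cl, path) {
  at <- cluster_atoms(cl)
  hdr <- sprintf("%d", nrow(at))
  cmt <- cl$title
  if (any(cl$B != 0)) {
    cmt <- trimws(paste(cmt, sprintf("B= %.10g %.10g %.10g", cl$B[1],
                                     cl$B[2], cl$B[3])))
  }
  out <- c(hdr, cmt)
  for (i in seq_along(cl$monomers)) {
    m <- cl$monomers[[i]]
    out <- c(out, sprintf("%-2s %18.12f %18.12f %18.12f", m$element,
                          m$xyz[, 1] * angstrom_per_bohr,
                          m$xyz[, 2] * angstrom_per_bohr,
                          m$xyz[, 3] * angstrom_per_bohr))
    if (i < length(cl$monomers)) out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Rigid water monomer in its local frame: O at origin, H atoms in the xz
# plane.  Geometry matches the rigid TIP3P model used to generate the
# clusters this generator emulates.
.water_template <- function(r_OH = 0.9572 / angstrom_per_bohr,
                            theta = 104.52 * pi / 180) {
  h1 <- c(r_OH * sin(theta / 2), 0, r_OH * cos(theta / 2))
  h2 <- c(-r_OH * sin(theta / 2), 0, r_OH * cos(theta / 2))
  rbind(O = c(0, 0, 0), H1 = h1, H2 = h2)
}

# Uniform random rotation matrix from a unit quaternion.
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic water cluster
#'
#' Places `n` rigid water monomers (gas-phase geometry r_OH = 0.9572
#' angstrom, H-O-H angle 104.52 degrees, as fixed by rigid three-site water
#' models) with uniformly random positions and orientations inside a cubic
#' box, rejecting placements whose O-O distance to any placed monomer falls
#' below `min_OO`.  This emulates a liquid-like droplet snapshot (the
#' physical route would be a molecular-dynamics snapshot, which is out of
#' scope here); the default box edge packs the monomers at liquid-water
#' density, so neighbouring molecules sit at hydrogen-bonding distances
#' as they do in an equilibrated droplet.
#'
#' @param n number of water monomers.
#' @param box cubic box edge length in bohr; the default scales liquid
#'   water's 30 cubic angstrom per molecule to `n` molecules.
#' @param min_OO minimum allowed O-O distance in bohr (default 4.7, about
#'   2.5 angstrom).
#' @param seed integer seed; the generator is bit-reproducible per seed.
#' @param max_retry placement attempts per monomer before giving up.
#' @return An `efm_cluster` of `n` water monomers.
#' @export
generate_water_cluster <- function(n, box = NULL, min_OO = 4.7,
                                   seed = 1L, max_retry = 5000L) {
  stopifnot(n >= 1)
  if (is.null(box)) box <- (30 * n)^(1 / 3) / angstrom_per_bohr
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  tmpl <- .water_template()
  opos <- matrix(0, 0, 3)
  mons <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      o <- runif(3, 0, box)
      if (nrow(opos) == 0 ||
          min(sqrt(colSums((t(opos) - o)^2))) >= min_OO) {
        R <- .random_rotation()
        xyz <- sweep(tmpl %*% t(R), 2, -o)
        mons[[i]] <- monomer(c("O", "H", "H"), xyz)
        opos <- rbind(opos, o)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place monomer %d of %d: box %.3g bohr",
                          " too small for min_OO %.3g bohr"), i, n, box,
                   min_OO))
    }
  }
  cluster(mons, title = sprintf("synthetic water cluster n=%d seed=%d", n,
                                as.integer(seed)))
}

#' Subsystem of a cluster
#'
#' @param indices 1-based monomer indices (unique); size 1 is a monomer,
#'   size 2 a dimer.
#' @param cl the owning `efm_cluster` (for validation).
#' @return Sorted integer vector of class `efm_subsystem`.
#' @export
subsystem <- function(indices, cl = NULL) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) != length(indices)) stop("subsystem indices must be unique")
  if (!is.null(cl) && (any(idx < 1) || any(idx > length(cl$monomers)))) {
    stop("subsystem indices out of range for cluster")
  }
  structure(idx, class = "efm_subsystem")
}
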