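# Many-body expansion assembly: exactness oracles, telescoping,
# counterpoise limits, extensivity, density assembly and interaction
# energies.

test_that("full-order expansion equals the conventional energy (oracle)", {
  # the master oracle of the expansion machinery: at k = N the
  # inclusion-exclusion assembly must telescope to the supersystem SCF
  cl2 <- water_dimer()
  mb2 <- mbe_full_order(cl2, "sto-3g", k = 2)
  cv2 <- conventional_energy(cl2, "sto-3g")
  expect_equal(mb2$energy, cv2$energy, tolerance = 1e-7)
  cl3 <- water_trimer()
  mb3 <- mbe_full_order(cl3, "sto-3g", k = 3)
  cv3 <- conventional_energy(cl3, "sto-3g")
  expect_equal(mb3$energy, cv3$energy, tolerance = 1e-7)
  expect_error(mbe_full_order(cl2, "sto-3g", k = 3), "exceeds")
})

test_that("expansion orders decompose as direct inclusion-exclusion", {
  cl3 <- water_trimer()
  mb1 <- mbe_full_order(cl3, "sto-3g", k = 1)
  mb2 <- mbe_full_order(cl3, "sto-3g", k = 2)
  mb3 <- mbe_full_order(cl3, "sto-3g", k = 3)
  E <- mb3$subsystem_energies
  # k = 1 is the sum of isolated monomer energies
  expect_equal(mb1$energy, E[["1"]] + E[["2"]] + E[["3"]],
               tolerance = 1e-12)
  # third-order increment by brute force
  third <- E[["1-2-3"]] -
    (E[["1-2"]] + E[["1-3"]] + E[["2-3"]]) +
    (E[["1"]] + E[["2"]] + E[["3"]])
  expect_equal(mb3$energy - mb2$energy, third, tolerance = 1e-10)
})

test_that("the embedded pair expansion telescopes exactly for a dimer", {
  cl <- water_dimer()
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb)
  cv <- conventional_energy(cl, "sto-3g")
  expect_equal(res$total, cv$energy, tolerance = 1e-9)
  # same statement with correlation
  res_mp2 <- efm_energy(cl, "sto-3g", field = emb, method = "hf+mp2")
  cv_mp2 <- conventional_energy(cl, "sto-3g", method = "hf+mp2")
  expect_equal(res_mp2$total, cv_mp2$energy, tolerance = 1e-8)
})

test_that("bookkeeping identity holds to machine precision", {
  cl <- water_trimer()
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb)
  expect_equal(res$total, sum(res$E_monomer) + sum(res$delta),
               tolerance = 1e-12)
  expect_equal(unname(res$delta["1-2"]),
               unname(res$E_dimer["1-2"] - res$E_monomer[1] -
                        res$E_monomer[2]),
               tolerance = 1e-12)
})

test_that("noninteracting monomers give vanishing pair corrections", {
  cl <- cluster(list(water_monomer(), water_monomer(c(500, 0, 0)),
                     water_monomer(c(0, 500, 0))))
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb, counterpoise = TRUE)
  expect_true(all(abs(res$delta) < 1e-6))
  expect_equal(res$total, sum(res$E_iso), tolerance = 1e-6)
  expect_equal(mean_interaction_energy(res), 0, tolerance = 1e-3)
  # counterpoise correction dies off at separation
  expect_lt(abs(res$cp_total - res$total), 1e-7)
})

test_that("energies are extensive and invariant to monomer relabeling", {
  cl <- water_dimer()
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb, include_isolated = FALSE)
  # duplicate the cluster 1000 bohr away: energy doubles
  clx <- cluster(c(cl$monomers,
                   lapply(cl$monomers, function(m)
                     monomer(m$element,
                             m$xyz + matrix(rep(c(1000, 0, 0), each = 3),
                                            3)))))
  embx <- converge_embedding(clx, "sto-3g")
  resx <- efm_energy(clx, "sto-3g", field = embx,
                     include_isolated = FALSE)
  expect_equal(resx$total, 2 * res$total, tolerance = 1e-6)
  # permutation of monomer labels
  cl3 <- water_trimer()
  e3 <- converge_embedding(cl3, "sto-3g")
  r3 <- efm_energy(cl3, "sto-3g", field = e3, include_isolated = FALSE)
  clp <- cluster(cl3$monomers[c(3, 1, 2)])
  ep <- converge_embedding(clp, "sto-3g")
  rp <- efm_energy(clp, "sto-3g", field = ep, include_isolated = FALSE)
  expect_equal(rp$total, r3$total, tolerance = 1e-10)
})

test_that("counterpoise pieces behave variationally at contact", {
  cl <- water_dimer()
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb, counterpoise = TRUE)
  # each monomer-in-dimer-basis energy (same embedding exclusion) lies
  # below the same monomer evaluated in its own basis, so at equal
  # exclusions the counterpoise-corrected pair binding is weaker
  e_own <- numeric(2)
  for (i in 1:2) {
    ch <- field_for_subsystem(emb, c(1, 2))
    e_own[i] <- scf_solve(monomer_basis(cl, i), charges = ch)$energy
    expect_lte(res$cp_terms[["1-2"]][i], e_own[i] + 1e-10)
  }
  d_cp <- unname(res$E_dimer["1-2"] - sum(res$cp_terms[["1-2"]]))
  expect_gte(d_cp, unname(res$E_dimer["1-2"]) - sum(e_own))
})

test_that("assembled densities conserve electrons for N = 1, 2, 3", {
  for (cl in list(cluster(list(water_monomer())), water_dimer(),
                  water_trimer())) {
    emb <- converge_embedding(cl, "sto-3g")
    res <- efm_energy(cl, "sto-3g", field = emb)
    asm <- assemble_density(res)
    nel <- 10 * length(cl$monomers)
    expect_equal(density_electron_count(asm), nel, tolerance = 1e-6)
  }
})

test_that("N = 2 assembled density equals the conventional dimer density", {
  cl <- water_dimer()
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb)
  asm <- assemble_density(res)
  cv <- conventional_energy(cl, "sto-3g")
  expect_lt(max(abs(asm$D - spatial_density(cv$scf))), 1e-6)
})

test_that("grid densities integrate to the electron count (smooth case)", {
  # H2 pair: no sharp core density, so a uniform grid integrates well
  cl <- cluster(list(h2_monomer(), h2_monomer(c(8, 0, 0))))
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb)
  asm <- assemble_density(res)
  g <- density_grid(cl, spacing = 0.25, margin = 5)
  f <- density_on_grid(asm, g)
  expect_equal(f$integral, 4, tolerance = 0.5 / 100 * 4)
  # difference density of noninteracting monomers vanishes everywhere
  clf <- cluster(list(h2_monomer(), h2_monomer(c(300, 0, 0))))
  ef <- converge_embedding(clf, "sto-3g")
  rf <- efm_energy(clf, "sto-3g", field = ef)
  af <- assemble_density(rf)
  gf <- density_grid(cluster(list(clf$monomers[[1]])), spacing = 0.3,
                     margin = 4)
  fa <- density_on_grid(af, gf)
  fi <- isolated_density_field(rf, gf)
  expect_lt(max(abs(density_difference(fa, fi)$values)), 1e-6)
})

test_that("field-on minus field-off trimer density integrates to zero", {
  cl0 <- water_trimer()
  clB <- water_trimer(B = c(0, 0, 0.1))
  g <- density_grid(cl0, spacing = 0.45, margin = 3.5)
  run <- function(cl) {
    emb <- converge_embedding(cl, "sto-3g", treatment = "auto")
    res <- efm_energy(cl, "sto-3g", field = emb, treatment = "auto")
    density_on_grid(assemble_density(res), g)
  }
  f0 <- run(cl0); fB <- run(clB)
  dd <- density_difference(fB, f0)
  # equal electron counts: the difference integrates to ~0 even where the
  # absolute quadrature of the sharp cores is crude
  expect_lt(abs(dd$integral), 1e-3)
  # cube output round-trip sanity
  p <- tempfile(fileext = ".cube")
  write_cube(dd, p)
  lines <- readLines(p)
  expect_equal(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1]), 9)
})

test_that("mean interaction energy requires matching references", {
  cl <- water_dimer()
  emb <- converge_embedding(cl, "sto-3g")
  res <- efm_energy(cl, "sto-3g", field = emb, include_isolated = FALSE)
  expect_error(mean_interaction_energy(res), "include_isolated")
  res2 <- efm_energy(cl, "sto-3g", field = emb)
  mie <- mean_interaction_energy(res2)
  expect_lt(mie, 0)  # hydrogen-bonded dimer is bound
  expect_equal(interaction_energy(res2), 2 * mie, tolerance = 1e-12)
})
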