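tetra_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
  sqrt(3)

test_that("initial estimate: centroid for 4+, mirrored pair for 3", {
  pts4 <- lapply(1:4, function(i) tetra_dirs[i, ] * 2.15 + c(1, 2, 3))
  est <- initial_zinc_estimate(pts4)
  expect_length(est, 1L)
  expect_coord_equal(est[[1]], c(1, 2, 3), tol = 1e-9)

  # equilateral triangle in z = 0 centred at origin
  phi <- c(90, 210, 330) * pi / 180
  pts3 <- lapply(phi, function(a) c(cos(a), sin(a), 0))
  est3 <- initial_zinc_estimate(pts3, offset = 1.5)
  expect_length(est3, 2L)
  expect_coord_equal(est3[[1]], c(0, 0, 1.5), tol = 1e-9)
  expect_coord_equal(est3[[2]], c(0, 0, -1.5), tol = 1e-9)

  coll <- list(c(0, 0, 0), c(1, 0, 0), c(2, 1e-8, 0))
  expect_error(initial_zinc_estimate(coll), "collinear")
})

test_that("atom selection picks the nearest listed atom, ties break on name", {
  his <- residue_from_atoms(rbind(
    atom_df("A", 1, "HIS", "ND1", "N", c(2.1, 0, 0)),
    atom_df("A", 1, "HIS", "NE2", "N", c(4.0, 0, 0))))
  ch <- select_binding_atoms(list(his), c(0, 0, 0))
  expect_equal(ch[[1]]$atom, "ND1")
  # exact tie -> ND1 (lexicographic)
  his_tie <- residue_from_atoms(rbind(
    atom_df("A", 1, "HIS", "NE2", "N", c(0, 2, 0)),
    atom_df("A", 1, "HIS", "ND1", "N", c(2, 0, 0))))
  expect_equal(select_binding_atoms(list(his_tie), c(0, 0, 0))[[1]]$atom,
               "ND1")
  # oracle: matches brute-force nearest over both atoms on random geometry
  set.seed(31)
  for (rep in 1:30) {
    p1 <- runif(3, -5, 5); p2 <- runif(3, -5, 5); q <- runif(3, -5, 5)
    glu <- residue_from_atoms(rbind(
      atom_df("A", 1, "GLU", "OE1", "O", p1),
      atom_df("A", 1, "GLU", "OE2", "O", p2)))
    got <- select_binding_atoms(list(glu), q)[[1]]$atom
    want <- if (sqrt(sum((p1 - q)^2)) <= sqrt(sum((p2 - q)^2))) "OE1" else
      "OE2"
    expect_equal(got, want)
  }
  # Cys ideal distance is 2.32, others 2.15
  cys <- residue_from_atoms(atom_df("A", 2, "CYS", "SG", "S", c(1, 1, 1)))
  expect_equal(select_binding_atoms(list(cys), c(0, 0, 0))[[1]]$d_ideal, 2.32)
  expect_equal(ch[[1]]$d_ideal, 2.15)
})

make_chosen <- function(coords, ideals) {
  lapply(seq_along(ideals), function(i)
    list(res_type = "HIS", atom = "NE2", coord = coords[i, ],
         d_ideal = ideals[i]))
}

test_that("LM refinement solves exactly solvable geometries", {
  # regular tetrahedron with circumradius 2.15: centre is the exact optimum
  coords <- tetra_dirs * 2.15
  pl <- refine_zinc_position(make_chosen(coords, rep(2.15, 4)),
                             start = c(0.3, -0.2, 0.1))
  expect_coord_equal(pl$zinc_coord, c(0, 0, 0), tol = 1e-4)
  expect_lt(pl$drmsd, 1e-6)
  expect_true(pl$converged)

  # equilateral triangle, side 3.3: closed-form apex height
  r <- 3.3 / sqrt(3)
  h <- sqrt(2.15^2 - r^2)
  phi <- c(90, 210, 330) * pi / 180
  tri <- t(vapply(phi, function(a) r * c(cos(a), sin(a), 0), c(0, 0, 0)))
  pl3 <- refine_zinc_position(make_chosen(tri, rep(2.15, 3)),
                              start = c(0, 0, 1.5))
  expect_coord_equal(pl3$zinc_coord, c(0, 0, h), tol = 1e-3)
  expect_lt(pl3$drmsd, 1e-6)

  # 1-D brute force over the symmetry axis agrees
  zs <- seq(0.2, 2, by = 1e-4)
  obj <- vapply(zs, function(z)
    sum((sqrt(r^2 + z^2) - 2.15)^2) * 3, 0)
  expect_equal(zs[which.min(obj)], h, tolerance = 1e-3)
})

test_that("LM objective matches a dense grid oracle on random sites", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:4, 1)
    dirs <- matrix(rnorm(3 * n), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    coords <- dirs * runif(n, 1.8, 2.6)
    ideals <- ifelse(runif(n) < 0.25, 2.32, 2.15)
    pl <- lm_placement(coords, ideals)
    oracle <- grid_search_zinc(coords, ideals, colMeans(coords))
    expect_lte(pl$objective, oracle$obj + 1e-9)
  }
})

test_that("dRMSD is invariant under global rotation/translation", {
  set.seed(51)
  coords <- matrix(rnorm(12, sd = 2), ncol = 3)
  ideals <- rep(2.15, 4)
  pl <- refine_zinc_position(make_chosen(coords, ideals), colMeans(coords))
  R <- znsight:::.random_rotation()
  t0 <- c(5, -3, 2)
  coords2 <- coords %*% t(R) + matrix(t0, 4, 3, byrow = TRUE)
  pl2 <- refine_zinc_position(make_chosen(coords2, ideals),
                              as.numeric(colMeans(coords2)))
  expect_equal(pl$drmsd, pl2$drmsd, tolerance = 1e-6)
})

test_that("imidazole angles are definitional on constructed geometry", {
  st <- make_ideal_site(c("HIS", "HIS", "GLU"))
  his <- Filter(function(r) r$res_type == "HIS",
                extract_binding_residues(st))[[1]]
  zinc <- attr(st, "true_zinc")
  ang <- imidazole_angles(his, zinc, "NE2")
  expect_lt(ang$alpha, 1e-6)
  expect_lt(ang$beta, 1e-6)

  # zinc along the plane normal from N -> alpha = 90
  ring <- lapply(c("CG", "ND1", "CD2", "CE1", "NE2"),
                 function(nm) znsight:::.atom_coord(his, nm))
  R <- do.call(rbind, ring)
  n <- svd(sweep(R, 2, colMeans(R)))$v[, 3]
  N <- znsight:::.atom_coord(his, "NE2")
  ang90 <- imidazole_angles(his, N + 2.15 * n, "NE2")
  expect_equal(ang90$alpha, 90, tolerance = 1e-6)

  # explicit 20-degree out-of-plane elevation of the ideal direction
  m <- (znsight:::.atom_coord(his, "CD2") +
          znsight:::.atom_coord(his, "CE1")) / 2
  axis_dir <- (N - m) / sqrt(sum((N - m)^2))
  dir20 <- cos(20 * pi / 180) * axis_dir + sin(20 * pi / 180) * n
  ang20 <- imidazole_angles(his, N + 2.15 * dir20, "NE2")
  expect_equal(ang20$alpha, 20, tolerance = 1e-6)
  expect_lt(ang20$beta, 1e-6)

  no_ring <- residue_from_atoms(atom_df("A", 1, "HIS", "NE2", "N", c(0, 0, 0)))
  expect_error(imidazole_angles(no_ring, c(1, 1, 1)), "ring atom")
})

test_that("three-residue side choice: His score wins, ties and no-His to A", {
  pa <- list(zinc_coord = c(0, 0, 1), side = "n/a")
  pb <- list(zinc_coord = c(0, 0, -1), side = "n/a")
  expect_equal(choose_three_residue_side(list(pa, pb), c(10, 3))$side, "B")
  expect_equal(choose_three_residue_side(list(pa, pb), c(3, 10))$side, "A")
  expect_equal(choose_three_residue_side(list(pa, pb), c(5, 5))$side, "A")
  expect_equal(choose_three_residue_side(list(pa, pb))$side, "A")
})

test_that("superposition RMSD: invariances and displaced-atom oracle", {
  set.seed(61)
  A <- matrix(rnorm(9, sd = 2), ncol = 3)
  expect_lt(superimpose_rmsd(A, A), 1e-9)
  R <- znsight:::.random_rotation()
  B <- A %*% t(R) + matrix(c(1, 2, 3), 3, 3, byrow = TRUE)
  expect_lt(superimpose_rmsd(A, B), 1e-6)
  # symmetry
  C <- A + matrix(rnorm(9, sd = 0.3), ncol = 3)
  expect_equal(superimpose_rmsd(A, C), superimpose_rmsd(C, A),
               tolerance = 1e-9)
  # one atom displaced 0.3 in a 3-atom site: optimal-fit RMSD < 0.3/sqrt(3),
  # and equals a brute-force permutation + Kabsch oracle
  types <- c("HIS", "HIS", "GLU")
  D <- A; D[1, ] <- D[1, ] + c(0.3, 0, 0)
  got <- superimpose_rmsd(A, D, types, types)
  naive <- 0.3 / sqrt(3)
  expect_lte(got, naive + 1e-9)
  perms <- list(c(1, 2, 3), c(2, 1, 3))  # HIS slots interchangeable
  oracle <- min(vapply(perms, function(p)
    znsight:::.kabsch_rmsd(A, D[p, ]), 0))
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_error(superimpose_rmsd(A, D, types, c("CYS", "HIS", "GLU")),
               "multisets differ")
})

test_that("rotamer sampling recovers a twisted His and never worsens score", {
  fix <- shared_fixture()
  for (twist in c(30, 45, 60)) {
    st <- make_ideal_site(c("HIS", "HIS", "GLU"), his_twist = twist)
    res <- extract_binding_residues(st)
    bps <- lapply(res, `[[`, "bp")
    starts <- initial_zinc_estimate(bps)
    chosen <- select_binding_atoms(res, starts[[1]])
    pl <- refine_zinc_position(chosen, starts[[1]])
    ang0 <- znsight:::.site_his_angles(res, chosen, pl$zinc_coord)
    sc0 <- his_angles_score(vapply(ang0, `[[`, 0, "alpha"),
                            vapply(ang0, `[[`, 0, "beta"))
    rs <- sample_his_rotamers(res, pl)
    expect_lt(rs$score, sc0)                       # strict improvement
    alphas <- vapply(rs$angles, `[[`, 0, "alpha")
    expect_lt(max(alphas), 15 + 1e-6)              # within one 15-deg step
  }
  # already-ideal configuration: unchanged, early stop
  st0 <- make_ideal_site(c("HIS", "HIS", "GLU"))
  res0 <- extract_binding_residues(st0)
  starts0 <- initial_zinc_estimate(lapply(res0, `[[`, "bp"))
  ch0 <- select_binding_atoms(res0, starts0[[1]])
  pl0 <- refine_zinc_position(ch0, starts0[[1]])
  rs0 <- sample_his_rotamers(res0, pl0)
  expect_lt(rs0$score, 1e-3)
  # 2-His site: evaluation count bounded by the distinct state count
  expect_lte(rs0$n_evaluations, 25^2)
  # no-His site: identity pass-through
  stn <- make_ideal_site(c("ASP", "GLU", "CYS"))
  resn <- extract_binding_residues(stn)
  startsn <- initial_zinc_estimate(lapply(resn, `[[`, "bp"))
  chn <- select_binding_atoms(resn, startsn[[1]])
  pln <- refine_zinc_position(chn, startsn[[1]])
  rsn <- sample_his_rotamers(resn, pln)
  expect_identical(rsn$n_evaluations, 0L)
  expect_equal(rsn$placement$zinc_coord, pln$zinc_coord)
})

test_that("mirror placements of a symmetric 3-residue site share dRMSD", {
  st <- make_ideal_site(c("ASP", "GLU", "CYS"))
  res <- extract_binding_residues(st)
  starts <- initial_zinc_estimate(lapply(res, `[[`, "bp"))
  pls <- lapply(starts, function(s0)
    refine_zinc_position(select_binding_atoms(res, s0), s0))
  expect_equal(pls[[1]]$drmsd, pls[[2]]$drmsd, tolerance = 1e-6)
})
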