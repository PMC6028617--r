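test_that("identity follows the documented internal-gap convention", {
  expect_equal(global_align("MKVL", "MKVL")$identity, 100)
  a <- global_align("ACD", "AD")
  expect_equal(a$pairs$pos_a, c(1, 3))
  expect_equal(a$pairs$pos_b, c(1, 2))
  expect_equal(a$identity, 100 * 2 / 3, tolerance = 1e-9)
  expect_error(global_align("", "AD"), "empty")
  # symmetry
  set.seed(5)
  s1 <- paste(sample(aa_states(), 30, TRUE), collapse = "")
  s2 <- paste(sample(aa_states(), 25, TRUE), collapse = "")
  expect_equal(global_align(s1, s2)$identity, global_align(s2, s1)$identity)
  # pairs strictly increasing in both sequences
  p <- global_align(s1, s2)$pairs
  expect_true(all(diff(p$pos_a) > 0) && all(diff(p$pos_b) > 0))
})

test_that("optimal alignment score matches exhaustive path enumeration", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  set.seed(7)
  for (k in 1:8) {
    la <- sample(2:5, 1); lb <- sample(2:5, 1)
    sa <- paste(sample(aa_states(), la, TRUE), collapse = "")
    sb <- paste(sample(aa_states(), lb, TRUE), collapse = "")
    expect_equal(global_align(sa, sb)$score,
                 brute_align_score(sa, sb, B62),
                 tolerance = 1e-9, label = paste(sa, sb))
  }
})

test_that("Kabsch superposition recovers exact rigid relations", {
  set.seed(2)
  A <- matrix(stats::rnorm(90), 30)
  s0 <- kabsch_superpose(A, A)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  B <- rigid_transform(A, angle = pi / 2)
  s1 <- kabsch_superpose(A, B)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(s1, B), A, tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "degenerate")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("reflections are excluded and the fit matches a rotation-grid oracle", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.4, 1.7))
  M <- P %*% diag(c(1, 1, -1))    # mirror image of a chiral set
  s <- kabsch_superpose(P, M)
  expect_gt(s$rmsd, 0)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  # coarse search over proper rotations can never beat the closed form
  Pc <- sweep(P, 2, colMeans(P)); Mc <- sweep(M, 2, colMeans(M))
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  half <- seq(0, pi, length.out = 13)
  best <- Inf
  for (a in ang) for (b in half) for (c in ang) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    R <- Rz1 %*% Ry %*% Rz2
    best <- min(best, sqrt(mean(rowSums((Pc - Mc %*% t(R))^2))))
  }
  expect_lte(s$rmsd, best + 1e-9)
  expect_lt(best - s$rmsd, 0.1 * best)   # 15-degree grid comes close
})

test_that("RMSD is invariant to pre-applied rigid transforms", {
  set.seed(4)
  A <- matrix(stats::rnorm(120), 40)
  B <- A + matrix(stats::rnorm(120, sd = 0.4), 40)
  r0 <- kabsch_superpose(A, B)$rmsd
  expect_equal(kabsch_superpose(rigid_transform(A), B)$rmsd, r0,
               tolerance = 1e-9)
  expect_equal(kabsch_superpose(A, rigid_transform(B, angle = 1.1))$rmsd, r0,
               tolerance = 1e-9)
})

test_that("superposition agrees with an independent least-squares fitter", {
  set.seed(3)
  A <- matrix(stats::rnorm(60), 20)
  B <- A + matrix(stats::rnorm(60, sd = 0.5), 20)
  mine <- kabsch_superpose(A, B)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(A)), as.vector(t(B))))
  ref <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(mine$rmsd, ref, tolerance = 1e-6)
})

test_that("per-domain fits behave like the whole-protein fit where they must", {
  set.seed(6)
  A <- matrix(stats::rnorm(180), 60)
  B <- A + matrix(stats::rnorm(180, sd = 0.3), 60)
  resno <- 1:60
  doms <- list(domain_definition("all", data.frame(start = 1, end = 60)))
  dr <- domain_rmsd(A, B, resno, resno, doms)
  expect_equal(dr$rmsd, kabsch_superpose(A, B)$rmsd, tolerance = 1e-12)

  two <- list(domain_definition("small", data.frame(start = 1, end = 25)),
              domain_definition("large", data.frame(start = 26, end = 60)))
  dr2 <- domain_rmsd(A, B, resno, resno, two)
  expect_equal(dr2$rmsd[dr2$domain == "small"],
               kabsch_superpose(A[1:25, ], B[1:25, ])$rmsd)
  # identical domains give zero
  dr3 <- domain_rmsd(A, A, resno, resno, two)
  expect_equal(dr3$rmsd, c(0, 0), tolerance = 1e-9)
  # each domain's own fit cannot exceed its RMSD under the global fit
  glob <- kabsch_superpose(A, B)
  Bg <- apply_superposition(glob, B)
  for (d in list(1:25, 26:60)) {
    under_global <- sqrt(mean(rowSums((A[d, ] - Bg[d, ])^2)))
    own <- kabsch_superpose(A[d, ], B[d, ])$rmsd
    expect_lte(own, under_global + 1e-12)
  }
  expect_error(domain_rmsd(A, B, resno, resno,
                           list(domain_definition("off",
                                                  data.frame(start = 90,
                                                             end = 95)))),
               "<3 pairs")
})

test_that("noise-perturbed domains land in the Monte-Carlo RMSD band", {
  # E[rmsd] ~ sigma * sqrt(3 - 6/n) after removing six rigid-fit dof
  set.seed(9)
  n <- 50; sigma <- 0.5
  A <- matrix(stats::rnorm(n * 3), n)
  r <- replicate(100, {
    B <- A + matrix(stats::rnorm(n * 3, sd = sigma), n)
    kabsch_superpose(A, B)$rmsd
  })
  expected <- sigma * sqrt(3 - 6 / n)
  expect_lt(abs(mean(r) - expected), 4 * stats::sd(r) / sqrt(length(r)) + 0.02)
})

test_that("centre-of-mass distances follow the documented conventions", {
  f <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 0, 0, 10)))
  st <- read_pdb(f)
  d <- com_distance(st, "A", data.frame(start = 1, end = 1),
                    data.frame(start = 2, end = 2))
  expect_equal(d, 10)
  expect_equal(com_distance(st, "A", data.frame(start = 1, end = 2),
                            data.frame(start = 1, end = 2)), 0)
  # mass weighting and C-alpha centroids agree closely on compact domains
  td <- generate_two_domain(40, 25, seed = 3)
  d1 <- com_distance(td$structure, "A", td$domains$small, td$domains$large)
  d2 <- com_distance(td$structure, "A", td$domains$small, td$domains$large,
                     mass_weighted = TRUE)
  expect_lt(abs(d1 - d2), 1)
  expect_equal(d1, 25, tolerance = 0.15)
})

test_that("the full comparison pipeline reports a coherent dossier", {
  td <- generate_two_domain(50, 30, seed = 8)
  stA <- td$structure
  stB <- transform_structure(stA, angle = 1.2, axis = c(0, 1, 1),
                             shift = c(12, -5, 3))
  set.seed(10)
  stB$atoms[, c("x", "y", "z")] <-
    stB$atoms[, c("x", "y", "z")] +
    matrix(stats::rnorm(nrow(stB$atoms) * 3, sd = 0.3), ncol = 3)
  stB$id <- "copy"
  doms <- list(domain_definition("small", td$domains$small),
               domain_definition("large", td$domains$large))
  cmp <- compare_structures(stA, stB, domains = doms)
  expect_equal(cmp$identity, 100)
  expect_equal(cmp$n_pairs, 100)
  expect_lt(cmp$rmsd, 0.7)
  expect_equal(nrow(cmp$domain_rmsd), 2)
  expect_true(all(cmp$domain_rmsd$rmsd > 0 & cmp$domain_rmsd$rmsd < 0.7))
  expect_equal(unname(cmp$com_distance[1]), 30, tolerance = 0.2)
  expect_equal(unname(cmp$com_distance[2]), 30, tolerance = 0.3)
})
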