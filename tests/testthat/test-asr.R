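# The enumeration oracles below sum the joint likelihood over every
# internal-node state assignment explicitly; they share nothing with the
# pruning implementation beyond the transition matrices.

balanced16 <- function(edge = 0.075) {
  tr <- ape::stree(16, "balanced")
  tr$edge.length <- rep(edge, nrow(tr$edge))
  ape::reorder.phylo(tr)
}

test_that("the CpREV model satisfies its defining identities", {
  m <- cprev_model()
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  flux <- m$pi * m$Q
  expect_lt(max(abs(flux - t(flux))), 1e-12)      # detailed balance
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- prob_matrix(m, t)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
  expect_equal(prob_matrix(m, 0), diag(20), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pruning log-likelihood matches an independent implementation", {
  skip_if_not_installed("phangorn")
  m <- cprev_model()
  tr <- balanced16()
  ev <- evolve_along_tree(evolution_spec(tr, m, n_sites = 60,
                                         indel_rate = 0.05, seed = 7))
  mine <- pruning_loglik(tr, ev$alignment, m)$loglik
  mat <- t(sapply(ev$alignment, function(s) strsplit(s, "")[[1]]))
  fit <- phangorn::pml(tr, phangorn::phyDat(mat, type = "AA"),
                       model = "cpREV")
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("discrete-gamma rate variation mixes categories correctly", {
  skip_if_not_installed("phangorn")
  m <- cprev_model()
  r <- discrete_gamma_rates(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_equal(r, phangorn::discrete.gamma(0.5, 4), tolerance = 1e-9)
  tr <- ape::stree(8, "balanced")
  tr$edge.length <- rep(0.15, nrow(tr$edge))
  tr <- ape::reorder.phylo(tr)
  ev <- evolve_along_tree(evolution_spec(tr, m, n_sites = 40, seed = 2))
  mine <- pruning_loglik(tr, ev$alignment, m, gamma_shape = 0.5)$loglik
  mat <- t(sapply(ev$alignment, function(s) strsplit(s, "")[[1]]))
  fit <- phangorn::pml(tr, phangorn::phyDat(mat, type = "AA"),
                       model = "cpREV", k = 4, shape = 0.5)
  expect_equal(mine, fit$logLik, tolerance = 1e-8)
  # posteriors remain proper distributions and approach the single-rate
  # result as the shape grows large
  po <- marginal_posteriors(tr, ev$alignment, m, node = 9,
                            gamma_shape = 0.5)
  expect_equal(colSums(po), rep(1, 40), tolerance = 1e-9,
               ignore_attr = TRUE)
  po_big <- marginal_posteriors(tr, ev$alignment, m, node = 9,
                                gamma_shape = 500)
  po_one <- marginal_posteriors(tr, ev$alignment, m, node = 9)
  expect_lt(max(abs(po_big - po_one)), 0.01)
})

test_that("degenerate columns follow the likelihood definitions", {
  m <- cprev_model()
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  # a column observed in one leaf only has likelihood pi_k
  k <- which(aa_states() == "K")
  expect_equal(site_likelihood(tr, c(A = "K", B = "-"), m), m$pi[k],
               tolerance = 1e-12)
  # an all-gap column carries no information
  expect_equal(site_likelihood(tr, c(A = "-", B = "-"), m), 1,
               tolerance = 1e-12)
  # taxon mismatch is reported with the symmetric difference
  expect_error(pruning_loglik(tr, c(A = "K", C = "E"), m), "taxon mismatch")
})

test_that("3-leaf likelihood equals exhaustive state enumeration", {
  m <- cprev_model()
  tr <- ape::read.tree(text = "((A:0.12,B:0.3):0.08,C:0.25);")
  PA <- prob_matrix(m, 0.12); PB <- prob_matrix(m, 0.3)
  PI <- prob_matrix(m, 0.08); PC <- prob_matrix(m, 0.25)
  for (col in list(c(A = "K", B = "E", C = "K"),
                   c(A = "A", B = "W", C = "C"),
                   c(A = "D", B = "-", C = "D"))) {
    lik <- site_likelihood(tr, col, m)
    obs <- match(col, aa_states())
    brute <- 0
    for (r in 1:20) for (i in 1:20) {
      term <- m$pi[r] * PI[r, i]
      term <- term * (if (is.na(obs[1])) 1 else PA[i, obs[1]])
      term <- term * (if (is.na(obs[2])) 1 else PB[i, obs[2]])
      term <- term * (if (is.na(obs[3])) 1 else PC[r, obs[3]])
      brute <- brute + term
    }
    expect_equal(log(lik), log(brute), tolerance = 1e-10)
  }
})

test_that("marginal posteriors equal brute-force joint enumeration", {
  m <- cprev_model()
  tr <- ape::read.tree(text = "((A:0.15,B:0.4):0.1,(C:0.2,D:0.3):0.12);")
  aln <- c(A = "K", B = "E", C = "K", D = "D")
  post <- marginal_posteriors(tr, aln, m, node = 6)   # ancestor of A,B
  PA <- prob_matrix(m, 0.15); PB <- prob_matrix(m, 0.4)
  PC <- prob_matrix(m, 0.2); PD <- prob_matrix(m, 0.3)
  PI <- prob_matrix(m, 0.1); PJ <- prob_matrix(m, 0.12)
  obs <- match(aln, aa_states())
  joint <- numeric(20)
  for (i in 1:20) {
    s <- 0
    for (r in 1:20) for (j in 1:20)
      s <- s + m$pi[r] * PI[r, i] * PJ[r, j] *
        PA[i, obs[1]] * PB[i, obs[2]] * PC[j, obs[3]] * PD[j, obs[4]]
    joint[i] <- s
  }
  expect_equal(as.numeric(post[, 1]), joint / sum(joint), tolerance = 1e-10)
  expect_equal(colSums(post), 1, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(marginal_posteriors(tr, aln, m, node = 2), "leaf")
})

test_that("likelihood is invariant to re-rooting under the reversible model", {
  m <- cprev_model()
  set.seed(21)
  tr <- ape::rtree(7)
  ev <- evolve_along_tree(evolution_spec(tr, m, n_sites = 30, seed = 2))
  base <- pruning_loglik(tr, ev$alignment, m)$loglik
  for (nd in (length(tr$tip.label) + 2):(length(tr$tip.label) + tr$Nnode)) {
    rerooted <- ape::root(tr, node = nd, resolve.root = TRUE)
    expect_equal(pruning_loglik(rerooted, ev$alignment, m)$loglik, base,
                 tolerance = 1e-10)
  }
})

test_that("posterior limits behave as theory dictates", {
  m <- cprev_model()
  # zero-length branch to an observed leaf clamps the ancestor
  tr <- ape::read.tree(text = "((A:0.0,B:0.5):0.2,C:0.3);")
  post <- marginal_posteriors(tr, c(A = "K", B = "E", C = "C"), m, node = 5)
  expect_equal(unname(post[which(aa_states() == "K"), 1]), 1,
               tolerance = 1e-9)
  # infinitely long branches wash out to the stationary prior
  tr2 <- ape::read.tree(text = "((A:60,B:60):60,C:60);")
  post2 <- marginal_posteriors(tr2, c(A = "K", B = "E", C = "C"), m,
                               node = 5)
  expect_equal(as.numeric(post2[, 1]), m$pi, tolerance = 1e-4)
})

test_that("tree-sample averaging is an arithmetic mean with coverage", {
  m <- cprev_model()
  tr <- ape::read.tree(text = "((A:0.15,B:0.4):0.1,(C:0.2,D:0.3):0.12);")
  aln <- c(A = "K", B = "E", C = "K", D = "D")
  single <- marginal_posteriors(tr, aln, m, node = 6)
  avg <- average_over_trees(list(tr, tr, tr), aln, m, c("A", "B"))
  expect_equal(avg$posteriors, single, tolerance = 1e-12)
  expect_equal(avg$coverage, 1)

  # two distinct trees: hand-computed mean of the two posterior vectors
  tr2 <- ape::read.tree(text = "((A:0.3,B:0.2):0.15,(C:0.2,D:0.3):0.12);")
  p2 <- marginal_posteriors(tr2, aln, m, node = 6)
  avg2 <- average_over_trees(list(tr, tr2), aln, m, c("A", "B"))
  expect_equal(avg2$posteriors, (single + p2) / 2, tolerance = 1e-12)

  # clade bookkeeping: AB monophyletic in 3 of 5 trees
  tr_no <- ape::read.tree(text = "((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")
  avg3 <- average_over_trees(list(tr, tr2, tr, tr_no, tr_no), aln, m,
                             c("A", "B"))
  expect_equal(avg3$coverage, 0.6)
  expect_equal(avg3$n_trees_used, 3L)
  expect_error(average_over_trees(list(tr_no), aln, m, c("A", "B")),
               "zero trees")
})

test_that("burn-in bookkeeping reproduces the sampling design arithmetic", {
  r <- retained_samples(1e7, 1000, n_runs = 2, burnin_fraction = 0.4)
  expect_equal(r$total, 20000L)
  expect_equal(r$retained, 12000L)
  expect_equal(retained_samples(1e6, 500, 1, 0)$retained, 2000L)
  expect_warning(r2 <- retained_samples(1003, 10, 1, 0.5), "flooring")
  expect_equal(r2$total, 100L)
})

test_that("parsimony gap correction resolves presence as documented", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- c(A = "K-A-", B = "K-A-", C = "KKA-", D = "KK--")
  mask <- hall_gap_correction(aln, tr, node = 6)  # ancestor of A,B
  expect_true(mask[1])        # no gaps anywhere: present
  expect_false(mask[2])       # whole AB clade deleted: absent
  expect_true(mask[3])
  expect_false(mask[4])       # all-gap column: absent
  # two-leaf ambiguity resolves to present
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_true(hall_gap_correction(c(A = "K", B = "-"), tr2, node = 3))
  # a column with residues in every leaf can never be absent
  set.seed(12)
  tr3 <- ape::rtree(6)
  full <- setNames(replicate(6, paste(sample(aa_states(), 10, TRUE),
                                      collapse = "")), tr3$tip.label)
  expect_true(all(hall_gap_correction(full, tr3, node = 8)))
})

test_that("reconstruction composes posteriors, tie-breaks and gap removal", {
  m <- cprev_model()
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  rec <- reconstruct_ancestor(tr, c(A = "K", B = "K"), c("A", "B"),
                              model = m)
  expect_equal(rec$final_sequence, "K")
  expect_equal(rec$pp_max, max(rec$posteriors[, 1]))

  # exact posterior tie under a symmetric model: alphabetical winner
  rec2 <- reconstruct_ancestor(tr, c(A = "A", B = "R"), c("A", "B"),
                               model = uniform_model())
  expect_equal(rec2$mpp_sequence, "A")

  # columns deleted across the target clade vanish from the final sequence
  tr4 <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  aln <- c(A = "K-IV", B = "K-IV", C = "KEIV", D = "KEIV")
  rec3 <- reconstruct_ancestor(tr4, aln, c("A", "B"), model = m)
  expect_equal(rec3$presence_mask, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(nchar(rec3$final_sequence), 3)
})

test_that("root states are recovered on short-branch simulations", {
  m <- cprev_model()
  tr <- balanced16()
  ev <- evolve_along_tree(evolution_spec(tr, m, n_sites = 200, seed = 11))
  rec <- reconstruct_ancestor(tr, ev$alignment, tr$tip.label, model = m)
  truth <- strsplit(ev$root_alignment, "")[[1]]
  mpp <- strsplit(rec$mpp_sequence, "")[[1]]
  expect_gte(mean(mpp == truth), 0.9)
})

test_that("mean max-PP rises as branches shrink", {
  m <- cprev_model()
  means <- vapply(c(0.5, 0.15, 0.02), function(edge) {
    tr <- ape::stree(8, "balanced")
    tr$edge.length <- rep(edge, nrow(tr$edge))
    tr <- ape::reorder.phylo(tr)
    ev <- evolve_along_tree(evolution_spec(tr, m, n_sites = 100, seed = 5))
    rec <- reconstruct_ancestor(tr, ev$alignment, tr$tip.label, model = m)
    mean(rec$pp_max)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
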