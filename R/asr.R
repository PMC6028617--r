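# Marginal ancestral sequence reconstruction under an empirical amino-acid
# model (CpREV): Felsenstein pruning likelihoods, per-site posterior state
# distributions at an internal node (optionally averaged over a posterior
# tree sample), max-posterior sequence, and parsimony-based gap correction.

#' Build a reversible amino-acid rate model
#'
#' Constructs the normalized rate matrix `Q` with `q_ij = s_ij * pi_j`
#' (i != j), rows summing to zero, scaled so the expected rate
#' `-sum(pi_i q_ii)` is 1 substitution per site per unit branch length.
#' Detailed balance `pi_i q_ij = pi_j q_ji` holds by construction. The
#' spectral decomposition of the pi-symmetrized generator is precomputed for
#' stable matrix exponentials.
#'
#' @param S symmetric 20 x 20 exchangeability matrix (non-negative
#'   off-diagonal; the diagonal is ignored).
#' @param pi stationary frequencies (length 20, positive, summing to 1).
#' @param name model label.
#' @return List of class `rate_model` with elements `S`, `pi`, `Q`, `name`,
#'   `states` and the cached eigendecomposition.
#' @export
rate_model <- function(S, pi, name = "custom") {
  S <- as.matrix(S)
  stopifnot(nrow(S) == 20, ncol(S) == 20, length(pi) == 20)
  if (max(abs(S - t(S))) > 1e-8) stop("exchangeability matrix not symmetric")
  if (any(pi <= 0)) stop("frequencies must be positive")
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- Q * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(S = S, pi = pi, Q = Q, name = name, states = aa_states(),
                 eig_values = eig$values,
                 eig_left = eig$vectors * (1 / sq),   # D^{-1/2} U (rows scaled)
                 eig_right = t(eig$vectors) * rep(sq, each = 20)),
            class = "rate_model")
}

#' The CpREV empirical amino-acid model
#'
#' Chloroplast-derived reversible replacement matrix (Adachi, Waddell,
#' Martin & Hasegawa 2000), read from the plain-text constants bundled with
#' the package.
#'
#' @return A [rate_model()].
#' @export
cprev_model <- function() {
  path <- system.file("extdata", "cprev.txt", package = "haloadapt")
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^#", lines)])
  iq <- which(lines == "EXCHANGEABILITIES")
  ifr <- which(lines == "FREQUENCIES")
  if (!length(iq) || !length(ifr)) stop("corrupted CpREV data file")
  q <- as.numeric(lines[(iq + 1):(ifr - 1)])
  bf <- as.numeric(lines[(ifr + 1):length(lines)])
  if (length(q) != 190 || length(bf) != 20 || anyNA(q) || anyNA(bf))
    stop("corrupted CpREV data file")
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- q  # column-major lower triangle (see data file header)
  S <- S + t(S)
  rownames(S) <- colnames(S) <- aa_states()
  rate_model(S, bf, name = "cpREV")
}

#' Transition probability matrix P(t) = exp(Q t)
#'
#' Computed through the cached symmetric eigendecomposition of the
#' pi-scaled generator; numerically exact for reversible `Q`.
#'
#' @param model a [rate_model()].
#' @param t branch length (expected substitutions/site, >= 0).
#' @return 20 x 20 row-stochastic matrix.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(t >= 0, is.finite(t))
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

# gap / missing-data symbols in alignments
.gap_chars <- c("-", ".", "?")

# integer-encode an alignment (named character vector of equal-length
# strings) against the model states; NA = missing (gap, X, ambiguity)
.encode_alignment <- function(alignment, states = aa_states()) {
  mats <- lapply(alignment, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    m <- match(ch, states)
    m
  })
  len <- unique(vapply(mats, length, integer(1)))
  if (length(len) != 1) stop("alignment rows differ in length")
  X <- do.call(rbind, mats)
  rownames(X) <- names(alignment)
  X
}

# presence (non-gap) matrix: TRUE where the leaf has a residue (X counts as
# present; '-', '.', '?' do not)
.presence_matrix <- function(alignment) {
  mats <- lapply(alignment, function(s) {
    ch <- strsplit(s, "")[[1]]
    !(ch %in% .gap_chars)
  })
  X <- do.call(rbind, mats)
  rownames(X) <- names(alignment)
  X
}

# check leaf labels against alignment taxa; error lists the symmetric
# difference
.check_taxa <- function(tree, alignment) {
  a <- setdiff(tree$tip.label, names(alignment))
  b <- setdiff(names(alignment), tree$tip.label)
  if (length(a) || length(b))
    stop("taxon mismatch between tree and alignment; only in tree: {",
         paste(a, collapse = ","), "}; only in alignment: {",
         paste(b, collapse = ","), "}")
}

# Postorder pass of Felsenstein pruning. Returns, for every node, the
# conditional likelihood matrix (states x sites, rescaled per site) and the
# per-site log rescaling, plus the per-edge P matrices and children lists.
.pruning_pass <- function(tree, X, model) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  phy <- ape::reorder.phylo(tree, "postorder")
  el <- phy$edge.length
  if (is.null(el)) stop("branch lengths required for likelihood computation")
  S <- ncol(X)
  ns <- length(model$states)
  X <- X[phy$tip.label, , drop = FALSE]
  partial <- vector("list", nnode)
  logscale <- matrix(0, nnode, S)
  for (i in seq_len(ntip)) {
    m <- matrix(0, ns, S)
    obs <- !is.na(X[i, ])
    m[cbind(X[i, obs], which(obs))] <- 1
    m[, !obs] <- 1
    partial[[i]] <- m
  }
  Pmats <- vector("list", nrow(phy$edge))
  children <- vector("list", nnode)
  msg <- vector("list", nrow(phy$edge))  # P_e %*% partial[child] per edge
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    children[[p]] <- c(children[[p]], e)
    if (is.null(partial[[ch]])) stop("postorder violated")  # defensive
    Pmats[[e]] <- prob_matrix(model, el[e])
    msg[[e]] <- Pmats[[e]] %*% partial[[ch]]
    if (all(!is.null(children[[p]])) &&
        length(children[[p]]) == sum(phy$edge[, 1] == p)) {
      m <- msg[[children[[p]][1]]]
      sc <- logscale[phy$edge[children[[p]][1], 2], ]
      for (e2 in children[[p]][-1]) {
        m <- m * msg[[e2]]
        sc <- sc + logscale[phy$edge[e2, 2], ]
      }
      mx <- apply(m, 2, max)
      zero <- mx == 0
      mx[zero] <- 1
      partial[[p]] <- sweep(m, 2, mx, "/")
      logscale[p, ] <- sc + log(mx)
      logscale[p, zero] <- -Inf
    }
  }
  root <- phy$edge[nrow(phy$edge), 1]
  list(phy = phy, partial = partial, logscale = logscale, Pmats = Pmats,
       msg = msg, children = children, root = root, ntip = ntip,
       nnode = nnode)
}

#' Discrete-gamma rate categories
#'
#' Equal-weight rate categories of a mean-1 Gamma(shape, shape)
#' distribution, each category carrying the mean rate of its
#' equal-probability bin (the standard discretisation; mean exactly 1).
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories.
#' @return Numeric vector of `k` relative rates.
#' @export
discrete_gamma_rates <- function(shape, k = 4) {
  stopifnot(shape > 0, k >= 1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape,
                     rate = shape)
  k * (stats::pgamma(b[-1], shape = shape + 1, rate = shape) -
         stats::pgamma(b[-(k + 1)], shape = shape + 1, rate = shape))
}

# single-rate site log-likelihoods (branch lengths scaled by `rate`)
.site_loglik_one <- function(tree, X, model, rate = 1) {
  tr <- tree
  tr$edge.length <- tr$edge.length * rate
  pp <- .pruning_pass(tr, X, model)
  L <- colSums(model$pi * pp$partial[[pp$root]])
  log(L) + pp$logscale[pp$root, ]
}

#' Log-likelihood of an alignment under pruning
#'
#' Felsenstein's pruning algorithm with per-branch `P(t) = exp(Qt)`; gaps
#' and ambiguous states are missing data (partial likelihood 1 for every
#' state). Computed with per-site rescaling in log space. With
#' `gamma_shape` set, site likelihoods are averaged over equal-weight
#' discrete-gamma rate categories (rate heterogeneity across sites,
#' default off).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param alignment named character vector of aligned sequences (leaf names
#'   must match tip labels).
#' @param model a [rate_model()].
#' @param gamma_shape optional gamma shape for across-site rate variation.
#' @param n_rate_categories number of discrete categories when
#'   `gamma_shape` is set.
#' @return List with `loglik` (total) and `site_loglik` (per column).
#' @export
pruning_loglik <- function(tree, alignment, model, gamma_shape = NULL,
                           n_rate_categories = 4) {
  .check_taxa(tree, alignment)
  X <- .encode_alignment(alignment, model$states)
  if (is.null(gamma_shape)) {
    site <- .site_loglik_one(tree, X, model)
  } else {
    rates <- discrete_gamma_rates(gamma_shape, n_rate_categories)
    percat <- vapply(rates, function(r) .site_loglik_one(tree, X, model, r),
                     numeric(ncol(X)))
    percat <- matrix(percat, ncol = length(rates))
    mx <- apply(percat, 1, max)
    site <- mx + log(rowMeans(exp(percat - mx)))
  }
  list(loglik = sum(site), site_loglik = site)
}

#' Likelihood of a single alignment column
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param column named character vector of one leaf state each (gaps
#'   allowed).
#' @param model a [rate_model()].
#' @return The column likelihood (not log).
#' @export
site_likelihood <- function(tree, column, model) {
  aln <- as.character(column)
  names(aln) <- names(column)
  exp(pruning_loglik(tree, aln, model)$site_loglik[1])
}

#' Marginal posterior state distributions at an internal node
#'
#' For every alignment column, the posterior probability of each amino acid
#' at `node` is proportional to the joint likelihood with the node clamped
#' to that state (computed by a standard two-pass message schedule; under a
#' reversible model the result does not depend on root placement).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param alignment named character vector of aligned sequences.
#' @param model a [rate_model()].
#' @param node internal node id in ape numbering (`ntip + 1` ... ). Leaves
#'   are observed and rejected.
#' @param gamma_shape optional gamma shape for across-site rate variation;
#'   categories are mixed per site in proportion to their likelihoods.
#' @param n_rate_categories number of discrete categories.
#' @return 20 x n_sites matrix of posterior probabilities (rows in
#'   [aa_states()] order; columns sum to 1).
#' @export
marginal_posteriors <- function(tree, alignment, model, node,
                                gamma_shape = NULL, n_rate_categories = 4) {
  .check_taxa(tree, alignment)
  ntip <- length(tree$tip.label)
  if (node <= ntip) stop("node ", node, " is a leaf; leaves are observed")
  if (node > ntip + tree$Nnode) stop("no such node: ", node)
  X <- .encode_alignment(alignment, model$states)
  one <- function(rate) {
    tr <- tree
    tr$edge.length <- tr$edge.length * rate
    pp <- .pruning_pass(tr, X, model)
    up <- .upward_messages(pp, model, targets = node)
    post <- pp$partial[[node]] * up[[node]]
    list(post = sweep(post, 2, colSums(post), "/"),
         site = log(colSums(model$pi * pp$partial[[pp$root]])) +
           pp$logscale[pp$root, ])
  }
  if (is.null(gamma_shape)) return(one(1)$post)
  rates <- discrete_gamma_rates(gamma_shape, n_rate_categories)
  cats <- lapply(rates, one)
  ll <- vapply(cats, `[[`, numeric(ncol(X)), "site")
  ll <- matrix(ll, ncol = length(rates))
  w <- exp(ll - apply(ll, 1, max))
  w <- w / rowSums(w)                       # per-site category weights
  post <- 0
  for (k in seq_along(cats))
    post <- post + sweep(cats[[k]]$post, 2, w[, k], "*")
  post
}

# Preorder pass computing, for each requested node, the "upward" message:
# P(data outside the node's subtree, state at node), up to per-site scaling
# (root message = pi). Leave-one-out sibling products via prefix/suffix.
.upward_messages <- function(pp, model, targets) {
  phy <- pp$phy
  ns <- length(model$states)
  S <- ncol(pp$partial[[pp$root]])
  up <- vector("list", pp$nnode)
  up[[pp$root]] <- matrix(model$pi, ns, S)
  # preorder = reverse postorder edge order
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (ch <= pp$ntip) next
    sib <- setdiff(pp$children[[p]], e)
    m <- up[[p]]
    for (e2 in sib) m <- m * pp$msg[[e2]]
    u <- crossprod(pp$Pmats[[e]], m)
    mx <- apply(u, 2, max)
    mx[mx == 0] <- 1
    up[[ch]] <- sweep(u, 2, mx, "/")
  }
  up
}

#' Internal node spanning a set of taxa
#'
#' @param tree a `phylo`.
#' @param taxa character vector of leaf labels (>= 2).
#' @param monophyletic require the node's descendant leaves to be exactly
#'   `taxa`; return `NA` when they are not.
#' @return Node id, or `NA` if `monophyletic` and the clade is absent.
#' @export
mrca_node <- function(tree, taxa, monophyletic = TRUE) {
  taxa <- intersect(taxa, tree$tip.label)
  if (length(taxa) < 2) return(NA_integer_)
  node <- ape::getMRCA(tree, taxa)
  if (monophyletic) {
    desc <- tree$tip.label[.clade_tips(tree, node)]
    if (!setequal(desc, taxa)) return(NA_integer_)
  }
  node
}

# tip indices descending from a node
.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .clade_tips, tree = tree))
}

#' Posterior probabilities averaged over a tree sample
#'
#' Computes [marginal_posteriors()] at the most recent common ancestor of
#' `clade_taxa` in every tree where that clade is monophyletic, and averages
#' the per-site posterior vectors arithmetically across those trees.
#'
#' @param trees list of rooted `phylo` objects (a posterior sample).
#' @param alignment named character vector of aligned sequences.
#' @param model a [rate_model()].
#' @param clade_taxa leaf labels defining the target ancestor.
#' @return List with `posteriors` (20 x n_sites), `coverage` (fraction of
#'   trees containing the clade), `n_trees_used`. Errors when no tree
#'   contains the clade.
#' @export
average_over_trees <- function(trees, alignment, model, clade_taxa) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  acc <- NULL; used <- 0L
  for (tr in trees) {
    node <- mrca_node(tr, clade_taxa)
    if (is.na(node)) next
    post <- marginal_posteriors(tr, alignment, model, node)
    acc <- if (is.null(acc)) post else acc + post
    used <- used + 1L
  }
  if (used == 0L) stop("target clade present in zero trees")
  list(posteriors = acc / used, coverage = used / length(trees),
       n_trees_used = used)
}

#' Retained posterior samples after burn-in
#'
#' Bookkeeping for an MCMC sampling design: `total = n_runs *
#' floor(n_generations / sample_frequency)` samples (a warning is issued
#' when the generations are not divisible by the sampling frequency), of
#' which `round(total * (1 - burnin_fraction))` are retained.
#'
#' @param n_generations generations per run.
#' @param sample_frequency sampling interval in generations.
#' @param n_runs number of independent runs.
#' @param burnin_fraction fraction discarded in `[0, 1)`.
#' @return List with `total` and `retained` (integers).
#' @export
retained_samples <- function(n_generations, sample_frequency, n_runs = 1,
                             burnin_fraction = 0) {
  stopifnot(n_generations > 0, sample_frequency > 0, n_runs > 0,
            burnin_fraction >= 0, burnin_fraction < 1)
  per_run <- n_generations / sample_frequency
  if (per_run != floor(per_run)) {
    warning("generations not divisible by sampling frequency; flooring",
            call. = FALSE)
    per_run <- floor(per_run)
  }
  total <- n_runs * per_run
  list(total = as.integer(total),
       retained = as.integer(round(total * (1 - burnin_fraction))))
}

#' Parsimony gap correction (ancestral presence/absence of columns)
#'
#' Per alignment column, leaves are coded present (residue, including `X`)
#' or absent (gap) and the binary character is optimised on the tree by
#' unit-cost parsimony (Sankoff up/down passes). The target node is deemed
#' to possess the column when "present" is among the most-parsimonious
#' states; parsimony-ambiguous columns therefore resolve to present.
#'
#' @param alignment named character vector of aligned sequences.
#' @param tree rooted `phylo` (branch lengths unused).
#' @param node internal node id.
#' @return Logical vector (per column): `TRUE` when the ancestor is inferred
#'   to possess a residue there.
#' @export
hall_gap_correction <- function(alignment, tree, node) {
  .check_taxa(tree, alignment)
  ntip <- length(tree$tip.label)
  if (node <= ntip) stop("node ", node, " is a leaf")
  P <- .presence_matrix(alignment)
  S <- ncol(P)
  phy <- ape::reorder.phylo(tree, "postorder")
  P <- P[phy$tip.label, , drop = FALSE]
  nnode <- ntip + tree$Nnode
  big <- S + 1  # exceeds any attainable parsimony cost
  down0 <- matrix(0, nnode, S); down1 <- matrix(0, nnode, S)
  for (i in seq_len(ntip)) {
    down0[i, ] <- ifelse(P[i, ], big, 0)
    down1[i, ] <- ifelse(P[i, ], 0, big)
  }
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  for (p in unique(phy$edge[, 1])) {
    c0 <- 0; c1 <- 0
    for (ch in kids[[as.character(p)]]) {
      c0 <- c0 + pmin(down0[ch, ], down1[ch, ] + 1)
      c1 <- c1 + pmin(down1[ch, ], down0[ch, ] + 1)
    }
    down0[p, ] <- c0; down1[p, ] <- c1
  }
  root <- phy$edge[nrow(phy$edge), 1]
  up0 <- matrix(0, nnode, S); up1 <- matrix(0, nnode, S)
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    s0 <- 0; s1 <- 0
    for (e2 in setdiff(kids[[as.character(p)]], ch)) {
      s0 <- s0 + pmin(down0[e2, ], down1[e2, ] + 1)
      s1 <- s1 + pmin(down1[e2, ], down0[e2, ] + 1)
    }
    a0 <- up0[p, ] + s0   # parent in state 0, excluding this child
    a1 <- up1[p, ] + s1
    up0[ch, ] <- pmin(a0, a1 + 1)
    up1[ch, ] <- pmin(a1, a0 + 1)
  }
  t0 <- down0[node, ] + up0[node, ]
  t1 <- down1[node, ] + up1[node, ]
  t1 <= t0
}

#' Ancestral sequence reconstruction at a clade's common ancestor
#'
#' Composes the pipeline: per-site marginal posteriors under the model
#' (averaged over a tree sample when several trees are given), the
#' max-posterior residue per column (ties broken towards the
#' alphabetically-first one-letter code), parsimony gap correction (for a
#' tree sample, a column is kept when it is inferred present in at least
#' half of the trees containing the clade), and the final sequence over the
#' retained columns.
#'
#' @param trees a rooted `phylo` or list of them.
#' @param alignment named character vector of aligned sequences.
#' @param clade_taxa leaf labels defining the ancestor of interest.
#' @param model a [rate_model()]; defaults to [cprev_model()].
#' @return Object of class `ancestral_reconstruction`: list with
#'   `posteriors` (20 x n_sites), `mpp_sequence` (full-length max-PP
#'   string), `pp_max` (per-site max posterior), `presence_mask`,
#'   `final_sequence`, `coverage`, `n_trees_used`.
#' @export
reconstruct_ancestor <- function(trees, alignment, clade_taxa,
                                 model = cprev_model()) {
  single <- inherits(trees, "phylo")
  tree_list <- if (single) list(trees) else trees
  avg <- average_over_trees(tree_list, alignment, model, clade_taxa)
  post <- avg$posteriors
  states <- model$states
  # max-PP residue with deterministic lexicographic tie-breaking
  ord <- order(states)
  mpp_idx <- apply(post, 2, function(p) {
    cand <- which(p >= max(p) - 1e-12)
    cand[order(match(cand, ord))][1]
  })
  mpp <- states[mpp_idx]
  pp_max <- post[cbind(mpp_idx, seq_len(ncol(post)))]
  pres_acc <- numeric(ncol(post)); used <- 0L
  for (tr in tree_list) {
    node <- mrca_node(tr, clade_taxa)
    if (is.na(node)) next
    pres_acc <- pres_acc + hall_gap_correction(alignment, tr, node)
    used <- used + 1L
  }
  presence <- (pres_acc / used) >= 0.5
  structure(list(
    posteriors = post,
    mpp_sequence = paste(mpp, collapse = ""),
    pp_max = pp_max,
    presence_mask = presence,
    final_sequence = paste(mpp[presence], collapse = ""),
    coverage = avg$coverage,
    n_trees_used = avg$n_trees_used), class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("<ancestral_reconstruction> %d columns, %d present,",
                     " final length %d\n"),
              ncol(x$posteriors), sum(x$presence_mask),
              nchar(x$final_sequence)))
  cat(sprintf("  mean max-PP %.3f; clade coverage %.2f (%d trees)\n",
              mean(x$pp_max), x$coverage, x$n_trees_used))
  invisible(x)
}
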