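# Ground-truth-bearing synthetic inputs: compact globular toy structures
# with planted core/surface compositions, and alignments evolved along a
# known tree under the amino-acid model with indels. Everything is
# deterministic given a seed; generated structures round-trip through the
# package's own I/O.

#' Specification for a synthetic globule
#'
#' @param n_residues number of residues (>= 1).
#' @param surface_composition,core_composition length-20 probability vectors
#'   over [aa_states()] (they are normalised); residue types of surface and
#'   core beads are drawn from these.
#' @param packing_radius minimum bead separation in Angstrom (the C-alpha
#'   virtual-bond scale, 3.8 A).
#' @param seed integer random seed (stamped into the output).
#' @return List of class `globule_spec`.
#' @export
globule_spec <- function(n_residues,
                         surface_composition = rep(1 / 20, 20),
                         core_composition = rep(1 / 20, 20),
                         packing_radius = 3.8, seed = 1L) {
  stopifnot(n_residues >= 1, length(surface_composition) == 20,
            length(core_composition) == 20,
            all(surface_composition >= 0), all(core_composition >= 0),
            packing_radius > 0)
  structure(list(n_residues = as.integer(n_residues),
                 surface_composition = surface_composition / sum(surface_composition),
                 core_composition = core_composition / sum(core_composition),
                 packing_radius = packing_radius, seed = as.integer(seed)),
            class = "globule_spec")
}

#' Composition vector helper
#'
#' Builds a length-20 composition over [aa_states()] from named weights,
#' e.g. `aa_composition(K = 0.3, A = 0.7)`.
#'
#' @param ... named non-negative weights by one-letter code.
#' @param baseline weight spread uniformly over unnamed residues.
#' @return Normalised length-20 numeric vector.
#' @export
aa_composition <- function(..., baseline = 0) {
  w <- c(...)
  out <- rep(0, 20)
  names(out) <- aa_states()
  if (length(w)) {
    stopifnot(all(names(w) %in% aa_states()))
    out[names(w)] <- w
  }
  unnamed <- setdiff(aa_states(), names(w))
  if (length(unnamed)) out[unnamed] <- baseline / length(unnamed)
  out / sum(out)
}

# representative pseudo side-chain atom per residue type (name, element);
# pointing radially it exposes the polar/charged ASA classes on toys
.pseudo_sidechain <- function(res1) {
  map <- list(D = c("OD1", "O"), E = c("OE1", "O"),
              K = c("NZ", "N"), R = c("NH1", "N"), H = c("ND1", "N"),
              S = c("OG", "O"), T = c("OG1", "O"), N = c("OD1", "O"),
              Q = c("OE1", "O"), Y = c("OH", "O"), W = c("NE1", "N"),
              C = c("SG", "S"), M = c("SD", "S"))
  m <- map[[res1]]
  if (is.null(m)) m <- c("CB", "C")
  m
}

#' Generate a compact globular toy structure with planted shells
#'
#' Beads (one per residue) are placed by rejection-sampled dense packing
#' (packing fraction 0.35, near the random-sequential-addition limit)
#' inside a sphere whose radius scales as `n^{1/3}`. Each residue is
#' rendered as a C-alpha, a pseudo side-chain atom 1.5 A away pointing
#' radially outward for surface residues and inward for core residues
#' (glycine gets no side chain), and four carbon filler atoms 1.8 A from
#' the C-alpha that stand in for the remaining heavy atoms, giving the
#' interior a protein-like solid density so that a water-sized probe cannot
#' percolate below the outermost bead layer. The planted buried core is
#' accordingly every bead deeper than about one packing radius below the
#' outermost bead; core residues draw their type from the core composition,
#' the rest from the surface composition. Deterministic given the seed.
#'
#' @param spec a [globule_spec()].
#' @param max_attempts rejection-sampling attempts per bead before giving
#'   up with an error suggesting a larger packing radius allowance.
#' @return List with `structure` (a `halo_structure`, seed recorded in
#'   `metadata$seed`) and `labels` (data.frame `resno`, `res1`,
#'   `planted_shell` with `"core"`/`"surface"`).
#' @export
generate_globule <- function(spec, max_attempts = 20000) {
  stopifnot(inherits(spec, "globule_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_residues
  d <- spec$packing_radius
  R <- max(d, (d / 2) * (n / 0.35)^(1 / 3))
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      u <- stats::rnorm(3)
      p <- u / sqrt(sum(u^2)) * R * stats::runif(1)^(1 / 3)
      if (i == 1 ||
          min(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                         rep(p, each = i - 1))^2)) >= d^2) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("bead packing failed after ", max_attempts,
           " attempts; increase packing allowance (fewer residues or ",
           "smaller packing_radius)")
  }
  rad <- sqrt(rowSums(pos^2))
  core <- rad <= max(rad) - 0.9 * d
  res1 <- character(n)
  if (any(core))
    res1[core] <- sample(aa_states(), sum(core), replace = TRUE,
                         prob = spec$core_composition)
  if (any(!core))
    res1[!core] <- sample(aa_states(), sum(!core), replace = TRUE,
                          prob = spec$surface_composition)
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- aa_one_to_three(res1[i])
    ats <- pos[i, , drop = FALSE]
    nm <- "CA"; el <- "C"
    if (res1[i] != "G") {
      sc <- .pseudo_sidechain(res1[i])
      dir <- pos[i, ]
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm < 1e-9) c(0, 0, 1) else dir / nrm
      if (core[i]) dir <- -dir   # core side chains point inward
      ats <- rbind(ats, pos[i, ] + 1.5 * dir)
      nm <- c(nm, sc[1]); el <- c(el, sc[2])
    }
    for (k in 1:4) {             # heavy-atom fillers
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      ats <- rbind(ats, pos[i, ] + 1.8 * u)
      nm <- c(nm, paste0("CF", k)); el <- c(el, "C")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = i, insert = "", resid = res3, elety = nm,
      element = el, x = ats[, 1], y = ats[, 2], z = ats[, 3],
      occupancy = 1, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$radius <- suppressWarnings(.assign_radii(atoms$element))
  atoms$sidechain <- !(atoms$elety %in% .backbone_atoms)
  st <- structure(list(id = sprintf("globule_seed%d", spec$seed),
                       atoms = atoms,
                       metadata = list(seed = spec$seed, radius = R)),
                  class = "halo_structure")
  list(structure = st,
       labels = data.frame(resno = seq_len(n), res1 = res1,
                           planted_shell = ifelse(core, "core", "surface"),
                           stringsAsFactors = FALSE))
}

#' Generate a rigid two-domain toy structure
#'
#' Two compact globules rendered as consecutive residue ranges of one
#' chain, their centres separated by `separation` Angstrom along x. Useful
#' ground truth for superposition and centre-of-mass metrics.
#'
#' @param n_per_domain residues per domain.
#' @param separation centre-to-centre distance (Angstrom).
#' @param seed integer seed.
#' @return List with `structure` and `domains` (list of two range
#'   data.frames usable with [domain_definition()]).
#' @export
generate_two_domain <- function(n_per_domain = 60, separation = 30,
                                seed = 1L) {
  g1 <- generate_globule(globule_spec(n_per_domain, seed = seed))
  g2 <- generate_globule(globule_spec(n_per_domain, seed = seed + 1000L))
  a1 <- g1$structure$atoms
  a2 <- g2$structure$atoms
  a2$x <- a2$x + separation
  a2$resno <- a2$resno + n_per_domain
  atoms <- rbind(a1, a2)
  st <- structure(list(id = sprintf("twodomain_seed%d", seed), atoms = atoms,
                       metadata = list(seed = seed)),
                  class = "halo_structure")
  list(structure = st,
       domains = list(
         small = data.frame(start = 1, end = n_per_domain),
         large = data.frame(start = n_per_domain + 1,
                            end = 2 * n_per_domain)))
}

#' Specification for sequence evolution along a tree
#'
#' @param tree rooted `phylo` with branch lengths (substitutions/site).
#' @param model a [rate_model()].
#' @param n_sites root sequence length (ignored when `root_sequence`
#'   given).
#' @param root_sequence optional root amino-acid string; by default the
#'   root is drawn from the model's stationary frequencies.
#' @param indel_rate indel events per site per unit branch length (>= 0).
#' @param mean_indel_length mean indel tract length (geometric, >= 1).
#' @param seed integer seed (recorded in the output).
#' @return List of class `evolution_spec`.
#' @export
evolution_spec <- function(tree, model, n_sites = 200, root_sequence = NULL,
                           indel_rate = 0, mean_indel_length = 3,
                           seed = 1L) {
  stopifnot(inherits(tree, "phylo"), indel_rate >= 0,
            mean_indel_length >= 1)
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 root_sequence = root_sequence, indel_rate = indel_rate,
                 mean_indel_length = mean_indel_length,
                 seed = as.integer(seed)),
            class = "evolution_spec")
}

#' Evolve sequences along a tree with substitutions and indels
#'
#' The root sequence is drawn from the stationary frequencies (or given).
#' Along every branch of length `t`, each site substitutes according to
#' `P(t) = exp(Qt)`; indel events arrive as a Poisson process with rate
#' `indel_rate * t * length`, each a deletion or insertion (equal odds) of
#' geometric length (mean `mean_indel_length`), applied to contiguous
#' blocks left to right. Insertions create fresh alignment columns (gaps in
#' all lineages not carrying them); deletions leave gaps. True sequences at
#' every internal node are returned alongside the leaf alignment.
#'
#' @param spec an [evolution_spec()].
#' @return List of class `evolution` with `alignment` (named aligned leaf
#'   strings), `ancestral` (named aligned strings for internal nodes,
#'   names `"node<N>"` in ape numbering), `root_alignment` (the root row),
#'   `tree`, `seed`, `n_columns`.
#' @export
evolve_along_tree <- function(spec) {
  stopifnot(inherits(spec, "evolution_spec"))
  withr::local_seed(spec$seed)
  model <- spec$model
  states <- model$states
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (!is.null(spec$root_sequence)) {
    rs <- match(strsplit(toupper(spec$root_sequence), "")[[1]], states)
    if (anyNA(rs)) stop("root_sequence contains non-standard letters")
  } else {
    rs <- sample.int(20, spec$n_sites, replace = TRUE, prob = model$pi)
  }
  L0 <- length(rs)
  # master column registry; insertions splice fresh ids after their anchor
  env <- new.env()
  env$master <- seq_len(L0)
  env$next_id <- L0 + 1L
  seqs <- vector("list", ntip + tree$Nnode)   # per node: ids + states
  seqs[[root]] <- list(ids = seq_len(L0), st = rs)
  evolve_branch <- function(ids, st, t) {
    L <- length(st)
    if (L && t > 0) {
      P <- prob_matrix(model, t)
      old <- st
      for (s in unique(old)) {
        idx <- which(old == s)
        st[idx] <- sample.int(20, length(idx), replace = TRUE,
                              prob = P[s, ])
      }
    }
    if (spec$indel_rate > 0 && L > 0) {
      n_ev <- stats::rpois(1, spec$indel_rate * t * L)
      for (k in seq_len(n_ev)) {
        L <- length(st)
        if (!L) break
        len <- stats::rgeom(1, 1 / spec$mean_indel_length) + 1L
        if (stats::runif(1) < 0.5) {            # deletion
          start <- sample.int(L, 1)
          drop <- start:min(L, start + len - 1L)
          ids <- ids[-drop]; st <- st[-drop]
        } else {                                 # insertion
          pos <- sample.int(L + 1L, 1) - 1L      # insert after position pos
          new_ids <- env$next_id + seq_len(len) - 1L
          env$next_id <- env$next_id + len
          anchor <- if (pos == 0L) 0L else match(ids[pos], env$master)
          env$master <- append(env$master, new_ids, after = anchor)
          new_st <- sample.int(20, len, replace = TRUE, prob = model$pi)
          ids <- append(ids, new_ids, after = pos)
          st <- append(st, new_st, after = pos)
        }
      }
    }
    list(ids = ids, st = st)
  }
  # preorder traversal (parents before children) = reverse postorder
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  phy <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sq <- seqs[[p]]
    seqs[[ch]] <- evolve_branch(sq$ids, sq$st, phy$edge.length[e])
  }
  master <- env$master
  render <- function(sq) {
    out <- rep("-", length(master))
    out[match(sq$ids, master)] <- states[sq$st]
    paste(out, collapse = "")
  }
  aln <- vapply(seq_len(ntip), function(i) render(seqs[[i]]), character(1))
  names(aln) <- tree$tip.label
  anc_ids <- (ntip + 1L):(ntip + tree$Nnode)
  anc <- vapply(anc_ids, function(i) render(seqs[[i]]), character(1))
  names(anc) <- paste0("node", anc_ids)
  structure(list(alignment = aln, ancestral = anc,
                 root_alignment = anc[[paste0("node", root)]],
                 tree = tree, seed = spec$seed,
                 n_columns = length(master)),
            class = "evolution")
}
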