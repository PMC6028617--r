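# Coordinate, sequence and tree I/O.
#
# PDB records are parsed/written through bio3d, Newick through ape and FASTA
# through Biostrings; this file only adds the validation and the light
# residue/atom data model the downstream analyses need.

#' Read a protein structure from a PDB file
#'
#' Parses the ATOM records of the first model into a flat atom table.
#' HETATM records (ligands, ions, waters) are excluded from the protein model
#' but retained under `metadata$het`. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken in favour of altloc "A", then
#' alphabetically). Residue names outside the 20 standard amino acids are
#' kept with `res_type = "UNK"` and a warning.
#'
#' @param path path to a PDB-format text file.
#' @param id structure identifier; defaults to the file name without extension.
#' @return An object of class `halo_structure`: a list with
#'   \describe{
#'     \item{id}{identifier}
#'     \item{atoms}{data.frame with columns `chain`, `resno`, `insert`,
#'       `resid` (three-letter, `UNK` for non-standard), `elety` (atom name),
#'       `element`, `x`, `y`, `z`, `occupancy`, `radius` (van der Waals,
#'       Angstrom), `sidechain` (logical)}
#'     \item{metadata}{list with `het` (excluded HETATM table) and any header
#'       information}
#'   }
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || !any(at$type == "ATOM")) {
    stop("no ATOM records in ", path)
  }
  het <- at[at$type == "HETATM", , drop = FALSE]
  at <- at[at$type == "ATOM", , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- "A"

  # altloc resolution: keep highest occupancy per (chain, resno, insert, name);
  # ties go to altloc "A" (then alphabetical order).
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }

  resid <- toupper(at$resid)
  unknown <- !(resid %in% names(.aa3to1))
  if (any(unknown)) {
    warning(sprintf("%d atom(s) in non-standard residue(s) (%s) kept as UNK",
                    sum(unknown), paste(unique(resid[unknown]), collapse = ",")),
            call. = FALSE)
    resid[unknown] <- "UNK"
  }

  element <- toupper(at$elesy)
  noel <- is.na(element) | !nzchar(element)
  if (any(noel)) {
    # fall back on the first alphabetic character of the atom name
    element[noel] <- substr(gsub("[^A-Za-z].*", "",
                                 sub("^[0-9]*", "", at$elety[noel])), 1, 1)
  }

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = resid, elety = at$elety, element = element,
    x = at$x, y = at$y, z = at$z, occupancy = at$o,
    radius = suppressWarnings(.assign_radii(element)),
    sidechain = !(at$elety %in% .backbone_atoms),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates in ", path)
  }
  structure(
    list(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
         atoms = atoms,
         metadata = list(het = het)),
    class = "halo_structure"
  )
}

#' @export
print.halo_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<halo_structure> %s: %d atoms, %d residues, %d chain(s)\n",
              x$id, nrow(x$atoms), length(unique(rk)),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM records (via bio3d) so that a written
#' structure round-trips through [read_pdb()] with coordinates preserved to
#' the PDB's three-decimal precision.
#'
#' @param structure a `halo_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# residue key strings "chain|resno|insert" in atom order
residue_keys <- function(structure) {
  a <- if (is.data.frame(structure)) structure else structure$atoms
  paste(a$chain, a$resno, a$insert, sep = "|")
}

#' Per-residue summary table of a structure
#'
#' @param structure a `halo_structure`.
#' @return data.frame with one row per residue in file order: `chain`,
#'   `resno`, `insert`, `resid`, `res1` (one-letter, `X` for UNK), `key`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- residue_keys(structure)
  first <- !duplicated(key)
  data.frame(
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resid = a$resid[first], res1 = aa_three_to_one(a$resid[first]),
    key = key[first], stringsAsFactors = FALSE
  )
}

#' Extract the one-letter sequence of a chain
#'
#' Residues appear in file order; non-standard residues become `X`. Breaks in
#' the author residue numbering are not padded with gaps but recorded in the
#' `"breaks"` attribute (the residue numbers after which a gap in numbering
#' occurs).
#'
#' @param structure a `halo_structure`.
#' @param chain chain identifier. With an empty/missing chain id on a
#'   single-chain structure, that chain is used (with a message).
#' @return Character scalar of one-letter codes with attribute `"breaks"`.
#' @export
extract_sequence <- function(structure, chain = "") {
  rt <- residue_table(structure)
  chains <- unique(rt$chain)
  if (!nzchar(chain)) {
    if (length(chains) != 1L)
      stop("chain must be given for a multi-chain structure (chains: ",
           paste(chains, collapse = ","), ")")
    message("no chain given; using the single chain '", chains, "'")
    chain <- chains
  }
  if (!chain %in% chains) stop("unknown chain '", chain, "'")
  rt <- rt[rt$chain == chain, , drop = FALSE]
  seq <- paste(rt$res1, collapse = "")
  brk <- rt$resno[which(diff(rt$resno) > 1)]
  attr(seq, "breaks") <- brk
  seq
}

#' Read one or more Newick trees
#'
#' Multi-tree files hold one tree per line. Branch lengths must be
#' non-negative and finite; leaf labels must be unique within a tree.
#' Unrooted trees are used as read, rooted at their basal node, with a
#' message.
#'
#' @param path path to a Newick file.
#' @param single if `TRUE` (default) a file with one tree returns a single
#'   `phylo`; otherwise (or for multi-tree files) a list of `phylo`.
#' @return An [ape::read.tree()] `phylo` object or a list of them.
#' @export
read_newick <- function(path, single = TRUE) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty Newick file: ", path)
  trees <- lapply(lines, function(ln) {
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = ln)),
                   error = function(e) NULL)
    if (is.null(tr)) stop("Newick parse error (unbalanced or malformed): ", ln)
    validate_tree(tr)
  })
  if (length(trees) == 1L && single) trees[[1]] else trees
}

#' Validate a phylogenetic tree
#'
#' Checks unique leaf labels and non-negative, finite branch lengths; notes
#' (with a message) when an unrooted tree is treated as rooted at its basal
#' node.
#'
#' @param tree a `phylo`.
#' @return The validated tree, invisibly usable.
#' @export
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ","))
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)))
      stop("non-finite branch length in tree")
    if (any(tree$edge.length < 0))
      stop("negative branch length in tree")
  }
  if (!ape::is.rooted(tree))
    message("unrooted tree treated as rooted at its basal node")
  tree
}

#' Write trees to a Newick file
#'
#' @param trees a `phylo` or list of `phylo`; one tree per line.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr) ape::write.tree(tr), character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of (possibly aligned) sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file (wrapped at 60 columns)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}
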