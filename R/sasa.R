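# Solvent-accessible surface area (Shrake-Rupley) and its polar/charged
# decomposition.
#
# Test points are a deterministic golden-section spiral on the unit sphere.
# Each atom's point set is expressed in a local frame built from its two
# nearest neighbours, so the point cloud co-rotates with the structure and
# total ASA is exactly invariant under rigid transforms. The price is that
# adding an atom can reorient nearby frames, so monotonicity of ASA under
# atom addition holds only up to the area of a single test point.

#' Parameters for the accessibility calculation
#'
#' @param probe_radius solvent probe radius in Angstrom (1.4, water).
#' @param n_sphere_points number of spiral test points per atom (>= 12).
#' @param radii_table named element -> radius (Angstrom) vector.
#' @param exclude_hydrogens drop H atoms before the calculation. Hydrogens
#'   are rare in crystallographic inputs; when present they are included
#'   unless excluded here.
#' @return A list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii_table = vdw_radii(), exclude_hydrogens = FALSE) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 12)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_table = radii_table,
                 exclude_hydrogens = isTRUE(exclude_hydrogens)),
            class = "sasa_params")
}

# Golden-section spiral: n deterministic, near-uniform points on the unit
# sphere.
sphere_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Local orthonormal frame for atom i from its two nearest neighbours
# (deterministic tie-break by index). Returns a 3x3 rotation whose rows are
# the frame axes; identity when the atom has no neighbours.
.local_frame <- function(i, coords, nbr_idx) {
  if (!length(nbr_idx)) return(diag(3))
  d2 <- colSums((t(coords[nbr_idx, , drop = FALSE]) - coords[i, ])^2)
  # quantize before ranking so exact-tie neighbours keep a stable order
  # under the ~1e-13 coordinate noise of a rigid transform
  ord <- nbr_idx[order(round(d2, 6), nbr_idx)]
  e1 <- NULL
  while (length(ord)) {
    v1 <- coords[ord[1L], ] - coords[i, ]
    n1 <- sqrt(sum(v1^2))
    if (n1 > 1e-8) { e1 <- v1 / n1; break }
    ord <- ord[-1L]          # coincident neighbour carries no direction
  }
  if (is.null(e1)) return(diag(3))
  e2 <- NULL
  for (j in ord[-1L]) {
    v2 <- coords[j, ] - coords[i, ]
    v2 <- v2 - sum(v2 * e1) * e1
    n2 <- sqrt(sum(v2^2))
    if (n2 > 1e-8) { e2 <- v2 / n2; break }
  }
  if (is.null(e2)) {
    # single (or collinear) neighbours: occlusion is axially symmetric about
    # e1, so any deterministic perpendicular gives identical counts
    k <- which.min(abs(e1))
    v2 <- numeric(3); v2[k] <- 1
    v2 <- v2 - sum(v2 * e1) * e1
    e2 <- v2 / sqrt(sum(v2^2))
  }
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rbind(e1, e2, e3)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For every atom, test points are placed on a sphere of radius
#' `r_vdw + probe` and a point is occluded when it lies within
#' `r_j + probe` of any other atom centre `j`. The atom's ASA is the exposed
#' fraction of `4 * pi * (r_vdw + probe)^2`.
#'
#' @param structure a `halo_structure`.
#' @param params a [sasa_params()] object.
#' @return Numeric vector of per-atom ASA (Angstrom^2), one entry per row of
#'   `structure$atoms` (NA for hydrogens when excluded).
#' @export
shrake_rupley <- function(structure, params = sasa_params()) {
  a <- structure$atoms
  if (!nrow(a)) stop("empty structure")
  keep <- rep(TRUE, nrow(a))
  if (params$exclude_hydrogens) keep <- a$element != "H"
  coords <- as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
  if (any(!is.finite(coords))) stop("non-finite atom coordinates")
  r <- params$radii_table[a$element[keep]]
  r[is.na(r)] <- .vdw_default
  r <- unname(r) + params$probe_radius
  n <- nrow(coords)
  pts <- sphere_spiral(params$n_sphere_points)
  m <- nrow(pts)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    di2 <- colSums((t(coords) - coords[i, ])^2)
    cut <- (r[i] + r)^2
    nbr <- which(di2 <= cut & seq_len(n) != i)
    if (!length(nbr)) { asa[i] <- 4 * pi * r[i]^2; next }
    fr <- .local_frame(i, coords, nbr)
    p <- pts %*% fr * r[i]
    p <- sweep(p, 2, coords[i, ], "+")
    # squared distance of every test point to every neighbour centre
    nb <- coords[nbr, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(nb^2), "+") - 2 * p %*% t(nb)
    occluded <- d2 <= rep(r[nbr]^2, each = m) + 1e-9
    exposed <- m - sum(rowSums(occluded) > 0)
    asa[i] <- exposed / m * 4 * pi * r[i]^2
  }
  out <- rep(NA_real_, nrow(a))
  out[keep] <- asa
  out
}

#' Aggregate atom ASA to residues with a polar/charged decomposition
#'
#' Residue total ASA is the sum over its atoms. The decomposition follows a
#' VADAR-style atom-class rule: *charged* is the ASA of side-chain oxygens of
#' Asp/Glu and side-chain nitrogens of Lys/Arg/His; *polar* is the ASA of all
#' other nitrogen, oxygen and sulfur atoms; *nonpolar* is everything else
#' (carbons, hydrogens). The three classes sum to the total.
#'
#' @param atom_asa numeric vector from [shrake_rupley()] (NA entries, e.g.
#'   excluded hydrogens, count as zero area).
#' @param structure the same `halo_structure`.
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `res_type` (three-letter), `res1`, `key`, `total_asa`, `polar_asa`,
#'   `charged_asa`, `nonpolar_asa` (Angstrom^2).
#' @export
residue_asa <- function(atom_asa, structure) {
  a <- structure$atoms
  stopifnot(length(atom_asa) == nrow(a))
  asa <- ifelse(is.na(atom_asa), 0, atom_asa)
  key <- residue_keys(structure)
  charged <- a$sidechain &
    paste(a$resid, a$elety, sep = "|") %in% .charged_atoms
  polar <- !charged & a$element %in% c("N", "O", "S")
  cls <- ifelse(charged, "charged", ifelse(polar, "polar", "nonpolar"))
  rt <- residue_table(structure)
  sum_by <- function(w) {
    v <- tapply(asa * w, key, sum)
    as.numeric(v[rt$key])
  }
  data.frame(
    rt[, c("chain", "resno", "insert", "key")],
    res_type = rt$resid, res1 = rt$res1,
    total_asa = sum_by(1),
    polar_asa = sum_by(cls == "polar"),
    charged_asa = sum_by(cls == "charged"),
    nonpolar_asa = sum_by(cls == "nonpolar"),
    stringsAsFactors = FALSE
  )
}

#' Structure-level accessibility report
#'
#' Convenience wrapper running [shrake_rupley()] and [residue_asa()].
#'
#' @inheritParams shrake_rupley
#' @return The [residue_asa()] data.frame.
#' @export
structure_asa <- function(structure, params = sasa_params()) {
  residue_asa(shrake_rupley(structure, params), structure)
}
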