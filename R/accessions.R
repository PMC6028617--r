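# Helpers for the deposited ADP-dependent kinase structures used in the
# published comparison: the ancestral Methanosarcinales PFK/GK (PDB 6C8Z)
# and the Pyrococcus horikoshii PFK (PDB 1U2X).

#' Locate or download deposited PDB coordinate files
#'
#' Looks for `<id>.pdb` in `cache_dir` and otherwise attempts to download
#' from RCSB. Downloads require network access; on failure the missing
#' entries are returned as paths that do not exist (callers decide how to
#' react).
#'
#' @param ids PDB accession codes, e.g. `c("6C8Z", "1U2X")`.
#' @param cache_dir directory searched first and used to store downloads.
#' @return Character vector of file paths (existing only if available).
#' @export
fetch_rcsb_pdb <- function(ids, cache_dir = file.path(tempdir(),
                                                      "haloadapt_pdb")) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  vapply(ids, function(id) {
    dest <- file.path(cache_dir, paste0(toupper(id), ".pdb"))
    if (!file.exists(dest)) {
      url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
      ok <- tryCatch(
        utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
        error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok && file.exists(dest)) unlink(dest)
    }
    dest
  }, character(1))
}

#' Domain definitions for the ADP-dependent kinase comparison
#'
#' Approximate residue ranges of the small (lid) and large (Rossmann)
#' domains of the ancestral Methanosarcinales PFK/GK (6C8Z, ranges "a") and
#' the P. horikoshii PFK (1U2X, ranges "b"). The deposited entries do not
#' annotate domain boundaries, so these are configuration defaults following
#' the family's lid-over-Rossmann architecture; refine them per analysis
#' when exact boundaries are available.
#'
#' @return List of two [domain_definition()] objects (`small`, `large`).
#' @export
adpk_domain_definitions <- function() {
  list(
    domain_definition(
      "small",
      ranges_a = data.frame(start = 105, end = 215),   # 6C8Z lid
      ranges_b = data.frame(start = 89, end = 196)),   # 1U2X lid
    domain_definition(
      "large",
      ranges_a = data.frame(start = c(1, 216), end = c(104, 500)),
      ranges_b = data.frame(start = c(1, 197), end = c(88, 460))))
}
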