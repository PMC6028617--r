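# Inner/outer shell partition and per-shell amino-acid composition
# statistics.
#
# A residue with total ASA >= 5 A^2 is surface exposed ("outer" shell),
# otherwise buried ("inner" shell). The statistical unit for group
# comparisons is the structure: one composition vector per protein per
# shell.

#' Partition residues into inner and outer shells
#'
#' @param accessibility a [residue_asa()] data.frame.
#' @param threshold ASA threshold in Angstrom^2 (default 5): residues with
#'   `total_asa >= threshold` are outer (surface exposed), the rest inner
#'   (buried core).
#' @return The input data.frame with an added `shell` factor
#'   (`"inner"`/`"outer"`); threshold stored as attribute `"threshold"`.
#' @export
classify_shells <- function(accessibility, threshold = 5) {
  stopifnot(threshold >= 0)
  out <- accessibility
  out$shell <- factor(ifelse(out$total_asa >= threshold, "outer", "inner"),
                      levels = c("inner", "outer"))
  attr(out, "threshold") <- threshold
  out
}

#' Amino-acid composition of one shell
#'
#' Percentage of each residue type among the residues of the chosen shell:
#' `100 * count(aa) / n_shell`. UNK residues are excluded from numerator and
#' denominator (their count is reported in attribute `"n_unk"`).
#'
#' @param shells output of [classify_shells()].
#' @param shell `"inner"` or `"outer"`.
#' @return Named numeric 20-vector of percentages in [aa_states()] order,
#'   summing to 100; attributes `"n"` (residues counted) and `"n_unk"`.
#'   An empty shell raises an error of class `haloadapt_empty_shell`.
#' @export
shell_composition <- function(shells, shell = c("outer", "inner")) {
  shell <- match.arg(shell)
  res <- shells$res1[shells$shell == shell]
  n_unk <- sum(res == "X")
  res <- res[res != "X"]
  if (!length(res)) {
    stop(structure(class = c("haloadapt_empty_shell", "error", "condition"),
                   list(message = paste0("empty ", shell, " shell"),
                        call = sys.call(-1))))
  }
  counts <- table(factor(res, levels = aa_states()))
  pct <- 100 * as.numeric(counts) / length(res)
  names(pct) <- aa_states()
  attr(pct, "n") <- length(res)
  attr(pct, "n_unk") <- n_unk
  pct
}

#' Per-structure, per-shell composition table for grouped structures
#'
#' @param accessibilities named list: group label -> named list of
#'   [residue_asa()] tables (one per structure).
#' @param threshold shell threshold in Angstrom^2.
#' @return Long data.frame: `group`, `structure`, `shell`, `res1`, `pct`.
#'   Structures with an empty shell contribute `NA` percentages for that
#'   shell (flagged, never zero-filled).
#' @export
composition_table <- function(accessibilities, threshold = 5) {
  rows <- list()
  for (grp in names(accessibilities)) {
    for (sid in names(accessibilities[[grp]])) {
      sh <- classify_shells(accessibilities[[grp]][[sid]], threshold)
      for (shell in c("inner", "outer")) {
        pct <- tryCatch(shell_composition(sh, shell),
                        haloadapt_empty_shell = function(e) {
                          p <- rep(NA_real_, 20); names(p) <- aa_states(); p
                        })
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, structure = sid, shell = shell,
          res1 = aa_states(), pct = as.numeric(pct),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Signed percent difference of a group mean against a control mean
#'
#' `100 * (group_mean - control_mean) / control_mean`; positive values are
#' enrichments, negative values depletions (a depletion of magnitude 72
#' corresponds to the reporting convention "decrease of 72%").
#'
#' @param group_mean,control_mean mean percentages (control must be > 0;
#'   zero controls yield `NA` with a warning).
#' @return Numeric vector of signed percent differences with attribute
#'   `"direction"` (`"increase"`/`"decrease"`/`"none"`).
#' @export
percent_difference <- function(group_mean, control_mean) {
  bad <- !is.na(control_mean) & control_mean == 0
  if (any(bad)) {
    warning("control mean of 0: percent difference undefined, returning NA",
            call. = FALSE)
    control_mean[bad] <- NA_real_
  }
  pd <- 100 * (group_mean - control_mean) / control_mean
  dir <- ifelse(is.na(pd), NA_character_,
                ifelse(pd > 0, "increase", ifelse(pd < 0, "decrease", "none")))
  attr(pd, "direction") <- dir
  pd
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (via [stats::kruskal.test()]). When every observation is
#' identical the test is degenerate and the documented convention H = 0,
#' p = 1 is returned.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 observations.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' For groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))` over tie groups, and a
#' two-sided normal p-value adjusted for multiplicity.
#'
#' @param groups list of numeric vectors (named names are used as labels).
#' @param adjust multiplicity adjustment: `"bonferroni"` (classical Dunn
#'   recommendation, default), `"holm"` or `"none"`.
#' @return data.frame with one row per unordered pair: `group1`, `group2`,
#'   `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
             z = as.numeric(z), p = p,
             p_adj = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Group comparison of shell compositions
#'
#' For every residue type and shell: Kruskal-Wallis across groups on the
#' per-structure percentages, Dunn's post hoc pairwise z, and the percent
#' difference of each group mean against the control group mean.
#'
#' @param comp long table from [composition_table()].
#' @param control control group label (the outgroup the paper-style percent
#'   differences are taken against).
#' @param adjust Dunn multiplicity adjustment, see [dunn_posthoc()].
#' @return List with
#'   \describe{
#'     \item{tests}{data.frame `shell`, `res1`, `H`, `p`}
#'     \item{pairwise}{data.frame of Dunn rows with `shell`, `res1` columns}
#'     \item{differences}{data.frame `shell`, `res1`, `group`, `group_mean`,
#'       `control_mean`, `percent_difference`, `direction`}
#'   }
#' @export
compare_groups <- function(comp, control, adjust = "bonferroni") {
  stopifnot(control %in% comp$group)
  tests <- list(); pairwise <- list(); diffs <- list()
  for (shell in unique(comp$shell)) {
    for (aa in aa_states()) {
      sub <- comp[comp$shell == shell & comp$res1 == aa & !is.na(comp$pct), ]
      grps <- split(sub$pct, sub$group)
      grps <- grps[lengths(grps) >= 2]
      if (length(grps) >= 2) {
        kw <- kruskal_wallis(grps)
        tests[[length(tests) + 1L]] <- data.frame(
          shell = shell, res1 = aa, H = kw$H, p = kw$p,
          stringsAsFactors = FALSE)
        dn <- dunn_posthoc(grps, adjust)
        pairwise[[length(pairwise) + 1L]] <-
          cbind(shell = shell, res1 = aa, dn, stringsAsFactors = FALSE)
      }
      means <- vapply(split(sub$pct, sub$group), mean, numeric(1))
      if (control %in% names(means)) {
        others <- setdiff(names(means), control)
        if (length(others)) {
          pd <- suppressWarnings(
            percent_difference(means[others], means[[control]]))
          diffs[[length(diffs) + 1L]] <- data.frame(
            shell = shell, res1 = aa, group = others,
            group_mean = as.numeric(means[others]),
            control_mean = means[[control]],
            percent_difference = as.numeric(pd),
            direction = attr(pd, "direction"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(tests = do.call(rbind, tests),
       pairwise = do.call(rbind, pairwise),
       differences = do.call(rbind, diffs))
}
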