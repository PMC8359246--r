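# Morphological prevalence accounting: Noyes-grade contingency tables,
# Pearson chi-square tests (no continuity correction), exclusion-list
# construction, and phantom coefficient-of-variation QC.

#' Round half up to a number of decimals
#'
#' Percentage formatting convention (1 decimal, half up), matching how knee
#' counts such as 3/48 print as 6.3%.
#' @param x numeric; @param digits decimals
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Is a knee morphologically abnormal?
#'
#' TRUE iff any compartment has modified Noyes grade >= 1. All six
#' compartments must be graded.
#'
#' @param grades named vector/list of grades for LFC, MFC, TRO, PAT, LT, MT
#' @return logical
#' @export
knee_abnormal <- function(grades) {
  g <- unlist(grades)
  missing <- setdiff(CARTILAGE_COMPARTMENTS, names(g))
  if (length(missing))
    stop("missing compartment grade(s): ", paste(missing, collapse = ", "))
  any(g[CARTILAGE_COMPARTMENTS] >= 1)
}

meta_grades <- function(meta) {
  g <- as.matrix(meta[, paste0("noyes_", CARTILAGE_COMPARTMENTS), drop = FALSE])
  colnames(g) <- CARTILAGE_COMPARTMENTS
  g
}

#' Knees to exclude from compositional analysis (Noyes >= 1 anywhere)
#' @param meta subject table with noyes_* columns
#' @return character vector of knee ids
#' @export
build_exclusion_list <- function(meta) {
  g <- meta_grades(meta)
  meta$knee_id[rowSums(g >= 1) > 0]
}

#' Pearson chi-square test of a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the row/column margins and
#' `df = (r - 1) (c - 1)`; no continuity correction (the convention that
#' reproduces the printed prevalence statistics). A zero margin makes the
#' test undefined and is an error.
#'
#' @param table r x c matrix of nonnegative counts
#' @return list with `statistic`, `df`, `p`, `expected`
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 rows and 2 columns")
  if (any(tab < 0)) stop("counts must be nonnegative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin: chi-square test undefined")
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Prevalence tables of cartilage abnormalities
#'
#' Per compartment: group x grade counts with percentages of the group knee
#' totals, plus the grade-level chi-square (primary) and the binary
#' (abnormal vs normal) chi-square; tests with a zero margin (no
#' abnormalities anywhere) are reported as NA, not errors. Per knee:
#' group x abnormal/normal counts via [knee_abnormal()].
#'
#' @param meta subject table with group and noyes_* columns
#' @return list with `per_compartment` (data.frame), `per_knee` (data.frame),
#'   `knee_table` (2 x 2 counts), `knee_chi_square`
#' @export
prevalence_table <- function(meta) {
  g <- meta_grades(meta)
  grp <- meta$group
  ntot <- c(A = sum(grp == "A"), B = sum(grp == "B"))
  rows <- list()
  for (comp in CARTILAGE_COMPARTMENTS) {
    counts <- vapply(c("A", "B"), function(gg)
      vapply(0:2, function(k) sum(g[grp == gg, comp] == k), 0L), integer(3))
    grade_tab <- t(counts)  # groups x grades
    nonzero_cols <- colSums(grade_tab) > 0
    chi_grade <- if (sum(nonzero_cols) >= 2)
      chi_square(grade_tab[, nonzero_cols, drop = FALSE])$statistic else
      NA_real_
    bin <- cbind(abnormal = rowSums(grade_tab[, -1, drop = FALSE]),
                 normal = grade_tab[, 1])
    chi_bin <- if (all(colSums(bin) > 0)) chi_square(bin) else NULL
    for (k in 0:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = comp, grade = k,
        count_A = grade_tab["A", k + 1], pct_A =
          round_half_up(100 * grade_tab["A", k + 1] / ntot["A"]),
        count_B = grade_tab["B", k + 1], pct_B =
          round_half_up(100 * grade_tab["B", k + 1] / ntot["B"]),
        chi_square_grade = if (k == 0) chi_grade else NA_real_,
        chi_square_binary = if (k == 0 && !is.null(chi_bin))
          chi_bin$statistic else NA_real_,
        p_binary = if (k == 0 && !is.null(chi_bin)) chi_bin$p else NA_real_)
    }
  }
  per_comp <- do.call(rbind, rows)
  abn <- apply(g, 1, function(r) any(r >= 1))
  knee_tab <- rbind(A = c(abnormal = sum(abn[grp == "A"]),
                          normal = sum(!abn[grp == "A"])),
                    B = c(abnormal = sum(abn[grp == "B"]),
                          normal = sum(!abn[grp == "B"])))
  knee_chi <- if (all(colSums(knee_tab) > 0) && all(rowSums(knee_tab) > 0))
    chi_square(knee_tab) else NULL
  per_knee <- data.frame(
    group = c("A", "B"),
    n_knees = as.integer(ntot),
    n_abnormal = knee_tab[, "abnormal"],
    pct_abnormal = round_half_up(100 * knee_tab[, "abnormal"] / ntot))
  list(per_compartment = per_comp, per_knee = per_knee,
       knee_table = knee_tab,
       knee_chi_square = if (!is.null(knee_chi)) knee_chi else
         list(statistic = NA_real_, df = NA, p = NA_real_))
}

#' Coefficients of variation for the repeatability phantom
#'
#' Fits each decay series, then reports per-vial CV (sample SD / mean x 100):
#' intra-scanner over repeats within each scanner, and inter-scanner over
#' per-scanner mean estimates.
#'
#' @param phantom data.frame from [generate_phantom_series()] (columns
#'   scanner, rep, vial, time_ms, signal), or a precomputed data.frame of
#'   estimates with columns scanner, rep, vial, t_ms (set `fitted = TRUE`)
#' @param fitted set TRUE if `phantom` already holds per-series estimates
#' @return list with `estimates`, `intra` (per scanner x vial CV %),
#'   `inter` (per vial CV % across scanner means); vials with nonpositive
#'   mean are flagged NA
#' @export
coefficient_of_variation <- function(phantom, fitted = FALSE) {
  if (!fitted) {
    keys <- unique(phantom[, c("scanner", "rep", "vial")])
    est <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sel <- phantom$scanner == keys$scanner[i] & phantom$rep == keys$rep[i] &
        phantom$vial == keys$vial[i]
      f <- fit_monoexp(phantom$time_ms[sel], phantom$signal[sel])
      data.frame(scanner = keys$scanner[i], rep = keys$rep[i],
                 vial = keys$vial[i], t_ms = f$t)
    }))
  } else est <- phantom
  cv <- function(x) {
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    if (length(x) < 2) return(NA_real_)
    100 * sd(x) / m
  }
  intra <- do.call(rbind, lapply(split(est, est[, c("scanner", "vial")]),
                                 function(d) data.frame(
                                   scanner = d$scanner[1], vial = d$vial[1],
                                   cv_pct = cv(d$t_ms))))
  rownames(intra) <- NULL
  scanner_means <- do.call(rbind, lapply(
    split(est, est[, c("scanner", "vial")]),
    function(d) data.frame(scanner = d$scanner[1], vial = d$vial[1],
                           t_ms = mean(d$t_ms))))
  inter <- do.call(rbind, lapply(split(scanner_means, scanner_means$vial),
                                 function(d) data.frame(
                                   vial = d$vial[1],
                                   cv_pct = if (nrow(d) >= 2) cv(d$t_ms)
                                   else NA_real_)))
  rownames(inter) <- NULL
  list(estimates = est, intra = intra, inter = inter,
       sd_convention = "sample (n-1)")
}
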