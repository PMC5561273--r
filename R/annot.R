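#' @title Monoisotopic atomic masses used for formula-based annotation
#' @description Masses (Da) of the most abundant isotope for the elements the
#'   annotation chain supports. Values follow standard IUPAC compilations.
#' @keywords internal
.monoisotopic_masses <- c(
  C  = 12.000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370668
)

#' Mass of a proton in Da, used for positive-mode adduct m/z.
#' @keywords internal
.proton_mass <- 1.00727646

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-notation strings of element symbols with optional integer
#' counts, e.g. `"C9H11NO2"` or `"H2O"`. Parentheses, charges and isotope
#' labels are not supported.
#'
#' @param formula a single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C9H11NO2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("`formula` must be a single non-empty string")
  }
  pos <- 1L
  n <- nchar(formula)
  counts <- integer(0)
  while (pos <= n) {
    rest <- substr(formula, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop(sprintf("malformed formula '%s' at position %d", formula, pos))
    }
    elem <- m[2]
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (!elem %in% names(.monoisotopic_masses)) {
      stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                   elem, formula, pos))
    }
    counts[elem] <- if (elem %in% names(counts)) counts[[elem]] + cnt else cnt
    pos <- pos + nchar(m[1])
  }
  counts
}

#' Monoisotopic mass of a parsed formula
#'
#' Sums per-element monoisotopic masses over the element counts returned by
#' [parse_formula()]. An empty count vector has mass 0.
#'
#' @param counts named integer vector of element counts.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(counts) {
  if (length(counts) == 0L) return(0)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be a named vector of element counts")
  }
  missing <- setdiff(names(counts), names(.monoisotopic_masses))
  if (length(missing) > 0L) {
    stop(sprintf("element(s) missing from mass table: %s",
                 paste(missing, collapse = ", ")))
  }
  sum(.monoisotopic_masses[names(counts)] * as.numeric(counts))
}

#' Protonated adduct m/z
#'
#' Theoretical m/z of the singly protonated molecular ion \[M+H\]+ observed in
#' positive-mode MALDI: neutral mass plus the proton mass 1.00727646 Da.
#'
#' @param mass neutral monoisotopic mass in Da, > 0.
#' @return m/z of the \[M+H\]+ ion.
#' @export
protonated_mz <- function(mass) {
  if (!is.numeric(mass) || any(mass <= 0)) stop("`mass` must be > 0")
  mass + .proton_mass
}

.adduct_shift <- function(adduct) {
  switch(adduct,
    "[M+H]+"  = .proton_mass,
    "[M+2H]+" = 2 * .proton_mass,
    "[M+Na]+" = .monoisotopic_masses[["Na"]] - 0.00054858,
    "[M+K]+"  = .monoisotopic_masses[["K"]] - 0.00054858,
    stop(sprintf("unsupported adduct '%s'", adduct))
  )
}

#' Bundled compound table
#'
#' Small reference table of pathway compounds (phenylalanine/tyrosine
#' metabolism) shipped with the package: name, molecular formula, pathway tag.
#' Users may supply their own CSV with the same columns to
#' [match_compound_to_bin()] and [annotate_bins()].
#'
#' @param path optional path to a user CSV `name,formula,pathway`.
#' @return data.frame with columns `name`, `formula`, `pathway`, plus computed
#'   `monoisotopic_mass`.
#' @export
compound_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.csv", package = "hostdiscrim",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula") %in% names(tab)))
  if (!"pathway" %in% names(tab)) tab$pathway <- NA_character_
  tab$monoisotopic_mass <- vapply(
    tab$formula, function(f) monoisotopic_mass(parse_formula(f)), numeric(1)
  )
  tab
}

#' Match a compound to m/z bins via adduct masses
#'
#' For each adduct, computes the theoretical m/z, locates the 0.2-Da bin it
#' falls in (half-open bins anchored at the range minimum) and the nominal
#' integer bin (floor of the theoretical m/z).
#'
#' @param name compound name.
#' @param formula molecular formula string.
#' @param binning a [binning_config()].
#' @param adducts character vector of adducts; default `"[M+H]+"`.
#'   `"[M+2H]+"`, `"[M+Na]+"` and `"[M+K]+"` are also available.
#' @return data.frame of hits: compound, adduct, theoretical m/z, 0.2-Da bin
#'   label, nominal bin. Adducts falling outside the binning range yield no
#'   row.
#' @export
match_compound_to_bin <- function(name, formula, binning = binning_config(),
                                  adducts = "[M+H]+") {
  mass <- monoisotopic_mass(parse_formula(formula))
  hits <- lapply(adducts, function(a) {
    mz <- mass + .adduct_shift(a)
    if (mz < binning$range_min || mz >= binning$range_max) return(NULL)
    edge <- bin_left_edge(mz, binning)
    data.frame(compound = name, formula = formula, adduct = a,
               theoretical_mz = mz,
               bin = sprintf("%.1f", edge),
               nominal_bin = floor(mz),
               stringsAsFactors = FALSE)
  })
  hits <- Filter(Negate(is.null), hits)
  if (length(hits) == 0L) return(NULL)
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Reverse query: compounds matching a nominal m/z bin
#'
#' Finds compounds in a compound table whose adduct m/z lies within
#' `tolerance_da` of the centre of the queried nominal (integer) bin, or whose
#' nominal bin equals the query.
#'
#' @param nominal_bin integer m/z bin to query.
#' @param compounds data.frame from [compound_table()].
#' @param binning a [binning_config()].
#' @param tolerance_da mass tolerance in Da (default 0.1) applied around each
#'   adduct m/z when deciding membership of the nominal bin.
#' @param adducts adducts to consider.
#' @return data.frame of hits with mass error relative to `nominal_bin + 0.5`
#'   omitted; `mass_error_da` is theoretical m/z minus the nominal bin value.
#' @export
match_bin_to_compounds <- function(nominal_bin, compounds = compound_table(),
                                   binning = binning_config(),
                                   tolerance_da = 0.1,
                                   adducts = "[M+H]+") {
  hits <- lapply(seq_len(nrow(compounds)), function(i) {
    h <- match_compound_to_bin(compounds$name[i], compounds$formula[i],
                               binning, adducts)
    if (is.null(h)) return(NULL)
    keep <- h$theoretical_mz >= nominal_bin - tolerance_da &
      h$theoretical_mz < nominal_bin + 1 + tolerance_da
    h <- h[keep, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    h$mass_error_da <- h$theoretical_mz - nominal_bin
    h
  })
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(compound = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      bin = character(0), nominal_bin = integer(0),
                      mass_error_da = numeric(0))
  }
  out
}

#' Annotate a list of bins against a compound table
#'
#' @param nominal_bins integer vector of nominal m/z bins (e.g. from
#'   [select_top_bins()] output).
#' @inheritParams match_bin_to_compounds
#' @return data.frame of all hits across the queried bins.
#' @export
annotate_bins <- function(nominal_bins, compounds = compound_table(),
                          binning = binning_config(), tolerance_da = 0.1,
                          adducts = "[M+H]+") {
  hits <- lapply(nominal_bins, function(b) {
    h <- match_bin_to_compounds(b, compounds, binning, tolerance_da, adducts)
    if (nrow(h) > 0L) h$query_bin <- b
    h
  })
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

.group_bin_values <- function(m, bin, group_species) {
  stopifnot(inherits(m, "profile_matrix"))
  bin <- as.character(bin)
  if (!bin %in% colnames(m$values)) {
    stop(sprintf("bin '%s' not present in matrix", bin))
  }
  rows <- m$meta$species %in% group_species
  if (!any(rows)) stop("empty group: no plants for the given species")
  m$values[rows, bin]
}

#' Log fold change of mean %TIC between two species groups
#'
#' Fold change of the group means of a bin's %TIC between two disjoint sets of
#' species (by default base-2 log). A pseudo-count of 1e-6 %TIC is added to
#' both means when either is zero, with a message.
#'
#' @param m a `profile_matrix`.
#' @param bin bin label (column name of the matrix).
#' @param group_a,group_b character vectors of species names; must be disjoint
#'   and non-empty.
#' @param log_base base of the logarithm (default 2).
#' @return log fold change, positive when group A is more abundant.
#' @export
group_log_fold_change <- function(m, bin, group_a, group_b, log_base = 2) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint")
  }
  mean_a <- mean(.group_bin_values(m, bin, group_a))
  mean_b <- mean(.group_bin_values(m, bin, group_b))
  if (mean_a <= 0 || mean_b <= 0) {
    message("zero group mean: adding pseudo-count 1e-6 %TIC to both means")
    mean_a <- mean_a + 1e-6
    mean_b <- mean_b + 1e-6
  }
  log(mean_a / mean_b, base = log_base)
}

#' Linear-model F test of log %TIC between two species groups
#'
#' Ordinary least squares of log(%TIC + eps) on a two-level group indicator
#' across individual plants; returns the F statistic with df1 = 1,
#' df2 = nA + nB - 2 and its two-sided P value. Degrees of freedom are always
#' derived from the data supplied.
#'
#' @inheritParams group_log_fold_change
#' @param eps pseudo-count added inside the log (default 1e-6 %TIC).
#' @return list with `F`, `df1`, `df2`, `p_value`, `log_fold_change`, and the
#'   group species lists.
#' @export
group_lm_ftest <- function(m, bin, group_a, group_b, eps = 1e-6) {
  ya <- .group_bin_values(m, bin, group_a)
  yb <- .group_bin_values(m, bin, group_b)
  if (length(ya) < 2L || length(yb) < 2L) {
    stop("need at least 2 plants per group")
  }
  y <- log(c(ya, yb) + eps)
  g <- factor(rep(c("A", "B"), c(length(ya), length(yb))))
  if (stats::var(y[g == "A"]) == 0 && stats::var(y[g == "B"]) == 0) {
    stop("zero within-group variance in both groups")
  }
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  list(F = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
       p_value = an[["Pr(>F)"]][1],
       log_fold_change = group_log_fold_change(m, bin, group_a, group_b),
       group_a = group_a, group_b = group_b)
}
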