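#' Physical constants used throughout the pipeline
#'
#' Returns the fixed masses and experiment-level constants used by the
#' Kendrick and ion-ladder machinery: the exact monoisotopic mass of the
#' (epi)catechin repeat unit C15H14O6 (the Kendrick base unit), its nominal
#' mass, the proton mass used for negative-mode deprotonation, the
#' 13C - 12C mass difference, the monoisotopic mass of hydrogen, the natural
#' abundance of 13C, and the sequencing read length used for MAG coverage.
#'
#' @param overrides named list of values replacing individual defaults
#'   (testing hook; unknown names are an error).
#'
#' @return named list of constants.
#' @export
#' @examples
#' ct_constants()$base_unit_exact_mass
ct_constants <- function(overrides = list()) {
  const <- list(
    base_unit_exact_mass = 290.079038,
    base_unit_nominal = 290,
    proton_mass = 1.00727646,
    c13_minus_c12 = 1.0033548,
    h_monoisotopic = 1.00782503,
    c13_natural_abundance = 0.0107,
    read_length = 151
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(const))
    if (length(bad)) {
      stop("unknown constant override(s): ", paste(bad, collapse = ", "))
    }
    const[names(overrides)] <- overrides
  }
  const
}

# Monoisotopic atomic masses (CODATA/AME); 12C is exactly 12 by definition.
.monoisotopic_masses <- c(
  C = 12,
  H = 1.00782503207,
  O = 15.99491461956,
  N = 14.0030740048,
  S = 31.97207100
)

# IUPAC standard (average) atomic weights.
.average_masses <- c(
  C = 12.011,
  H = 1.008,
  O = 15.999,
  N = 14.007,
  S = 32.06
)

#' Construct a chemical formula
#'
#' A formula is a named integer vector of element counts restricted to
#' C, H, O, N, S. At least one count must be positive and none negative.
#'
#' @param C,H,O,N,S element counts (non-negative integers).
#' @return object of class `chem_formula`.
#' @export
#' @examples
#' chem_formula(C = 15, H = 14, O = 6)
chem_formula <- function(C = 0, H = 0, O = 0, N = 0, S = 0) {
  counts <- c(C = C, H = H, O = O, N = N, S = S)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("formula must contain at least one atom")
  structure(as.integer(round(counts)),
            names = names(counts), class = "chem_formula")
}

#' Parse a Hill-style formula string such as "C15H14O6"
#'
#' @param x a formula string over the elements C, H, O, N, S.
#' @return object of class `chem_formula`.
#' @export
parse_chem_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  counts <- c(C = 0L, H = 0L, O = 0L, N = 0L, S = 0L)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    if (!sym %in% names(counts)) stop("unknown element symbol: ", sym)
    num <- sub("^[A-Za-z]+", "", p)
    counts[[sym]] <- counts[[sym]] + if (nzchar(num)) as.integer(num) else 1L
  }
  do.call(chem_formula, as.list(counts))
}

#' @export
format.chem_formula <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

.check_formula <- function(formula) {
  if (!inherits(formula, "chem_formula")) {
    if (is.character(formula)) return(parse_chem_formula(formula))
    stop("expected a chem_formula or a formula string")
  }
  formula
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times monoisotopic atomic mass over the formula's elements,
#' with 12C exactly 12 Da. The (epi)catechin unit C15H14O6 evaluates to
#' 290.079038 Da, the constant of the Kendrick rescaling.
#'
#' @param formula a `chem_formula` (or formula string).
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(chem_formula(C = 15, H = 14, O = 6))
monoisotopic_mass <- function(formula) {
  formula <- .check_formula(formula)
  sum(as.numeric(formula) * .monoisotopic_masses[names(formula)])
}

#' Average (standard atomic weight) mass of a formula
#'
#' @param formula a `chem_formula` (or formula string).
#' @return mass in Da.
#' @export
#' @examples
#' average_mass(ct_oligomer_formula(16)) # DP-16 condensed tannin, ~4614 Da
average_mass <- function(formula) {
  formula <- .check_formula(formula)
  sum(as.numeric(formula) * .average_masses[names(formula)])
}

#' Molecular formula of a condensed-tannin oligomer
#'
#' Proanthocyanidin oligomers are flavan-3-ol (catechin/epicatechin,
#' C15H14O6) units joined by C4->C8 interflavan bonds, each bond costing two
#' hydrogens: an n-mer is C(15n) H(12n+2) O(6n). Catechin and epicatechin
#' are constitutional isomers, so the terminal catechin unit needs no
#' special-casing in mass space.
#'
#' @param n degree of polymerization (integer >= 1).
#' @return `chem_formula` of the neutral oligomer.
#' @export
#' @examples
#' ct_oligomer_formula(2) # procyanidin B-type dimer, C30H26O12
ct_oligomer_formula <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("oligomer size n must be a single integer >= 1")
  }
  n <- as.integer(n)
  chem_formula(C = 15L * n, H = 12L * n + 2L, O = 6L * n)
}

#' m/z of a deprotonated, possibly 13C-substituted ion
#'
#' Negative-mode deprotonation: \eqn{(M + c \cdot \Delta_{13C} - z m_p)/z}
#' for charge states z = 1 ([M-H]-) or z = 2 ([M-2H]2-), where c is the
#' number of 13C substitutions.
#'
#' @param formula neutral formula (`chem_formula` or string).
#' @param z charge magnitude, 1 or 2.
#' @param c13_count number of 13C atoms (0 <= c13_count <= C count).
#' @param constants list from [ct_constants()].
#' @return m/z in Da per charge.
#' @export
#' @examples
#' ion_mz(ct_oligomer_formula(1), z = 1) # [M-H]- of (epi)catechin
ion_mz <- function(formula, z, c13_count = 0, constants = ct_constants()) {
  formula <- .check_formula(formula)
  if (!z %in% c(1L, 2L)) stop("charge z must be 1 or 2")
  if (c13_count < 0 || c13_count != round(c13_count)) {
    stop("c13_count must be a non-negative integer")
  }
  if (c13_count > formula[["C"]]) {
    stop("c13_count exceeds the formula's carbon count")
  }
  if (formula[["H"]] < z) stop("not enough hydrogens to remove ", z, " protons")
  (monoisotopic_mass(formula) + c13_count * constants$c13_minus_c12 -
     z * constants$proton_mass) / z
}

#' Theoretical condensed-tannin oligomer ion ladder
#'
#' Enumerates every (oligomer size, charge, 13C count) combination, labels
#' its isotopologue parity (mono / c13_odd / c13_even), and sorts by m/z
#' with ties broken by (n, z, c13_count). This ladder anchors all peak
#' classification.
#'
#' @param n_max largest oligomer size (default 6, monomer through hexamer).
#' @param z_set charge magnitudes to include (subset of `c(1, 2)`).
#' @param c13_max largest 13C substitution count.
#' @param constants list from [ct_constants()].
#' @return data.frame with columns n, z, c13_count, parity, formula, mz.
#' @export
#' @examples
#' head(ct_ion_ladder(n_max = 2, c13_max = 1))
ct_ion_ladder <- function(n_max = 6, z_set = c(1L, 2L), c13_max = 4,
                          constants = ct_constants()) {
  if (n_max < 1 || n_max != round(n_max)) stop("n_max must be an integer >= 1")
  if (!length(z_set) || !all(z_set %in% c(1L, 2L))) {
    stop("z_set must be a non-empty subset of {1, 2}")
  }
  if (c13_max < 0) stop("c13_max must be >= 0")
  grid <- expand.grid(n = seq_len(n_max), z = sort(unique(as.integer(z_set))),
                      c13_count = 0:c13_max, KEEP.OUT.ATTRS = FALSE)
  grid$parity <- ifelse(grid$c13_count == 0, "mono",
                        ifelse(grid$c13_count %% 2 == 1, "c13_odd", "c13_even"))
  grid$formula <- vapply(grid$n, function(n) format(ct_oligomer_formula(n)), "")
  grid$mz <- mapply(function(n, z, c13) {
    ion_mz(ct_oligomer_formula(n), z, c13, constants)
  }, grid$n, grid$z, grid$c13_count)
  grid <- grid[order(grid$mz, grid$n, grid$z, grid$c13_count), ]
  rownames(grid) <- NULL
  grid[, c("n", "z", "c13_count", "parity", "formula", "mz")]
}

#' Write an ion ladder as delimited text
#'
#' @param ladder data.frame from [ct_ion_ladder()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ion_ladder <- function(ladder, path) {
  out <- ladder
  out$mz <- sprintf("%.10f", out$mz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
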