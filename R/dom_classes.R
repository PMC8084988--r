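#' Default van Krevelen compound-class table
#'
#' Biochemical compound classes defined by half-open H:C and O:C windows, in
#' match order (first match wins). The ranges are the ones in common use for
#' dissolved-organic-matter van Krevelen classification; names carry a
#' "-like" suffix to signal that the assignment is heuristic. Fully
#' overridable, e.g. via [read_class_table()].
#'
#' @return data.frame with columns name, oc_lo, oc_hi, hc_lo, hc_hi
#'   (O:C and H:C windows, each `[lo, hi)`).
#' @export
default_class_table <- function() {
  data.frame(
    name = c("lipid-like", "protein-like", "amino-sugar-like",
             "carbohydrate-like", "unsaturated-hydrocarbon-like",
             "lignin-like", "tannin-like", "condensed-aromatic-like"),
    oc_lo = c(0, 0.3, 0.55, 0.7, 0, 0.125, 0.65, 0),
    oc_hi = c(0.3, 0.55, 0.7, 1.5, 0.125, 0.65, 1.1, 0.95),
    hc_lo = c(1.5, 1.5, 1.5, 1.5, 0.8, 0.8, 0.8, 0.2),
    hc_hi = c(2.5, 2.3, 2.2, 2.5, 1.5, 1.5, 1.5, 0.8)
  )
}

#' Read a compound-class table from JSON
#'
#' Expects a JSON list of objects `{name, oc: [lo, hi], hc: [lo, hi]}` in
#' match order.
#'
#' @param path JSON file path.
#' @return data.frame in the layout of [default_class_table()].
#' @export
read_class_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tab <- do.call(rbind, lapply(raw, function(e) {
    data.frame(name = e$name,
               oc_lo = e$oc[[1]], oc_hi = e$oc[[2]],
               hc_lo = e$hc[[1]], hc_hi = e$hc[[2]])
  }))
  if (any(tab$oc_lo >= tab$oc_hi) || any(tab$hc_lo >= tab$hc_hi)) {
    stop("class table ranges must satisfy lo < hi")
  }
  tab
}

#' Reconstruct neutral mass from negative-mode m/z
#'
#' Assumes [M-zH]z- deprotonation: M = z * m/z + z * proton mass.
#'
#' @param mz observed m/z.
#' @param z charge magnitude (default 1).
#' @param constants list from [ct_constants()].
#' @return neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, z = 1, constants = ct_constants()) {
  z * mz + z * constants$proton_mass
}

#' Enumerate CHO formula candidates for a neutral mass
#'
#' Exhaustive search over CcHhOo within the element bounds, keeping
#' candidates whose exact mass lies within `tol_ppm` of `neutral_mass` and
#' that pass standard validity filters: double-bond equivalents
#' DBE = C - H/2 + 1 a non-negative integer (so H even), 0 <= O:C <= 1.2 and
#' 0.3 <= H:C <= 2.5. Candidates are ranked by absolute ppm error with
#' deterministic ties by lexicographic (C, H, O).
#'
#' @param neutral_mass neutral monoisotopic mass in Da (> 0).
#' @param tol_ppm mass tolerance in ppm (> 0).
#' @param element_bounds named list of `c(lo, hi)` count bounds for C, H, O.
#' @return data.frame with columns C, H, O, formula, mass, mass_error_ppm,
#'   dbe; zero rows when nothing matches.
#' @export
#' @examples
#' assign_formula(290.079038, tol_ppm = 1)[1, ]
assign_formula <- function(neutral_mass, tol_ppm = 1,
                           element_bounds = list(C = c(1, 60), H = c(2, 120),
                                                 O = c(0, 40))) {
  if (!is.numeric(neutral_mass) || neutral_mass <= 0) {
    stop("neutral_mass must be > 0")
  }
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  mC <- .monoisotopic_masses[["C"]]
  mH <- .monoisotopic_masses[["H"]]
  mO <- .monoisotopic_masses[["O"]]
  tol_da <- neutral_mass * tol_ppm * 1e-6
  cand <- list()
  c_rng <- max(element_bounds$C[1], 1):min(element_bounds$C[2],
                                           floor(neutral_mass / mC))
  for (C in c_rng) {
    o_max <- min(element_bounds$O[2], floor(1.2 * C),
                 floor((neutral_mass - C * mC) / mO))
    if (o_max < element_bounds$O[1]) next
    for (O in element_bounds$O[1]:o_max) {
      h_float <- (neutral_mass - C * mC - O * mO) / mH
      for (H in unique(c(floor(h_float), ceiling(h_float)))) {
        if (H %% 2 != 0) next                      # integer DBE requires even H
        if (H < element_bounds$H[1] || H > element_bounds$H[2]) next
        dbe <- C - H / 2 + 1
        if (dbe < 0) next
        hc <- H / C
        if (hc < 0.3 || hc > 2.5) next
        mass <- C * mC + H * mH + O * mO
        if (abs(mass - neutral_mass) > tol_da) next
        cand[[length(cand) + 1L]] <- data.frame(
          C = C, H = H, O = O, mass = mass, dbe = dbe,
          mass_error_ppm = (mass - neutral_mass) / neutral_mass * 1e6)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(C = integer(), H = integer(), O = integer(),
                      formula = character(), mass = numeric(),
                      mass_error_ppm = numeric(), dbe = numeric()))
  }
  res <- do.call(rbind, cand)
  res <- res[order(abs(res$mass_error_ppm), res$C, res$H, res$O), ]
  res$formula <- paste0("C", res$C, "H", res$H,
                        ifelse(res$O > 0, paste0("O", res$O), ""))
  rownames(res) <- NULL
  res[, c("C", "H", "O", "formula", "mass", "mass_error_ppm", "dbe")]
}

#' Assign a compound class from H:C and O:C ratios
#'
#' Returns the first class in the table whose H:C and O:C half-open windows
#' contain the formula's ratios, or "unclassified".
#'
#' @param formula a `chem_formula`, formula string, or a list/row with C, H,
#'   O counts.
#' @param class_table data.frame in the layout of [default_class_table()].
#' @return class name (character scalar).
#' @export
#' @examples
#' classify_formula(chem_formula(C = 6, H = 12, O = 6)) # carbohydrate-like
classify_formula <- function(formula, class_table = default_class_table()) {
  if (inherits(formula, "chem_formula") || is.character(formula)) {
    formula <- .check_formula(formula)
    C <- formula[["C"]]; H <- formula[["H"]]; O <- formula[["O"]]
  } else {
    C <- formula$C; H <- formula$H; O <- formula$O
  }
  if (is.na(C) || C <= 0) stop("classification requires a positive carbon count")
  hc <- H / C
  oc <- O / C
  hit <- which(oc >= class_table$oc_lo & oc < class_table$oc_hi &
                 hc >= class_table$hc_lo & hc < class_table$hc_hi)
  if (length(hit)) class_table$name[hit[1]] else "unclassified"
}

#' Compound-class relative abundance per sample
#'
#' Assigns a formula to every peak (top-ranked CHO candidate for the neutral
#' mass reconstructed under [M-H]-), classifies it, and reports per-sample
#' class percentages. Percentages are count-based by default ("percent of
#' identified peaks"); set `weight = "intensity"` for intensity weighting.
#' Samples with no classifiable peak are omitted from the output (missing,
#' not zero).
#'
#' @param peaks data.frame with columns mz, sample_id (and intensity when
#'   intensity weighting is requested).
#' @param tol_ppm formula-assignment tolerance in ppm.
#' @param class_table data.frame in the layout of [default_class_table()].
#' @param element_bounds passed to [assign_formula()].
#' @param weight "count" (default) or "intensity".
#' @param constants list from [ct_constants()].
#' @return data.frame with columns sample_id, class, percent; percentages
#'   sum to 100 within each reported sample.
#' @export
class_relative_abundance <- function(peaks, tol_ppm = 1,
                                     class_table = default_class_table(),
                                     element_bounds = list(C = c(1, 60),
                                                           H = c(2, 120),
                                                           O = c(0, 40)),
                                     weight = c("count", "intensity"),
                                     constants = ct_constants()) {
  weight <- match.arg(weight)
  cls <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- assign_formula(neutral_mass_from_mz(peaks$mz[i], 1, constants),
                           tol_ppm, element_bounds)
    cls[i] <- if (nrow(cand)) classify_formula(cand[1, ], class_table)
              else NA_character_
  }
  keep <- !is.na(cls)
  if (!any(keep)) {
    return(data.frame(sample_id = character(), class = character(),
                      percent = numeric()))
  }
  w <- if (weight == "intensity") peaks$intensity[keep] else rep(1, sum(keep))
  df <- data.frame(sample_id = peaks$sample_id[keep], class = cls[keep], w = w)
  agg <- stats::aggregate(w ~ sample_id + class, df, sum)
  tot <- stats::aggregate(w ~ sample_id, df, sum)
  names(tot)[2] <- "total"
  agg <- merge(agg, tot, by = "sample_id")
  agg$percent <- 100 * agg$w / agg$total
  agg <- agg[order(agg$sample_id, agg$class), c("sample_id", "class", "percent")]
  rownames(agg) <- NULL
  agg
}
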