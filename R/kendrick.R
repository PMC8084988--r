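#' Kendrick coordinates with the (epi)catechin base unit
#'
#' Rescales m/z so that the flavan-3-ol repeat unit has integer Kendrick
#' mass: KM = m/z * (290 / 290.079038), NM = ceiling(KM), KMD = NM - KM.
#' With the ceiling convention the 12C monoisotopic polymer line sits near
#' KMD 0 and KMD always lies in [0, 1).
#'
#' @param mz numeric vector of m/z values (> 0).
#' @param constants list from [ct_constants()].
#' @return data.frame with columns km, nm_cat, kmd (one row per m/z).
#' @export
#' @examples
#' kendrick_coords(c(290.079038, 289.071762))
kendrick_coords <- function(mz, constants = ct_constants()) {
  if (!length(mz) || any(!is.finite(mz)) || any(mz <= 0)) {
    stop("all m/z values must be finite and > 0")
  }
  km <- mz * (constants$base_unit_nominal / constants$base_unit_exact_mass)
  nm_cat <- ceiling(km)
  data.frame(km = km, nm_cat = nm_cat, kmd = nm_cat - km)
}

#' Read an FTICR-MS peak list
#'
#' Delimited text with header
#' `mz,intensity,sample_id,treatment,timepoint,replicate`; m/z is parsed at
#' full printed precision.
#'
#' @param path file path.
#' @return data.frame of peaks.
#' @export
read_peak_list <- function(path) {
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(mz = "numeric"))
  required <- c("mz", "intensity", "sample_id", "treatment", "timepoint",
                "replicate")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) {
    stop("peak list is missing column(s): ", paste(missing, collapse = ", "))
  }
  peaks
}

#' Classify peaks against the theoretical oligomer ion ladder
#'
#' Each peak is matched to the ladder entry with the smallest absolute ppm
#' error, provided that error is within `tol_ppm`; otherwise it is left
#' unassigned. Ties are broken by (lower n, lower z, lower c13_count). The
#' assignment is a pure function of (mz, ladder, tol_ppm): sample metadata
#' is carried through untouched.
#'
#' @param peaks data.frame with at least an `mz` column (typically from
#'   [read_peak_list()]).
#' @param ladder data.frame from [ct_ion_ladder()].
#' @param tol_ppm matching tolerance in ppm (default 3, FTICR-class mass
#'   accuracy).
#' @return `peaks` augmented with columns assigned (logical), n, z,
#'   c13_count, parity, mz_theoretical, mass_error_ppm (NA when
#'   unassigned), plus km/nm_cat/kmd Kendrick coordinates.
#' @export
classify_peaks <- function(peaks, ladder, tol_ppm = 3) {
  if (!nrow(ladder)) stop("ladder must be non-empty")
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0")
  out <- as.data.frame(peaks)
  out$assigned <- logical(nrow(out))
  out$n <- out$z <- out$c13_count <- rep(NA_integer_, nrow(out))
  out$parity <- rep(NA_character_, nrow(out))
  out$mz_theoretical <- out$mass_error_ppm <- rep(NA_real_, nrow(out))
  if (nrow(out)) {
    # rank ladder rows once so which.min respects the (n, z, c13) tie-break
    ord <- order(ladder$n, ladder$z, ladder$c13_count)
    lad <- ladder[ord, ]
    for (i in seq_len(nrow(out))) {
      ppm <- (out$mz[i] - lad$mz) / lad$mz * 1e6
      j <- which.min(abs(ppm))
      if (abs(ppm[j]) <= tol_ppm) {
        out$assigned[i] <- TRUE
        out$n[i] <- lad$n[j]
        out$z[i] <- lad$z[j]
        out$c13_count[i] <- lad$c13_count[j]
        out$parity[i] <- lad$parity[j]
        out$mz_theoretical[i] <- lad$mz[j]
        out$mass_error_ppm[i] <- ppm[j]
      }
    }
    kc <- kendrick_coords(out$mz)
    out$km <- kc$km
    out$nm_cat <- kc$nm_cat
    out$kmd <- kc$kmd
  } else {
    out$km <- out$nm_cat <- out$kmd <- numeric(0)
  }
  out
}

#' Isotopic split between 13C-odd and monoisotopic/13C-even KMD lines
#'
#' For z-charged polymer ions, Kendrick plots show z horizontal lines
#' separated by 1/z KMD: doubly-charged odd-13C isotopologues sit ~0.5 KMD
#' above the main line, while even counts return to it. For each (n, z)
#' group with both parities observed, this computes the circular (modulo 1)
#' distance between the mean KMD of the odd-13C peaks and the mean KMD of
#' the mono/even peaks.
#'
#' @param assignments data.frame from [classify_peaks()].
#' @return data.frame with columns n, z, delta_kmd (distance in [0, 0.5]);
#'   zero rows when no group has both parity lines.
#' @export
isotopic_split_check <- function(assignments) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  groups <- unique(a[, c("n", "z")])
  # circular mean on the unit KMD circle, so lines wrapping the 0/1
  # boundary (high 13C counts) average correctly
  circ_mean <- function(x) {
    (atan2(mean(sin(2 * pi * x)), mean(cos(2 * pi * x))) / (2 * pi)) %% 1
  }
  res <- data.frame(n = integer(), z = integer(), delta_kmd = numeric())
  for (k in seq_len(nrow(groups))) {
    g <- a[a$n == groups$n[k] & a$z == groups$z[k], ]
    odd <- g$kmd[g$parity == "c13_odd"]
    even <- g$kmd[g$parity != "c13_odd"]
    if (length(odd) && length(even)) {
      d <- (circ_mean(odd) - circ_mean(even)) %% 1
      res <- rbind(res, data.frame(n = groups$n[k], z = groups$z[k],
                                   delta_kmd = min(d, 1 - d)))
    }
  }
  res[order(res$n, res$z), ]
}

#' Oligomer richness per treatment, timepoint and oligomer size
#'
#' Counts assigned peaks by (treatment, timepoint, n); a rise in small-n
#' counts over time is the depolymerization signal.
#'
#' @param assignments data.frame from [classify_peaks()] carrying
#'   treatment/timepoint metadata.
#' @param by_parity also split counts by isotopologue parity line.
#' @return data.frame of counts (zero rows if nothing is assigned).
#' @export
oligomer_richness <- function(assignments, by_parity = FALSE) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  keys <- c("treatment", "timepoint", "n", if (by_parity) "parity")
  if (!nrow(a)) {
    out <- a[, keys, drop = FALSE]
    out$count <- integer(0)
    return(out)
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(a))), a[keys], sum)
  agg <- agg[do.call(order, agg[keys]), ]
  rownames(agg) <- NULL
  agg
}

#' Binned density of peaks in (m/z, KMD) space
#'
#' Rectangular-bin surrogate for the hexagon-binned Kendrick plots: counts
#' of peaks per (m/z bin, KMD bin) in long format. Total count is conserved.
#'
#' @param peaks data.frame with an `mz` column (kmd computed if absent).
#' @param mz_bins,kmd_bins number of bins along each axis (>= 1).
#' @return data.frame with columns mz_bin (center), kmd_bin (center), count.
#' @export
hexbin_kmd <- function(peaks, mz_bins = 80, kmd_bins = 50) {
  if (mz_bins < 1 || kmd_bins < 1) stop("bin counts must be >= 1")
  if (!nrow(peaks)) {
    return(data.frame(mz_bin = numeric(), kmd_bin = numeric(),
                      count = integer()))
  }
  kmd <- if ("kmd" %in% names(peaks)) peaks$kmd else kendrick_coords(peaks$mz)$kmd
  mz_breaks <- seq(min(peaks$mz), max(peaks$mz), length.out = mz_bins + 1)
  kmd_breaks <- seq(0, 1, length.out = kmd_bins + 1)
  ix <- pmin(pmax(findInterval(peaks$mz, mz_breaks, rightmost.closed = TRUE), 1L),
             mz_bins)
  iy <- pmin(pmax(findInterval(kmd, kmd_breaks, rightmost.closed = TRUE), 1L),
             kmd_bins)
  tab <- stats::aggregate(list(count = rep(1L, nrow(peaks))),
                          list(ix = ix, iy = iy), sum)
  data.frame(
    mz_bin = (mz_breaks[tab$ix] + mz_breaks[tab$ix + 1]) / 2,
    kmd_bin = (kmd_breaks[tab$iy] + kmd_breaks[tab$iy + 1]) / 2,
    count = tab$count
  )
}

#' Oligomer-region rectangles for Kendrick plot annotation
#'
#' Derives, per oligomer size, the m/z extent of its ladder ions (widened by
#' the matching tolerance) paired with the two parity-line KMD bands
#' (0 +/- `kmd_halfwidth` for the main line, 0.5 +/- `kmd_halfwidth` for the
#' doubly-charged odd-13C line).
#'
#' @param ladder data.frame from [ct_ion_ladder()].
#' @param tol_ppm matching tolerance used to widen the m/z extent.
#' @param kmd_halfwidth half-width of the KMD bands (default 0.05).
#' @return data.frame with columns n, line, mz_lo, mz_hi, kmd_lo, kmd_hi.
#' @export
oligomer_regions <- function(ladder, tol_ppm = 3, kmd_halfwidth = 0.05) {
  res <- do.call(rbind, lapply(split(ladder, ladder$n), function(g) {
    lo <- min(g$mz) * (1 - tol_ppm * 1e-6)
    hi <- max(g$mz) * (1 + tol_ppm * 1e-6)
    data.frame(n = g$n[1], line = c("main", "split"),
               mz_lo = lo, mz_hi = hi,
               kmd_lo = c(0, 0.5 - kmd_halfwidth),
               kmd_hi = c(kmd_halfwidth, 0.5 + kmd_halfwidth))
  }))
  rownames(res) <- NULL
  res
}
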