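# Shared fixtures and independent oracles for the test suite.

# Build a protein table whose sequences are concatenations of tryptic
# peptides (each peptide ends in K, so digestion recovers it exactly).
protein_table <- function(..., origins) {
  seqs <- vapply(list(...), paste, "", collapse = "")
  data.frame(
    protein_id = paste0("P", seq_along(seqs)),
    sequence = seqs,
    length = nchar(seqs),
    origin = origins,
    origin_type = ifelse(startsWith(origins, "unbinned:"), "unbinned", "mag")
  )
}

# Brute-force uniqueness oracle: for every protein with an observed
# peptide, enumerate all observed peptides it contains and check whether
# any is contained in no other protein.
brute_force_classify <- function(peptides, proteins) {
  res <- list()
  for (i in seq_len(nrow(proteins))) {
    mine <- peptides[vapply(peptides, function(p)
      grepl(p, proteins$sequence[i], fixed = TRUE), logical(1))]
    if (!length(mine)) next
    has_unique <- FALSE
    for (p in mine) {
      others <- proteins$sequence[-i]
      if (!any(vapply(others, function(s) grepl(p, s, fixed = TRUE),
                      logical(1)))) {
        has_unique <- TRUE
        break
      }
    }
    cls <- if (has_unique) {
      if (proteins$origin_type[i] == "mag") "binned_unique"
      else "unbinned_unique"
    } else "non_unique"
    res[[length(res) + 1L]] <- data.frame(
      protein_id = proteins$protein_id[i], uniqueness_class = cls)
  }
  do.call(rbind, res)
}

# Brute-force nearest-ppm peak classifier (independent of classify_peaks
# internals): exhaustive search over the whole ladder per peak.
brute_force_assign <- function(mz, ladder, tol_ppm) {
  vapply(mz, function(x) {
    ppm <- abs(x - ladder$mz) / ladder$mz * 1e6
    best <- ppm == min(ppm)
    cand <- ladder[best, ]
    cand <- cand[order(cand$n, cand$z, cand$c13_count), ]
    if (min(ppm) <= tol_ppm) {
      paste(cand$n[1], cand$z[1], cand$c13_count[1])
    } else {
      NA_character_
    }
  }, "")
}

# A small scenario for plumbing tests (not the study conditions).
small_scenario <- function(seed = 7) {
  scenario_config(
    seed = seed, timepoints = c(0, 10), replicates = 2, noise_peaks = 30,
    proteome_timepoints = c(3, 10), total_spectra = 600,
    unbinned_spectra = 60, shared_spectra = 40, proteins_per_mag = 4,
    protein_length = 200
  )
}
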