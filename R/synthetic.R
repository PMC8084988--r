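# Formula pools used for matrix (non-CT) noise peaks, keyed by the
# van Krevelen class each formula falls in under default_class_table().
.noise_formula_pool <- list(
  "carbohydrate-like" = c("C6H12O6", "C12H22O11", "C5H10O5"),
  "lignin-like" = c("C10H12O3", "C11H14O4"),
  "tannin-like" = c("C7H8O5", "C8H10O6"),
  "lipid-like" = c("C16H32O2", "C18H34O2"),
  "protein-like" = c("C10H18O4", "C8H14O3"),
  "condensed-aromatic-like" = c("C12H6O2"),
  "unsaturated-hydrocarbon-like" = c("C10H8")
)

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic study: the reactor sampling design
#' (three treatments, eight timepoints, three replicates), the CT oligomer
#' dynamics per treatment (small oligomers appear at day 10 in biotic soil
#' but only at day 20 in autoclaved soil, while penta/hexamers are present
#' throughout), the mass-jitter and intensity models, matrix-peak
#' composition trends (carbohydrate-like fraction declining over time in
#' biotic soil), the metabolite effect table (e.g. CT monomers enriched at
#' day 10, later-phase phenolics at days 14-20), and the MAG roster with
#' phase-structured contribution trajectories (a Kosakonia-like MAG at 80%
#' of the binned-unique pool in phase 2).
#'
#' @param seed integer random seed (mandatory; fixed seed gives
#'   bit-identical outputs).
#' @param timepoints sampling days.
#' @param replicates replicates per treatment.
#' @param mass_jitter_ppm Gaussian m/z jitter sigma in ppm.
#' @param intensity_meanlog,intensity_sdlog lognormal intensity model.
#' @param c13_abundance natural 13C abundance for isotopologue draws.
#' @param c13_max largest 13C substitution generated.
#' @param n_max largest oligomer size.
#' @param ion_copies isotopologue draws per (oligomer, charge) per sample.
#' @param noise_peaks matrix noise peaks per sample.
#' @param oligomer_schedule data.frame(treatment, timepoint, n) of planted
#'   oligomer sizes; NULL for the default dynamics described above.
#' @param metabolite_effects data.frame(compound, timepoint, log2fc) of
#'   planted biotic-vs-autoclaved enrichments; NULL for the default roster.
#' @param mag_trajectories data.frame(treatment, timepoint, mag_id, share)
#'   of planted binned-unique contribution shares; NULL for the default
#'   phase structure.
#' @param proteome_timepoints days with metaproteome samples.
#' @param proteins_per_mag,protein_length,total_spectra,unbinned_spectra,shared_spectra
#'   proteome generator sizes.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            timepoints = c(0, 1, 3, 5, 7, 10, 14, 20),
                            replicates = 3,
                            mass_jitter_ppm = 1,
                            intensity_meanlog = log(1e6),
                            intensity_sdlog = 1,
                            c13_abundance = 0.0107,
                            c13_max = 4,
                            n_max = 6,
                            ion_copies = 6,
                            noise_peaks = 120,
                            oligomer_schedule = NULL,
                            metabolite_effects = NULL,
                            mag_trajectories = NULL,
                            proteome_timepoints = c(1, 3, 7, 10, 14, 20),
                            proteins_per_mag = 8,
                            protein_length = 300,
                            total_spectra = 3000,
                            unbinned_spectra = 150,
                            shared_spectra = 100) {
  if (missing(seed) || is.na(seed)) stop("a random seed is mandatory")
  if (is.null(oligomer_schedule)) {
    oligomer_schedule <- rbind(
      expand.grid(treatment = "biotic_CT", timepoint = timepoints,
                  n = seq(5, n_max), stringsAsFactors = FALSE),
      expand.grid(treatment = "biotic_CT",
                  timepoint = intersect(c(10, 14, 20), timepoints),
                  n = 1:4, stringsAsFactors = FALSE),
      expand.grid(treatment = "autoclaved_CT", timepoint = timepoints,
                  n = seq(5, n_max), stringsAsFactors = FALSE),
      expand.grid(treatment = "autoclaved_CT",
                  timepoint = intersect(20, timepoints),
                  n = 1:4, stringsAsFactors = FALSE)
    )
  }
  if (is.null(metabolite_effects)) {
    metabolite_effects <- rbind(
      data.frame(compound = "epicatechin", timepoint = 10, log2fc = 2.5),
      data.frame(compound = "catechin", timepoint = 10, log2fc = 2.5),
      data.frame(compound = "quercetin", timepoint = 10, log2fc = 2.0),
      data.frame(compound = "phenylpropanoid_C6C3", timepoint = c(10, 14),
                 log2fc = 2.0),
      data.frame(compound = "phenylacetate_C6C2", timepoint = c(14, 20),
                 log2fc = 2.0),
      data.frame(compound = "dopa", timepoint = c(14, 20), log2fc = 2.0),
      data.frame(compound = "acetate", timepoint = c(14, 20), log2fc = 2.0),
      data.frame(compound = "butyrate", timepoint = c(14, 20), log2fc = 2.0)
    )
  }
  mags <- c("MAG_kosakonia", "MAG_holophaga", "MAG_sporomusa_1",
            "MAG_sporomusa_2", "MAG_chromatiaceae")
  if (is.null(mag_trajectories)) {
    share_for <- function(treatment, tp) {
      if (treatment == "unamended") {
        c(0.125, 0.125, 0.125, 0.125, 0.5)
      } else if (tp <= 1) {
        rep(0.2, 5)                       # phase 1: undifferentiated
      } else if (tp <= 7) {
        c(0.8, 0.05, 0.05, 0.05, 0.05)    # phase 2: Kosakonia-like dominance
      } else {
        c(0.1, 0.4, 0.3, 0.1, 0.1)        # phase 3: Holophaga/Sporomusales
      }
    }
    mag_trajectories <- do.call(rbind, lapply(c("biotic_CT", "unamended"),
      function(tr) {
        do.call(rbind, lapply(proteome_timepoints, function(tp) {
          data.frame(treatment = tr, timepoint = tp, mag_id = mags,
                     share = share_for(tr, tp))
        }))
      }))
  }
  structure(list(
    seed = as.integer(seed), timepoints = timepoints,
    replicates = replicates, mass_jitter_ppm = mass_jitter_ppm,
    intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog,
    c13_abundance = c13_abundance, c13_max = c13_max, n_max = n_max,
    ion_copies = ion_copies, noise_peaks = noise_peaks,
    oligomer_schedule = oligomer_schedule,
    metabolite_effects = metabolite_effects,
    mag_roster = mags, mag_trajectories = mag_trajectories,
    proteome_timepoints = proteome_timepoints,
    proteins_per_mag = proteins_per_mag, protein_length = protein_length,
    total_spectra = total_spectra, unbinned_spectra = unbinned_spectra,
    shared_spectra = shared_spectra
  ), class = "scenario_config")
}

#' Draw 13C substitution counts for a molecule
#'
#' Binomial draws over the molecule's carbon count at natural 13C
#' abundance, capped at `cap` (higher orders are negligible at the CHO
#' sizes handled here).
#'
#' @param n number of draws.
#' @param carbons carbon count of the molecule.
#' @param abundance per-atom 13C probability.
#' @param cap largest substitution count returned.
#' @return integer vector of length `n`.
#' @export
draw_c13_counts <- function(n, carbons, abundance = 0.0107, cap = 4) {
  pmin(stats::rbinom(n, carbons, abundance), cap)
}

# deterministic integer split of `total` proportional to `w` (sums exactly)
.apportion <- function(w, total) {
  cum <- round(cumsum(w) / sum(w) * total)
  diff(c(0L, cum))
}

#' Generate synthetic FTICR-MS peak lists with ground truth
#'
#' For every treatment/timepoint/replicate, plants CT oligomer ions per the
#' schedule (both charge states, 13C counts drawn binomially from the
#' oligomer's carbon count) with Gaussian ppm jitter, plus CHO matrix noise
#' peaks drawn from fixed formula pools of the van Krevelen classes with a
#' declining carbohydrate-like fraction over time in biotic soil. Emits the
#' peak list and a machine-readable truth table side by side.
#'
#' @param config list from [scenario_config()].
#' @return list with `peaks` (mz, intensity, sample_id, treatment,
#'   timepoint, replicate) and `truth` (per-peak kind, planted ion identity
#'   or noise class, exact m/z).
#' @export
generate_fticr <- function(config) {
  set.seed(config$seed)
  const <- ct_constants()
  classes <- names(.noise_formula_pool)
  base_w <- c(0.40, 0.15, 0.15, 0.10, 0.10, 0.05, 0.05)
  names(base_w) <- classes
  rows <- list()
  for (tr in c("biotic_CT", "autoclaved_CT", "unamended")) {
    for (tp in config$timepoints) {
      sched <- config$oligomer_schedule
      n_set <- sort(unique(sched$n[sched$treatment == tr &
                                     sched$timepoint == tp]))
      w <- base_w
      if (tr == "biotic_CT") {
        # carbohydrate-like fraction declines linearly to 1/4 by day 20
        w["carbohydrate-like"] <- base_w["carbohydrate-like"] *
          (1 - 0.75 * tp / max(config$timepoints))
        w <- w / sum(w)
      }
      for (rep_i in seq_len(config$replicates)) {
        sid <- sprintf("%s_d%02d_r%d", tr, tp, rep_i)
        # planted CT oligomer ions
        for (n in n_set) {
          for (z in c(1L, 2L)) {
            c13 <- draw_c13_counts(config$ion_copies, 15L * n,
                                   config$c13_abundance, config$c13_max)
            for (c13_i in sort(unique(c13))) {
              mz_true <- ion_mz(ct_oligomer_formula(n), z, c13_i, const)
              mz <- mz_true * (1 + stats::rnorm(1) * config$mass_jitter_ppm * 1e-6)
              rows[[length(rows) + 1L]] <- data.frame(
                mz = mz,
                intensity = stats::rlnorm(1, config$intensity_meanlog,
                                          config$intensity_sdlog),
                sample_id = sid, treatment = tr, timepoint = tp,
                replicate = rep_i, kind = "ct_ion", n = n, z = z,
                c13_count = c13_i, formula = NA_character_,
                class = NA_character_, mz_true = mz_true)
            }
          }
        }
        # matrix noise peaks with deterministic class composition
        counts <- .apportion(w, config$noise_peaks)
        for (ci in seq_along(classes)) {
          if (counts[ci] == 0) next
          pool <- .noise_formula_pool[[classes[ci]]]
          picks <- sample(pool, counts[ci], replace = TRUE)
          for (f in picks) {
            m <- monoisotopic_mass(f)
            mz_true <- m - const$proton_mass
            mz <- mz_true * (1 + stats::rnorm(1) * config$mass_jitter_ppm * 1e-6)
            rows[[length(rows) + 1L]] <- data.frame(
              mz = mz,
              intensity = stats::rlnorm(1, config$intensity_meanlog,
                                        config$intensity_sdlog),
              sample_id = sid, treatment = tr, timepoint = tp,
              replicate = rep_i, kind = "noise", n = NA_integer_,
              z = NA_integer_, c13_count = NA_integer_, formula = f,
              class = classes[ci], mz_true = mz_true)
          }
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(peaks = truth[, c("mz", "intensity", "sample_id", "treatment",
                         "timepoint", "replicate")],
       truth = truth)
}

#' Generate a synthetic metabolite area table with ground truth
#'
#' Lognormal replicate peak areas for a roster of CT-degradation-relevant
#' compounds (CT monomers, quercetin, C6-C3/C6-C2 phenolics, DOPA, a
#' disaccharide, short-chain fatty acids) across three treatments, with
#' planted per-timepoint log2 fold changes of biotic over autoclaved soil.
#' The disaccharide declines identically in biotic and unamended soil
#' (microbial consumption) but not in the autoclaved control.
#'
#' @param config list from [scenario_config()].
#' @param sdlog2 replicate noise standard deviation on the log2 scale
#'   (default 0.25).
#' @return list with `areas` (compound, treatment, timepoint, replicate,
#'   area) and `truth` (planted log2fc per compound/timepoint, zero rows
#'   implicit for unlisted pairs).
#' @export
generate_metabolites <- function(config, sdlog2 = 0.25) {
  set.seed(config$seed + 1L)
  eff <- config$metabolite_effects
  compounds <- sort(unique(c(eff$compound, "disaccharide", "formate",
                             "null_compound")))
  base <- stats::setNames(18 + 2 * (seq_along(compounds) %% 4), compounds)
  decline <- c(disaccharide = 0.15)   # log2 units per day, biotic + unamended
  rows <- list()
  for (cp in compounds) {
    for (tr in c("biotic_CT", "autoclaved_CT", "unamended")) {
      for (tp in config$timepoints) {
        mu <- base[[cp]]
        if (cp %in% names(decline) && tr %in% c("biotic_CT", "unamended")) {
          mu <- mu - decline[[cp]] * tp
        }
        if (tr == "biotic_CT") {
          lfc <- eff$log2fc[eff$compound == cp & eff$timepoint == tp]
          if (length(lfc)) mu <- mu + lfc[1]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cp, treatment = tr, timepoint = tp,
          replicate = seq_len(config$replicates),
          area = 2^(mu + stats::rnorm(config$replicates, 0, sdlog2)))
      }
    }
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- NULL
  grid <- expand.grid(compound = compounds, timepoint = config$timepoints,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, eff, by = c("compound", "timepoint"), all.x = TRUE)
  grid$log2fc[is.na(grid$log2fc)] <- 0
  list(areas = areas, truth = grid[order(grid$compound, grid$timepoint), ])
}

.random_protein <- function(length) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep(1, 20)
  w[aa %in% c("K", "R")] <- 1.5   # boosted so tryptic peptides stay observable
  paste(sample(aa, length, replace = TRUE, prob = w), collapse = "")
}

#' Generate a synthetic metaproteome scenario with ground truth
#'
#' Builds a toy protein database (random sequences per MAG, two genes on
#' unbinned scaffolds, and one sequence deliberately duplicated across two
#' MAGs so no peptide can be unique to either copy), samples tryptic-peptide
#' spectral counts per sample following the planted MAG contribution
#' trajectories, and emits a MAG coverage table including records placed
#' exactly on, just below and just above the 75%-breadth / 3x-coverage
#' presence thresholds.
#'
#' @param config list from [scenario_config()].
#' @return list with `proteins` (database table as from
#'   [read_protein_fasta()]), `observations` (peptide report),
#'   `coverage` (coverage table), and `truth` (list: mag_shares,
#'   protein_classes, presence).
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed + 2L)
  mags <- config$mag_roster
  proteins <- list()
  for (m in mags) {
    for (k in seq_len(config$proteins_per_mag)) {
      proteins[[length(proteins) + 1L]] <- data.frame(
        protein_id = sprintf("%s_p%02d", m, k),
        sequence = .random_protein(config$protein_length),
        origin = m, origin_type = "mag")
    }
  }
  for (k in 1:2) {
    proteins[[length(proteins) + 1L]] <- data.frame(
      protein_id = sprintf("scaffold_%03d_p1", k),
      sequence = .random_protein(config$protein_length),
      origin = sprintf("unbinned:scaffold_%03d", k), origin_type = "unbinned")
  }
  dup_seq <- .random_protein(config$protein_length)
  for (k in 1:2) {
    proteins[[length(proteins) + 1L]] <- data.frame(
      protein_id = sprintf("dup_p%d", k), sequence = dup_seq,
      origin = mags[k], origin_type = "mag")
  }
  proteins <- do.call(rbind, proteins)
  proteins$length <- nchar(proteins$sequence)
  observable <- lapply(proteins$sequence, function(s) {
    peps <- tryptic_digest(s)
    peps[nchar(peps) >= 6 & nchar(peps) <= 30]
  })
  names(observable) <- proteins$protein_id
  if (any(lengths(observable) < 2)) {
    stop("a generated protein has fewer than 2 observable tryptic peptides")
  }

  traj <- config$mag_trajectories
  obs <- list()
  samples <- unique(traj[, c("treatment", "timepoint")])
  emit <- function(protein_ids, total, sid) {
    if (total == 0) return()
    per_prot <- as.integer(stats::rmultinom(1, total,
                                            rep(1, length(protein_ids))))
    for (pi in seq_along(protein_ids)) {
      if (per_prot[pi] == 0) next
      peps <- observable[[protein_ids[pi]]]
      per_pep <- as.integer(stats::rmultinom(1, per_prot[pi],
                                             rep(1, length(peps))))
      keep <- per_pep > 0
      obs[[length(obs) + 1L]] <<- data.frame(
        peptide = peps[keep], sample_id = sid, spectral_count = per_pep[keep])
    }
  }
  for (s in seq_len(nrow(samples))) {
    tr <- samples$treatment[s]; tp <- samples$timepoint[s]
    sid <- sprintf("%s_d%02d", tr, tp)
    shares <- traj[traj$treatment == tr & traj$timepoint == tp, ]
    shares <- shares[match(mags, shares$mag_id), ]
    per_mag <- as.integer(stats::rmultinom(1, config$total_spectra,
                                           shares$share))
    for (mi in seq_along(mags)) {
      ids <- proteins$protein_id[proteins$origin == mags[mi] &
                                   !startsWith(proteins$protein_id, "dup_")]
      emit(ids, per_mag[mi], sid)
    }
    emit(proteins$protein_id[proteins$origin_type == "unbinned"],
         config$unbinned_spectra, sid)
    emit(proteins$protein_id[startsWith(proteins$protein_id, "dup_")],
         config$shared_spectra, sid)
  }
  observations <- do.call(rbind, obs)
  observations <- stats::aggregate(spectral_count ~ peptide + sample_id,
                                   observations, sum)

  # coverage: deterministic link to planted share, plus threshold-boundary MAGs
  cov <- traj
  cov$sample_id <- sprintf("%s_d%02d", cov$treatment, cov$timepoint)
  cov$breadth <- pmin(0.5 + cov$share * 1.5, 0.99)
  cov$reads_per_base <- cov$share * 0.2
  cov <- cov[, c("mag_id", "sample_id", "treatment", "timepoint", "breadth",
                 "reads_per_base")]
  edge <- data.frame(
    mag_id = c("MAG_edge_exact", "MAG_edge_breadth", "MAG_edge_depth"),
    sample_id = cov$sample_id[1], treatment = cov$treatment[1],
    timepoint = cov$timepoint[1],
    breadth = c(0.75, 0.74, 0.90),
    reads_per_base = c(3 / 151, 1.0, 0.01))
  cov <- rbind(cov, edge)

  truth_classes <- data.frame(
    protein_id = proteins$protein_id,
    uniqueness_class = ifelse(startsWith(proteins$protein_id, "dup_"),
                              "non_unique",
                              ifelse(proteins$origin_type == "unbinned",
                                     "unbinned_unique", "binned_unique")))
  presence <- cov
  presence$present <- presence$breadth >= 0.75 &
    presence$reads_per_base * 151 >= 3
  list(proteins = proteins, observations = observations, coverage = cov,
       truth = list(mag_shares = traj, protein_classes = truth_classes,
                    presence = presence))
}

#' Reactor recipe
#'
#' @param soil_mass soil in the slurry, g.
#' @param slurry_volume slurry volume, mL.
#' @param slurry_dilution fraction of reactor volume that is slurry
#'   (1:10 dilution = 0.1).
#' @param ct_dose final CT dose in the reactor, mg/mL.
#' @return list of class `reactor_recipe`.
#' @export
reactor_recipe <- function(soil_mass = 5, slurry_volume = 125,
                           slurry_dilution = 0.1, ct_dose = 1.5) {
  if (soil_mass <= 0 || slurry_volume <= 0 || ct_dose <= 0) {
    stop("all recipe quantities must be positive")
  }
  if (slurry_dilution <= 0 || slurry_dilution > 1) {
    stop("slurry_dilution must lie in (0, 1]")
  }
  structure(list(soil_mass = soil_mass, slurry_volume = slurry_volume,
                 slurry_dilution = slurry_dilution, ct_dose = ct_dose),
            class = "reactor_recipe")
}

#' CT loading per gram of soil implied by a reactor recipe
#'
#' Soil per mL of reactor is (soil_mass / slurry_volume) x dilution; the
#' loading is the CT dose divided by that. The default recipe (5 g soil in
#' 125 mL slurry, added 1:10, dosed at 1.5 mg CT/mL) gives 375 mg CT per g
#' soil.
#'
#' @param recipe list from [reactor_recipe()].
#' @return loading in mg CT per g soil.
#' @export
#' @examples
#' ct_loading(reactor_recipe())
ct_loading <- function(recipe) {
  soil_per_ml <- recipe$soil_mass / recipe$slurry_volume *
    recipe$slurry_dilution
  recipe$ct_dose / soil_per_ml
}

#' Write a full synthetic scenario to disk
#'
#' Generates all four pipeline inputs (FTICR peak list, metabolite area
#' table, protein FASTA + peptide report, MAG coverage table) plus their
#' truth tables, as plain text under `dir`.
#'
#' @param config list from [scenario_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written input-file paths,
#'   invisibly.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ft <- generate_fticr(config)
  mb <- generate_metabolites(config)
  pr <- generate_proteome(config)
  paths <- c(
    peaks = file.path(dir, "fticr_peaks.csv"),
    metabolites = file.path(dir, "metabolite_areas.csv"),
    fasta = file.path(dir, "proteins.fasta"),
    peptides = file.path(dir, "peptide_report.csv"),
    coverage = file.path(dir, "mag_coverage.csv")
  )
  utils::write.csv(ft$peaks, paths["peaks"], row.names = FALSE, quote = FALSE)
  utils::write.csv(ft$truth, file.path(dir, "fticr_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(mb$areas, paths["metabolites"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(mb$truth, file.path(dir, "metabolite_truth.csv"),
                   row.names = FALSE)
  seqs <- Biostrings::AAStringSet(pr$proteins$sequence)
  names(seqs) <- sprintf("%s mag=%s", pr$proteins$protein_id,
                         pr$proteins$origin)
  Biostrings::writeXStringSet(seqs, paths["fasta"])
  utils::write.csv(pr$observations, paths["peptides"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(pr$coverage, paths["coverage"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(pr$truth$mag_shares, file.path(dir, "mag_share_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(pr$truth$protein_classes,
                   file.path(dir, "protein_class_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(pr$truth$presence, file.path(dir, "presence_truth.csv"),
                   row.names = FALSE)
  invisible(paths)
}
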