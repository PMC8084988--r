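test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("AKRPK"), c("AK", "RPK"))
  expect_equal(tryptic_digest("MAAA"), "MAAA")
  expect_equal(tryptic_digest("AKCK", missed_cleavages = 1),
               c("AK", "CK", "AKCK"))
  expect_error(tryptic_digest("AKBX"), "position 3")
  expect_error(tryptic_digest(""), "non-empty")
  # digest covers the sequence exactly once at 0 missed cleavages
  s <- "MKTAYRPLLKDDRSTK"
  expect_equal(paste(tryptic_digest(s), collapse = ""), s)
})

test_that("peptides map to every containing protein by exact substring", {
  prot <- protein_table("AAAAAK", "CCCCCK", c("AAAAAK", "CCCCCK"),
                        origins = c("MAG_1", "MAG_2", "MAG_3"))
  m <- map_peptides(c("AAAAAK", "CCCCCK", "WWWWWK"), prot)
  expect_equal(m[["AAAAAK"]], c("P1", "P3"))
  expect_equal(m[["CCCCCK"]], c("P2", "P3"))
  expect_equal(m[["WWWWWK"]], character(0))

  # I/L distinct by default, collapsible on request
  prot2 <- protein_table("IIIIIK", origins = "MAG_1")
  expect_equal(map_peptides("LLLLLK", prot2)[["LLLLLK"]], character(0))
  expect_equal(map_peptides("LLLLLK", prot2, il_equivalent = TRUE)[["LLLLLK"]],
               "P1")
})

test_that("uniqueness classification distinguishes binned, unbinned and shared hits", {
  p1 <- "AAAAAK"; p2 <- "CCCCCK"; p3 <- "DDDDDK"
  prot <- protein_table(c(p1, p2), c(p2, p3), p2,
                        origins = c("MAG_1", "unbinned:scaffold_9", "MAG_2"))
  m <- map_peptides(c(p1, p2, p3), prot)
  cls <- classify_proteins(m, prot)
  expect_equal(cls$uniqueness_class[match(c("P1", "P2", "P3"),
                                          cls$protein_id)],
               c("binned_unique", "unbinned_unique", "non_unique"))
  expect_equal(cls$distinct_peptides[cls$protein_id == "P1"], 2L)
  expect_equal(cls$unique_peptides[cls$protein_id == "P3"], 0L)

  # single protein, single observed peptide
  solo <- protein_table(p1, origins = "MAG_1")
  cls1 <- classify_proteins(map_peptides(p1, solo), solo)
  expect_equal(cls1$uniqueness_class, "binned_unique")

  # duplicated sequences in different MAGs can never be unique
  dup <- protein_table(c(p1, p2), c(p1, p2),
                       origins = c("MAG_1", "MAG_2"))
  cls2 <- classify_proteins(map_peptides(c(p1, p2), dup), dup)
  expect_equal(cls2$uniqueness_class, c("non_unique", "non_unique"))

  # proteins with no observed peptide are excluded
  partial <- classify_proteins(map_peptides(p1, prot), prot)
  expect_equal(partial$protein_id, "P1")
})

test_that("classification matches the brute-force oracle and ignores input order", {
  cfg <- small_scenario()
  pr <- generate_proteome(cfg)
  peptides <- unique(pr$observations$peptide)
  got <- classify_proteins(map_peptides(peptides, pr$proteins), pr$proteins)
  want <- brute_force_classify(peptides, pr$proteins)
  merged <- merge(got, want, by = "protein_id")
  expect_equal(nrow(merged), nrow(got))
  expect_equal(merged$uniqueness_class.x, merged$uniqueness_class.y)

  # planted classes recovered
  truthm <- merge(got, pr$truth$protein_classes, by = "protein_id")
  expect_equal(truthm$uniqueness_class.x, truthm$uniqueness_class.y)

  # order invariance
  shuf <- pr$proteins[rev(seq_len(nrow(pr$proteins))), ]
  got2 <- classify_proteins(map_peptides(peptides, shuf), shuf)
  m2 <- merge(got, got2, by = "protein_id")
  expect_equal(m2$uniqueness_class.x, m2$uniqueness_class.y)
})

test_that("the identification filter thresholds distinct observed peptides", {
  q <- data.frame(protein_id = c("a", "b", "c"),
                  distinct_peptides = c(1L, 2L, 5L),
                  unique_peptides = c(0L, 1L, 2L))
  expect_equal(identification_filter(q)$protein_id, c("b", "c"))
  expect_equal(identification_filter(q, 1)$protein_id, c("a", "b", "c"))
  expect_equal(identification_filter(q, 2, "protein_unique")$protein_id, "c")
})

test_that("NSAF normalizes spectral counts by length and sums to one", {
  spc <- matrix(c(10, 10, 40), ncol = 1,
                dimnames = list(c("a", "b", "c"), "s1"))
  got <- nsaf(spc, c(100, 200, 400))
  expect_equal(as.numeric(got), c(0.4, 0.2, 0.4))

  expect_equal(as.numeric(nsaf(matrix(7, 1, 1, dimnames = list("a", "s")),
                               123)), 1)
  # scale invariance
  expect_equal(nsaf(spc * 2, c(100, 200, 400)), got)
  expect_error(nsaf(matrix(0, 1, 1), 10), "nonzero")
  expect_error(nsaf(spc, c(1, 2)), "align")
})

test_that("per-sample NSAF sums to 1 across the full synthetic quantitation", {
  cfg <- small_scenario()
  pr <- generate_proteome(cfg)
  q <- protein_quant(pr$observations, pr$proteins)
  expect_true(all(abs(colSums(q$nsaf) - 1) < 1e-9))
  expect_true(all(q$nsaf >= 0 & q$nsaf <= 1))
})

test_that("MAG contributions aggregate binned-unique counts to percentages", {
  quant <- list(
    quants = data.frame(
      protein_id = c("a", "b", "u"),
      origin = c("MAG_1", "MAG_2", "unbinned:s1"),
      uniqueness_class = c("binned_unique", "binned_unique",
                           "unbinned_unique"),
      distinct_peptides = c(3L, 3L, 3L)),
    spc = matrix(c(80, 20, 999), ncol = 1,
                 dimnames = list(c("a", "b", "u"), "s1")))
  contrib <- mag_contribution(quant)
  expect_equal(as.numeric(contrib[c("MAG_1", "MAG_2"), "s1"]), c(80, 20))
  expect_equal(sum(contrib[, "s1"]), 100)

  solo <- quant
  solo$quants <- solo$quants[1, ]; solo$spc <- solo$spc[1, , drop = FALSE]
  expect_equal(as.numeric(mag_contribution(solo)), 100)
})

test_that("planted phase-2 dominance is recovered from the default proteome scenario", {
  cfg <- scenario_config(seed = 402)
  pr <- generate_proteome(cfg)
  q <- protein_quant(pr$observations, pr$proteins)
  contrib <- mag_contribution(q)
  expect_equal(as.numeric(contrib["MAG_kosakonia", "biotic_CT_d03"]), 80,
               tolerance = 2 / 80)  # within 2 percentage points
})

test_that("sample clustering is deterministic and separates planted treatments", {
  prof <- matrix(c(1, 0, 1, 0, 0, 1), nrow = 2,
                 dimnames = list(c("m1", "m2"), c("s1", "s1dup", "s2")))
  tree <- cluster_samples(prof)
  first <- tree$merge[1, ]
  expect_equal(sort(tree$labels[-first]), c("s1", "s1dup"))
  expect_equal(tree$height[1], 0)
  expect_error(cluster_samples(prof[, 1, drop = FALSE]), "at least 2")

  # planted divergence: biotic dominated by one MAG at every sampled day,
  # unamended by another -> treatments split at the top of the tree
  mags <- c("MAG_kosakonia", "MAG_holophaga", "MAG_sporomusa_1",
            "MAG_sporomusa_2", "MAG_chromatiaceae")
  traj <- do.call(rbind, lapply(c("biotic_CT", "unamended"), function(tr) {
    do.call(rbind, lapply(c(3, 10), function(tp) {
      data.frame(treatment = tr, timepoint = tp, mag_id = mags,
                 share = if (tr == "biotic_CT") c(0.8, 0.05, 0.05, 0.05, 0.05)
                         else c(0.05, 0.05, 0.05, 0.05, 0.8))
    }))
  }))
  cfg <- scenario_config(seed = 8, proteome_timepoints = c(3, 10),
                         mag_trajectories = traj, proteins_per_mag = 4,
                         protein_length = 200, total_spectra = 600,
                         unbinned_spectra = 60, shared_spectra = 40)
  pr <- generate_proteome(cfg)
  q <- protein_quant(pr$observations, pr$proteins)
  contrib <- mag_contribution(q)
  tree <- cluster_samples(contrib)
  two <- stats::cutree(tree, k = 2)
  grp <- split(names(two), two)
  treatments <- lapply(grp, function(g) unique(sub("_d[0-9]+$", "", g)))
  expect_true(all(lengths(treatments) == 1))
})

test_that("the MAG presence rule applies inclusive breadth and coverage thresholds", {
  cov <- data.frame(
    mag_id = c("m1", "m2", "m3", "m4"),
    sample_id = "s1", treatment = "CT", timepoint = 5,
    breadth = c(0.80, 0.74, 0.90, 0.75),
    reads_per_base = c(0.03, 1.0, 0.01, 3 / 151))
  res <- mag_presence(cov)
  expect_equal(res$per_sample$coverage[1], 4.53)
  expect_equal(res$per_sample$present, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$per_treatment$present[res$per_treatment$mag_id == "m4"],
               TRUE)

  # treatment-level presence is presence at ANY timepoint
  cov2 <- rbind(cov, within(cov[2, ], {
    timepoint <- 10; breadth <- 0.9; reads_per_base <- 0.5
  }))
  res2 <- mag_presence(cov2)
  expect_true(res2$per_treatment$present[res2$per_treatment$mag_id == "m2"])

  expect_error(mag_presence(within(cov, breadth <- breadth + 1)), "breadth")
})

test_that("the presence rule is monotone in breadth and depth", {
  set.seed(9)
  base <- data.frame(mag_id = "m", sample_id = "s", treatment = "CT",
                     timepoint = 1,
                     breadth = runif(200), reads_per_base = runif(200, 0, 0.1))
  before <- mag_presence(base)$per_sample$present
  bumped <- base
  bumped$breadth <- pmin(base$breadth + runif(200, 0, 0.2), 1)
  bumped$reads_per_base <- base$reads_per_base + runif(200, 0, 0.05)
  after <- mag_presence(bumped)$per_sample$present
  expect_true(all(after >= before))
})

test_that("FASTA round-trip preserves sequences and origin annotations", {
  cfg <- small_scenario()
  pr <- generate_proteome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_scenario(cfg, dir)
  back <- read_protein_fasta(paths[["fasta"]])
  expect_equal(back$protein_id, pr$proteins$protein_id)
  expect_equal(back$sequence, pr$proteins$sequence)
  expect_equal(back$origin, pr$proteins$origin)
  expect_equal(back$origin_type, pr$proteins$origin_type)

  obs <- read_peptide_report(paths[["peptides"]])
  expect_setequal(names(obs), c("peptide", "sample_id", "spectral_count"))
})
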