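#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, returning
#' fully tryptic peptides with up to `missed_cleavages` internal missed
#' sites; fully cleaved fragments come first (by start position), followed
#' by the missed-cleavage spans.
#'
#' @param sequence amino-acid sequence (standard 20 residues).
#' @param missed_cleavages maximum internal missed cleavage sites (>= 0).
#' @return character vector of peptides.
#' @export
#' @examples
#' tryptic_digest("AKRPK")         # "AK", "RPK" (no cleavage before proline)
#' tryptic_digest("AKCK", missed_cleavages = 1)
tryptic_digest <- function(sequence, missed_cleavages = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d", res[bad[1]],
                 bad[1]))
  }
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  n <- length(res)
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[cuts + 1] != "P"]
  bounds <- c(0L, cuts, n)            # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  peptides <- character(0)
  for (mc in 0:missed_cleavages) {          # fully tryptic first, then spans
    for (i in seq_len(nfrag - mc)) {
      peptides <- c(peptides,
                    substr(sequence, bounds[i] + 1L, bounds[i + mc + 1L]))
    }
  }
  peptides
}

#' Read a protein database FASTA with MAG/unbinned origin annotation
#'
#' Headers encode the origin as `>protein_id mag=MAG_007` for binned genes
#' or `>protein_id mag=unbinned:scaffold_123` for genes on unbinned
#' scaffolds.
#'
#' @param path FASTA file path.
#' @return data.frame with columns protein_id, sequence, length, origin,
#'   origin_type ("mag" or "unbinned").
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  protein_id <- sub("\\s.*$", "", headers)
  origin <- sub("^.*\\bmag=([^\\s]+).*$", "\\1", headers, perl = TRUE)
  if (any(origin == headers)) {
    stop("FASTA header(s) lack the 'mag=' origin annotation")
  }
  data.frame(
    protein_id = protein_id,
    sequence = as.character(seqs),
    length = Biostrings::width(seqs),
    origin = origin,
    origin_type = ifelse(startsWith(origin, "unbinned:"), "unbinned", "mag")
  )
}

#' Read a peptide observation report
#'
#' Delimited text with header `peptide,sample_id,spectral_count` (post-FDR
#' peptide-spectrum-match counts per sample).
#'
#' @param path file path.
#' @param min_length minimum peptide length in residues (default 6); shorter
#'   peptides are dropped with a warning.
#' @return data.frame of observations.
#' @export
read_peptide_report <- function(path, min_length = 6) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("peptide", "sample_id", "spectral_count")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("peptide report is missing column(s): ", paste(missing, collapse = ", "))
  }
  short <- nchar(obs$peptide) < min_length
  if (any(short)) {
    warning(sum(short), " peptide observation(s) below ", min_length,
            " residues dropped")
    obs <- obs[!short, , drop = FALSE]
  }
  obs
}

#' Map peptides to the proteins containing them
#'
#' Exact substring containment of each peptide in each protein sequence;
#' isoleucine and leucine are distinct by default (set `il_equivalent` to
#' collapse them, as some search engines do).
#'
#' @param peptides character vector of peptide sequences (deduplicated
#'   internally).
#' @param proteins data.frame from [read_protein_fasta()].
#' @param il_equivalent treat I and L as the same residue.
#' @return named list: peptide -> character vector of protein_ids (empty for
#'   unmapped peptides).
#' @export
map_peptides <- function(peptides, proteins, il_equivalent = FALSE) {
  if (!nrow(proteins)) stop("protein database must be non-empty")
  peptides <- unique(peptides)
  seqs <- proteins$sequence
  if (il_equivalent) {
    seqs <- gsub("I", "L", seqs, fixed = TRUE)
  }
  out <- lapply(peptides, function(p) {
    if (il_equivalent) p <- gsub("I", "L", p, fixed = TRUE)
    proteins$protein_id[grepl(p, seqs, fixed = TRUE)]
  })
  names(out) <- peptides
  out
}

#' Three-way uniqueness classification of identified proteins
#'
#' A protein with at least one observed peptide mapping to it alone is
#' "binned_unique" when its gene lies in a MAG and "unbinned_unique" when it
#' lies on an unbinned scaffold; proteins identified only through shared
#' peptides are "non_unique". Proteins with no observed peptide are
#' excluded. Also counts, per protein, distinct observed peptides and those
#' unique to it.
#'
#' @param mapping named list from [map_peptides()] over the observed
#'   peptides.
#' @param proteins data.frame from [read_protein_fasta()].
#' @return data.frame with columns protein_id, origin, origin_type,
#'   uniqueness_class, distinct_peptides, unique_peptides.
#' @export
classify_proteins <- function(mapping, proteins) {
  hits_per_pep <- lengths(mapping)
  prot_ids <- unique(unlist(mapping, use.names = FALSE))
  prot_ids <- proteins$protein_id[proteins$protein_id %in% prot_ids]  # stable order
  if (!length(prot_ids)) {
    return(data.frame(protein_id = character(), origin = character(),
                      origin_type = character(), uniqueness_class = character(),
                      distinct_peptides = integer(), unique_peptides = integer()))
  }
  rows <- lapply(prot_ids, function(id) {
    mapped <- vapply(mapping, function(ids) id %in% ids, logical(1))
    distinct <- sum(mapped)
    uniq <- sum(mapped & hits_per_pep == 1L)
    info <- proteins[match(id, proteins$protein_id), ]
    cls <- if (uniq >= 1L) {
      if (info$origin_type == "mag") "binned_unique" else "unbinned_unique"
    } else "non_unique"
    data.frame(protein_id = id, origin = info$origin,
               origin_type = info$origin_type, uniqueness_class = cls,
               distinct_peptides = distinct, unique_peptides = uniq)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identification filter on distinct observed peptides
#'
#' Retains proteins with at least `min_distinct_peptides` observed peptides.
#' The default counts distinct observed peptide sequences mapping to the
#' protein; `count = "protein_unique"` applies the stricter reading that
#' counts only peptides mapping to no other protein.
#'
#' @param quants data.frame from [classify_proteins()] (or any table with
#'   distinct_peptides / unique_peptides columns).
#' @param min_distinct_peptides threshold (default 2).
#' @param count which peptide count to threshold on.
#' @return filtered data.frame.
#' @export
identification_filter <- function(quants, min_distinct_peptides = 2,
                                  count = c("distinct", "protein_unique")) {
  count <- match.arg(count)
  col <- if (count == "distinct") "distinct_peptides" else "unique_peptides"
  quants[quants[[col]] >= min_distinct_peptides, , drop = FALSE]
}

#' Per-sample spectral counts per protein
#'
#' Spectral counts of each observed peptide are attributed to every protein
#' it maps to (no parsimony apportionment; non-unique identifications are a
#' separate reported class rather than being razored away, and MAG
#' contribution profiles use only binned-unique proteins, which shared
#' peptides cannot inflate).
#'
#' @param observations data.frame from [read_peptide_report()].
#' @param mapping named list from [map_peptides()].
#' @param protein_ids proteins to tabulate (rows of the output).
#' @return matrix of spectral counts, proteins x samples.
#' @export
spectral_count_matrix <- function(observations, mapping, protein_ids) {
  samples <- sort(unique(observations$sample_id))
  mat <- matrix(0, nrow = length(protein_ids), ncol = length(samples),
                dimnames = list(protein_ids, samples))
  for (k in seq_len(nrow(observations))) {
    targets <- intersect(mapping[[observations$peptide[k]]], protein_ids)
    if (length(targets)) {
      mat[targets, observations$sample_id[k]] <-
        mat[targets, observations$sample_id[k]] + observations$spectral_count[k]
    }
  }
  mat
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Per sample, each protein's spectral count is divided by its length to
#' give a spectral abundance, which is then divided by the sum of spectral
#' abundances over all quantified proteins in that sample; NSAF therefore
#' sums to 1 within each sample.
#'
#' @param spc matrix of spectral counts (proteins x samples), e.g. from
#'   [spectral_count_matrix()].
#' @param lengths protein lengths in residues, aligned with `rownames(spc)`.
#' @return matrix of NSAF values with the same dimensions as `spc`.
#' @export
nsaf <- function(spc, lengths) {
  if (length(lengths) != nrow(spc)) {
    stop("lengths must align with the rows of the spectral-count matrix")
  }
  if (any(lengths <= 0)) stop("protein lengths must be > 0")
  if (any(colSums(spc) == 0)) {
    stop("every sample must have at least one nonzero spectral count")
  }
  sa <- spc / lengths
  sweep(sa, 2, colSums(sa), "/")
}

#' End-to-end protein quantitation
#'
#' Maps observed peptides to the database, classifies uniqueness, applies
#' the identification filter, and computes per-sample spectral counts and
#' NSAF over the retained proteins.
#'
#' @param observations data.frame from [read_peptide_report()].
#' @param proteins data.frame from [read_protein_fasta()].
#' @param min_distinct_peptides identification threshold (default 2).
#' @param il_equivalent passed to [map_peptides()].
#' @return list with elements quants (classification table), spc and nsaf
#'   (matrices over retained proteins), mapping, and unmapped_peptides.
#' @export
protein_quant <- function(observations, proteins, min_distinct_peptides = 2,
                          il_equivalent = FALSE) {
  mapping <- map_peptides(unique(observations$peptide), proteins,
                          il_equivalent)
  quants <- classify_proteins(mapping, proteins)
  quants <- identification_filter(quants, min_distinct_peptides)
  spc <- spectral_count_matrix(observations, mapping, quants$protein_id)
  keep_samples <- colSums(spc) > 0
  spc <- spc[, keep_samples, drop = FALSE]
  plen <- proteins$length[match(quants$protein_id, proteins$protein_id)]
  list(
    quants = quants,
    spc = spc,
    nsaf = nsaf(spc, plen),
    mapping = mapping,
    unmapped_peptides = names(mapping)[lengths(mapping) == 0]
  )
}

#' MAG contributions to the binned-unique peptide pool
#'
#' Per sample, aggregates spectral counts of binned-unique proteins by MAG
#' and reports each MAG's percentage of that pool (summing to 100 per
#' sample). `weight = "peptide"` counts distinct peptides instead of
#' spectra.
#'
#' @param quant list from [protein_quant()] (uses quants + spc), or pass
#'   `quants` and `spc` explicitly.
#' @param weight "spectral" (default) or "peptide".
#' @return matrix of percentages, MAGs x samples.
#' @export
mag_contribution <- function(quant, weight = c("spectral", "peptide")) {
  weight <- match.arg(weight)
  quants <- quant$quants
  bu <- quants$uniqueness_class == "binned_unique"
  if (!any(bu)) stop("no binned-unique proteins to aggregate")
  ids <- quants$protein_id[bu]
  mags <- quants$origin[bu]
  w <- quant$spc[ids, , drop = FALSE]
  if (weight == "peptide") {
    w <- (w > 0) * quants$distinct_peptides[bu]
  }
  agg <- rowsum(w, group = mags)
  tot <- colSums(agg)
  if (any(tot == 0)) {
    agg <- agg[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(agg, 2, tot, "/") * 100
}

#' Hierarchical clustering of metaproteome samples
#'
#' Agglomerative clustering of samples on their MAG-contribution profiles
#' (Bray-Curtis distance, average linkage by default; both configurable).
#' Samples are ordered by id before clustering so ties resolve
#' deterministically.
#'
#' @param contrib matrix of contributions, MAGs x samples (e.g. from
#'   [mag_contribution()]).
#' @param distance dissimilarity index passed to [vegan::vegdist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an `hclust` object with samples as leaves.
#' @export
cluster_samples <- function(contrib, distance = "bray", linkage = "average") {
  if (ncol(contrib) < 2) stop("clustering requires at least 2 samples")
  prof <- t(contrib[, order(colnames(contrib)), drop = FALSE])
  d <- vegan::vegdist(prof, method = distance)
  stats::hclust(d, method = linkage)
}

#' MAG presence from read-mapping coverage
#'
#' A MAG is present in a sample when reads map to at least `min_breadth` of
#' its genome AND its average coverage (reads_per_base x read length) is at
#' least `min_coverage`; both thresholds are inclusive. Treatment-level
#' presence is presence at ANY timepoint of that treatment.
#'
#' @param coverage data.frame with columns mag_id, sample_id, treatment,
#'   timepoint, breadth, reads_per_base.
#' @param min_breadth breadth threshold (default 0.75).
#' @param min_coverage coverage threshold in X (default 3).
#' @param read_length read length in bp (default from [ct_constants()]).
#' @return list with `per_sample` (coverage augmented with coverage and
#'   present columns) and `per_treatment` (mag_id, treatment, present).
#' @export
mag_presence <- function(coverage, min_breadth = 0.75, min_coverage = 3,
                         read_length = ct_constants()$read_length) {
  if (any(coverage$breadth < 0 | coverage$breadth > 1)) {
    stop("breadth must lie in [0, 1]")
  }
  if (any(coverage$reads_per_base < 0)) stop("reads_per_base must be >= 0")
  per_sample <- coverage
  per_sample$coverage <- per_sample$reads_per_base * read_length
  per_sample$present <- per_sample$breadth >= min_breadth &
    per_sample$coverage >= min_coverage
  per_treatment <- stats::aggregate(present ~ mag_id + treatment, per_sample,
                                    any)
  per_treatment <- per_treatment[order(per_treatment$mag_id,
                                       per_treatment$treatment), ]
  rownames(per_treatment) <- NULL
  list(per_sample = per_sample, per_treatment = per_treatment)
}
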