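#' Read a long-format metabolite area table
#'
#' Delimited text with header `compound,treatment,timepoint,replicate,area`.
#'
#' @param path file path.
#' @return data.frame of peak areas.
#' @export
read_metabolite_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "treatment", "timepoint", "replicate", "area")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("metabolite table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' log2-transform peak areas
#'
#' @param areas data.frame with compound/area columns, or a numeric vector.
#' @return same shape with areas replaced by log2 areas.
#' @export
log2_transform <- function(areas) {
  if (is.numeric(areas)) {
    if (any(areas <= 0)) stop("peak areas must be > 0 before log transform")
    return(log2(areas))
  }
  bad <- which(areas$area <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive area for compound '%s' (row %d)",
                 areas$compound[bad[1]], bad[1]))
  }
  areas$area <- log2(areas$area)
  areas
}

#' Moderated two-group test on log2 metabolite areas, per timepoint
#'
#' At each timepoint, each compound's biotic-minus-autoclaved difference in
#' mean log2 area is tested with a variance-moderated two-sample t
#' statistic: the compound's pooled within-group variance is shrunk toward
#' the across-compound mean pooled variance at that timepoint with weight
#' `prior_df` pseudo-degrees of freedom,
#' \deqn{s^2_{mod} = (d_0 \bar{s}^2 + d s^2) / (d_0 + d),}
#' and the t statistic is referred to a t distribution on d0 + d degrees of
#' freedom (two-sided). `prior_df = 0` reduces to the ordinary
#' pooled-variance two-sample t test. A compound is called significant when
#' p < `alpha` AND log2 fold change > `fc_threshold` (one-sided enrichment
#' in the first group). No multiple-testing correction is applied by
#' default; set `adjust = "BH"` for Benjamini-Hochberg on each timepoint.
#'
#' @param areas long-format data.frame (see [read_metabolite_table()]) on
#'   the raw area scale; log2 is applied internally.
#' @param groups length-2 character vector: (enriched-in, reference)
#'   treatments; default `c("biotic_CT", "autoclaved_CT")`.
#' @param prior_df prior degrees of freedom for variance shrinkage
#'   (default 4).
#' @param alpha significance level on p (default 0.05).
#' @param fc_threshold log2 fold-change threshold (default 1.5, on the log2
#'   scale).
#' @param adjust "none" (default) or "BH".
#' @return data.frame with columns compound, timepoint, log2fc, p_value,
#'   significant.
#' @export
moderated_test <- function(areas, groups = c("biotic_CT", "autoclaved_CT"),
                           prior_df = 4, alpha = 0.05, fc_threshold = 1.5,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(groups) == 2)
  areas <- log2_transform(areas[areas$treatment %in% groups, , drop = FALSE])
  calls <- list()
  for (tp in sort(unique(areas$timepoint))) {
    sub <- areas[areas$timepoint == tp, ]
    compounds <- sort(unique(sub$compound))
    stat <- data.frame(compound = compounds, timepoint = tp, log2fc = NA_real_,
                       s2 = NA_real_, df = NA_real_, se_scale = NA_real_)
    for (i in seq_along(compounds)) {
      x <- sub$area[sub$compound == compounds[i] & sub$treatment == groups[1]]
      y <- sub$area[sub$compound == compounds[i] & sub$treatment == groups[2]]
      if (length(x) < 2 || length(y) < 2) {
        stop(sprintf("compound '%s' at day %s has < 2 replicates per group",
                     compounds[i], tp))
      }
      df <- length(x) + length(y) - 2
      stat$log2fc[i] <- mean(x) - mean(y)
      stat$s2[i] <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
      stat$df[i] <- df
      stat$se_scale[i] <- sqrt(1 / length(x) + 1 / length(y))
    }
    s2_prior <- mean(stat$s2)
    s2_mod <- (prior_df * s2_prior + stat$df * stat$s2) / (prior_df + stat$df)
    tval <- stat$log2fc / sqrt(s2_mod * stat$se_scale^2)
    df_mod <- stat$df + prior_df
    p <- 2 * stats::pt(-abs(tval), df_mod)
    # degenerate zero-variance case with no shrinkage available
    zero <- s2_mod == 0
    p[zero] <- ifelse(stat$log2fc[zero] == 0, 1, 0)
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    calls[[length(calls) + 1L]] <- data.frame(
      compound = stat$compound, timepoint = tp, log2fc = stat$log2fc,
      p_value = p,
      significant = p < alpha & stat$log2fc > fc_threshold
    )
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$compound, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Significant timepoints per compound
#'
#' @param calls data.frame from [moderated_test()].
#' @return named list: compound -> sorted numeric vector of significant
#'   timepoints (empty when never significant).
#' @export
enrichment_summary <- function(calls) {
  compounds <- sort(unique(calls$compound))
  out <- lapply(compounds, function(cp) {
    sort(calls$timepoint[calls$compound == cp & calls$significant])
  })
  names(out) <- compounds
  out
}
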