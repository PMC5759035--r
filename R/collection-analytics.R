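## Descriptive statistics of the deconvolved collection: single vs
## multi-member well composition, cOTU redundancy across wells, culture
## media specificity, and the occurrence-vs-abundance comparison at the
## deepest known taxonomic rank.

## Reporting convention for percentages: one decimal below 10%, whole
## numbers at or above 10% (so 49.3, 9.5 and 74 print as such).
format_percent <- function(x) {
  ifelse(x < 10, round(x, 1), round(x, 0))
}

#' Single/multi composition of identified wells
#'
#' @param wotus_per_well named integer vector: well_id -> number of wOTUs
#' @return list: `n_wells_identified`, `n_single_wells`, `n_multi_wells`,
#'   `fraction_single` and `fraction_multi` (percent, reporting-rounded),
#'   `histogram` (table of wOTUs-per-well)
#' @export
well_composition_stats <- function(wotus_per_well) {
  if (any(wotus_per_well < 1))
    stop_cbc("every identified well must have at least one wOTU")
  n <- length(wotus_per_well)
  n_single <- sum(wotus_per_well == 1)
  ## composition fractions are reported to one decimal
  list(n_wells_identified = n,
       n_single_wells = n_single,
       n_multi_wells = n - n_single,
       fraction_single = round(100 * n_single / n, 1),
       fraction_multi = round(100 * (n - n_single) / n, 1),
       histogram = table(wotus_per_well))
}

#' Redundancy of cOTUs across wells
#'
#' @param cotu_wells named list: cotu_id -> character vector of wells
#' @param few_threshold "found in fewer than k wells" cutoff (default 5)
#' @return list: `well_counts` (named integer), `max_redundancy`,
#'   `most_redundant_cotu`, `n_below_threshold`, `n_singletons`
#' @export
cotu_redundancy <- function(cotu_wells, few_threshold = 5) {
  counts <- vapply(cotu_wells, function(w) length(unique(w)), integer(1))
  list(well_counts = counts,
       max_redundancy = if (length(counts)) max(counts) else 0L,
       most_redundant_cotu = if (length(counts))
         names(counts)[which.max(counts)] else NA_character_,
       n_below_threshold = sum(counts < few_threshold),
       n_singletons = sum(counts == 1))
}

#' Culture-media specificity of cOTUs
#'
#' Partitions cOTUs by the number of media they grew in and reports the
#' per-medium breakdown of medium-exclusive cOTUs.
#'
#' @param cotu_media named list: cotu_id -> character vector of media
#' @param media closed media vocabulary (default LB8, LB35, YPD)
#' @return list: `n_unique_cotus`, `exclusive_counts` (per medium),
#'   `n_exclusive`, `n_two_media`, `n_all_media`, and reporting-rounded
#'   `pct_exclusive`, `pct_all_media`
#' @export
media_specificity <- function(cotu_media,
                              media = c("LB8", "LB35", "YPD")) {
  seen <- unique(unlist(cotu_media))
  bad <- setdiff(seen, media)
  if (length(bad))
    stop_cbc("unknown medium label(s): %s", paste(bad, collapse = ", "))
  n_media <- vapply(cotu_media, function(m) length(unique(m)), integer(1))
  n <- length(cotu_media)
  exclusive <- vapply(media, function(md) {
    sum(n_media == 1 & vapply(cotu_media, function(m) m[1] == md,
                              logical(1)))
  }, integer(1))
  list(n_unique_cotus = n,
       exclusive_counts = exclusive,
       n_exclusive = sum(n_media == 1),
       n_two_media = sum(n_media == 2),
       n_all_media = sum(n_media == length(media)),
       pct_exclusive = format_percent(100 * sum(n_media == 1) / n),
       pct_all_media = format_percent(100 *
                                        sum(n_media == length(media)) / n))
}

#' Occurrence vs habitat abundance at the deepest known rank
#'
#' Groups cOTUs by their collapsed display label, counts wells containing
#' at least one member of each group (a well counts once per group), sums
#' the habitat abundance linked to each group, and reports the Spearman
#' rank correlation between occurrence and abundance.
#'
#' @param cotu_wells named list: cotu_id -> wells
#' @param cotu_labels named character: cotu_id -> collapsed display label
#' @param cotu_abundance named numeric: cotu_id -> habitat abundance of
#'   its linked mOTUs (0 for unlinked)
#' @return list: `table` (data frame `label`, `n_wells`, `abundance`),
#'   `spearman_rho`, `p_value` (NA when fewer than 3 groups)
#' @export
occurrence_abundance <- function(cotu_wells, cotu_labels, cotu_abundance) {
  ids <- names(cotu_wells)
  labels <- cotu_labels[ids]
  groups <- split(ids, labels)
  tab <- do.call(rbind, lapply(names(groups), function(lb) {
    members <- groups[[lb]]
    data.frame(label = lb,
               n_wells = length(unique(unlist(cotu_wells[members]))),
               abundance = sum(cotu_abundance[members], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$n_wells), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) >= 3) {
    ct <- suppressWarnings(stats::cor.test(tab$n_wells, tab$abundance,
                                           method = "spearman"))
    rho <- unname(ct$estimate); pv <- ct$p.value
  } else {
    rho <- NA_real_; pv <- NA_real_
  }
  list(table = tab, spearman_rho = rho, p_value = pv)
}
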