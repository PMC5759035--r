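## Abundance-ranked synthetic community design: rank cultured cOTUs by the
## core abundance of their linked mOTUs across the target habitats, pick
## the top k, and choose a minimal set of culture wells covering them by
## greedy set cover (a well may contribute several members, and the
## co-members of selected multi-member wells become part of the community).

#' Rank cultured cOTUs by linked core abundance
#'
#' @param links data frame from [link_to_cotus()]
#' @param motu_abundance matrix habitats x mOTUs of relative abundances
#' @param habitats target habitats (rows of `motu_abundance`)
#' @param core named list habitat -> logical core flags (from
#'   [define_core()]); only core mOTUs contribute to scores
#' @param mode `"max"` (default) or `"sum"` aggregation of a cOTU's linked
#'   core abundance across target habitats
#' @return data frame `cotu_id`, `score`, sorted by descending score then
#'   cotu_id
#' @export
rank_candidates <- function(links, motu_abundance, habitats, core,
                            mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (!nrow(links)) {
    warning("no linked cOTUs to rank", call. = FALSE)
    return(data.frame(cotu_id = character(0), score = numeric(0)))
  }
  per_hab <- vapply(habitats, function(h) {
    ab <- motu_abundance[h, ]
    ab[!core[[h]][colnames(motu_abundance)]] <- 0
    vapply(split(links$motu_id, links$cotu_id), function(motus) {
      sum(ab[unique(motus)])
    }, numeric(1))
  }, numeric(length(unique(links$cotu_id))))
  per_hab <- matrix(per_hab, ncol = length(habitats),
                    dimnames = list(sort(unique(links$cotu_id)), habitats))
  score <- if (mode == "max") apply(per_hab, 1, max) else rowSums(per_hab)
  out <- data.frame(cotu_id = rownames(per_hab), score = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$cotu_id), , drop = FALSE]
}

#' Select a minimal well set covering the chosen cOTUs
#'
#' Greedy set cover: repeatedly pick the well covering the most uncovered
#' chosen cOTUs, breaking ties toward wells with fewer non-chosen
#' co-members and then by well id. The full member list of the selected
#' wells (co-members included) is returned.
#'
#' @param chosen_cotus cOTU ids to cover
#' @param well_members named list: well_id -> cOTU ids present in the well
#' @return list: `wells` (selected ids), `members` (all cOTUs carried by
#'   the selected wells), `co_members` (members beyond the chosen set)
#' @export
select_wells <- function(chosen_cotus, well_members) {
  uncovered <- unique(chosen_cotus)
  coverable <- unique(unlist(well_members))
  missing <- setdiff(uncovered, coverable)
  if (length(missing))
    stop_cbc("cOTU(s) present in no well: %s", paste(missing, collapse = ", "))
  selected <- character(0)
  while (length(uncovered)) {
    gain <- vapply(well_members, function(m) length(intersect(m, uncovered)),
                   integer(1))
    extras <- vapply(well_members, function(m) length(setdiff(m, chosen_cotus)),
                     integer(1))
    o <- order(-gain, extras, names(well_members))
    best <- o[1]
    if (gain[best] == 0L) stop_cbc("internal error: set cover stalled")
    selected <- c(selected, names(well_members)[best])
    uncovered <- setdiff(uncovered, well_members[[best]])
  }
  members <- sort(unique(unlist(well_members[selected])))
  list(wells = selected, members = members,
       co_members = setdiff(members, chosen_cotus))
}

#' Core-abundance coverage of a cOTU selection
#'
#' Per habitat: the summed core abundance of the mOTUs linked to the
#' selected cOTUs, as a percentage of the habitat's total core abundance.
#'
#' @param selected_cotus cOTU ids in the community
#' @param links data frame from [link_to_cotus()]
#' @param motu_abundance matrix habitats x mOTUs
#' @param core named list habitat -> logical core flags
#' @param habitats habitats to report (default: all rows)
#' @return named numeric vector of percentages
#' @export
community_coverage <- function(selected_cotus, links, motu_abundance, core,
                               habitats = rownames(motu_abundance)) {
  linked_motus <- unique(links$motu_id[links$cotu_id %in% selected_cotus])
  vapply(habitats, function(h) {
    ab <- motu_abundance[h, ]
    core_ids <- names(core[[h]])[core[[h]]]
    total <- sum(ab[core_ids])
    if (total <= 0) return(0)
    100 * sum(ab[intersect(core_ids, linked_motus)]) / total
  }, numeric(1))
}

#' Design an abundance-ranked synthetic community
#'
#' @param links data frame from [link_to_cotus()]
#' @param motu_abundance matrix habitats x mOTUs
#' @param habitats target habitats for the ranking
#' @param well_members named list: well_id -> cOTU ids
#' @param k_otus number of top-ranked cOTUs to cover (default 10)
#' @param core named list habitat -> logical core flags; computed from
#'   `motu_abundance` when `NULL`
#' @param mode score aggregation, see [rank_candidates()]
#' @return list of class `cbc_syncom_design`: `ranking`, `chosen_cotus`,
#'   `wells`, `members`, `co_members`, `coverage` (percent per habitat)
#' @export
design_syncom <- function(links, motu_abundance, habitats, well_members,
                          k_otus = 10, core = NULL, mode = "max") {
  if (is.null(core)) {
    core <- lapply(rownames(motu_abundance), function(h)
      define_core(motu_abundance[h, ]))
    names(core) <- rownames(motu_abundance)
  }
  ranking <- rank_candidates(links, motu_abundance, habitats, core,
                             mode = mode)
  chosen <- head(ranking$cotu_id[ranking$score > 0], k_otus)
  chosen <- intersect(chosen, unique(unlist(well_members)))
  sel <- select_wells(chosen, well_members)
  structure(list(
    ranking = ranking, chosen_cotus = chosen, wells = sel$wells,
    members = sel$members, co_members = sel$co_members,
    coverage = community_coverage(sel$members, links, motu_abundance,
                                  core)), class = "cbc_syncom_design")
}

#' @export
print.cbc_syncom_design <- function(x, ...) {
  cat(sprintf("SynCom design: %d wells carrying %d cOTUs (%d co-members)\n",
              length(x$wells), length(x$members), length(x$co_members)))
  cov <- paste(sprintf("%s %.1f%%", names(x$coverage), x$coverage),
               collapse = ", ")
  cat("  core coverage:", cov, "\n")
  invisible(x)
}
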