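## Ground-truthed synthetic world emulating every input of a community-based
## culture collection study: a 16S-like reference universe with clade
## structure, skewed habitat abundance profiles, multi-member culture wells
## sequenced as error-bearing long consensus reads, a short-read
## culture-independent survey, and an inoculation experiment. Every stage is
## seeded and records its truth so downstream inference can be scored.

#' Generate a clade-structured reference taxon universe
#'
#' Taxa are substitution-mutated copies of per-clade ancestral sequences,
#' which are themselves mutated copies of a common root. Within-clade
#' divergence is lower than between-clade divergence, and ranked lineage
#' labels (phylum to genus) are assigned per clade.
#'
#' @param n_taxa number of taxa
#' @param seq_length reference length in bases (default 750)
#' @param n_clades number of clades (<= n_taxa)
#' @param within_clade_divergence,between_clade_divergence per-base
#'   substitution rates; must satisfy 0 < within < between < 0.5
#' @param seed integer seed
#' @return data frame: `taxon_id`, `sequence`, `clade`, `phylum` ... `genus`
#' @export
generate_reference_taxa <- function(n_taxa, seq_length = 750, n_clades = 5,
                                    within_clade_divergence = 0.02,
                                    between_clade_divergence = 0.25,
                                    seed = 1) {
  if (n_clades > n_taxa) stop_cbc("n_clades must not exceed n_taxa")
  if (!(within_clade_divergence > 0 &&
        within_clade_divergence < between_clade_divergence &&
        between_clade_divergence < 0.5))
    stop_cbc("need 0 < within_clade_divergence < between_clade_divergence < 0.5")
  set.seed(seed)
  root <- random_dna(1, seq_length)
  substitute_only <- function(seq, rate) {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(bases)) < rate)
    for (i in hit) bases[i] <- sample(setdiff(DNA_ALPHABET, bases[i]), 1L)
    paste(bases, collapse = "")
  }
  ancestors <- vapply(seq_len(n_clades), function(c) {
    substitute_only(root, between_clade_divergence)
  }, character(1))
  clade <- rep(seq_len(n_clades), length.out = n_taxa)
  sequences <- vapply(seq_len(n_taxa), function(i) {
    if (n_taxa == 1) return(ancestors[clade[i]])
    substitute_only(ancestors[clade[i]], within_clade_divergence)
  }, character(1))
  df <- data.frame(
    taxon_id = sprintf("taxon_%03d", seq_len(n_taxa)),
    sequence = sequences, clade = clade,
    phylum = sprintf("Phylum_%d", ceiling(clade / 4)),
    class = sprintf("Class_%d", ceiling(clade / 2)),
    order = sprintf("Order_%d", clade),
    family = sprintf("Family_%d", clade),
    genus = sprintf("Genus_%d", clade),
    stringsAsFactors = FALSE)
  df
}

#' Generate skewed per-habitat relative-abundance profiles
#'
#' Abundances are drawn log-normal and normalised per habitat, emulating
#' core-microbiome skew in which a small fraction of the taxa holds most of
#' the relative abundance: at the default sigma the top 20% of taxa hold
#' at least 80% of the total in over 95% of draws.
#'
#' @param taxon_ids character vector of taxa
#' @param habitats character vector of habitat names
#' @param lognormal_sigma log-scale standard deviation (0 gives a uniform
#'   profile); default 2.5
#' @param core_fraction nominal fraction of taxa regarded as the abundant
#'   core, carried as an attribute for reporting (default 0.2)
#' @param seed integer seed
#' @return matrix habitats x taxa, rows summing to 1
#' @export
generate_habitat_profiles <- function(taxon_ids, habitats,
                                      lognormal_sigma = 2.5,
                                      core_fraction = 0.2, seed = 1) {
  if (!length(taxon_ids)) stop_cbc("empty taxa")
  check_fraction(core_fraction, "core_fraction", 1e-9, 1 - 1e-9)
  set.seed(seed)
  n <- length(taxon_ids)
  m <- matrix(0, nrow = length(habitats), ncol = n,
              dimnames = list(habitats, taxon_ids))
  for (h in seq_along(habitats)) {
    x <- if (lognormal_sigma == 0) rep(1, n) else rlnorm(n, 0, lognormal_sigma)
    m[h, ] <- x / sum(x)
  }
  attr(m, "core_fraction") <- core_fraction
  m
}

## Random well barcodes with a guaranteed minimum pairwise Hamming distance.
generate_barcodes <- function(n, length = 12, min_dist = 5) {
  codes <- character(0)
  tries <- 0
  while (length(codes) < n) {
    cand <- random_dna(1, length)
    ok <- all(vapply(codes, function(b) {
      sum(strsplit(cand, "")[[1]] != strsplit(b, "")[[1]]) >= min_dist
    }, logical(1)))
    if (ok) codes <- c(codes, cand)
    tries <- tries + 1
    if (tries > n * 200) stop_cbc("barcode generation failed; raise length")
  }
  codes
}

#' Simulate the culture collection: wells, members, consensus reads
#'
#' Each well draws one source habitat and one culture medium, then either a
#' single member (with probability `1 - multi_member_prob`) or 2 to
#' `members_max` members, sampled without replacement proportionally to the
#' habitat abundances of the taxa able to grow on the well's medium. Each
#' member emits consensus-like reads with substitution/indel errors and an
#' integer pass count (1 + geometric). Read sequences carry the well
#' barcode as a prefix; headers carry `well=`, `passes=`, `medium=`.
#'
#' @param taxa data frame from [generate_reference_taxa()]
#' @param habitat_profiles matrix from [generate_habitat_profiles()]; its
#'   rows named in `source_weights` are used for well sourcing
#' @param n_wells number of wells
#' @param source_weights named numeric vector of well-provenance weights
#'   (default rhizosphere:endophytic_root:endophytic_stalk = 1717:923:302)
#' @param multi_member_prob probability a well holds more than one member
#' @param members_max maximum members per multi-member well
#' @param reads_per_member integer range `c(lo, hi)` of reads per member
#' @param per_base_error per-base read error rate (substitutions,
#'   insertions and deletions at 80:10:10)
#' @param passes_mean mean of the pass-count distribution (1 + geometric)
#' @param media culture media vocabulary
#' @param medium_growth_prob probability a taxon grows on a given medium
#'   (each taxon is guaranteed at least one medium)
#' @param barcode_length,barcode_error well-barcode length and per-base
#'   substitution rate applied to the barcode prefix (default 0)
#' @param seed integer seed
#' @return list: `reads` (`cbc_seqs`), `wells` (data frame `well_id`,
#'   `source_habitat`, `medium`), `barcode_map` (barcode -> well_id),
#'   `well_truth` (well_id -> data frame `taxon_id`, `n_reads`),
#'   `medium_growth` (logical taxa x media matrix)
#' @export
simulate_collection <- function(taxa, habitat_profiles, n_wells = 400,
                                source_weights = c(rhizosphere = 1717,
                                                   endophytic_root = 923,
                                                   endophytic_stalk = 302),
                                multi_member_prob = 0.5, members_max = 4,
                                reads_per_member = c(3, 8),
                                per_base_error = 0.005, passes_mean = 5,
                                media = c("LB8", "LB35", "YPD"),
                                medium_growth_prob = 0.6,
                                barcode_length = 12, barcode_error = 0,
                                seed = 1) {
  check_fraction(multi_member_prob, "multi_member_prob")
  check_fraction(per_base_error, "per_base_error")
  check_fraction(medium_growth_prob, "medium_growth_prob", 1e-12, 1)
  if (!all(names(source_weights) %in% rownames(habitat_profiles)))
    stop_cbc("source_weights names must be habitat profile rows")
  set.seed(seed)

  n_taxa <- nrow(taxa)
  growth <- matrix(rbinom(n_taxa * length(media), 1,
                          medium_growth_prob) == 1,
                   nrow = n_taxa, dimnames = list(taxa$taxon_id, media))
  for (i in seq_len(n_taxa))  # every taxon must grow somewhere
    if (!any(growth[i, ])) growth[i, sample(length(media), 1L)] <- TRUE

  plate <- (seq_len(n_wells) - 1) %/% 96 + 1
  pos <- (seq_len(n_wells) - 1) %% 96
  well_ids <- sprintf("P%02d-%s%02d", plate, LETTERS[pos %/% 12 + 1],
                      pos %% 12 + 1)
  barcodes <- generate_barcodes(n_wells, length = barcode_length)
  barcode_map <- stats::setNames(well_ids, barcodes)

  source_habitat <- sample(names(source_weights), n_wells, replace = TRUE,
                           prob = source_weights / sum(source_weights))
  medium <- sample(media, n_wells, replace = TRUE)

  reads_id <- character(0); reads_seq <- character(0)
  reads_annot <- list()
  well_truth <- vector("list", n_wells); names(well_truth) <- well_ids
  counter <- 0L
  geom_p <- 1 / passes_mean
  for (w in seq_len(n_wells)) {
    ab <- habitat_profiles[source_habitat[w], ]
    growable <- which(growth[, medium[w]] & ab > 0)
    if (!length(growable)) {
      warning(sprintf("well %s skipped: no growable taxon on %s",
                      well_ids[w], medium[w]), call. = FALSE)
      next
    }
    n_members <- if (runif(1) < multi_member_prob && length(growable) > 1) {
      resample(2:max(2, members_max))
    } else 1L
    n_members <- min(n_members, length(growable))
    members <- if (length(growable) == 1L) growable else {
      resample(growable, n_members,
               prob = ab[growable] / sum(ab[growable]))
    }
    truth_rows <- data.frame(taxon_id = taxa$taxon_id[members],
                             n_reads = 0L, stringsAsFactors = FALSE)
    for (mi in seq_along(members)) {
      n_reads <- resample(reads_per_member[1]:reads_per_member[2])
      truth_rows$n_reads[mi] <- n_reads
      ref <- taxa$sequence[members[mi]]
      for (r in seq_len(n_reads)) {
        counter <- counter + 1L
        amplicon <- mutate_sequence(ref, per_base_error)
        bc <- if (barcode_error > 0) {
          mutate_sequence(barcodes[w], barcode_error, sub_frac = 1,
                          ins_frac = 0)
        } else barcodes[w]
        passes <- 1L + rgeom(1, geom_p)
        reads_id <- c(reads_id, sprintf("ccs_%06d", counter))
        reads_seq <- c(reads_seq, paste0(bc, amplicon))
        reads_annot[[counter]] <- c(well = well_ids[w],
                                    passes = as.character(passes),
                                    medium = medium[w])
      }
    }
    well_truth[[w]] <- truth_rows
  }
  keep_wells <- !vapply(well_truth, is.null, logical(1))
  list(reads = seq_records(reads_id, reads_seq,
                           annotations = reads_annot),
       wells = data.frame(well_id = well_ids, source_habitat = source_habitat,
                          medium = medium,
                          stringsAsFactors = FALSE)[keep_wells, ],
       barcode_map = barcode_map,
       well_truth = well_truth[keep_wells],
       medium_growth = growth)
}

#' Simulate a short-read amplicon survey
#'
#' Reads are drawn per habitat (or per sample: any profile row works)
#' proportionally to taxon abundances, cut from a fixed reference region,
#' error-mutated, and given per-base Phred scores drawn uniformly from
#' `quality_range`. A `plastid_fraction` of reads comes from plastid
#' reference sequences instead.
#'
#' @param taxa reference taxa data frame
#' @param habitat_profiles matrix rows = habitats/samples to sequence
#' @param region `c(start, end)` 1-based inclusive within the reference
#' @param n_reads_per_habitat reads per profile row
#' @param per_base_error per-base error rate
#' @param plastid_refs character vector of plastid sequences (default:
#'   3 random synthetic plastid stand-ins of the region length)
#' @param plastid_fraction fraction of reads drawn from plastids
#' @param quality_range integer `c(lo, hi)` per-base Phred range
#' @param seed integer seed
#' @return list: `reads` (`cbc_seqs`, FASTQ-ready, `sample=` annotation),
#'   `motus` (data frame `motu_id`, `taxon_id`, `sequence`),
#'   `motu_abundance` (habitats x mOTUs matrix of true relative
#'   abundances), `counts` (realised habitats x mOTUs read counts),
#'   `plastid_refs`
#' @export
simulate_survey <- function(taxa, habitat_profiles, region = c(201, 450),
                            n_reads_per_habitat = 3000,
                            per_base_error = 0.01, plastid_refs = NULL,
                            plastid_fraction = 0.0,
                            quality_range = c(25, 40), seed = 1) {
  seq_len_ref <- nchar(taxa$sequence[1])
  if (region[1] < 1 || region[2] > seq_len_ref || region[2] <= region[1])
    stop_cbc("region outside reference length")
  check_fraction(plastid_fraction, "plastid_fraction")
  set.seed(seed)
  region_len <- region[2] - region[1] + 1
  if (is.null(plastid_refs)) plastid_refs <- random_dna(3, region_len)
  motu_seq <- substr(taxa$sequence, region[1], region[2])
  motus <- data.frame(motu_id = sub("taxon", "motu", taxa$taxon_id),
                      taxon_id = taxa$taxon_id, sequence = motu_seq,
                      stringsAsFactors = FALSE)
  habs <- rownames(habitat_profiles)
  counts <- matrix(0L, length(habs), nrow(motus),
                   dimnames = list(habs, motus$motu_id))
  reads_id <- character(0); reads_seq <- character(0)
  reads_q <- list(); reads_annot <- list()
  counter <- 0L
  for (h in habs) {
    n_plastid <- rbinom(1, n_reads_per_habitat, plastid_fraction)
    n_16s <- n_reads_per_habitat - n_plastid
    draw <- as.integer(rmultinom(1, n_16s, habitat_profiles[h, ]))
    counts[h, ] <- draw
    src <- c(rep(seq_len(nrow(motus)), draw),
             -sample(length(plastid_refs), n_plastid, replace = TRUE))
    for (s in src) {
      counter <- counter + 1L
      template <- if (s > 0) motu_seq[s] else plastid_refs[-s]
      read <- mutate_sequence(template, per_base_error)
      reads_id <- c(reads_id, sprintf("sr_%07d", counter))
      reads_seq <- c(reads_seq, read)
      qs <- quality_range[1]:quality_range[2]
      reads_q[[counter]] <- if (length(qs) == 1L) {
        rep(qs, nchar(read))
      } else sample(qs, nchar(read), replace = TRUE)
      reads_annot[[counter]] <- c(sample = h,
                                  origin = if (s > 0) motus$taxon_id[s]
                                           else "plastid")
    }
  }
  list(reads = seq_records(reads_id, reads_seq, quality = reads_q,
                           annotations = reads_annot),
       motus = motus,
       motu_abundance = habitat_profiles[, , drop = FALSE] |>
         `colnames<-`(motus$motu_id),
       counts = counts, plastid_refs = plastid_refs)
}

#' Simulate the inoculation experiment as an OTU count table
#'
#' Uninoculated samples are multinomial draws from the baseline habitat
#' profiles; inoculated samples come from the same profiles after
#' multiplying the synthetic-community members by `enrichment` and
#' renormalising.
#'
#' @param habitat_profiles matrix habitats (plant compartments) x taxa
#' @param syncom_members taxon ids of the inoculant (must be profile
#'   columns)
#' @param enrichment multiplicative enrichment (> 0); scalar or named
#'   per-habitat vector
#' @param n_replicates plants per treatment group (>= 2)
#' @param depth reads per sample (multinomial size); 0 is flagged
#'   degenerate
#' @param seed integer seed
#' @return list: `table` (samples x taxa counts), `metadata` (sample
#'   data frame), `expected` (samples x taxa true proportions)
#' @export
simulate_inoculation <- function(habitat_profiles, syncom_members,
                                 enrichment = 50, n_replicates = 5,
                                 depth = 50000, seed = 1) {
  if (n_replicates < 2) stop_cbc("n_replicates must be >= 2")
  if (any(enrichment <= 0)) stop_cbc("enrichment must be > 0")
  missing <- setdiff(syncom_members, colnames(habitat_profiles))
  if (length(missing))
    stop_cbc("syncom member(s) absent from profiles: %s",
             paste(missing, collapse = ", "))
  set.seed(seed)
  habs <- rownames(habitat_profiles)
  enr <- if (length(enrichment) == 1L) {
    stats::setNames(rep(enrichment, length(habs)), habs)
  } else enrichment
  rows <- list(); meta <- list(); expected <- list()
  for (h in habs) {
    base <- habitat_profiles[h, ]
    boosted <- base
    boosted[syncom_members] <- boosted[syncom_members] * enr[[h]]
    boosted <- boosted / sum(boosted)
    for (grp in c("inoculated", "uninoculated")) {
      p <- if (grp == "inoculated") boosted else base
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_%s_r%d", h, grp, r)
        cnt <- if (depth > 0) as.integer(rmultinom(1, depth, p)) else
          rep(0L, length(p))
        rows[[sid]] <- cnt
        expected[[sid]] <- p
        parts <- strsplit(h, "_", fixed = TRUE)[[1]]
        meta[[sid]] <- data.frame(
          sample_id = sid, treatment = grp,
          organ = parts[length(parts)],
          compartment = parts[1], stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- colnames(habitat_profiles)
  metadata <- validate_metadata(do.call(rbind, meta))
  rownames(metadata) <- NULL
  out <- list(table = tab, metadata = metadata,
              expected = do.call(rbind, expected))
  if (depth == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Simulate per-plant biomass under inoculation
#'
#' Normal draws around group means; defaults use the fresh-weight means
#' observed in the maize inoculation experiment the generator emulates.
#'
#' @param n_per_group plants per treatment
#' @param mean_inoculated,mean_uninoculated group means (grams)
#' @param cv coefficient of variation of the draws
#' @param seed integer seed
#' @return data frame `plant_id`, `treatment`, `weight`
#' @export
simulate_plant_weights <- function(n_per_group = 5, mean_inoculated = 7.82,
                                   mean_uninoculated = 2.31, cv = 0.15,
                                   seed = 1) {
  set.seed(seed)
  w_in <- pmax(rnorm(n_per_group, mean_inoculated, cv * mean_inoculated),
               0.01)
  w_un <- pmax(rnorm(n_per_group, mean_uninoculated, cv * mean_uninoculated),
               0.01)
  data.frame(
    plant_id = sprintf("plant_%02d", seq_len(2 * n_per_group)),
    treatment = rep(c("inoculated", "uninoculated"), each = n_per_group),
    weight = c(w_in, w_un), stringsAsFactors = FALSE)
}

#' Assemble the full synthetic world and its truth manifest
#'
#' Convenience wrapper running the reference, profile, collection and
#' survey generators under seeds derived from one master seed.
#'
#' @param config pipeline configuration, see [cbc_config()]
#' @param seed master integer seed
#' @return a list of class `cbc_truth`
#' @export
simulate_cbc_world <- function(config = cbc_config(), seed = 1) {
  g <- config$generator
  taxa <- generate_reference_taxa(
    n_taxa = g$n_taxa, seq_length = g$seq_length, n_clades = g$n_clades,
    within_clade_divergence = g$within_clade_divergence,
    between_clade_divergence = g$between_clade_divergence,
    seed = derive_seed(seed, "taxa"))
  habitats <- g$habitats
  profiles <- generate_habitat_profiles(
    taxa$taxon_id, habitats, lognormal_sigma = g$lognormal_sigma,
    core_fraction = g$core_fraction, seed = derive_seed(seed, "profiles"))
  collection <- simulate_collection(
    taxa, profiles, n_wells = g$n_wells,
    multi_member_prob = g$multi_member_prob, members_max = g$members_max,
    reads_per_member = g$reads_per_member,
    per_base_error = g$ccs_error, passes_mean = g$passes_mean,
    medium_growth_prob = g$medium_growth_prob,
    seed = derive_seed(seed, "collection"))
  survey <- simulate_survey(
    taxa, profiles, region = g$survey_region,
    n_reads_per_habitat = g$survey_reads_per_habitat,
    per_base_error = g$survey_error,
    plastid_fraction = g$plastid_fraction,
    seed = derive_seed(seed, "survey"))
  truth <- list(taxa = taxa, habitat_profiles = profiles,
                collection = collection, survey = survey,
                seeds = list(master = seed),
                config = config)
  class(truth) <- "cbc_truth"
  validate_truth(truth)
  truth
}

#' Validate a truth manifest's structural invariants
#' @param truth a `cbc_truth` object
#' @return `truth`, invisibly; errors on violation
#' @export
validate_truth <- function(truth) {
  p <- truth$habitat_profiles
  if (any(abs(rowSums(p) - 1) > 1e-9))
    stop_cbc("habitat profiles must sum to 1")
  wt_taxa <- unique(unlist(lapply(truth$collection$well_truth,
                                  function(x) x$taxon_id)))
  if (!all(wt_taxa %in% truth$taxa$taxon_id))
    stop_cbc("well truth references unknown taxa")
  invisible(truth)
}

#' @export
print.cbc_truth <- function(x, ...) {
  cat("Synthetic CBC world\n")
  cat(sprintf("  taxa: %d in %d clades, %d bp\n", nrow(x$taxa),
              length(unique(x$taxa$clade)), nchar(x$taxa$sequence[1])))
  cat(sprintf("  habitats: %s\n",
              paste(rownames(x$habitat_profiles), collapse = ", ")))
  cat(sprintf("  wells: %d (%d consensus reads)\n",
              nrow(x$collection$wells), nrow(x$collection$reads)))
  cat(sprintf("  survey reads: %d\n", nrow(x$survey$reads)))
  invisible(x)
}
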