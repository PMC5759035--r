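## End-to-end orchestration: a single nested configuration carrying every
## threshold of the pipeline (printed study values where the study states
## them, declared assumptions otherwise) and a runner that chains the
## stages on generator output, writing plain-text artifacts per stage.

#' Default pipeline configuration
#'
#' Returns the nested configuration list; named overrides are deep-merged
#' and validated (unknown keys are rejected, thresholds range-checked).
#'
#' @param ... named overrides, e.g. `generator = list(n_wells = 100)`
#' @return a named list of class `cbc_config`
#' @export
cbc_config <- function(...) {
  defaults <- list(
    generator = list(
      n_taxa = 30, seq_length = 750, n_clades = 6,
      within_clade_divergence = 0.02, between_clade_divergence = 0.25,
      habitats = c("rhizosphere", "endophytic_root", "endophytic_stalk"),
      lognormal_sigma = 2.5, core_fraction = 0.2,
      n_wells = 400, multi_member_prob = 0.5, members_max = 4,
      reads_per_member = c(3, 8), ccs_error = 0.005, passes_mean = 5,
      medium_growth_prob = 0.6,
      survey_region = c(201, 450), survey_reads_per_habitat = 3000,
      survey_error = 0.01, plastid_fraction = 0.05),
    identify = list(
      max_mismatch = 1, min_passes = 2, db_min_identity = 0.80,
      peer_min_identity = 0.97, cluster_threshold = 0.97),
    taxonomy = list(cutoff = 0.9, bootstraps = 100, subsample = 32),
    crossref = list(
      motu_filter_identity = 0.75, match_identity = 0.97,
      match_coverage = 0.90, core_cutoff = 0.90),
    design = list(k_otus = 10, mode = "max"),
    colonize = list(
      maize_habitats = c("exophytic_root", "endophytic_root",
                         "exophytic_stem"),
      natural_syncom_weight = 0.05,
      enrichment = 50, n_replicates = 5, depth = 50000,
      profile_reads_per_sample = 800,
      max_ee = 0.25, length_range = c(230, 270),
      plastid_k = 21, plastid_share = 0.05,
      alpha = 0.05, n_perm = 999))
  config <- merge_config(defaults, list(...))
  validate_config(config)
  class(config) <- c("cbc_config", "list")
  config
}

merge_config <- function(defaults, overrides, path = "") {
  if (!length(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_cbc("unknown config key(s): %s",
             paste0(path, unknown, collapse = ", "))
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      paste0(path, key, "$"))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

validate_config <- function(config) {
  g <- config$generator
  check_fraction(g$multi_member_prob, "generator$multi_member_prob")
  check_fraction(g$ccs_error, "generator$ccs_error", 0, 0.5)
  check_fraction(g$plastid_fraction, "generator$plastid_fraction")
  check_fraction(config$identify$cluster_threshold,
                 "identify$cluster_threshold", 0.5, 1)
  check_fraction(config$crossref$motu_filter_identity,
                 "crossref$motu_filter_identity")
  check_fraction(config$crossref$core_cutoff, "crossref$core_cutoff", 0, 1)
  check_fraction(config$taxonomy$cutoff, "taxonomy$cutoff")
  if (config$colonize$max_ee < 0) stop_cbc("colonize$max_ee must be >= 0")
  check_fraction(config$colonize$alpha, "colonize$alpha", 1e-6, 0.5)
  if (config$colonize$enrichment <= 0)
    stop_cbc("colonize$enrichment must be > 0")
  invisible(config)
}

write_stage_yaml <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full pipeline on generator output
#'
#' Chains simulate -> identify (demultiplex, coverage, reliability, wOTU /
#' cOTU clustering, taxonomy) -> crossref -> analytics -> design ->
#' colonize on the synthetic world, writing plain-text artifacts per
#' stage under `outdir`. Deterministic for a fixed seed and config.
#'
#' @param config a `cbc_config` list
#' @param outdir output directory (created if needed); `NULL` skips all
#'   file output
#' @param seed master integer seed
#' @return list of class `cbc_run` with per-stage results: `truth`,
#'   `identify`, `crossref`, `analytics`, `design`, `colonize`,
#'   `summary`
#' @export
run_cbc_pipeline <- function(config = cbc_config(), outdir = NULL,
                             seed = 1) {
  validate_config(config)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(fun, name) if (!is.null(outdir))
    fun(file.path(outdir, name))

  ## --- simulate -----------------------------------------------------
  truth <- simulate_cbc_world(config, seed = seed)
  emit(function(p) write_sequences(truth$collection$reads, p), "ccs.fasta")

  ## --- identify -----------------------------------------------------
  idf <- config$identify
  dmx <- demultiplex(truth$collection$reads, truth$collection$barcode_map,
                     max_mismatch = idf$max_mismatch)
  cov <- filter_by_coverage(dmx$assigned, min_passes = idf$min_passes)
  curated <- seq_records(truth$taxa$taxon_id, truth$taxa$sequence)
  rel <- reliability_filter(cov$retained, curated,
                            db_min_identity = idf$db_min_identity,
                            peer_min_identity = idf$peer_min_identity)
  ccs <- rel$retained
  wells <- split(seq_len(nrow(ccs)), seq_annot(ccs, "well"))
  wotu_rows <- list(); wotus_per_well <- integer(0)
  well_clusters <- list()
  for (w in names(wells)) {
    wc <- cluster_well(ccs[wells[[w]], , drop = FALSE],
                       threshold = idf$cluster_threshold)
    well_clusters[[w]] <- wc
    wotus_per_well[w] <- wc$n_wotus
    for (i in seq_along(wc$wotus)) {
      wotu_rows[[length(wotu_rows) + 1L]] <- data.frame(
        well_id = w, wotu_id = sprintf("%s|w%02d", w, i),
        centroid_sequence = wc$wotus[[i]]$centroid_sequence,
        medium = seq_annot(ccs[wells[[w]][1], , drop = FALSE], "medium"),
        n_ccs = length(wc$wotus[[i]]$member_ids),
        stringsAsFactors = FALSE)
    }
  }
  wotu_table <- do.call(rbind, wotu_rows)
  coll <- cluster_collection(wotu_table,
                             threshold = idf$cluster_threshold)
  ## ccs -> cotu via its well's wOTU membership
  ccs_to_cotu <- character(0)
  for (w in names(wells)) {
    wcl <- well_clusters[[w]]
    for (i in seq_along(wcl$wotus)) {
      wid <- sprintf("%s|w%02d", w, i)
      cid <- coll$mapping$cotu_id[coll$mapping$wotu_id == wid]
      ccs_to_cotu[wcl$wotus[[i]]$member_ids] <- cid
    }
  }
  centroid_seqs <- vapply(coll$cotus, `[[`, character(1),
                          "centroid_sequence")
  names(centroid_seqs) <- vapply(coll$cotus, `[[`, character(1), "cotu_id")
  taxres <- classify_set(centroid_seqs, truth$taxa,
                         seed = derive_seed(seed, "taxonomy"),
                         cutoff = config$taxonomy$cutoff,
                         bootstraps = config$taxonomy$bootstraps,
                         subsample = config$taxonomy$subsample)
  identify <- list(demux = dmx, coverage = cov, reliability = rel,
                   wotu_table = wotu_table, wotus_per_well = wotus_per_well,
                   cotus = coll$cotus, mapping = coll$mapping,
                   ccs_to_cotu = ccs_to_cotu, taxonomy = taxres)
  if (!is.null(outdir)) {
    write.table(wotu_table[, c("well_id", "wotu_id", "medium", "n_ccs")],
                file.path(outdir, "wotus.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(coll$mapping, file.path(outdir, "cotu_mapping.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_sequences(seq_records(names(centroid_seqs), centroid_seqs),
                    file.path(outdir, "cotu_centroids.fasta"))
  }

  ## --- crossref -----------------------------------------------------
  cx <- config$crossref
  motus <- truth$survey$motus
  motu_ab <- truth$survey$motu_abundance
  flt <- filter_motus(motus, curated,
                      min_identity = cx$motu_filter_identity)
  pairs <- match_motus(flt$retained, ccs,
                       min_identity = cx$match_identity,
                       min_query_coverage = cx$match_coverage)
  links <- link_to_cotus(pairs, ccs_to_cotu)
  core <- lapply(rownames(motu_ab), function(h)
    define_core(motu_ab[h, ], cumulative_cutoff = cx$core_cutoff))
  names(core) <- rownames(motu_ab)
  recovery <- lapply(rownames(motu_ab), function(h)
    recovery_estimate(links, motu_ab[h, ], core = core[[h]], habitat = h))
  names(recovery) <- rownames(motu_ab)
  crossref <- list(links = links, core = core, recovery = recovery)
  if (!is.null(outdir)) {
    write.table(links, file.path(outdir, "links.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rec_df <- do.call(rbind, lapply(recovery, function(r)
      data.frame(habitat = r$habitat, n_matched_cotus = r$n_matched_cotus,
                 n_matched_motus = r$n_matched_motus,
                 recovered_core_abundance = r$recovered_core_abundance)))
    write.table(rec_df, file.path(outdir, "recovery.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## --- analytics ----------------------------------------------------
  cotu_wells <- lapply(coll$cotus, `[[`, "wells")
  names(cotu_wells) <- names(centroid_seqs)
  cotu_media <- lapply(coll$cotus, `[[`, "media")
  names(cotu_media) <- names(centroid_seqs)
  labels <- stats::setNames(taxres$display_label, taxres$id)
  rhizo_ab <- stats::setNames(rep(0, length(centroid_seqs)),
                              names(centroid_seqs))
  for (i in seq_len(nrow(links))) {
    rhizo_ab[links$cotu_id[i]] <- rhizo_ab[links$cotu_id[i]] +
      motu_ab["rhizosphere", links$motu_id[i]]
  }
  analytics <- list(
    composition = well_composition_stats(wotus_per_well),
    redundancy = cotu_redundancy(cotu_wells),
    media = media_specificity(cotu_media),
    occurrence = occurrence_abundance(cotu_wells, labels, rhizo_ab))
  emit(function(p) write_stage_yaml(list(
    composition = analytics$composition[c("n_wells_identified",
                                          "n_single_wells", "n_multi_wells",
                                          "fraction_single")],
    media = analytics$media[c("n_unique_cotus", "n_exclusive",
                              "n_two_media", "n_all_media")],
    max_redundancy = analytics$redundancy$max_redundancy), p),
    "analytics.yaml")

  ## --- design -------------------------------------------------------
  well_members <- split(coll$mapping$cotu_id,
                        wotu_table$well_id[match(coll$mapping$wotu_id,
                                                 wotu_table$wotu_id)])
  design <- design_syncom(links, motu_ab,
                          habitats = rownames(motu_ab),
                          well_members = well_members,
                          k_otus = config$design$k_otus, core = core,
                          mode = config$design$mode)
  emit(function(p) write_stage_yaml(list(
    wells = design$wells, members = design$members,
    co_members = design$co_members,
    coverage = as.list(round(design$coverage, 3))), p), "design.yaml")

  ## --- colonize -----------------------------------------------------
  cz <- config$colonize
  ## the truth taxa behind the selected cOTUs form the inoculant
  member_taxa <- unique(vapply(design$members, function(cid) {
    seq <- centroid_seqs[[cid]]
    best <- 0; best_taxon <- NA_character_
    for (i in seq_len(nrow(truth$taxa))) {
      r <- global_identity(seq, truth$taxa$sequence[i])
      if (r$identity > best) { best <- r$identity
        best_taxon <- truth$taxa$taxon_id[i] }
    }
    best_taxon
  }, character(1)))
  maize_profiles <- generate_habitat_profiles(
    truth$taxa$taxon_id, cz$maize_habitats,
    lognormal_sigma = config$generator$lognormal_sigma,
    seed = derive_seed(seed, "maize"))
  ## community members come from another host's microbiome and are
  ## naturally rare in the plant the inoculant is probed on: down-weight
  ## them in the baseline
  maize_profiles[, member_taxa] <-
    maize_profiles[, member_taxa] * cz$natural_syncom_weight
  maize_profiles <- maize_profiles / rowSums(maize_profiles)
  inoc <- simulate_inoculation(maize_profiles, member_taxa,
                               enrichment = cz$enrichment,
                               n_replicates = cz$n_replicates,
                               depth = cz$depth,
                               seed = derive_seed(seed, "inoculation"))
  ## sequence the plants: short reads per sample from the true
  ## per-sample proportions, then the profiling chain
  maize_reads <- simulate_survey(
    truth$taxa, inoc$expected,
    region = config$generator$survey_region,
    n_reads_per_habitat = cz$profile_reads_per_sample,
    per_base_error = config$generator$survey_error,
    plastid_refs = truth$survey$plastid_refs,
    plastid_fraction = config$generator$plastid_fraction,
    seed = derive_seed(seed, "maize_reads"))
  profile <- build_profile(maize_reads$reads, truth$survey$plastid_refs,
                           max_ee = cz$max_ee,
                           length_range = cz$length_range,
                           plastid_k = cz$plastid_k,
                           plastid_fraction = cz$plastid_share,
                           threshold = idf$cluster_threshold)
  rel_tab <- relative_abundance(profile$table)
  meta_row <- match(rownames(rel_tab), inoc$metadata$sample_id)
  groups <- as.character(inoc$metadata$treatment)[meta_row]
  sample_hab <- sub("_(inoculated|uninoculated)_r[0-9]+$", "",
                    rownames(rel_tab))
  ## identify the community's OTUs in the profiled table: centroids at
  ## >= the OTU radius to a member taxon's amplicon region
  region <- config$generator$survey_region
  member_region <- substr(truth$taxa$sequence[
    match(member_taxa, truth$taxa$taxon_id)], region[1], region[2])
  syncom_otus <- names(profile$centroids)[vapply(
    profile$centroids, function(cen) {
      any(vapply(member_region, function(m)
        global_identity(cen, m)$identity >= idf$cluster_threshold,
        logical(1)))
    }, logical(1))]
  disp <- displacement_summary(rel_tab, syncom_otus, groups, sample_hab,
                               alpha = cz$alpha)
  d <- bray_curtis(rel_tab)
  ord <- pcoa_ordination(d)
  anosim_by_hab <- lapply(unique(sample_hab), function(h) {
    sel <- sample_hab == h
    anosim_test(d[sel, sel], groups[sel], n_perm = cz$n_perm,
                seed = derive_seed(seed, paste0("anosim_", h)))
  })
  names(anosim_by_hab) <- unique(sample_hab)
  kw <- per_otu_kw(rel_tab, groups, alpha = cz$alpha)
  weights <- simulate_plant_weights(n_per_group = cz$n_replicates,
                                    seed = derive_seed(seed, "weights"))
  growth <- growth_response(weights)
  colonize <- list(table = profile$table, qc = profile$qc,
                   metadata = inoc$metadata, displacement = disp,
                   pcoa = ord, anosim = anosim_by_hab, kw = kw,
                   growth = growth, syncom_taxa = member_taxa,
                   syncom_otus = syncom_otus, truth_counts = inoc$table)
  if (!is.null(outdir)) {
    write_otu_table(profile$table, file.path(outdir, "maize_counts.tsv"))
    write_sample_metadata(inoc$metadata,
                          file.path(outdir, "maize_metadata.tsv"))
    write.table(disp$summary, file.path(outdir, "displacement.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_wells_identified = analytics$composition$n_wells_identified,
    fraction_single = analytics$composition$fraction_single,
    n_unique_cotus = length(coll$cotus),
    recovery = vapply(recovery, `[[`, numeric(1),
                      "recovered_core_abundance"),
    syncom_size = length(design$members),
    displacement = disp$summary,
    anosim_R = vapply(anosim_by_hab, `[[`, numeric(1), "statistic"),
    growth_fold = growth$fold_change)
  emit(function(p) write_stage_yaml(list(
    n_wells_identified = summary$n_wells_identified,
    fraction_single = summary$fraction_single,
    n_unique_cotus = summary$n_unique_cotus,
    recovery = as.list(round(summary$recovery, 2)),
    syncom_size = summary$syncom_size,
    anosim_R = as.list(round(summary$anosim_R, 3)),
    growth_fold = summary$growth_fold, seed = seed), p), "summary.yaml")

  structure(list(truth = truth, identify = identify, crossref = crossref,
                 analytics = analytics, design = design,
                 colonize = colonize, summary = summary),
            class = "cbc_run")
}

#' @export
print.cbc_run <- function(x, ...) {
  s <- x$summary
  cat("CBC pipeline run\n")
  cat(sprintf("  wells identified: %d (%.1f%% single-wOTU)\n",
              s$n_wells_identified, s$fraction_single))
  cat(sprintf("  unique cOTUs: %d\n", s$n_unique_cotus))
  cat(sprintf("  core recovery: %s\n",
              paste(sprintf("%s %.1f%%", names(s$recovery), s$recovery),
                    collapse = ", ")))
  cat(sprintf("  SynCom: %d members, growth fold %.1f\n",
              s$syncom_size, s$growth_fold))
  invisible(x)
}
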