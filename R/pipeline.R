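#' Build the per-culture metric panel
#'
#' Computes, for every culture sample, the evaluation metrics that feed the
#' comprehensive rank: family-level Jensen-Shannon divergence from the
#' matched donor's feces, ASV-level Euclidean distance from the feces,
#' ASV-level Shannon and Gini-Simpson diversity, and — when the corresponding
#' assay tables are supplied — pathway-level functional JSD, the qPCR gene
#' variation score and ΔOD600.
#'
#' @param table ASV-level [feature_table()] holding cultures and one feces
#'   sample per donor.
#' @param tax a [taxonomy()].
#' @param meta a [sample_metadata()] (roles feces/culture).
#' @param pathway optional pathway-abundance [feature_table()] (samples x
#'   pathway categories).
#' @param od optional OD table (sample_id, time_h, od_culture,
#'   od_supernatant).
#' @param ct optional qPCR table (sample_id, gene, ct) with a `"16S"` row
#'   per sample.
#' @return data.frame, one row per culture: sample_id, donor, medium,
#'   time_h, replicate + one column per available metric.
#' @export
build_metric_panel <- function(table, tax, meta, pathway = NULL, od = NULL,
                               ct = NULL) {
  al <- align(table, meta)
  table <- al$table; meta <- al$meta
  fam <- to_relative(aggregate_taxa(table, tax, "family"))
  asv <- to_relative(table)
  feces_of <- stats::setNames(meta$sample_id[meta$role == "feces"],
                              meta$donor[meta$role == "feces"])
  if (any(duplicated(names(feces_of))))
    stop("more than one feces sample for donor(s): ",
         paste(unique(names(feces_of)[duplicated(names(feces_of))]),
               collapse = ", "))
  cult <- meta[meta$role == "culture", , drop = FALSE]
  if (nrow(cult) == 0L) stop("no culture samples in metadata")
  no_feces <- setdiff(cult$donor, names(feces_of))
  if (length(no_feces) > 0L)
    stop("no feces reference for donor(s): ", paste(no_feces, collapse = ", "))

  panel <- data.frame(sample_id = cult$sample_id, donor = cult$donor,
                      medium = cult$medium, time_h = cult$time_h,
                      replicate = cult$replicate, stringsAsFactors = FALSE)
  panel$d_js_family <- vapply(seq_len(nrow(cult)), function(i)
    jsd(fam[cult$sample_id[i], ], fam[feces_of[[cult$donor[i]]], ]),
    numeric(1L))
  panel$euclidean_asv <- vapply(seq_len(nrow(cult)), function(i)
    euclidean(asv[cult$sample_id[i], ], asv[feces_of[[cult$donor[i]]], ]),
    numeric(1L))
  panel$shannon_asv <- unname(shannon(asv[cult$sample_id, , drop = FALSE]))
  panel$simpson_asv <- unname(simpson(asv[cult$sample_id, , drop = FALSE]))

  if (!is.null(pathway)) {
    pw <- unclass(pathway)
    panel$d_js_pathway <- vapply(seq_len(nrow(cult)), function(i) {
      sid <- cult$sample_id[i]; fid <- feces_of[[cult$donor[i]]]
      if (!sid %in% rownames(pw) || !fid %in% rownames(pw)) return(NA_real_)
      functional_jsd(pw[sid, ], pw[fid, ])
    }, numeric(1L))
  }
  if (!is.null(od)) {
    panel$delta_od600 <- od$delta_od[match(panel$sample_id, od$sample_id)]
  }
  if (!is.null(ct)) {
    panel$gene_variation <- vapply(seq_len(nrow(cult)), function(i)
      gene_variation_from_ct(ct, cult$sample_id[i], feces_of[[cult$donor[i]]]),
      numeric(1L))
  }
  panel
}

# qPCR gene variation of one culture vs its feces: per-gene fold changes of
# 2^(CT16S - CTgene), averaged as mean |log2 FC|
gene_variation_from_ct <- function(ct, culture_id, feces_id) {
  one <- function(sid) {
    x <- ct[ct$sample_id == sid, , drop = FALSE]
    ref <- x$ct[x$gene == "16S"]
    if (length(ref) != 1L) return(NULL)
    genes <- x[x$gene != "16S", , drop = FALSE]
    stats::setNames(2^(ref - genes$ct), genes$gene)
  }
  ra_c <- one(culture_id); ra_f <- one(feces_id)
  if (is.null(ra_c) || is.null(ra_f)) return(NA_real_)
  shared <- intersect(names(ra_c), names(ra_f))
  if (length(shared) == 0L) return(NA_real_)
  gene_variation_score(fold_change_log2(ra_c[shared], ra_f[shared]))
}

default_run_config <- function() {
  list(simulation = NULL, inputs = NULL,
       factors = NULL,
       preset = "fig5", direction_map = NULL,
       rank_blocks = "donor",
       aggregation_rank = "family",
       jsd_level = "family", euclidean_level = "asv",
       n_perm = 999, seed = NULL, out_dir = NULL,
       enterotype_per_donor = TRUE, enterotype_k_range = 2:6)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$factors) || length(cfg$factors) == 0L)
    stop("config must give the PERMANOVA factor order ('factors')")
  if (is.null(cfg$seed)) stop("config must give a seed")
  has_sim <- !is.null(cfg$simulation)
  has_in <- !is.null(cfg$inputs)
  if (has_sim == has_in)
    stop("config must give exactly one of 'simulation' or 'inputs'")
  if (is.null(cfg$out_dir)) stop("config must give 'out_dir'")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Run the full culture-evaluation pipeline
#'
#' Orchestrates: input loading (or simulation), sample alignment, the metric
#' panel, Bray-Curtis PERMANOVA over the culture samples, per-donor (or
#' pooled) enterotyping at genus level, and the comprehensive rank. All
#' stage outputs are written as TSV together with a machine-readable JSON
#' manifest (config with every default echoed, seed, md5 of each artifact),
#' so a rerun with the same config and seed is byte-identical.
#'
#' @param config named list or path to a YAML file. Required: `factors`
#'   (PERMANOVA factor order), `seed`, `out_dir` and exactly one of
#'   `simulation` (arguments for [community_sim_spec()]) or `inputs` (paths
#'   `feature_table`, `taxonomy`, `metadata`, optional `pathway`, `od`,
#'   `ct`). Optional: `preset` ("fig5", "fig1c" or "custom"),
#'   `direction_map` (for "custom"), `rank_blocks` ("donor" or "all"),
#'   `n_perm`, `enterotype_per_donor`, `enterotype_k_range`.
#' @return the output directory, invisibly; artifacts: `panel.tsv`,
#'   `permanova.tsv`, `enterotype.tsv`, `ranks.tsv`, `media_summary.tsv`,
#'   `manifest.json`.
#' @export
run_evaluation <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- simulate_experiment(do.call(community_sim_spec, sim_args))
    table <- sim$table; tax <- sim$taxonomy; meta <- sim$metadata
    pathway <- od <- ct <- NULL
  } else {
    table <- read_feature_table(cfg$inputs$feature_table)
    tax <- read_taxonomy(cfg$inputs$taxonomy)
    meta <- read_metadata(cfg$inputs$metadata)
    pathway <- if (!is.null(cfg$inputs$pathway))
      read_feature_table(cfg$inputs$pathway) else NULL
    od <- if (!is.null(cfg$inputs$od)) read_od_table(cfg$inputs$od) else NULL
    ct <- if (!is.null(cfg$inputs$ct)) read_ct_table(cfg$inputs$ct) else NULL
  }
  al <- align(table, meta)
  table <- al$table; meta <- al$meta

  panel <- build_metric_panel(table, tax, meta, pathway = pathway,
                              od = od, ct = ct)

  cult_ids <- meta$sample_id[meta$role == "culture"]
  rel <- to_relative(unclass(table)[cult_ids, , drop = FALSE])
  d <- distance_matrix(rel, metric = "braycurtis")
  pmv <- permanova(d, meta, cfg$factors, n_perm = cfg$n_perm, seed = cfg$seed)

  genus_tab <- aggregate_taxa(table, tax, "genus")
  ent_rows <- if (isTRUE(cfg$enterotype_per_donor)) {
    do.call(rbind, lapply(split(meta$sample_id, meta$donor), function(ids) {
      et <- enterotype(feature_table(unclass(genus_tab)[ids, , drop = FALSE]),
                       k_range = cfg$enterotype_k_range, seed = cfg$seed)
      as.data.frame(et)
    }))
  } else {
    as.data.frame(enterotype(genus_tab, k_range = cfg$enterotype_k_range,
                             seed = cfg$seed))
  }
  rownames(ent_rows) <- NULL

  dmap <- switch(cfg$preset,
                 fig1c = fig1c_directions(),
                 fig5 = fig5_directions(),
                 custom = unlist(cfg$direction_map),
                 stop("unknown preset '", cfg$preset, "'"))
  dmap <- dmap[names(dmap) %in% names(panel)]
  if (length(dmap) == 0L) stop("no panel metric matches the direction map")
  blocks <- if (identical(cfg$rank_blocks, "donor")) panel$donor else NULL
  ranks <- comprehensive_rank(panel, dmap, blocks = blocks)
  media <- summarize_media(ranks)

  pm_out <- data.frame(Factor = rownames(pmv), as.data.frame(pmv),
                       check.names = FALSE)
  files <- c(panel = write_tsv(panel, file.path(cfg$out_dir, "panel.tsv")),
             permanova = write_tsv(pm_out, file.path(cfg$out_dir, "permanova.tsv")),
             enterotype = write_tsv(ent_rows, file.path(cfg$out_dir, "enterotype.tsv")),
             ranks = write_tsv(as.data.frame(ranks),
                               file.path(cfg$out_dir, "ranks.tsv")),
             media_summary = write_tsv(media$summary,
                                       file.path(cfg$out_dir, "media_summary.tsv")))
  write_manifest(cfg, files)
  message("evaluation artifacts written to ", cfg$out_dir,
          "; best medium: ", paste(media$best, collapse = ", "))
  invisible(cfg$out_dir)
}

write_manifest <- function(cfg, files) {
  manifest <- list(config = cfg[order(names(cfg))],
                   artifacts = lapply(stats::setNames(as.list(files), names(files)),
                                      function(p) list(file = basename(p),
                                                       md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(NULL)
}

#' Run the drug-metabolism track
#'
#' Either simulates an LC-MS assay ([simulate_drug_assay()]) or reads
#' calibration and measurement TSVs, quantifies every peak-area ratio via
#' its analyte's calibration curve, and writes concentrations, per-donor
#' remaining fractions and inter-donor summaries.
#'
#' @param config named list or YAML path. Required: `seed`, `out_dir` and
#'   exactly one of `drug_simulation` (arguments for [drug_sim_spec()]) or
#'   `inputs` (paths `calibration`, `measurements`). Optional: `reference`
#'   ("control" or "nominal"), `nominal_uM`.
#' @return the output directory, invisibly; artifacts:
#'   `concentrations.tsv`, `remaining.tsv`, `interdonor.tsv`,
#'   `manifest.json`.
#' @export
run_drug_track <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(drug_simulation = NULL, inputs = NULL,
                                reference = "control", nominal_uM = 500,
                                seed = NULL, out_dir = NULL), config)
  if (is.null(cfg$seed)) stop("config must give a seed")
  if (is.null(cfg$out_dir)) stop("config must give 'out_dir'")
  has_sim <- !is.null(cfg$drug_simulation)
  if (has_sim == !is.null(cfg$inputs))
    stop("config must give exactly one of 'drug_simulation' or 'inputs'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (has_sim) {
    sim_args <- cfg$drug_simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- simulate_drug_assay(do.call(drug_sim_spec, sim_args))
    meas <- sim$measurements
    spec <- sim$truth$spec
    curves <- lapply(names(spec$calibration), function(a)
      calibration_curve(spec$calibration[[a]][["slope"]],
                        spec$calibration[[a]][["intercept"]], analyte = a))
    names(curves) <- names(spec$calibration)
  } else {
    curves <- read_calibration(cfg$inputs$calibration)
    meas <- read_measurements(cfg$inputs$measurements)
  }
  q <- quantify_assay(meas, curves, reference = cfg$reference,
                      nominal_uM = cfg$nominal_uM)
  inter <- do.call(rbind, lapply(names(q$interdonor), function(dr) {
    v <- q$interdonor[[dr]]
    data.frame(drug = dr, time_h = q$t_final, mean_remaining = v$mean,
               sd = v$sd, cv = v$cv, n_donors = v$n, stringsAsFactors = FALSE)
  }))
  files <- c(concentrations = write_tsv(q$concentrations,
                                        file.path(cfg$out_dir, "concentrations.tsv")),
             remaining = write_tsv(q$remaining,
                                   file.path(cfg$out_dir, "remaining.tsv")),
             interdonor = write_tsv(inter,
                                    file.path(cfg$out_dir, "interdonor.tsv")))
  write_manifest(cfg, files)
  invisible(cfg$out_dir)
}
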