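#' Specification of a synthetic culture experiment
#'
#' Collects the design (donors x media x time points x replicates) and the
#' generative parameters of the community simulator. Effects are additive on
#' log abundance (multiplicative on abundance); by default donor effects
#' dominate medium effects, which dominate time effects — the structure the
#' culture-fidelity analysis assumes. Replicates differ only through
#' Dirichlet-multinomial sampling noise.
#'
#' @param n_donors,n_media,n_replicates design sizes.
#' @param time_points_h culture harvest times (hours).
#' @param n_taxa,n_families number of ASVs and the families they are evenly
#'   partitioned into (medium and time effects are drawn per family).
#' @param donor_effect_sd,medium_effect_sd,time_effect_sd SDs of the
#'   Gaussian log-scale effects.
#' @param dirichlet_concentration concentration of the Dirichlet around each
#'   sample's expected profile (`Inf` = no compositional overdispersion).
#' @param depth sequencing reads per sample.
#' @param seed RNG seed.
#' @return list of class `"community_sim_spec"`.
#' @export
community_sim_spec <- function(n_donors = 3, n_media = 7,
                               time_points_h = c(6, 24), n_replicates = 2,
                               n_taxa = 150, n_families = 15,
                               donor_effect_sd = 1.5, medium_effect_sd = 1.0,
                               time_effect_sd = 0.3,
                               dirichlet_concentration = 200,
                               depth = 10000, seed = 1) {
  stopifnot(n_donors >= 1, n_media >= 1, n_replicates >= 1,
            length(time_points_h) >= 1, n_taxa >= 2, n_families >= 1,
            donor_effect_sd >= 0, medium_effect_sd >= 0, time_effect_sd >= 0,
            depth >= 1)
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be positive")
  structure(as.list(environment()), class = "community_sim_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a culture experiment
#'
#' For each donor a baseline log-abundance profile is drawn around a shared
#' community backbone; Gaussian medium and time effects, shared by all taxa
#' of a family within a factor level, shift the cultures; each sample's
#' proportions come from a Dirichlet centred on the exponentiated profile and
#' its counts from a multinomial at the requested depth. One feces sample per
#' donor carries the donor baseline only.
#'
#' @param spec a [community_sim_spec()].
#' @return list with `table` (a [feature_table()], cultures + feces),
#'   `taxonomy`, `metadata` (a [sample_metadata()]) and `truth` (expected
#'   proportions per sample and the effect draws, for recovery tests).
#' @export
simulate_experiment <- function(spec = community_sim_spec()) {
  stopifnot(inherits(spec, "community_sim_spec"))
  if (spec$depth < spec$n_taxa)
    warning("depth below the number of taxa; many taxa will be unobserved")
  set.seed(spec$seed)
  nt <- spec$n_taxa
  taxa <- sprintf("ASV%03d", seq_len(nt))
  fam_of <- sprintf("Family%02d", ((seq_len(nt) - 1L) %% spec$n_families) + 1L)
  genus_of <- sprintf("Genus%03d", ((seq_len(nt) - 1L) %% (spec$n_families * 3L)) + 1L)
  tax <- taxonomy(data.frame(
    taxon_id = taxa, kingdom = "Bacteria",
    phylum = sprintf("Phylum%d", ((seq_len(nt) - 1L) %% 5L) + 1L),
    class = NA, order = NA, family = fam_of, genus = genus_of,
    stringsAsFactors = FALSE))

  donors <- sprintf("D%d", seq_len(spec$n_donors))
  media <- sprintf("M%d", seq_len(spec$n_media))
  times <- sort(spec$time_points_h)
  reps <- sprintf("R%d", seq_len(spec$n_replicates))

  base <- stats::rnorm(nt, 0, 1.5)                 # shared community backbone
  donor_eff <- matrix(stats::rnorm(spec$n_donors * nt, 0, spec$donor_effect_sd),
                      spec$n_donors, nt, dimnames = list(donors, taxa))
  fam_levels <- unique(fam_of)
  med_fam <- matrix(stats::rnorm(spec$n_media * length(fam_levels), 0,
                                 spec$medium_effect_sd),
                    spec$n_media, length(fam_levels),
                    dimnames = list(media, fam_levels))
  time_fam <- matrix(stats::rnorm(length(times) * length(fam_levels), 0,
                                  spec$time_effect_sd),
                     length(times), length(fam_levels),
                     dimnames = list(as.character(times), fam_levels))

  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
  draw_sample <- function(expected) {
    p <- if (is.finite(spec$dirichlet_concentration))
      rdirichlet1(spec$dirichlet_concentration * expected) else expected
    as.numeric(stats::rmultinom(1L, size = spec$depth, prob = p))
  }

  rows <- list(); meta_rows <- list(); expected_list <- list()
  for (d in donors) {
    p_feces <- softmax(base + donor_eff[d, ])
    sid <- paste0(d, "_feces")
    rows[[sid]] <- draw_sample(p_feces)
    expected_list[[sid]] <- p_feces
    meta_rows[[sid]] <- data.frame(sample_id = sid, donor = d, medium = NA,
                                   time_h = 0, replicate = "R1", role = "feces",
                                   stringsAsFactors = FALSE)
    for (m in media) {
      for (t in times) {
        eta <- base + donor_eff[d, ] + med_fam[m, fam_of] +
          time_fam[as.character(t), fam_of]
        p <- softmax(eta)
        for (r in reps) {
          sid <- paste(d, m, paste0("T", t), r, sep = "_")
          rows[[sid]] <- draw_sample(p)
          expected_list[[sid]] <- p
          meta_rows[[sid]] <- data.frame(sample_id = sid, donor = d,
                                         medium = m, time_h = t,
                                         replicate = r, role = "culture",
                                         stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- taxa
  meta <- sample_metadata(do.call(rbind, meta_rows))
  list(table = feature_table(counts),
       taxonomy = tax,
       metadata = meta,
       truth = list(expected = do.call(rbind, expected_list),
                    base = base, donor_effect = donor_eff,
                    medium_effect_by_family = med_fam,
                    time_effect_by_family = time_fam,
                    spec = spec))
}

#' Simulate an OD600 growth curve
#'
#' Logistic growth \eqn{OD(t) = K / (1 + e^{-r (t - lag)})} for the whole
#' culture, a small constant background for the centrifuged supernatant,
#' both with additive Gaussian noise.
#'
#' @param K carrying capacity (asymptotic OD600), > 0.
#' @param r growth rate per hour, >= 0 (0 gives a flat curve).
#' @param lag inflection time (hours).
#' @param times sampling times (hours), canonically `c(6, 12, 24, 48)`.
#' @param noise_sd additive Gaussian noise SD.
#' @param supernatant_od constant supernatant background.
#' @param seed RNG seed.
#' @return data.frame with columns time_h, od_culture, od_supernatant.
#' @export
simulate_growth <- function(K, r, lag = 6, times = c(6, 12, 24, 48),
                            noise_sd = 0.02, supernatant_od = 0.05, seed = 1) {
  stopifnot(K > 0, r >= 0)
  set.seed(seed)
  od <- K / (1 + exp(-r * (times - lag)))
  data.frame(time_h = times,
             od_culture = pmax(od + stats::rnorm(length(times), 0, noise_sd), 0),
             od_supernatant = pmax(supernatant_od +
                                     stats::rnorm(length(times), 0, noise_sd), 0))
}

#' Specification of a synthetic drug-metabolism assay
#'
#' @param drug drug name (the parent analyte carries this name).
#' @param initial_conc_uM dosed concentration (default 500 µM).
#' @param decay_rate_per_h first-order microbial decay rate, one value per
#'   donor (named or unnamed vector).
#' @param metabolite_yield fraction of degraded parent converted to the
#'   tracked metabolite, in `[0, 1]`.
#' @param control_decay_rate_per_h abiotic decay rate of the no-microbiome
#'   control.
#' @param metabolite name of the metabolite analyte.
#' @param calibration named list: for each of `drug` and `metabolite`, a
#'   `c(slope =, intercept =)` pair of the calibration line.
#' @param noise_cv lognormal coefficient of variation of the peak areas.
#' @param time_points_h sampling times (hours).
#' @param seed RNG seed.
#' @return list of class `"drug_sim_spec"`.
#' @export
drug_sim_spec <- function(drug = "levodopa", initial_conc_uM = 500,
                          decay_rate_per_h = rep(0.03, 10),
                          metabolite_yield = 0.8,
                          control_decay_rate_per_h = 0.001,
                          metabolite = "metabolite",
                          calibration = list(),
                          noise_cv = 0.05,
                          time_points_h = c(6, 12, 24), seed = 1) {
  stopifnot(initial_conc_uM > 0, all(decay_rate_per_h >= 0),
            metabolite_yield >= 0, metabolite_yield <= 1,
            control_decay_rate_per_h >= 0, noise_cv >= 0)
  if (length(calibration) == 0L)
    calibration <- stats::setNames(
      list(c(slope = 1, intercept = 0), c(slope = 1, intercept = 0)),
      c(drug, metabolite))
  if (!all(c(drug, metabolite) %in% names(calibration)))
    stop("calibration must cover both the drug and the metabolite analyte")
  structure(as.list(environment()), class = "drug_sim_spec")
}

#' Simulate an LC-MS drug-metabolism assay
#'
#' First-order kinetics per donor: parent
#' \eqn{C(t) = C_0 e^{-k_d t}}, metabolite
#' \eqn{M(t) = yield (C_0 - C(t))}; the no-microbiome control decays at its
#' own (abiotic) rate. Concentrations are mapped to peak-area ratios through
#' each analyte's calibration line and multiplied by lognormal noise of the
#' stated CV (mean 1). Negative computed areas are clipped to 0 with a
#' warning.
#'
#' @param spec a [drug_sim_spec()].
#' @return list with `measurements` (donor, drug, analyte, time_h, condition,
#'   area_ratio) and `truth` (the noiseless concentrations).
#' @export
simulate_drug_assay <- function(spec = drug_sim_spec()) {
  stopifnot(inherits(spec, "drug_sim_spec"))
  set.seed(spec$seed)
  donors <- names(spec$decay_rate_per_h)
  if (is.null(donors)) donors <- sprintf("D%d", seq_along(spec$decay_rate_per_h))
  times <- sort(spec$time_points_h)
  sdlog <- sqrt(log1p(spec$noise_cv^2))
  noisy <- function(x) {
    if (spec$noise_cv == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  to_area <- function(conc, analyte) {
    cal <- spec$calibration[[analyte]]
    a <- noisy(cal[["slope"]] * conc + cal[["intercept"]])
    neg <- a < 0
    if (any(neg)) {
      warning(sum(neg), " negative computed peak area(s) clipped to 0")
      a[neg] <- 0
    }
    a
  }
  rows <- list(); truth_rows <- list()
  for (i in seq_along(donors)) {
    kd <- spec$decay_rate_per_h[i]
    parent <- spec$initial_conc_uM * exp(-kd * times)
    metab <- spec$metabolite_yield * (spec$initial_conc_uM - parent)
    rows[[length(rows) + 1L]] <- data.frame(
      donor = donors[i], drug = spec$drug,
      analyte = rep(c(spec$drug, spec$metabolite), each = length(times)),
      time_h = rep(times, 2L), condition = "culture",
      area_ratio = c(to_area(parent, spec$drug),
                     to_area(metab, spec$metabolite)),
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      donor = donors[i], drug = spec$drug, time_h = times,
      parent_uM = parent, metabolite_uM = metab, stringsAsFactors = FALSE)
  }
  ctrl <- spec$initial_conc_uM * exp(-spec$control_decay_rate_per_h * times)
  rows[[length(rows) + 1L]] <- data.frame(
    donor = "none", drug = spec$drug, analyte = spec$drug,
    time_h = times, condition = "control",
    area_ratio = to_area(ctrl, spec$drug), stringsAsFactors = FALSE)
  list(measurements = do.call(rbind, rows),
       truth = list(culture = do.call(rbind, truth_rows),
                    control = data.frame(time_h = times, parent_uM = ctrl),
                    spec = spec))
}

#' Simulate qPCR cycle thresholds from relative abundances
#'
#' Inverse of the qPCR quantification \eqn{RA = 2^{CT_{16S} - CT_{target}}}:
#' \eqn{CT_{target} = CT_{16S} - \log_2 RA + \epsilon}.
#'
#' @param ra target relative abundances in `(0, 1]`.
#' @param ct_16s 16S cycle threshold(s), recycled.
#' @param noise_sd Gaussian CT noise SD.
#' @param seed RNG seed.
#' @return CT values for the target gene.
#' @export
simulate_qpcr <- function(ra, ct_16s = 20, noise_sd = 0, seed = 1) {
  if (any(ra <= 0 | ra > 1)) stop("relative abundances must lie in (0, 1]")
  set.seed(seed)
  ct_16s - log2(ra) + stats::rnorm(length(ra), 0, noise_sd)
}
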