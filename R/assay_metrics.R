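#' Biomass growth from optical density
#'
#' ΔOD600 = whole-culture OD600 minus the OD600 of its centrifuged
#' supernatant, a proxy for bacterial biomass. Negative values (measurement
#' noise) are preserved but reported, so the ranking sees the raw data.
#'
#' @param od_culture,od_supernatant absorbance readings (>= 0).
#' @return ΔOD600, vectorised.
#' @export
delta_od <- function(od_culture, od_supernatant) {
  if (any(od_culture < 0) || any(od_supernatant < 0))
    stop("absorbances must be non-negative")
  out <- od_culture - od_supernatant
  if (any(out < 0))
    message(sum(out < 0), " negative deltaOD600 value(s) kept (noise)")
  out
}

#' qPCR relative abundance of a target gene
#'
#' \eqn{2^{CT_{16S} - CT_{target}}}: the abundance of a functional gene
#' relative to total bacterial 16S in the same sample.
#'
#' @param ct_16s,ct_target cycle-threshold values (40-cycle protocol).
#' @param censor_cycles no-amplification targets censored at this cycle; the
#'   returned value is the upper bound \eqn{2^{CT_{16S} - censor}} flagged by
#'   the `"censored"` attribute.
#' @return positive relative abundance, vectorised; `"censored"` attribute
#'   marks upper-bound values.
#' @export
relative_abundance <- function(ct_16s, ct_target, censor_cycles = 40) {
  if (any(ct_16s <= 0 | ct_16s > censor_cycles, na.rm = TRUE))
    stop("16S CT outside (0, ", censor_cycles, "]")
  censored <- is.na(ct_target)
  ct_target[censored] <- censor_cycles
  if (any(ct_target <= 0 | ct_target > censor_cycles))
    stop("target CT outside (0, ", censor_cycles, "]")
  out <- 2^(ct_16s - ct_target)
  if (any(censored))
    message(sum(censored), " target(s) did not amplify; upper bound at cycle ",
            censor_cycles, " reported")
  attr(out, "censored") <- censored
  out
}

#' Log2 fold change of a gene's relative abundance, culture vs feces
#'
#' \eqn{\log_2(RA_{culture} / RA_{feces})}. Undefined when the feces
#' abundance is zero or missing; reported as `NA`, never as infinity.
#'
#' @param ra_culture,ra_feces relative abundances from [relative_abundance()].
#' @return log2 fold change, vectorised; `NA` where undefined.
#' @export
fold_change_log2 <- function(ra_culture, ra_feces) {
  out <- rep(NA_real_, length(ra_culture))
  ok <- !is.na(ra_culture) & !is.na(ra_feces) & ra_culture > 0 & ra_feces > 0
  out[ok] <- log2(ra_culture[ok] / ra_feces[ok])
  if (any(!ok))
    message(sum(!ok), " fold change(s) undefined (zero or missing abundance)")
  out
}

#' Functional-gene variation score of a culture
#'
#' Mean absolute log2 fold change across the assayed genes (e.g. baiJ, bsh,
#' bcoA): 0 when every gene kept its fecal abundance, larger the further the
#' culture's functional profile drifted. Ranked ascending in the composite
#' score (lower = closer to feces). Undefined (censored/missing) fold changes
#' are excluded with a log entry.
#'
#' @param fold_changes numeric vector of per-gene log2 fold changes.
#' @return non-negative score.
#' @export
gene_variation_score <- function(fold_changes) {
  if (length(fold_changes) == 0L) stop("need at least one gene")
  miss <- is.na(fold_changes)
  if (all(miss)) stop("all fold changes missing")
  if (any(miss))
    message(sum(miss), " missing fold change(s) excluded from the variation score")
  mean(abs(fold_changes[miss == FALSE]))
}

#' Functional divergence of a culture at pathway level
#'
#' Jensen-Shannon divergence (base 2) between the culture's and the matched
#' feces' pathway-abundance rows, each normalised to a probability profile.
#' Delegates to [jsd()].
#'
#' @param culture,feces non-negative pathway-abundance vectors over the same
#'   pathway categories.
#' @return number in `[0, 1]`.
#' @export
functional_jsd <- function(culture, feces) {
  jsd(culture / sum(culture), feces / sum(feces))
}

#' Read an OD600 measurement table
#'
#' @param path TSV with columns sample_id, time_h, od_culture, od_supernatant.
#' @return validated data.frame with a delta_od column appended.
#' @export
read_od_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "od_culture", "od_supernatant")
  if (!all(need %in% names(df)))
    stop("OD table needs columns: ", paste(need, collapse = ", "))
  df$delta_od <- delta_od(df$od_culture, df$od_supernatant)
  df
}

#' Read a qPCR CT table
#'
#' @param path TSV with columns sample_id, gene, ct.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("CT table needs columns: ", paste(need, collapse = ", "))
  if (any(df$ct <= 0 | df$ct > 40, na.rm = TRUE))
    stop("CT values outside (0, 40]")
  df
}
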