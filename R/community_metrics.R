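#' Convert counts to relative abundances
#'
#' Total-sum scaling: each sample row is divided by its total so it becomes a
#' probability profile. No rarefaction is performed; all downstream metrics
#' operate on proportions.
#'
#' @param table a [feature_table()] (samples x taxa).
#' @return matrix of per-sample proportions, rows summing to 1.
#' @export
to_relative <- function(table) {
  m <- unclass(table)
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  sweep(m, 1L, tot, "/")
}

#' Aggregate a feature table to a higher taxonomic rank
#'
#' Counts of taxa sharing the same label at `rank` are summed; taxa with a
#' missing rank go into the `"unclassified_<rank>"` bucket, so per-sample
#' totals are conserved exactly.
#'
#' @param table a [feature_table()] at ASV (or finer) level.
#' @param tax a [taxonomy()] covering the table's taxa.
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @return a [feature_table()] whose columns are the rank labels.
#' @export
aggregate_taxa <- function(table, tax, rank = "family") {
  if (!rank %in% ranks_ordered)
    stop("unsupported rank '", rank, "'; use one of: ",
         paste(ranks_ordered, collapse = ", "))
  m <- unclass(table)
  lab <- tax[[rank]][match(colnames(m), tax$taxon_id)]
  lab[is.na(lab)] <- paste0("unclassified_", rank)
  agg <- t(rowsum(t(m), group = lab))
  feature_table(agg[, order(colnames(agg)), drop = FALSE])
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} with the convention \eqn{0 \log 0 = 0}.
#' In base 2 (the default) the unit is bits; a uniform profile over n taxa
#' scores \eqn{\log_2 n}.
#'
#' @param p numeric proportion vector (or matrix of profiles, rows = samples).
#' @param base logarithm base.
#' @return non-negative number (or one per row).
#' @export
shannon <- function(p, base = 2) {
  if (is.matrix(p)) return(apply(p, 1L, shannon, base = base))
  p <- check_profile(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity index
#'
#' \eqn{1 - \sum_i p_i^2}: the probability that two randomly drawn reads
#' belong to different taxa. Higher means more diverse, so it ranks in the
#' same (descending) direction as Shannon in the composite score.
#'
#' @inheritParams shannon
#' @return number in `[0, 1]` (or one per row).
#' @export
simpson <- function(p) {
  if (is.matrix(p)) return(apply(p, 1L, simpson))
  p <- check_profile(p)
  1 - sum(p^2)
}

check_profile <- function(p, tol = 1e-9) {
  if (any(p < 0)) stop("profile has negative entries")
  s <- sum(p)
  if (abs(s - 1) > tol) {
    if (s <= 0) stop("profile sums to zero")
    p <- p / s
  }
  p
}

#' Jensen-Shannon divergence between two profiles
#'
#' \eqn{D_{JS}(P, Q) = \frac12 KL(P \| M) + \frac12 KL(Q \| M)} with
#' \eqn{M = \frac12 (P + Q)}, logarithms in base 2 so the value lies in
#' `[0, 1]`; zero-probability terms contribute 0. This is the divergence
#' itself, not its square root. Used to measure how far a culture's
#' composition has moved from the donor's feces.
#'
#' @param p,q proportion vectors over the same taxon universe (zero-filled
#'   where a taxon is absent).
#' @param base logarithm base (2 gives the `[0, 1]` range).
#' @return number in `[0, 1]` for base 2.
#' @export
jsd <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q))
  p <- check_profile(p); q <- check_profile(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i], base = base))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Euclidean distance between two relative-abundance profiles
#'
#' \eqn{\sqrt{\sum_i (p_i - q_i)^2}} on proportions (not counts), matching
#' its use alongside ASV-level composition.
#'
#' @inheritParams jsd
#' @return non-negative number.
#' @export
euclidean <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(sum((check_profile(p) - check_profile(q))^2))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' \eqn{BC = \sum_i |p_i - q_i| / \sum_i (p_i + q_i)}; 0 for identical
#' profiles, 1 for disjoint supports. The substrate of the PERMANOVA factor
#' partitioning.
#'
#' @inheritParams jsd
#' @return number in `[0, 1]`.
#' @export
braycurtis <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- check_profile(p); q <- check_profile(q)
  sum(abs(p - q)) / sum(p + q)
}

#' Pairwise distance matrix over sample profiles
#'
#' @param profiles matrix of per-sample proportions (rows = samples), e.g.
#'   from [to_relative()].
#' @param metric `"jsd"`, `"euclidean"` or `"braycurtis"`.
#' @return symmetric matrix with zero diagonal, `metric` attached as the
#'   `"metric"` attribute.
#' @export
distance_matrix <- function(profiles, metric = c("braycurtis", "jsd", "euclidean")) {
  metric <- match.arg(metric)
  f <- switch(metric, jsd = jsd, euclidean = euclidean, braycurtis = braycurtis)
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- f(profiles[i, ], profiles[j, ])
      }
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Divergence of each culture from its source feces profile
#'
#' One value per culture sample: the chosen dissimilarity between the
#' culture's profile and the matched donor's feces profile at the same
#' taxonomic level (canonically Jensen-Shannon at family level, Euclidean at
#' ASV level).
#'
#' @param cultures matrix of culture profiles (rows = samples).
#' @param source single feces profile (numeric vector over the same taxa).
#' @param metric `"jsd"`, `"euclidean"` or `"braycurtis"`.
#' @param culture_donor,source_donor optional donor labels; if both given
#'   they must all match.
#' @return named numeric vector, one value per culture.
#' @export
divergence_from_source <- function(cultures, source,
                                   metric = c("jsd", "euclidean", "braycurtis"),
                                   culture_donor = NULL, source_donor = NULL) {
  metric <- match.arg(metric)
  if (!is.null(culture_donor) && !is.null(source_donor) &&
      !all(culture_donor == source_donor))
    stop("donor mismatch between culture(s) and source feces profile")
  f <- switch(metric, jsd = jsd, euclidean = euclidean, braycurtis = braycurtis)
  apply(cultures, 1L, f, q = source)
}

#' Export metric values as a long-format table
#'
#' @param values named numeric vector (names = sample ids).
#' @param metric metric label.
#' @param level profile level tag (asv, family, pathway, ...).
#' @return data.frame with columns sample_id, metric, level, value.
#' @export
metric_long <- function(values, metric, level) {
  data.frame(sample_id = names(values), metric = metric, level = level,
             value = as.numeric(values), stringsAsFactors = FALSE)
}
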