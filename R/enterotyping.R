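#' Calinski-Harabasz index from a distance matrix
#'
#' Distance-based variance decomposition: within-cluster SS is
#' \eqn{\sum_c \frac{1}{n_c} \sum_{i<j \in c} d_{ij}^2}, the total SS the same
#' sum over all samples, and \eqn{CH = (B/(k-1)) / (W/(n-k))} with
#' \eqn{B = T - W}.
#'
#' @param d symmetric distance matrix.
#' @param clustering integer/character cluster assignment per sample.
#' @return the CH index (larger = better-separated clustering).
#' @export
calinski_harabasz <- function(d, clustering) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  k <- length(unique(clustering))
  if (k < 2L || k >= n) stop("need 2 <= k < n clusters for the CH index")
  ssq <- function(idx) sum(d[idx, idx, drop = FALSE]^2) / (2 * length(idx))
  w <- sum(vapply(split(seq_len(n), clustering), ssq, numeric(1L)))
  tot <- ssq(seq_len(n))
  b <- tot - w
  (b / (k - 1)) / (w / (n - k))
}

#' Enterotype clustering of community profiles
#'
#' The canonical enterotyping recipe: Jensen-Shannon distances between
#' genus-level relative-abundance profiles, partitioning around medoids (PAM)
#' for each candidate k, and the k with the largest Calinski-Harabasz index
#' retained. Each cluster is labelled by the genus with the highest mean
#' relative abundance among its samples, prefixed `"g_"`.
#'
#' Whether any split is real is decided against a permutation null: each
#' taxon column is shuffled independently across samples (destroying sample
#' structure while keeping taxon marginals), PAM + CH is re-run, and if the
#' observed best CH does not exceed the best CH found on any null replicate,
#' the smallest allowed k is returned with a degeneracy warning.
#'
#' @param table a genus-level [feature_table()] (>= 4 samples).
#' @param k_range candidate cluster counts (default 2..6); truncated with a
#'   warning when it exceeds n - 1.
#' @param seed RNG seed (drives the permutation null; PAM itself is
#'   deterministic on a fixed distance matrix).
#' @param distance `"jsd"` (canonical) or another [distance_matrix()] metric.
#' @param null_reps column-shuffle replicates for the degeneracy check.
#' @return object of class `"enterotype_result"`: list with elements `k`,
#'   `assignment` (named integer vector), `label` (cluster -> dominant genus),
#'   `quality` (per-k CH values), `medoids`, `distance`.
#' @export
enterotype <- function(table, k_range = 2:6, seed = 1, distance = "jsd",
                       null_reps = 5) {
  m <- unclass(table)
  if (nrow(m) < 4L) stop("enterotyping needs at least 4 samples")
  rel <- to_relative(m)
  d <- distance_matrix(rel, metric = distance)
  if (max(d) <= 1e-12)
    stop("all samples are identical; PAM clustering is degenerate")
  k_max <- nrow(m) - 1L
  if (max(k_range) > k_max) {
    warning("k_range truncated to 2..", k_max, " (only ", nrow(m), " samples)")
    k_range <- k_range[k_range <= k_max]
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L || min(k_range) < 2L)
    stop("k_range must contain values in 2..(n-1)")
  set.seed(seed)
  best_ch <- function(dd) {
    fits <- lapply(k_range, function(k)
      cluster::pam(stats::as.dist(dd), k = k, diss = TRUE))
    ch <- vapply(seq_along(k_range), function(i)
      calinski_harabasz(dd, fits[[i]]$clustering), numeric(1L))
    list(fits = fits, ch = ch)
  }
  obs <- best_ch(d)
  ch <- stats::setNames(obs$ch, paste0("k", k_range))
  fits <- obs$fits
  best <- which.max(ch)
  null_max <- vapply(seq_len(null_reps), function(r) {
    shuffled <- apply(rel, 2L, sample)
    rownames(shuffled) <- rownames(rel)
    dn <- distance_matrix(shuffled / rowSums(shuffled), metric = distance)
    if (max(dn) <= 1e-12) return(0)
    max(best_ch(dn)$ch)
  }, numeric(1L))
  if (!is.finite(ch[best]) || ch[best] <= max(null_max)) {
    warning("no clustering beats the column-shuffle null; ",
            "returning the smallest allowed k")
    best <- 1L
  }
  fit <- fits[[best]]
  clustering <- fit$clustering
  labels <- cluster_dominant_genus(rel, clustering)
  structure(list(k = k_range[best],
                 assignment = clustering,
                 label = labels,
                 quality = ch,
                 medoids = fit$medoids,
                 distance = d),
            class = "enterotype_result")
}

# label = genus with highest mean relative abundance within the cluster
cluster_dominant_genus <- function(rel, clustering) {
  ks <- sort(unique(clustering))
  labs <- vapply(ks, function(k) {
    mu <- colMeans(rel[clustering == k, , drop = FALSE])
    names(mu)[which.max(mu)]
  }, character(1L))
  stats::setNames(paste0("g_", sub("^g_", "", labs)), ks)
}

#' @export
print.enterotype_result <- function(x, ...) {
  cat("Enterotype clustering (JSD + PAM)\n")
  cat("k =", x$k, "chosen by Calinski-Harabasz:\n")
  print(round(x$quality, 2))
  tab <- table(x$label[as.character(x$assignment)])
  cat("cluster sizes by dominant genus:\n")
  print(tab)
  invisible(x)
}

#' Enterotype assignments as a data.frame
#'
#' @param x an `enterotype_result`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns sample_id, cluster, label.
#' @export
as.data.frame.enterotype_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(sample_id = names(x$assignment),
             cluster = unname(x$assignment),
             label = unname(x$label[as.character(x$assignment)]),
             stringsAsFactors = FALSE)
}
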