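#' Rank a metric's values with an explicit direction
#'
#' Ascending: the smallest value gets rank 1 (divergence/similarity metrics,
#' where lower means closer to feces). Descending: the largest value gets
#' rank 1 (diversity and growth metrics, where higher is better). Ties get
#' the mean of the tied rank positions; missing values get the worst rank
#' (n) with a log entry.
#'
#' @param values numeric vector (length n, possibly with NA).
#' @param direction `"ascending"` or `"descending"`.
#' @return numeric ranks, a tie-averaged permutation of 1..n over the
#'   non-missing entries.
#' @export
rank_metric <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (all(is.na(values))) stop("need at least one non-missing value")
  v <- if (direction == "descending") -values else values
  r <- rank(v, ties.method = "average", na.last = "keep")
  if (anyNA(r)) {
    message(sum(is.na(r)), " missing value(s) assigned the worst rank")
    r[is.na(r)] <- length(values)
  }
  r
}

#' Direction map presets for the composite rank
#'
#' `fig1c_directions()`: the three-metric screen over one donor's cultures
#' (Euclidean and family-level JSD ascending, Shannon descending).
#' `fig5_directions()`: the full seven-metric panel — the four
#' distance-to-feces metrics ascending, growth and the two diversity indices
#' descending.
#'
#' @return named character vector metric -> direction.
#' @export
fig1c_directions <- function() {
  c(euclidean_asv = "ascending",
    d_js_family = "ascending",
    shannon_asv = "descending")
}

#' @rdname fig1c_directions
#' @export
fig5_directions <- function() {
  c(d_js_family = "ascending",
    euclidean_asv = "ascending",
    d_js_pathway = "ascending",
    gene_variation = "ascending",
    delta_od600 = "descending",
    shannon_asv = "descending",
    simpson_asv = "descending")
}

#' Comprehensive rank of cultures from a metric panel
#'
#' The composite scoring procedure: within each block (a donor, or the whole
#' culture set), every metric is converted to ranks with its own direction
#' via [rank_metric()], and the per-culture mean of the metric ranks is the
#' comprehensive rank. A smaller comprehensive rank means higher growth,
#' similarity and diversity.
#'
#' @param panel data.frame with one row per culture: any key columns (e.g.
#'   donor, medium, time_h) plus one numeric column per metric named in
#'   `direction_map`.
#' @param direction_map named vector metric -> `"ascending"`/`"descending"`;
#'   must cover every metric to be ranked. See [fig1c_directions()],
#'   [fig5_directions()].
#' @param blocks optional block id per row (e.g. `panel$donor` for per-donor
#'   ranking); `NULL` ranks the whole panel as one block.
#' @return data.frame of class `"rank_table"`: the key columns, `block`, one
#'   `rank_<metric>` column per metric, and `comprehensive_rank`, sorted by
#'   block then comprehensive rank.
#' @export
comprehensive_rank <- function(panel, direction_map, blocks = NULL) {
  metrics <- names(direction_map)
  missing_m <- setdiff(metrics, names(panel))
  if (length(missing_m) > 0L)
    stop("panel is missing metric column(s): ", paste(missing_m, collapse = ", "))
  bad_dir <- setdiff(direction_map, c("ascending", "descending"))
  if (length(bad_dir) > 0L)
    stop("unknown direction(s): ", paste(bad_dir, collapse = ", "))
  if (is.null(blocks)) blocks <- rep("all", nrow(panel))
  if (length(blocks) != nrow(panel)) stop("blocks must match panel rows")
  if (any(!nzchar(as.character(blocks))) || anyNA(blocks))
    stop("empty block id")
  key_cols <- setdiff(names(panel), metrics)
  out_list <- lapply(split(seq_len(nrow(panel)), blocks), function(idx) {
    if (length(idx) == 0L) stop("empty block")
    block_panel <- panel[idx, , drop = FALSE]
    ranks <- vapply(metrics, function(m)
      rank_metric(block_panel[[m]], direction_map[[m]]), numeric(length(idx)))
    if (length(idx) == 1L) ranks <- matrix(ranks, nrow = 1L,
                                           dimnames = list(NULL, metrics))
    colnames(ranks) <- paste0("rank_", metrics)
    cbind(block_panel[key_cols],
          block = blocks[idx],
          as.data.frame(ranks),
          comprehensive_rank = rowMeans(ranks))
  })
  out <- do.call(rbind, out_list)
  out <- out[order(out$block, out$comprehensive_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Summarise comprehensive ranks per medium across donor blocks
#'
#' Mean (and SD) of the comprehensive rank of each medium over the donor
#' blocks; the medium with the minimal mean rank is declared best. Exact ties
#' for best are reported, never broken.
#'
#' @param rank_table output of [comprehensive_rank()] with a `medium` column
#'   and per-donor blocks.
#' @return list with `summary` (data.frame medium, mean_rank, sd_rank,
#'   n_blocks, sorted by mean), `best` (character vector: the minimal-mean
#'   medium or the tied set), `tie` (logical).
#' @export
summarize_media <- function(rank_table) {
  if (!"medium" %in% names(rank_table))
    stop("rank table needs a 'medium' column")
  sp <- split(rank_table$comprehensive_rank, rank_table$medium)
  s <- data.frame(medium = names(sp),
                  mean_rank = vapply(sp, mean, numeric(1L)),
                  sd_rank = vapply(sp, stats::sd, numeric(1L)),
                  n_blocks = vapply(sp, length, integer(1L)),
                  row.names = NULL, stringsAsFactors = FALSE)
  s <- s[order(s$mean_rank), , drop = FALSE]
  rownames(s) <- NULL
  best <- s$medium[abs(s$mean_rank - s$mean_rank[1L]) < 1e-12]
  list(summary = s, best = best, tie = length(best) > 1L)
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("comprehensive rank table: %d cultures, %d block(s), %d metric(s)\n",
              nrow(x), length(unique(x$block)),
              sum(startsWith(names(x), "rank_"))))
  print(as.data.frame(x), ...)
  invisible(x)
}
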