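# in-code fixtures shared across the suite

make_table <- function(counts, samples = NULL, taxa = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% sprintf("S%d", seq_len(nrow(m)))
  colnames(m) <- taxa %||% sprintf("ASV%d", seq_len(ncol(m)))
  feature_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full factorial culture design + one feces sample per donor
make_design <- function(n_donors, n_media, times, n_reps) {
  donors <- sprintf("D%d", seq_len(n_donors))
  g <- expand.grid(donor = donors, medium = sprintf("M%d", seq_len(n_media)),
                   time_h = times, replicate = sprintf("R%d", seq_len(n_reps)),
                   stringsAsFactors = FALSE)
  cult <- data.frame(sample_id = paste(g$donor, g$medium, g$time_h,
                                       g$replicate, sep = "_"),
                     g, role = "culture", stringsAsFactors = FALSE)
  feces <- data.frame(sample_id = paste0(donors, "_feces"), donor = donors,
                      medium = NA, time_h = 0, replicate = "R1",
                      role = "feces", stringsAsFactors = FALSE)
  sample_metadata(rbind(cult, feces))
}

# two-group distance matrix: within-group distance 0, between-group 1
block_distance <- function(groups) {
  n <- length(groups)
  d <- 1 - outer(groups, groups, "==")
  storage.mode(d) <- "double"
  dimnames(d) <- list(sprintf("S%d", 1:n), sprintf("S%d", 1:n))
  d
}

meta_for_groups <- function(groups, extra = NULL) {
  df <- data.frame(sample_id = sprintf("S%d", seq_along(groups)),
                   donor = groups, medium = "M1", time_h = 6,
                   replicate = "R1", role = "culture",
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  sample_metadata(df)
}

# distance-based one-way SS oracle: SS_total - SS_within via the classical
# pairwise-distance identity, independent of the projection machinery
oneway_ss_oracle <- function(d, groups) {
  ss_of <- function(idx) sum(d[idx, idx]^2) / (2 * length(idx))
  total <- ss_of(seq_len(nrow(d)))
  within <- sum(vapply(split(seq_len(nrow(d)), groups), ss_of, numeric(1)))
  list(factor = total - within, residual = within, total = total)
}

random_profile <- function(n) {
  p <- stats::rexp(n)
  p / sum(p)
}
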