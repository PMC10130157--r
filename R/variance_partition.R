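#' Degrees of freedom for a multi-factor culture design
#'
#' Main-effect degrees of freedom are `#levels - 1` per factor (levels counted
#' among the supplied samples); the residual is `(n - 1) - sum(df)`.
#'
#' @param meta a [sample_metadata()] (or any data.frame).
#' @param factors character vector of factor column names, in model order.
#' @return named integer vector of per-factor df plus `Residuals` and `Total`.
#' @export
design_df <- function(meta, factors) {
  missing_f <- setdiff(factors, names(meta))
  if (length(missing_f) > 0L)
    stop("factor(s) not in metadata: ", paste(missing_f, collapse = ", "))
  n <- nrow(meta)
  df <- vapply(factors, function(f) {
    length(unique(meta[[f]][!is.na(meta[[f]])])) - 1L
  }, integer(1L))
  resid <- (n - 1L) - sum(df)
  if (resid < 0L) stop("design has more model df than samples allow")
  c(df, Residuals = resid, Total = n - 1L)
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm_ <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1L, rm_), 2L, rm_) + gm
}

hat_matrix <- function(x) {
  q <- qr(x)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

#' PERMANOVA accounting from sums of squares
#'
#' Builds the ANOVA-style table (MeanSqs, pseudo-F, R-squared) from sequential
#' factor sums of squares and the residual. The total SS is the sum of the
#' components, so that SS additivity and the R-squared normalisation
#' (all R-squared values, residual included, sum to 1) hold exactly.
#'
#' @param ss_factors named numeric vector of sequential factor SS.
#' @param df_factors integer vector of matching factor df.
#' @param ss_residual,df_residual residual SS and df.
#' @param p_values optional permutation p-values per factor.
#' @return data.frame with rows `factors, Residuals, Total` and columns
#'   `Df, SumsOfSqs, MeanSqs, F.Models, R2, Pr(>F)`.
#' @export
permanova_accounting <- function(ss_factors, df_factors, ss_residual,
                                 df_residual, p_values = NULL) {
  ss_total <- sum(ss_factors) + ss_residual
  ms <- ss_factors / df_factors
  ms_res <- if (df_residual > 0) ss_residual / df_residual else NA_real_
  f <- if (!is.na(ms_res) && ms_res > 0) ms / ms_res else rep(NA_real_, length(ms))
  r2 <- if (ss_total > 0) ss_factors / ss_total else rep(NA_real_, length(ss_factors))
  r2_res <- if (ss_total > 0) ss_residual / ss_total else NA_real_
  out <- data.frame(
    Df = c(df_factors, df_residual, sum(df_factors) + df_residual),
    SumsOfSqs = c(ss_factors, ss_residual, ss_total),
    MeanSqs = c(ms, ms_res, NA_real_),
    F.Models = c(f, NA_real_, NA_real_),
    R2 = c(r2, r2_res, if (ss_total > 0) 1 else NA_real_),
    `Pr(>F)` = c(if (is.null(p_values)) rep(NA_real_, length(ss_factors)) else p_values,
                 NA_real_, NA_real_),
    row.names = c(names(ss_factors), "Residuals", "Total"),
    check.names = FALSE)
  if (ss_total > 0) {
    stopifnot(abs(sum(out$SumsOfSqs[seq_len(nrow(out) - 1L)]) -
                  out$SumsOfSqs[nrow(out)]) < 1e-8,
              abs(sum(out$R2[seq_len(nrow(out) - 1L)]) - 1) < 1e-8)
  }
  class(out) <- c("permanova", "data.frame")
  out
}

# Sequential (Type I) SS of each factor: inner products of the Gower-centred
# matrix with the projection increments of the nested design subspaces.
sequential_projectors <- function(meta, factors) {
  n <- nrow(meta)
  dat <- as.data.frame(lapply(as.data.frame(meta)[factors], factor))
  names(dat) <- factors
  h_prev <- matrix(1 / n, n, n)   # intercept-only hat
  rank_prev <- 1L
  projs <- vector("list", length(factors))
  dfs <- integer(length(factors))
  for (j in seq_along(factors)) {
    fml <- stats::as.formula(paste("~", paste(factors[seq_len(j)], collapse = "+")))
    x <- stats::model.matrix(fml, data = dat)
    q <- qr(x)
    if (q$rank == rank_prev)
      stop("factor '", factors[j],
           "' is aliased with preceding terms (adds no rank to the design)")
    h <- hat_matrix(x)
    projs[[j]] <- h - h_prev
    dfs[j] <- q$rank - rank_prev
    h_prev <- h
    rank_prev <- q$rank
  }
  list(projectors = projs, df = dfs, hat_full = h_prev,
       df_residual = n - rank_prev)
}

ss_from_projectors <- function(G, sp) {
  ss <- vapply(sp$projectors, function(p) sum(p * G), numeric(1L))
  ss_res <- sum(diag(G)) - sum(sp$hat_full * G)
  list(ss = ss, ss_res = ss_res)
}

#' Multi-factor PERMANOVA with sequential sums of squares
#'
#' Partitions the total sum of squares of a dissimilarity matrix among
#' experimental factors, in the user-given order (sequential / Type I SS),
#' with permutation p-values. The dissimilarity matrix is Gower-centred
#' (\eqn{G = C(-\frac12 d^2)C}); each factor's SS is the inner product of
#' G with the projection increment of the nested design subspaces; the
#' pseudo-F tests every factor against the single residual mean square.
#' p-values use free permutation of sample labels and the
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + N)} estimator; when the number of
#' distinct permutations (n!) does not exceed `n_perm`, all of them are
#' enumerated instead and the exact tail probability is reported.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with sample names.
#' @param meta a [sample_metadata()] (or data.frame) covering the samples.
#' @param factors character vector of factor columns, in model order. Order
#'   matters: SS are sequential.
#' @param n_perm number of permutations (default 999); `0` skips p-values.
#' @param seed RNG seed for the permutations.
#' @return a `"permanova"` table, see [permanova_accounting()].
#' @export
permanova <- function(d, meta, factors, n_perm = 999, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs sample names")
  if (!all(ids %in% meta$sample_id))
    stop("metadata missing for sample(s): ",
         paste(setdiff(ids, meta$sample_id), collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  for (f in factors) {
    if (any(is.na(meta[[f]])))
      stop("factor '", f, "' has missing levels for some samples")
  }
  n <- nrow(d)
  G <- gower_center(d)
  sp <- sequential_projectors(meta, factors)
  obs <- ss_from_projectors(G, sp)
  ss <- stats::setNames(obs$ss, factors)
  ms_res <- if (sp$df_residual > 0) obs$ss_res / sp$df_residual else NA_real_
  f_obs <- (ss / sp$df) / ms_res

  p_values <- rep(NA_real_, length(factors))
  if (n_perm > 0) {
    total_ss <- sum(diag(G))
    if (total_ss <= .Machine$double.eps * n) {
      # constant dissimilarities: F is undefined, nothing to test
      p_values <- rep(1, length(factors))
    } else {
      exhaustive <- is.finite(factorial(n)) && factorial(n) <= n_perm
      perms <- if (exhaustive) {
        message("permanova: only ", factorial(n),
                " distinct permutations; enumerating exhaustively")
        all_permutations(n)
      } else {
        if (!is.null(seed)) set.seed(seed)
        replicate(n_perm, sample.int(n), simplify = FALSE)
      }
      f_perm <- vapply(perms, function(p) {
        Gp <- G[p, p]
        s <- ss_from_projectors(Gp, sp)
        msr <- if (sp$df_residual > 0) s$ss_res / sp$df_residual else NA_real_
        (s$ss / sp$df) / msr
      }, numeric(length(factors)))
      if (length(factors) == 1L) f_perm <- matrix(f_perm, nrow = 1L)
      ge <- rowSums(f_perm >= matrix(f_obs, nrow = length(factors),
                                     ncol = ncol(f_perm)) - 1e-12,
                    na.rm = TRUE)
      p_values <- if (exhaustive) ge / length(perms) else (1 + ge) / (1 + n_perm)
      p_values[is.nan(f_obs)] <- 1   # 0/0: no effect and no residual
    }
  }
  out <- permanova_accounting(ss, sp$df, obs$ss_res, sp$df_residual, p_values)
  attr(out, "n_perm") <- n_perm
  attr(out, "factors") <- factors
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

# all distinct rearrangements of a label vector (multiset permutations)
multiset_permutations <- function(labels, limit = 10000L) {
  lev <- unique(labels)
  counts <- table(factor(labels, levels = lev))
  n_distinct <- factorial(length(labels)) / prod(factorial(counts))
  if (n_distinct > limit)
    stop("too many distinct label permutations (", format(n_distinct),
         " > ", limit, ")")
  rec <- function(remaining) {
    if (sum(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (i in seq_along(lev)) {
      if (remaining[i] > 0L) {
        r2 <- remaining
        r2[i] <- r2[i] - 1L
        for (tail in rec(r2)) out[[length(out) + 1L]] <- c(lev[i], tail)
      }
    }
    out
  }
  rec(as.integer(counts))
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every distinct assignment of the factor's labels to the samples
#' and reports the exact tail probability of the observed pseudo-F (observed
#' assignment included in the reference set). Serves as the exact oracle for
#' the sampling-based p-value of [permanova()].
#'
#' @inheritParams permanova
#' @param factor_name single factor column in `meta`.
#' @param limit refuse designs with more distinct assignments than this.
#' @return exact p-value.
#' @export
exhaustive_permutation_p <- function(d, meta, factor_name, limit = 10000L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  ids <- rownames(d)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  labels <- as.character(meta[[factor_name]])
  n <- nrow(d)
  G <- gower_center(d)
  if (sum(diag(G)) <= .Machine$double.eps * n) return(1)
  f_of <- function(lab) {
    x <- stats::model.matrix(~ f, data = data.frame(f = factor(lab)))
    h <- hat_matrix(x)
    df1 <- qr(x)$rank - 1L
    dfr <- n - qr(x)$rank
    ssf <- sum((h - matrix(1 / n, n, n)) * G)
    ssr <- sum(diag(G)) - sum(h * G)
    (ssf / df1) / (ssr / dfr)
  }
  f_obs <- f_of(labels)
  if (is.nan(f_obs)) return(1)
  fs <- vapply(multiset_permutations(labels, limit = limit), f_of, numeric(1L))
  mean(fs >= f_obs - 1e-12)
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("PERMANOVA (sequential sums of squares)\n")
  if (!is.null(attr(x, "n_perm")))
    cat("Permutations:", attr(x, "n_perm"), "(free)\n")
  y <- as.data.frame(x)
  y$R2 <- round(y$R2, 3)
  print(format(y, digits = digits, na.encode = FALSE), ...)
  invisible(x)
}
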