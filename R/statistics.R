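# studentized-range quantiles at Duncan's protected levels, memoized:
# the quantile only depends on (alpha, k, df), which repeats across the
# per-statistic groupings of a run and across simulation replicates
.duncan_q_cache <- new.env(parent = emptyenv())

duncan_q <- function(alpha, k, df) {
  key <- paste(alpha, k, df, sep = "|")
  q <- .duncan_q_cache[[key]]
  if (is.null(q)) {
    spans <- 2:k
    q <- stats::qtukey((1 - alpha)^(spans - 1), spans, df)
    .duncan_q_cache[[key]] <- q
  }
  q
}

#' One-way ANOVA with Duncan's multiple range grouping
#'
#' Fits the one-way ANOVA and constructs Duncan's multiple range compact
#' letter display. For a range spanning `r` ordered means the critical
#' value is the studentized-range quantile at Duncan's protected level
#' `1 - (1 - alpha)^(r - 1)` on the pooled within-group mean square, with
#' the harmonic mean of the group sizes as the per-group n. Two means
#' differ when their gap exceeds the critical range for their span, and
#' letters are assigned by sweeping the means in ascending order, so the
#' display is coherent: a letter always covers a contiguous run of sorted
#' means. Zero within-group variance degenerates to exact comparison of
#' the group means.
#'
#' @param values named list of numeric replicate vectors, one per group
#'   (>= 2 groups, each with >= 2 replicates).
#' @param alpha significance level (default 0.05).
#' @return An object of class `duncan_grouping`: list with `sample_ids`,
#'   `group_letters` (same order as `sample_ids`), `means`, `alpha`,
#'   `F_statistic`, `p_value`, `df_error`, `ms_error`, and
#'   `critical_ranges` (indexed by span `r = 2..k`).
#' @export
anova_duncan <- function(values, alpha = 0.05) {
  if (!is.list(values) || length(values) < 2L) {
    stop("need at least 2 groups")
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    names(values) <- paste0("group", seq_along(values))
  }
  sizes <- lengths(values)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 replicates; offending group(s): ",
         paste(names(values)[sizes < 2L], collapse = ", "))
  }
  ids <- names(values)
  k <- length(values)
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(ids, sizes), levels = ids)
  n_tot <- length(y)
  means <- vapply(values, mean, 0)
  grand <- mean(y)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- n_tot - k
  ms_between <- ss_between / df1
  ms_error <- ss_within / df2
  if (ms_error > 0) {
    F_stat <- ms_between / ms_error
    p_val <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  } else if (ss_between > 0) {
    F_stat <- Inf
    p_val <- 0
  } else {
    F_stat <- NaN # all observations identical
    p_val <- 1
  }

  n_h <- k / sum(1 / sizes) # harmonic mean group size
  spans <- 2:k
  crit <- if (ms_error > 0) {
    duncan_q(alpha, k, df2) * sqrt(ms_error / n_h)
  } else {
    rep(0, length(spans))
  }
  names(crit) <- spans

  ord <- order(means)
  sorted <- means[ord]
  crit_full <- c(0, crit) # span r = 1..k
  # For each start i, the widest span whose range test is non-significant;
  # a non-significant containing range protects everything inside it.
  ends <- integer(k)
  for (i in seq_len(k)) {
    js <- i:k
    ok <- sorted[js] - sorted[i] <= crit_full[js - i + 1L] + 1e-12
    ends[i] <- max(js[ok])
  }
  # maximal runs -> letters (each letter covers a contiguous sorted run)
  runs <- list()
  last_end <- 0L
  for (i in seq_len(k)) {
    if (ends[i] > last_end || (last_end < i)) {
      runs[[length(runs) + 1L]] <- c(i, ends[i])
      last_end <- ends[i]
    }
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- character(k)
  for (r in seq_along(runs)) {
    span <- runs[[r]][1]:runs[[r]][2]
    lab[span] <- paste0(lab[span], letters_pool[r])
  }
  group_letters <- character(k)
  group_letters[ord] <- lab

  structure(
    list(
      sample_ids = ids,
      group_letters = group_letters,
      means = means,
      alpha = alpha,
      F_statistic = F_stat,
      p_value = p_val,
      df_error = df2,
      ms_error = ms_error,
      critical_ranges = crit
    ),
    class = "duncan_grouping"
  )
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat(sprintf("Duncan multiple range grouping (alpha = %g)\n", x$alpha))
  cat(sprintf("F = %.4g, p = %.4g\n", x$F_statistic, x$p_value))
  print(data.frame(sample = x$sample_ids, mean = x$means,
                   letters = x$group_letters, row.names = NULL))
  invisible(x)
}

#' Principal component analysis on the correlation matrix
#'
#' Standardizes each variable to zero mean and unit variance, then
#' eigendecomposes the correlation matrix. Explained variance percentages
#' are `100 * eigenvalue / p` and always sum to 100. Scores are the
#' standardized data projected on the loadings. Component signs are fixed
#' so that the largest-magnitude loading of each component is positive.
#'
#' @param table numeric matrix or data frame, samples in rows, variables
#'   in columns (>= 3 samples, >= 2 variables, no constant variable).
#' @return An object of class `pca_result`: `variable_names`, `loadings`
#'   (variables x components), `scores` (samples x components),
#'   `eigenvalues` (non-increasing), `explained_variance_pct`.
#' @export
pca_correlation <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("table must be numeric")
  if (nrow(x) < 3L) stop("need at least 3 samples, got ", nrow(x))
  if (ncol(x) < 2L) stop("need at least 2 variables, got ", ncol(x))
  if (anyNA(x)) stop("table contains missing values")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s) have no correlation structure: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  load <- e$vectors
  # deterministic sign: dominant loading positive
  for (j in seq_len(ncol(load))) {
    peak <- which.max(abs(load[, j]))
    if (load[peak, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- z %*% load
  rownames(scores) <- rownames(x)
  structure(
    list(
      variable_names = colnames(x),
      loadings = load,
      scores = scores,
      eigenvalues = ev,
      explained_variance_pct = 100 * ev / sum(ev)
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA on the correlation matrix\n")
  pct <- x$explained_variance_pct
  for (j in seq_along(pct)) {
    cat(sprintf("  PC%d: %.1f%% of variance\n", j, pct[j]))
  }
  invisible(x)
}

#' Linear correlation of visible and chemical fat content
#'
#' Ordinary least-squares fit of chemically measured fat on image-derived
#' visible fat content, with the coefficient of determination
#' `R2 = 1 - SSres / SStot`.
#'
#' @param vfc per-sample visible fat content (percent).
#' @param chemical per-sample chemical fat content (percent), same length
#'   and order; pairs with missing values are dropped with a warning.
#' @param n_min minimum number of complete pairs (default 3).
#' @return An object of class `fat_correlation`: `slope`, `intercept`,
#'   `R2`, `n_points`, plus the fitted `model`.
#' @export
correlate_vfc_chemical <- function(vfc, chemical, n_min = 3L) {
  if (length(vfc) != length(chemical)) {
    stop("vfc and chemical must have equal length (",
         length(vfc), " vs ", length(chemical), ")")
  }
  keep <- stats::complete.cases(vfc, chemical)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) dropped for missing values")
    vfc <- vfc[keep]
    chemical <- chemical[keep]
  }
  if (length(vfc) < n_min) {
    stop("need at least ", n_min, " complete pairs, got ", length(vfc))
  }
  if (stats::sd(vfc) == 0) {
    stop("visible fat content is constant; fit is undefined")
  }
  fit <- stats::lm(chemical ~ vfc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((chemical - mean(chemical))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      R2 = 1 - ss_res / ss_tot,
      n_points = length(vfc),
      model = fit
    ),
    class = "fat_correlation"
  )
}

#' @export
print.fat_correlation <- function(x, ...) {
  cat(sprintf(
    "chemical = %.3f + %.3f * visible   (R2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$R2, x$n_points
  ))
  invisible(x)
}
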