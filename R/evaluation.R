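#' Per-CNV, per-called-state imputation accuracy
#'
#' A CNV is correctly imputed in an animal when the imputed copy number
#' equals the called copy number. Accuracy is computed per locus and
#' per called state within breed and flank size. Two denominators are
#' supported:
#' \describe{
#'   \item{`"per_state_called"`}{(default) the number of validation
#'     animals in which the locus was called with that state -- the
#'     "divided by the number of times that CNV was called in the
#'     validation population" convention.}
#'   \item{`"all_validation"`}{all validation animals of the breed.}
#' }
#' States never called in validation produce no record (not a zero).
#'
#' @param results data.frame from [run_imputation_experiment()].
#' @param denominator accuracy denominator convention.
#' @return data.frame of accuracy records: `breed`, `locus_id`,
#'   `flank_k`, `called_state`, `n_called`, `n_correct`, `accuracy`,
#'   `population_frequency`, `length_kb`, `mean_bayes_factor`.
#' @export
imputation_accuracy <- function(results,
                                denominator = c("per_state_called",
                                                "all_validation")) {
  denominator <- match.arg(denominator)
  if (nrow(results) == 0) {
    return(data.frame(breed = character(0), locus_id = character(0),
                      flank_k = integer(0), called_state = integer(0),
                      n_called = integer(0), n_correct = integer(0),
                      accuracy = numeric(0),
                      population_frequency = integer(0),
                      length_kb = numeric(0),
                      mean_bayes_factor = numeric(0)))
  }
  key <- interaction(results$breed, results$locus_id, results$flank_k,
                     results$called_cn, drop = TRUE)
  groups <- split(results, key)
  n_val_by_breed <- tapply(results$animal_id, results$breed,
                           function(a) length(unique(a)))
  out <- lapply(groups, function(g) {
    denom <- if (denominator == "per_state_called") nrow(g) else
      as.integer(n_val_by_breed[[g$breed[1]]])
    data.frame(breed = g$breed[1], locus_id = g$locus_id[1],
               flank_k = g$flank_k[1], called_state = g$called_cn[1],
               n_called = nrow(g), n_correct = sum(g$correct),
               accuracy = sum(g$correct) / denom,
               population_frequency = g$population_frequency[1],
               length_kb = g$length_kb[1],
               mean_bayes_factor = mean(g$bayes_factor, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$breed, res$locus_id, res$flank_k, res$called_state), ,
      drop = FALSE]
}

#' Adjusted Rand index of two labelings
#'
#' Hubert-Arabie chance-corrected pair-counting agreement computed
#' from the contingency table. Values lie in [-1, 1]: 1 for identical
#' partitions, about 0 for independent random labelings, negative for
#' less agreement than chance. When both labelings are a single
#' cluster the chance-adjustment denominator is 0; the index is then
#' returned as 0 with a warning (agreement is trivially perfect but
#' carries no information).
#'
#' @param labels_a,labels_b equal-length vectors (any atomic type).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * 4) {
    warning("both labelings form a single cluster; ARI undefined, returning 0")
    return(0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Groups with fewer than 2 values are excluded with a warning. Pairs
#' are declared different at adjusted p < 0.05.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length.
#' @return list with `means` (named group means), `anova_f`,
#'   `anova_p`, and `tukey` (data.frame: `pair`, `diff`, `p_adj`,
#'   `significant`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with < 2 values: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 values")
  # degenerate zero-spread data: aov's F would be 0/0
  gm <- tapply(values, groups, mean)
  resid_ss <- sum((values - gm[groups])^2)
  if (resid_ss == 0 && max(gm) == min(gm)) {
    lev <- levels(groups)
    prs <- utils::combn(lev, 2, function(p) paste(p[2], p[1], sep = "-"))
    return(list(means = gm, anova_f = 0, anova_p = 1,
                tukey = data.frame(pair = prs, diff = 0, p_adj = 1,
                                   significant = FALSE,
                                   stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(values ~ groups)
  at <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(means = tapply(values, groups, mean),
       anova_f = at[["F value"]][1], anova_p = at[["Pr(>F)"]][1],
       tukey = tukey)
}

#' Pearson correlation with Fisher r-to-z confidence interval
#'
#' `r` by the product-moment formula; the `1 - alpha` confidence
#' interval is `tanh(atanh(r) +/- z / sqrt(n - 3))`. A correlation is
#' considered different from zero only when the interval excludes
#' zero.
#'
#' @param x,y numeric vectors, `n >= 4`, finite, non-constant.
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @return list: `r`, `n`, `ci95` (length-2), `significant`.
#' @export
pearson_fisher_ci <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  z <- stats::qnorm(1 - alpha / 2)
  # clamp so atanh stays finite at |r| = 1; the boundary CI end is
  # restored exactly below
  zr <- atanh(max(min(r, 1 - 1e-15), -1 + 1e-15))
  lo <- tanh(zr - z / sqrt(n - 3))
  hi <- tanh(zr + z / sqrt(n - 3))
  if (r >= 1) hi <- 1
  if (r <= -1) lo <- -1
  list(r = r, n = n, ci95 = c(lo, hi), significant = lo > 0 | hi < 0)
}

#' Bayes factor of correctly vs incorrectly imputed CNVs
#'
#' Tests, per breed and pooled, whether the per-call Bayes factor
#' differs between validation CNV instances whose imputed copy number
#' matched the called copy number and those where it did not (one-way
#' ANOVA with two levels). Only instances that carry a Bayes factor
#' (i.e. actual consensus calls) enter. A stratum with an empty level
#' is skipped.
#'
#' @param results data.frame from [run_imputation_experiment()] with
#'   `bayes_factor` and `correct`.
#' @return data.frame: `stratum`, `n_correct`, `n_incorrect`,
#'   `mean_diff` (correct minus incorrect), `f`, `p`, `direction`.
#' @export
compare_bayes_factors <- function(results) {
  results <- results[!is.na(results$bayes_factor), , drop = FALSE]
  strata <- c(as.list(unique(results$breed)), list(NULL))
  rows <- lapply(strata, function(b) {
    d <- if (is.null(b)) results else
      results[results$breed == b, , drop = FALSE]
    name <- if (is.null(b)) "pooled" else b
    n1 <- sum(d$correct); n0 <- sum(!d$correct)
    if (n1 < 2 || n0 < 2) {
      return(data.frame(stratum = name, n_correct = n1, n_incorrect = n0,
                        mean_diff = NA_real_, f = NA_real_, p = NA_real_,
                        direction = "skipped", stringsAsFactors = FALSE))
    }
    fit <- stats::anova(stats::aov(d$bayes_factor ~ d$correct))
    md <- mean(d$bayes_factor[d$correct]) - mean(d$bayes_factor[!d$correct])
    dir <- if (fit[["Pr(>F)"]][1] >= 0.05) "none" else
      if (md > 0) "positive" else "negative"
    data.frame(stratum = name, n_correct = n1, n_incorrect = n0,
               mean_diff = md, f = fit[["F value"]][1],
               p = fit[["Pr(>F)"]][1], direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Table- and figure-style imputation reports
#'
#' Builds the three standard presentations of the accuracy records:
#' a quartile summary of accuracy by called state and breed (type-7
#' linear-interpolation quantiles), a listing of loci reaching at
#' least `min_accuracy` within a breed (with population frequency and
#' accuracy as a percentage), and scatter-ready tables of accuracy
#' against population frequency and against genomic length, with the
#' called state as the series variable.
#'
#' @param records accuracy records from [imputation_accuracy()].
#' @param min_accuracy threshold of the high-accuracy listing.
#' @return list with `by_state_breed`, `high_accuracy`,
#'   `scatter_frequency`, `scatter_length`.
#' @export
render_reports <- function(records, min_accuracy = 0.85) {
  stopifnot(nrow(records) >= 1)
  q3 <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
  key <- interaction(records$called_state, records$breed, drop = TRUE)
  by_sb <- do.call(rbind, lapply(split(records, key), function(g) {
    q <- q3(g$accuracy)
    data.frame(breed = g$breed[1], called_state = g$called_state[1],
               n_cnvs = length(unique(g$locus_id)),
               q1_accuracy = q[1], median_accuracy = q[2],
               q3_accuracy = q[3], stringsAsFactors = FALSE)
  }))
  rownames(by_sb) <- NULL
  hi <- records[records$accuracy >= min_accuracy, , drop = FALSE]
  high <- data.frame(locus_id = hi$locus_id, breed = hi$breed,
                     called_state = hi$called_state, flank_k = hi$flank_k,
                     population_frequency = hi$population_frequency,
                     accuracy_pct = 100 * hi$accuracy,
                     stringsAsFactors = FALSE)
  rownames(high) <- NULL
  scatter <- function(xcol) {
    data.frame(breed = records$breed, locus_id = records$locus_id,
               called_state = records$called_state,
               flank_k = records$flank_k,
               x = records[[xcol]], accuracy_pct = 100 * records$accuracy,
               stringsAsFactors = FALSE)
  }
  list(by_state_breed = by_sb, high_accuracy = high,
       scatter_frequency = scatter("population_frequency"),
       scatter_length = scatter("length_kb"))
}
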