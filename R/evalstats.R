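# Per-patient and aggregated Dice evaluation, paired Wilcoxon comparison,
# and report tables.
#
# DSC = 2|P n R| / (|P| + |R|) per patient and class. The aggregated
# (pooled) Dice sums intersections and mask sizes across all patients
# before forming the ratio, which makes it robust against single all-miss
# cases. When a class is absent from both prediction and reference the DSC
# is defined as 1 and flagged; flagged pairs are excluded from Wilcoxon
# pairing by default.

labels_of <- function(x) {
  if (inherits(x, "labelmap")) x$labels
  else if (inherits(x, "case_record")) x$reference$labels
  else x
}

check_pair_geometry <- function(pred, ref) {
  p <- labels_of(pred); r <- labels_of(ref)
  if (!identical(dim(p), dim(r)))
    stopf("dsc: prediction grid %s does not match reference grid %s",
          paste(dim(p), collapse = "x"), paste(dim(r), collapse = "x"))
  list(p = p, r = r)
}

#' Dice similarity coefficient for one class
#'
#' @param pred,ref label maps (or plain integer arrays) on the same grid.
#' @param label class id (1 = GTVp, 2 = GTVn).
#' @return the DSC in `[0, 1]`. When the class is absent from both masks the
#'   defined-empty value 1 is returned, carrying attribute `both_empty = TRUE`.
#' @export
dsc <- function(pred, ref, label = 1L) {
  g <- check_pair_geometry(pred, ref)
  p <- g$p == label; r <- g$r == label
  denom <- sum(p) + sum(r)
  if (denom == 0) return(structure(1, both_empty = TRUE))
  structure(2 * sum(p & r) / denom, both_empty = FALSE)
}

#' Aggregated (pooled) Dice over a set of cases
#'
#' Pools intersections and mask sizes across all pairs before forming the
#' ratio: `2 * sum_i |P_i n R_i| / (sum_i |P_i| + sum_i |R_i|)`. Reduces to
#' the per-case DSC for a single pair.
#'
#' @param pairs list of `list(pred = , ref = )` label-map pairs.
#' @param label class id.
#' @return pooled Dice in `[0, 1]`; the defined-empty value 1 with attribute
#'   `both_empty = TRUE` when every mask of this class is empty.
#' @export
agg_dsc <- function(pairs, label = 1L) {
  stopifnot(length(pairs) >= 1)
  inter <- size <- 0
  for (pair in pairs) {
    g <- check_pair_geometry(pair$pred, pair$ref)
    p <- g$p == label; r <- g$r == label
    inter <- inter + sum(p & r)
    size <- size + sum(p) + sum(r)
  }
  if (size == 0) return(structure(1, both_empty = TRUE))
  structure(2 * inter / size, both_empty = FALSE)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped. For n <= 15 remaining pairs the p-value is
#' computed from the exact null distribution by exhaustive enumeration of
#' all 2^n sign assignments (valid in the presence of tied ranks); for
#' larger n a normal approximation with tie correction is used.
#'
#' @param a,b equal-length numeric vectors of paired per-case scores.
#' @param alpha significance level (default 0.05).
#' @return a list with `statistic` (V, sum of positive signed ranks), `p`,
#'   `significant`, `n_used` (pairs after dropping zeros), and `degenerate`
#'   (`TRUE` when every difference is zero, in which case the test is
#'   reported non-significant with p = 1).
#' @export
wilcoxon_paired <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = 1, significant = FALSE,
                n_used = 0L, degenerate = TRUE))
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  if (n <= 15) {
    # exact null: all sign assignments equally likely under H0
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% rk)
    mu <- n * (n + 1) / 4
    p <- mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    p <- min(1, p)
  }
  list(statistic = v, p = p, significant = p < alpha, n_used = n,
       degenerate = FALSE)
}

#' Evaluate predictions against references for one configuration
#'
#' @param pairs named list of `list(pred = , ref = )` pairs; names are case ids
#'   (defaults to `case_1`, ... when unnamed).
#' @return an `eval_result`: `per_case` data frame with per-class and mean
#'   DSC, `aggregated` list with pooled Dice per class and their average,
#'   `n_cases`, and `both_empty` flags per case/class.
#' @export
evaluate_pairs <- function(pairs) {
  n <- length(pairs)
  stopifnot(n >= 1)
  ids <- names(pairs) %||% sprintf("case_%d", seq_len(n))
  if (is.null(names(pairs))) names(pairs) <- ids
  per <- data.frame(case_id = ids,
                    dsc_gtvp = NA_real_, dsc_gtvn = NA_real_,
                    mean_dsc = NA_real_,
                    empty_gtvp = FALSE, empty_gtvn = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d1 <- dsc(pairs[[i]]$pred, pairs[[i]]$ref, 1L)
    d2 <- dsc(pairs[[i]]$pred, pairs[[i]]$ref, 2L)
    per$dsc_gtvp[i] <- as.numeric(d1)
    per$dsc_gtvn[i] <- as.numeric(d2)
    per$mean_dsc[i] <- (as.numeric(d1) + as.numeric(d2)) / 2
    per$empty_gtvp[i] <- isTRUE(attr(d1, "both_empty"))
    per$empty_gtvn[i] <- isTRUE(attr(d2, "both_empty"))
  }
  agg1 <- agg_dsc(pairs, 1L); agg2 <- agg_dsc(pairs, 2L)
  structure(list(per_case = per,
                 aggregated = list(agg_dsc_gtvp = as.numeric(agg1),
                                   agg_dsc_gtvn = as.numeric(agg2),
                                   avg_agg_dsc = (as.numeric(agg1) + as.numeric(agg2)) / 2),
                 n_cases = n),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  a <- x$aggregated
  cat(sprintf("<eval_result %d cases | aggDSC GTVp %.2f GTVn %.2f avg %.2f (x100)>\n",
              x$n_cases, 100 * a$agg_dsc_gtvp, 100 * a$agg_dsc_gtvn,
              100 * a$avg_agg_dsc))
  invisible(x)
}

#' Build report tables comparing configurations
#'
#' Produces an aggregated-Dice summary table (one row per configuration,
#' scores x100 with two decimals, matching the usual presentation) and a
#' per-case table. Each non-best configuration is compared against the best
#' (highest average pooled Dice) with a paired two-sided Wilcoxon
#' signed-rank test on per-case mean DSC; significant differences are
#' starred. Cases where a class is absent from both masks are excluded from
#' the pairing.
#'
#' @param results named list of `eval_result` objects (one per configuration).
#' @param alpha significance level for the Wilcoxon comparisons.
#' @param out_dir optional directory; when given, `summary.csv` and
#'   `per_case.csv` are written there.
#' @param best_epochs optional named integer vector (by configuration):
#'   the epoch whose validation score selected each model, reported as a
#'   `best_epoch` column.
#' @return a list with data frames `summary` and `per_case`, and `best`
#'   (name of the best configuration).
#' @export
eval_report <- function(results, alpha = 0.05, out_dir = NULL,
                        best_epochs = NULL) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  ids <- lapply(results, function(r) r$per_case$case_id)
  base_ids <- sort(ids[[1]])
  for (k in seq_along(ids)) {
    if (!identical(sort(ids[[k]]), base_ids)) {
      d <- union(setdiff(ids[[k]], base_ids), setdiff(base_ids, ids[[k]]))
      stopf("eval_report: configurations cover different case sets (differ: %s)",
            paste(d, collapse = ", "))
    }
  }
  avg <- vapply(results, function(r) r$aggregated$avg_agg_dsc, 0)
  best <- names(results)[which.max(avg)]
  mean_scores <- function(r) {
    pc <- r$per_case[order(r$per_case$case_id), ]
    keep <- !(pc$empty_gtvp & pc$empty_gtvn)
    list(scores = pc$mean_dsc, keep = keep)
  }
  bs <- mean_scores(results[[best]])
  summary_df <- data.frame(configuration = names(results),
                           agg_dsc_gtvp = NA_real_, agg_dsc_gtvn = NA_real_,
                           avg_agg_dsc = NA_real_, p_vs_best = NA_real_,
                           star = "", stringsAsFactors = FALSE)
  if (!is.null(best_epochs))
    summary_df$best_epoch <- as.integer(best_epochs[summary_df$configuration])
  for (k in seq_along(results)) {
    r <- results[[k]]
    summary_df$agg_dsc_gtvp[k] <- round(100 * r$aggregated$agg_dsc_gtvp, 2)
    summary_df$agg_dsc_gtvn[k] <- round(100 * r$aggregated$agg_dsc_gtvn, 2)
    summary_df$avg_agg_dsc[k] <- round(100 * r$aggregated$avg_agg_dsc, 2)
    if (names(results)[k] != best) {
      ms <- mean_scores(r)
      keep <- ms$keep & bs$keep
      w <- wilcoxon_paired(ms$scores[keep], bs$scores[keep], alpha = alpha)
      summary_df$p_vs_best[k] <- w$p
      summary_df$star[k] <- if (isTRUE(w$significant)) "*" else ""
    }
  }
  per_case <- do.call(rbind, lapply(names(results), function(nm) {
    pc <- results[[nm]]$per_case
    cbind(configuration = nm, pc[, c("case_id", "dsc_gtvp", "dsc_gtvn", "mean_dsc")])
  }))
  per_case$dsc_gtvp <- round(100 * per_case$dsc_gtvp, 2)
  per_case$dsc_gtvn <- round(100 * per_case$dsc_gtvn, 2)
  per_case$mean_dsc <- round(100 * per_case$mean_dsc, 2)
  rownames(per_case) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(per_case, file.path(out_dir, "per_case.csv"), row.names = FALSE)
  }
  list(summary = summary_df, per_case = per_case, best = best)
}

#' Box plot of per-case mean DSC by configuration
#'
#' Mirrors the usual per-patient comparison figure: one box per
#' configuration over per-case mean DSC, significant differences from the
#' best configuration starred in the axis labels.
#'
#' @param results named list of `eval_result` objects.
#' @param alpha significance level for the stars.
#' @return a `ggplot` object (requires the ggplot2 package).
#' @export
plot_percase_dsc <- function(results, alpha = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_percase_dsc requires the ggplot2 package")
  rep <- eval_report(results, alpha = alpha)
  stars <- stats::setNames(rep$summary$star, rep$summary$configuration)
  df <- do.call(rbind, lapply(names(results), function(nm) {
    data.frame(configuration = paste0(nm, stars[[nm]]),
               mean_dsc = 100 * results[[nm]]$per_case$mean_dsc)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = configuration, y = mean_dsc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-case mean DSC (x100)") +
    ggplot2::theme_minimal()
}
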