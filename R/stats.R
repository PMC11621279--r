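#' Majority-class baseline accuracy
#'
#' The accuracy of always predicting the more frequent class -- the floor
#' every model must beat. Reported as a percentage with two decimals
#' (e.g. a 130/55 split over 185 days gives 70.27).
#'
#' @param labels Nonempty binary label vector.
#' @return Percentage, rounded to two decimals.
#' @export
majority_baseline <- function(labels) {
  if (length(labels) == 0) stop("empty labels", call. = FALSE)
  round(100 * max(table(labels)) / length(labels), 2)
}

#' Kruskal-Wallis test across accuracy groups
#'
#' Rank-based omnibus test (tie-corrected H statistic, chi-square
#' reference) for whether the accuracy distributions of several
#' configurations differ. Wraps `stats::kruskal.test`.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return List with `statistic` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty", call. = FALSE)
  all_v <- unlist(groups)
  if (length(unique(all_v)) == 1) {
    stop("all observations identical: Kruskal-Wallis statistic is degenerate",
         call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Dunn's post-hoc pairwise tests with Bonferroni correction
#'
#' All pairwise z-tests on the joint ranking (with tie correction), run
#' after a Kruskal-Wallis test has indicated an overall difference. Raw
#' two-sided p-values are multiplied by the number of pairs and capped at
#' one (`p_adj = min(1, m * p_raw)`, `m = choose(k, 2)`).
#'
#' @param groups Named list of >= 2 nonempty numeric vectors.
#' @param alpha Significance threshold for the flags (default 0.05).
#' @return List with symmetric matrices `z`, `p_adjusted` (diagonal `NA`)
#'   and logical `significant`.
#' @export
dunn_bonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty", call. = FALSE)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  all_v <- unlist(groups)
  if (length(unique(all_v)) == 1) {
    stop("all observations identical: ranks are degenerate", call. = FALSE)
  }
  n_tot <- length(all_v)
  r <- rank(all_v)
  grp <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, grp, mean)
  n_g <- lengths(groups)
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  m <- choose(k, 2)
  z <- p_adj <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
      zij <- (rbar[i] - rbar[j]) / se
      pij <- 2 * stats::pnorm(-abs(zij))
      z[i, j] <- z[j, i] <- zij
      p_adj[i, j] <- p_adj[j, i] <- min(1, m * pij)
    }
  }
  list(z = z, p_adjusted = p_adj, significant = p_adj < alpha)
}

#' One-sample t-test of fold accuracies against a baseline
#'
#' Two-sided test of whether the mean of a configuration's fold accuracies
#' differs from the majority baseline. Wraps `stats::t.test`.
#'
#' @param accuracies Numeric vector (>= 2 values) of fold accuracies, on
#'   the same scale as `baseline`.
#' @param baseline The comparison value (e.g. [majority_baseline()]).
#' @param alpha Significance threshold (default 0.05).
#' @return List with `t`, `p_value`, `significant`.
#' @export
one_sample_t <- function(accuracies, baseline, alpha = 0.05) {
  if (length(accuracies) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(accuracies) == 0) {
    stop("zero variance: t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(accuracies, mu = baseline)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Full statistical comparison report over a completed grid
#'
#' Assembles the comparison framework: the majority baseline from the
#' labels, each modality's best-configuration fold test accuracies, the
#' Kruskal-Wallis omnibus test across those groups, Dunn-Bonferroni
#' pairwise comparisons (run downstream of the omnibus test), and a
#' per-modality one-sample t-test against the baseline.
#'
#' @param grid Output of [run_grid()].
#' @param labels Binary day labels of the evaluated cohort.
#' @param alpha Significance threshold (default 0.05).
#' @return A `stat_report`: list with `baseline`, `kw` (statistic,
#'   p-value), `dunn` (z / adjusted-p / significance matrices) and
#'   `t_table` (one row per modality).
#' @export
build_report <- function(grid, labels, alpha = 0.05) {
  modalities <- unique(grid$modality)
  if (length(modalities) < 2) stop("grid must cover >= 2 modalities", call. = FALSE)
  best_acc <- lapply(modalities, function(m) {
    row <- best_configuration(grid, m)
    100 * row$result[[1]]$test_acc
  })
  names(best_acc) <- modalities
  baseline <- majority_baseline(labels)
  kw <- kruskal_wallis(best_acc)
  dunn <- dunn_bonferroni(best_acc, alpha = alpha)
  t_table <- purrr::map_dfr(modalities, function(m) {
    tt <- one_sample_t(best_acc[[m]], baseline, alpha = alpha)
    tibble::tibble(modality = m, t = tt$t, p_value = tt$p_value,
                   significant = tt$significant)
  })
  structure(list(baseline = baseline, kw = kw, dunn = dunn, t_table = t_table,
                 best_accuracies = best_acc),
            class = "stat_report")
}

#' @exportS3Method base::print
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> baseline %.2f%%; Kruskal-Wallis H = %.3f, p = %.4g\n",
              x$baseline, x$kw$statistic, x$kw$p_value))
  sig <- which(x$dunn$significant, arr.ind = TRUE)
  sig <- sig[sig[, 1] < sig[, 2], , drop = FALSE]
  if (nrow(sig) == 0) {
    cat("no significant pairwise differences (Dunn-Bonferroni)\n")
  } else {
    nm <- rownames(x$dunn$p_adjusted)
    for (r in seq_len(nrow(sig))) {
      cat(sprintf("%s vs %s: adjusted p = %.3g\n", nm[sig[r, 1]], nm[sig[r, 2]],
                  x$dunn$p_adjusted[sig[r, 1], sig[r, 2]]))
    }
  }
  print(x$t_table)
  invisible(x)
}
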