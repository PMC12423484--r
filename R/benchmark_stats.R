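# Evaluation machinery for benchmarking structure-prioritization metrics
# against docking scoring functions (DSFs):
#   - minBAG-constrained resampling of complexes by binding affinity
#     (pBA = -log10(BindingAffinity[M]))
#   - Spearman ranking power with percentile confidence intervals
#   - early-enrichment virtual-screening metrics: eROCE and enrichment
#     factors at 1/5/10%
#   - pose-prediction success binning by fraction of DSFs with RMSD < 2 A
#   - pairwise Wilcoxon group comparison with Holm adjustment

#' Spearman rank correlation
#'
#' With average ranks assigned to ties this is the Pearson correlation of
#' the rank vectors, and it equals the classic closed form
#' rho = 1 - 6 * sum(d_i^2) / (n (n^2 - 1)) exactly on tie-free data.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @return correlation in \[-1, 1\]; `NA` with a `"reason"` attribute when a
#'   vector has zero rank variance (all values equal).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    return(structure(NA_real_, reason = "zero rank variance"))
  }
  stats::cor(x, y, method = "spearman")
}

#' Summarize consecutive binding-affinity gaps
#'
#' Sorts the pBA values increasingly and reports the mean and sample
#' standard deviation of the consecutive differences (the realized binding
#' affinity gaps, BAG).
#'
#' @param pba numeric vector of pBA values (>= 2 values).
#' @return list with `mean`, `sd`, and the vector of `gaps`.
#' @examples
#' bag_summary(c(2.89, 5.66, 7.96, 9.00, 11.09))  # mean 2.05, sd 0.73
#' @export
bag_summary <- function(pba) {
  stopifnot(length(pba) >= 2L, all(is.finite(pba)))
  gaps <- diff(sort(pba))
  list(mean = mean(gaps), sd = stats::sd(gaps), gaps = gaps)
}

#' Sample complexes with a minimum binding-affinity gap (minBAG)
#'
#' Draws a subset of records whose sorted pBA values are separated by at
#' least `minbag` log units: (1) a random anchor activity is drawn uniformly
#' on `anchor_range`; (2) a grid is built from the anchor toward both ends
#' of the activity range with step `minbag`; (3) each grid point selects the
#' record with the closest pBA (ties to the lowest index), duplicates
#' removed; (4) a sweep in increasing pBA drops any record closer than
#' `minbag` to the previously kept one; (5) three-quarters (floor) of the
#' survivors are subsampled uniformly without replacement, which counteracts
#' over-selection of the marginal activity values. Replicates with fewer
#' than 3 survivors are redrawn up to `max_retries` times.
#'
#' Uses R's RNG: set a seed for reproducibility.
#'
#' @param pba numeric vector of pBA values (>= 2).
#' @param minbag minimum gap in pBA log units (> 0).
#' @param anchor_range range the anchor is drawn from; default `c(2, 14)`,
#'   the span of affinities in typical benchmark sets.
#' @param max_retries redraw budget for degenerate replicates.
#' @param subsample_frac fraction of survivors kept in step (5); 1 disables
#'   the subsampling (useful to inspect the raw gap-constrained selection).
#' @return integer indices into `pba`, ordered by increasing pBA, whose
#'   consecutive pBA gaps are all >= `minbag`.
#' @export
minbag_sample <- function(pba, minbag, anchor_range = c(2, 14),
                          max_retries = 100L, subsample_frac = 0.75) {
  stopifnot(length(pba) >= 2L, all(is.finite(pba)), minbag > 0)
  lo <- min(anchor_range[1], min(pba))
  hi <- max(anchor_range[2], max(pba))
  for (attempt in seq_len(max_retries)) {
    anchor <- stats::runif(1, anchor_range[1], anchor_range[2])
    down <- rev(seq(anchor, lo, by = -minbag))
    up <- if (anchor + minbag <= hi) seq(anchor + minbag, hi, by = minbag)
          else numeric()
    grid <- c(down, up)
    # closest record to each grid point; which.min resolves ties by index
    picked <- unique(vapply(grid, function(g) which.min(abs(pba - g)),
                            integer(1)))
    ord <- picked[order(pba[picked], picked)]
    keep <- ord[1]
    last <- pba[ord[1]]
    for (i in ord[-1]) {
      if (pba[i] - last >= minbag) {
        keep <- c(keep, i)
        last <- pba[i]
      }
    }
    n_sub <- floor(subsample_frac * length(keep))
    if (n_sub >= 3L) {
      sel <- if (n_sub == length(keep)) keep else sort(sample(keep, n_sub))
      return(sel[order(pba[sel], sel)])
    }
  }
  stop("degenerate minBAG sampling: fewer than 3 survivors after ",
       max_retries, " retries", call. = FALSE)
}

#' Resampled ranking statistic under a minBAG constraint
#'
#' Repeats [minbag_sample()] `n_reps` times and computes `statistic`
#' (default [spearman_rho()]) between the selected pBA values and the metric
#' on each replicate, summarizing with mean, median and a 2.5/97.5
#' percentile interval, plus the mean realized gap.
#'
#' @param records data frame with columns `pdb_id` (optional) and `pba`, or
#'   a numeric pBA vector.
#' @param metric metric values: either named by `pdb_id` (must cover all
#'   records) or unnamed and aligned with `records`.
#' @param minbag minimum binding-affinity gap.
#' @param n_reps number of replicates (benchmark convention: 1000).
#' @param statistic function of (pba, metric) returning a scalar.
#' @param anchor_range passed to [minbag_sample()].
#' @return object of class `resample_summary`.
#' @export
resample_statistic <- function(records, metric, minbag, n_reps = 1000L,
                               statistic = spearman_rho,
                               anchor_range = c(2, 14)) {
  if (is.data.frame(records)) {
    pba <- records$pba
    ids <- if ("pdb_id" %in% names(records)) records$pdb_id else NULL
  } else {
    pba <- as.numeric(records)
    ids <- names(records)
  }
  if (!is.null(names(metric))) {
    if (is.null(ids)) stop("metric is named but records carry no pdb_id",
                           call. = FALSE)
    missing_ids <- setdiff(ids, names(metric))
    if (length(missing_ids)) {
      stop("metric values missing for: ",
           paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
    }
    metric <- unname(metric[ids])
  }
  if (length(metric) != length(pba)) {
    stop("metric must cover every record", call. = FALSE)
  }

  stat <- numeric(n_reps)
  gap_means <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- minbag_sample(pba, minbag, anchor_range)
    stat[r] <- as.numeric(statistic(pba[idx], metric[idx]))
    gap_means[r] <- mean(diff(pba[idx]))
  }
  qs <- stats::quantile(stat, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(minbag = minbag, n_reps = n_reps, per_rep_stat = stat,
         mean = mean(stat, na.rm = TRUE),
         median = stats::median(stat, na.rm = TRUE),
         ci_low = qs[1], ci_high = qs[2],
         mean_gap = mean(gap_means)),
    class = "resample_summary"
  )
}

#' @export
print.resample_summary <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<resample_summary> minBAG %g, %d reps: mean %s, median %s, 95%% CI [%s, %s], mean gap %s\n",
    x$minbag, x$n_reps, format(x$mean, digits = digits),
    format(x$median, digits = digits), format(x$ci_low, digits = digits),
    format(x$ci_high, digits = digits), format(x$mean_gap, digits = digits)))
  invisible(x)
}

.check_labels <- function(labels) {
  lab <- as.logical(labels)
  if (anyNA(lab)) stop("labels must be logical or 0/1", call. = FALSE)
  lab
}

#' Exponential ROC enrichment (eROCE)
#'
#' The mean over actives of exp(-alpha * FPR_i), where FPR_i is the false
#' positive rate at active i's rank: the fraction of decoys ranked strictly
#' before it (tied decoys, identified through `scores`, count half). With
#' the conventional alpha = 32.19, actives ranked before the first 5% of
#' decoys receive weights between 1 and ~0.2, focusing the metric on early
#' enrichment.
#'
#' @param labels logical (or 0/1) vector in rank order, best-scored first;
#'   `TRUE` = active, `FALSE` = decoy. Needs at least one of each.
#' @param alpha exponent controlling the early-recognition focus.
#' @param scores optional scores in the same order, used only to detect ties.
#' @return value in (0, 1]; bounded below by exp(-alpha).
#' @export
eroce <- function(labels, alpha = 32.19, scores = NULL) {
  lab <- .check_labels(labels)
  n_a <- sum(lab)
  n_d <- sum(!lab)
  if (n_a < 1L || n_d < 1L) {
    stop("need at least one active and one decoy", call. = FALSE)
  }
  if (is.null(scores)) {
    # at an active position, cumsum of decoys counts those strictly before
    fpr <- cumsum(!lab)[lab] / n_d
  } else {
    if (length(scores) != length(lab)) {
      stop("scores must match labels in length", call. = FALSE)
    }
    act_idx <- which(lab)
    fpr <- vapply(act_idx, function(i) {
      tied <- !lab & scores == scores[i]
      before <- !lab & seq_along(lab) < i & !tied
      (sum(before) + 0.5 * sum(tied)) / n_d
    }, numeric(1))
  }
  mean(exp(-alpha * fpr))
}

#' Enrichment factor at a top fraction of the ranked list
#'
#' EF = NA_f / (NA * f), where NA_f is the number of actives among the top
#' `ceiling(f * N)` entries of the ranked list and NA the total number of
#' actives. EF = 1 matches random expectation; the ceiling of the metric at
#' fraction f is 1/f.
#'
#' @inheritParams eroce
#' @param fraction top fraction(s) of the list, each in (0, 1]; conventional
#'   values 0.01, 0.05, 0.10.
#' @return named numeric vector of enrichment factors, one per fraction.
#' @export
enrichment_factor <- function(labels, fraction = c(0.01, 0.05, 0.10)) {
  lab <- .check_labels(labels)
  n_a <- sum(lab)
  if (n_a < 1L) stop("need at least one active", call. = FALSE)
  if (any(fraction <= 0 | fraction > 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  n <- length(lab)
  ef <- vapply(fraction, function(f) {
    top <- ceiling(f * n)
    sum(lab[seq_len(top)]) / (n_a * f)
  }, numeric(1))
  names(ef) <- sprintf("EF%g%%", 100 * fraction)
  ef
}

#' Evaluate a ranked virtual-screening result
#'
#' @inheritParams eroce
#' @param fractions top fractions for the enrichment factors.
#' @return object of class `screening_eval` with `n_actives`, `n_decoys`,
#'   `alpha`, `eroce`, `ef`, and the `success` flag (eROCE > 0.1, strict).
#' @export
screening_eval <- function(labels, alpha = 32.19,
                           fractions = c(0.01, 0.05, 0.10), scores = NULL) {
  lab <- .check_labels(labels)
  e <- eroce(lab, alpha = alpha, scores = scores)
  structure(
    list(n_actives = sum(lab), n_decoys = sum(!lab), alpha = alpha,
         eroce = e, ef = enrichment_factor(lab, fractions),
         success = e > 0.1),
    class = "screening_eval"
  )
}

#' Virtual-screening success rule
#'
#' Success is defined as eROCE strictly greater than 0.1 (roughly
#' equivalent, on typical benchmark rankings, to EF1% > 5, EF5% > 3 and
#' EF10% > 2).
#'
#' @param eval a `screening_eval` object or a bare eROCE value.
#' @return logical flag.
#' @export
vs_success <- function(eval) {
  e <- if (inherits(eval, "screening_eval")) eval$eroce else as.numeric(eval)
  e > 0.1
}

#' @export
print.screening_eval <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<screening_eval> %d actives / %d decoys: eROCE %s (alpha %g) — %s\n",
    x$n_actives, x$n_decoys, format(x$eroce, digits = digits), x$alpha,
    if (x$success) "success (eROCE > 0.1)" else "not successful"))
  print(round(x$ef, digits))
  invisible(x)
}

.DEFAULT_BIN_LABELS <- c("<25%", "25-50%", "50-75%", "75-95%", ">95%")

.assign_bin <- function(f) {
  # [0,0.25) [0.25,0.5) [0.5,0.75) [0.75,0.95] (0.95,1]
  ifelse(f < 0.25, .DEFAULT_BIN_LABELS[1],
  ifelse(f < 0.50, .DEFAULT_BIN_LABELS[2],
  ifelse(f < 0.75, .DEFAULT_BIN_LABELS[3],
  ifelse(f <= 0.95, .DEFAULT_BIN_LABELS[4], .DEFAULT_BIN_LABELS[5]))))
}

#' Group complexes by their pose-prediction success fraction
#'
#' For each complex, the success fraction is the share of docking scoring
#' functions (DSFs) whose best redocked pose has RMSD strictly below
#' `threshold` (default 2 Angstrom). Complexes are then partitioned into
#' five bins: <25%, 25-50%, 50-75%, 75-95% and >95% of DSFs successful
#' (0.95 itself falls in the fourth bin).
#'
#' @param rmsd_table data frame with columns `pdb_id`, `dsf_id`, `rmsd`
#'   (Angstrom, >= 0; `NA` entries are dropped from that complex's
#'   denominator with a warning).
#' @param threshold RMSD success cutoff in Angstrom (strict `<`).
#' @param metric_values optional named vector (by `pdb_id`) whose per-group
#'   distributions are attached (e.g. LBI, PBI or resolution).
#' @return object of class `success_grouping`: `threshold`, per-complex
#'   `fractions`, `groups` (label -> pdb_ids), `counts`, and
#'   `per_group_values` when metrics were supplied.
#' @export
bin_by_success <- function(rmsd_table, threshold = 2.0,
                           metric_values = NULL) {
  stopifnot(all(c("pdb_id", "dsf_id", "rmsd") %in% names(rmsd_table)))
  na_rows <- is.na(rmsd_table$rmsd)
  if (any(na_rows)) {
    warning(sprintf("%d RMSD entries missing; excluded from denominators",
                    sum(na_rows)), call. = FALSE)
    rmsd_table <- rmsd_table[!na_rows, , drop = FALSE]
  }
  if (any(rmsd_table$rmsd < 0)) stop("RMSD must be >= 0", call. = FALSE)
  succ <- tapply(rmsd_table$rmsd < threshold, rmsd_table$pdb_id, mean)
  fractions <- as.numeric(succ)
  names(fractions) <- names(succ)
  bin <- .assign_bin(fractions)
  groups <- split(names(fractions), factor(bin, levels = .DEFAULT_BIN_LABELS))
  counts <- vapply(groups, length, integer(1))
  per_group_values <- NULL
  if (!is.null(metric_values)) {
    per_group_values <- lapply(groups, function(ids) {
      unname(metric_values[intersect(ids, names(metric_values))])
    })
  }
  structure(
    list(threshold = threshold, bins = .DEFAULT_BIN_LABELS,
         fractions = fractions, groups = groups, counts = counts,
         per_group_values = per_group_values),
    class = "success_grouping"
  )
}

#' @export
print.success_grouping <- function(x, ...) {
  cat(sprintf("<success_grouping> RMSD < %g A; %d complexes\n",
              x$threshold, length(x$fractions)))
  print(x$counts)
  if (!is.null(x$per_group_values)) {
    med <- vapply(x$per_group_values,
                  function(v) if (length(v)) stats::median(v) else NA_real_,
                  numeric(1))
    cat("group medians of supplied metric:\n")
    print(round(med, 3))
  }
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum comparison of groups
#'
#' Two-sided pairwise Wilcoxon tests with Holm multiplicity adjustment
#' (via [stats::pairwise.wilcox.test()]). Pairs involving a group with
#' fewer than `min_n` values are marked not assessable (`NA`).
#'
#' @param groups named list mapping a group label to its numeric values
#'   (>= 2 groups).
#' @param alpha significance level for the `significant` flags.
#' @param min_n minimum group size for a pair to be assessed.
#' @return list with symmetric matrices `p` (Holm-adjusted p-values) and
#'   `significant`, plus `alpha`.
#' @export
pairwise_wilcoxon <- function(groups, alpha = 0.05, min_n = 3L) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  labels <- names(groups)
  k <- length(labels)
  p <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  ok <- vapply(groups, function(v) sum(is.finite(v)) >= min_n, logical(1))
  usable <- labels[ok]
  if (length(usable) >= 2L) {
    values <- unlist(groups[usable], use.names = FALSE)
    g <- factor(rep(usable, vapply(groups[usable], length, integer(1))),
                levels = usable)
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, g, p.adjust.method = "holm",
                                  exact = FALSE)
    )$p.value
    for (i in rownames(pw)) for (j in colnames(pw)) {
      if (!is.na(pw[i, j])) p[i, j] <- p[j, i] <- pw[i, j]
    }
  }
  diag(p) <- NA_real_
  significant <- p < alpha
  list(p = p, significant = significant, alpha = alpha)
}
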