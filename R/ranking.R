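# Metric direction table: +1 = higher is better, -1 = lower is better.
metric_directions <- c(dsc = 1, vs = 1, hd95 = -1,
                       bne0 = -1, bne1 = -1, bne2 = -1)

# Fractional ranks (tied values share the mean of their positions); used
# for every intermediate ranking that feeds a further mean.
rank_values <- function(values, direction) {
  rank(-direction * values, ties.method = "average")
}

# Published ranks: tied teams share the best tied position, the next rank
# is skipped (competition style), matching leaderboard presentation.
publish_ranks <- function(mean_ranks) {
  rank(mean_ranks, ties.method = "min")
}

check_score_table <- function(table) {
  required <- c("team", "case_id", "label_code", "dsc", "hd95", "vs",
                "bne0", "bne1", "bne2", "missing")
  miss <- setdiff(required, names(table))
  if (length(miss))
    stop("score table lacks columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

drop_excluded <- function(table) {
  if ("both_empty" %in% names(table)) table[!table$both_empty, , drop = FALSE]
  else table
}

#' Fill missing-prediction cells with worst-case penalties
#'
#' Cells where a label present in the ground truth is absent from a
#' team's prediction receive the worst possible values: Dice and VS of 0,
#' an HD95 of twice the maximum HD95 observed for that label among all
#' non-missing submissions, and Betti number errors of twice the worst
#' observed error per dimension for that label. The penalty pool is per
#' label across all teams and cases by default (`scope = "label"`);
#' `scope = "label_case"` restricts it to the same case.
#'
#' @param table A score table (see [evaluate_cohort()]).
#' @param scope `"label"` (default) or `"label_case"`.
#' @return The table with no remaining `NA` holes in penalised columns.
#' @export
apply_missing_penalties <- function(table, scope = c("label", "label_case")) {
  scope <- match.arg(scope)
  check_score_table(table)
  table <- drop_excluded(table)
  miss <- which(table$missing)
  if (!length(miss)) return(table)

  pool_of <- function(i) {
    same <- table$label_code == table$label_code[i] & !table$missing
    if (scope == "label_case")
      same <- same & table$case_id == table$case_id[i]
    same
  }
  for (i in miss) {
    pool <- pool_of(i)
    if (!any(pool))
      stop("label ", table$label_code[i],
           " is missing from every submission",
           if (scope == "label_case") " for this case" else "",
           "; penalty undefined")
    table$dsc[i] <- 0
    table$vs[i] <- 0
    table$hd95[i] <- 2 * max(table$hd95[pool], na.rm = TRUE)
    for (col in c("bne0", "bne1", "bne2"))
      table[[col]][i] <- 2 * max(table[[col]][pool], na.rm = TRUE)
  }
  table
}

team_metric_means <- function(table, metric, pooling = c("cells", "per_label")) {
  pooling <- match.arg(pooling)
  if (!metric %in% names(metric_directions))
    stop("unknown metric: ", metric)
  if (anyNA(table[[metric]]))
    stop("score table has NA ", metric,
         " values; run apply_missing_penalties() first")
  if (pooling == "cells") {
    tapply(table[[metric]], table$team, mean)
  } else {
    per_label <- tapply(table[[metric]],
                        list(table$team, table$label_code), mean)
    rowMeans(per_label)
  }
}

#' Mean-then-rank for a single metric
#'
#' Averages each team's metric values over all (label, case) cells, then
#' ranks teams in the metric's direction (higher Dice/VS better, lower
#' HD95/BNE better). Tied means share the mean of their rank positions.
#'
#' @param table A penalised score table.
#' @param metric One of `"dsc"`, `"hd95"`, `"vs"`, `"bne0"`, `"bne1"`,
#'   `"bne2"`.
#' @param pooling `"cells"` pools all (label, case) cells into one mean
#'   (default); `"per_label"` averages within each label first, then
#'   across labels.
#' @return Named numeric vector of fractional ranks, one per team.
#' @export
metric_ranking <- function(table, metric, pooling = c("cells", "per_label")) {
  check_score_table(table)
  table <- drop_excluded(table)
  means <- team_metric_means(table, metric, pooling)
  r <- rank_values(as.numeric(means), metric_directions[[metric]])
  setNames(r, names(means))
}

check_same_teams <- function(rankings) {
  teams <- lapply(rankings, function(r) sort(names(r)))
  if (!all(vapply(teams[-1], identical, TRUE, teams[[1]])))
    stop("rankings cover different team sets")
  names(rankings[[1]])
}

#' Aggregate ranking across metrics
#'
#' Combines per-metric rankings with equal weight: each team's ranks are
#' averaged and teams are re-ranked on the mean. Tied mean ranks are
#' published as shared positions with the next rank skipped.
#'
#' @param per_metric A named list of per-team rank vectors (e.g. the
#'   Dice, HD95 and VS rankings) over identical team sets.
#' @return Named integer-valued vector of final ranks; the `mean_rank`
#'   attribute carries the underlying mean ranks (fractional re-ranking
#'   of which is available via `attr(, "fractional")` for use in further
#'   aggregation).
#' @export
aggregate_ranking <- function(per_metric) {
  stopifnot(is.list(per_metric), length(per_metric) >= 1L)
  teams <- check_same_teams(per_metric)
  mat <- vapply(per_metric, function(r) r[teams], numeric(length(teams)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(teams))
  mean_rank <- rowMeans(mat)
  out <- publish_ranks(mean_rank)
  names(out) <- teams
  attr(out, "mean_rank") <- setNames(mean_rank, teams)
  attr(out, "fractional") <- setNames(rank(mean_rank, ties.method = "average"),
                                      teams)
  out
}

#' Betti-number-error ranking
#'
#' Ranks teams per topological dimension by mean BNE (lower better), then
#' combines the three per-dimension rankings into one overall BNE rank.
#' The default combines by averaging the per-dimension ranks
#' (`method = "rank"`); `method = "value"` instead ranks the mean of the
#' three per-dimension mean BNE values.
#'
#' @param table A penalised score table.
#' @param method `"rank"` (default) or `"value"`.
#' @param pooling Passed to [metric_ranking()].
#' @return A list with `per_dimension` (list of rank vectors for
#'   bne0/bne1/bne2), `overall` (published ranks) and `fractional`
#'   (fractional overall ranks, for use inside the topology-integrative
#'   ranking).
#' @export
bne_ranking <- function(table, method = c("rank", "value"),
                        pooling = c("cells", "per_label")) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  dims <- c("bne0", "bne1", "bne2")
  per_dim <- lapply(setNames(dims, dims), function(m)
    metric_ranking(table, m, pooling))
  if (method == "rank") {
    agg <- aggregate_ranking(per_dim)
    overall <- agg
    frac <- attr(agg, "fractional")
  } else {
    means <- vapply(setNames(dims, dims), function(m)
      team_metric_means(drop_excluded(table), m, pooling),
      numeric(length(unique(table$team))))
    combined <- rowMeans(means)
    overall <- publish_ranks(combined)
    names(overall) <- rownames(means)
    frac <- setNames(rank(combined, ties.method = "average"), rownames(means))
  }
  list(per_dimension = per_dim, overall = overall, fractional = frac)
}

#' Per-tissue BNE leaderboard
#'
#' Runs [bne_ranking()] independently on each tissue label and appends
#' each team's average rank across tissues — the per-tissue topology
#' leaderboard layout.
#'
#' @param table A penalised score table.
#' @param method Passed to [bne_ranking()].
#' @return A data frame with one row per team: one column of published
#'   BNE ranks per label plus an `average` column, sorted by average.
#' @export
per_label_bne_ranking <- function(table, method = c("rank", "value")) {
  method <- match.arg(method)
  check_score_table(table)
  labels <- sort(unique(table$label_code))
  teams <- sort(unique(table$team))
  mat <- vapply(labels, function(l) {
    sub <- table[table$label_code == l, , drop = FALSE]
    as.numeric(bne_ranking(sub, method = method)$overall[teams])
  }, numeric(length(teams)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(teams))
  out <- as.data.frame(mat)
  names(out) <- as.character(labels)
  out <- cbind(team = teams, out, average = rowMeans(mat),
               stringsAsFactors = FALSE)
  out[order(out$average), , drop = FALSE]
}

#' Topology-integrative ranking (TIR)
#'
#' Extends the three-metric aggregate ranking with the overall BNE
#' ranking: the final rank is the rank of the mean of the four per-metric
#' ranks, all with equal weight.
#'
#' @param dsc_rank,hd95_rank,vs_rank Per-team fractional rank vectors
#'   from [metric_ranking()].
#' @param bne_rank Per-team fractional overall BNE ranks (the
#'   `fractional` element of [bne_ranking()]).
#' @return Published ranks as in [aggregate_ranking()].
#' @export
topology_integrative_ranking <- function(dsc_rank, hd95_rank, vs_rank,
                                         bne_rank) {
  aggregate_ranking(list(dsc = dsc_rank, hd95 = hd95_rank,
                         vs = vs_rank, bne = bne_rank))
}

#' Per-label aggregate ranking
#'
#' The full three-metric mean-then-rank aggregation restricted to a
#' single tissue label.
#'
#' @param table A penalised score table.
#' @param label Integer label code.
#' @return Published ranks as in [aggregate_ranking()].
#' @export
per_label_ranking <- function(table, label) {
  check_score_table(table)
  sub <- table[table$label_code == label, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for label ", label)
  aggregate_ranking(list(
    dsc = metric_ranking(sub, "dsc"),
    hd95 = metric_ranking(sub, "hd95"),
    vs = metric_ranking(sub, "vs")
  ))
}

#' Subset rankings by metadata grouping
#'
#' Recomputes the full aggregate ranking independently on each subset of
#' cases sharing a metadata attribute (site, quality rating, pathology
#' status or reconstruction method). Empty subsets are skipped with a
#' warning.
#'
#' @param table A penalised score table.
#' @param metadata Data frame as from [read_case_metadata()].
#' @param group_by One of `"site"`, `"quality"`, `"pathological"`,
#'   `"sr_method"`.
#' @return Named list mapping each group value to its published ranks.
#' @export
subset_ranking <- function(table, metadata,
                           group_by = c("site", "quality", "pathological",
                                        "sr_method")) {
  group_by <- match.arg(group_by)
  check_score_table(table)
  if (!all(table$case_id %in% metadata$case_id))
    stop("metadata lacks entries for some cases in the score table")
  values <- sort(unique(metadata[[group_by]]))
  out <- list()
  for (v in values) {
    ids <- metadata$case_id[metadata[[group_by]] == v]
    sub <- table[table$case_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) {
      warning("subset ", group_by, " = ", v, " has no cases; skipped")
      next
    }
    out[[as.character(v)]] <- aggregate_ranking(list(
      dsc = metric_ranking(sub, "dsc"),
      hd95 = metric_ranking(sub, "hd95"),
      vs = metric_ranking(sub, "vs")
    ))
  }
  out
}

#' Bootstrap ranking stability
#'
#' Case-level bootstrap of [metric_ranking()]: in each replicate the
#' cases are resampled with replacement and teams are re-ranked. Returns
#' the per-team rank distribution over replicates; deterministic given
#' the seed.
#'
#' @param table A penalised score table.
#' @param metric Metric name as in [metric_ranking()].
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A list with `ranks` (replicates x teams matrix of fractional
#'   ranks) and `frequency` (teams x rank table of relative frequencies).
#' @export
bootstrap_stability <- function(table, metric, replicates = 1000L,
                                seed = 0L) {
  stopifnot(replicates >= 1L)
  check_score_table(table)
  table <- drop_excluded(table)
  if (anyNA(table[[metric]]))
    stop("run apply_missing_penalties() before bootstrapping")
  cases <- sort(unique(table$case_id))
  teams <- sort(unique(table$team))
  # per-(team, case) means; with a complete table every case carries the
  # same number of cells, so resampled pooled means equal means of these
  percase <- tapply(table[[metric]], list(table$team, table$case_id), mean)
  percase <- percase[teams, cases, drop = FALSE]
  dir <- metric_directions[[metric]]

  set.seed(seed)
  ranks <- matrix(NA_real_, nrow = replicates, ncol = length(teams),
                  dimnames = list(NULL, teams))
  for (r in seq_len(replicates)) {
    pick <- sample.int(length(cases), replace = TRUE)
    means <- rowMeans(percase[, pick, drop = FALSE])
    ranks[r, ] <- rank_values(means, dir)
  }
  freq <- t(apply(ranks, 2, function(x)
    table(factor(x, levels = sort(unique(as.vector(ranks))))) / replicates))
  list(ranks = ranks, frequency = freq, seed = seed, replicates = replicates)
}

#' Pairwise significance of team differences
#'
#' One-sided paired Wilcoxon signed-rank tests on per-case metric values
#' (each case summarised by its mean over labels): entry (i, j) is the
#' Holm-adjusted p-value for "team i is better than team j" in the
#' metric's direction, adjusted across each row's opponents. Pairs with
#' fewer than `min_cases` paired cases are marked untestable (`NA`); the
#' diagonal is `NA` by construction. Pairs whose per-case values are
#' identical on every case yield p = 1.
#'
#' @param table A penalised score table.
#' @param metric Metric name.
#' @param min_cases Minimum number of paired cases (default 5).
#' @return Teams x teams matrix of adjusted p-values.
#' @export
significance_matrix <- function(table, metric, min_cases = 5L) {
  check_score_table(table)
  table <- drop_excluded(table)
  if (anyNA(table[[metric]]))
    stop("run apply_missing_penalties() before significance testing")
  teams <- sort(unique(table$team))
  cases <- sort(unique(table$case_id))
  percase <- tapply(table[[metric]], list(table$team, table$case_id), mean)
  percase <- percase[teams, cases, drop = FALSE]
  alt <- if (metric_directions[[metric]] > 0) "greater" else "less"

  p <- matrix(NA_real_, length(teams), length(teams),
              dimnames = list(teams, teams))
  for (i in seq_along(teams)) {
    for (j in seq_along(teams)) {
      if (i == j) next
      x <- percase[i, ]
      y <- percase[j, ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_cases) next  # untestable, stays NA
      if (all(x[ok] == y[ok])) {
        p[i, j] <- 1
        next
      }
      p[i, j] <- suppressWarnings(
        wilcox.test(x[ok], y[ok], paired = TRUE, alternative = alt)$p.value
      )
    }
    tested <- !is.na(p[i, ])
    p[i, tested] <- p.adjust(p[i, tested], method = "holm")
  }
  p
}

#' Full ranking report
#'
#' Convenience wrapper running the whole ranking stack on a penalised
#' score table: per-metric rankings, the three-metric aggregate, the BNE
#' rankings, the topology-integrative ranking, per-label rankings,
#' optional subset rankings, bootstrap stability and significance
#' matrices per metric.
#'
#' @param table A score table (penalties are applied internally).
#' @param metadata Optional metadata data frame enabling subset rankings.
#' @param replicates Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @param penalty_scope Passed to [apply_missing_penalties()].
#' @return A list of class `ranking_report`.
#' @export
ranking_report <- function(table, metadata = NULL, replicates = 1000L,
                           seed = 0L, penalty_scope = "label") {
  table <- apply_missing_penalties(table, scope = penalty_scope)
  per_metric <- list(
    dsc = metric_ranking(table, "dsc"),
    hd95 = metric_ranking(table, "hd95"),
    vs = metric_ranking(table, "vs")
  )
  aggregate <- aggregate_ranking(per_metric)
  bne <- bne_ranking(table)
  tir <- topology_integrative_ranking(per_metric$dsc, per_metric$hd95,
                                      per_metric$vs, bne$fractional)
  labels <- sort(unique(table$label_code))
  per_label <- lapply(setNames(labels, labels), function(l)
    per_label_ranking(table, l))
  subsets <- NULL
  if (!is.null(metadata)) {
    subsets <- lapply(
      setNames(nm = c("site", "quality", "pathological", "sr_method")),
      function(g) subset_ranking(table, metadata, g))
  }
  boot <- lapply(setNames(nm = c("dsc", "hd95", "vs")), function(m)
    bootstrap_stability(table, m, replicates = replicates, seed = seed))
  sig <- lapply(setNames(nm = c("dsc", "hd95", "vs")), function(m)
    significance_matrix(table, m))
  structure(
    list(per_metric_rank = per_metric, aggregate_rank = aggregate,
         bne = bne, tir_rank = tir, per_label_rank = per_label,
         subset_ranks = subsets, bootstrap = boot, significance = sig,
         seed = seed, table = table),
    class = "ranking_report"
  )
}

#' @export
print.ranking_report <- function(x, ...) {
  teams <- names(x$aggregate_rank)
  ord <- order(x$aggregate_rank)
  df <- data.frame(
    team = teams,
    dsc_rank = x$per_metric_rank$dsc[teams],
    hd95_rank = x$per_metric_rank$hd95[teams],
    vs_rank = x$per_metric_rank$vs[teams],
    final = as.integer(x$aggregate_rank),
    bne = as.integer(x$bne$overall[teams]),
    tir = as.integer(x$tir_rank[teams])
  )[ord, ]
  rownames(df) <- NULL
  cat("Ranking report (", length(teams), " teams, seed ", x$seed, ")\n",
      sep = "")
  print(df)
  invisible(x)
}
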