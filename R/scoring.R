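#' Evaluate one (ground truth, prediction) pair
#'
#' Computes every per-label score used by the ranking engine: Dice, HD95
#' (mm), volume similarity, the prediction's Betti numbers and its Betti
#' number error against the expected-topology table.
#'
#' Missing-label handling: if a label present in the ground truth is
#' absent from the prediction, the row is flagged `missing`, Dice and VS
#' are 0, and HD95/BNE are left `NA` for [apply_missing_penalties()] to
#' fill (they require the whole cohort). If a label is empty in both
#' maps, the row is flagged `both_empty` and is excluded from ranking
#' means (a warning is emitted).
#'
#' @param gt,pred [label_map()]s on identical grids (shape mismatch is a
#'   hard error; no resampling is performed).
#' @param expected Expected-topology table, as from [expected_topology()].
#' @return A data frame with one row per non-background label: columns
#'   `label_code`, `label_name`, `dsc`, `hd95`, `vs`, `b0`, `b1`, `b2`,
#'   `bne0`, `bne1`, `bne2`, `missing`, `both_empty`.
#' @export
evaluate_case <- function(gt, pred,
                          expected = expected_topology(gt$dictionary)) {
  stopifnot(inherits(gt, "label_map"), inherits(pred, "label_map"))
  if (!identical(dim(gt$grid), dim(pred$grid)))
    stop("ground truth and prediction have mismatched grid shapes; ",
         "resampling is deliberately not performed")
  spacing <- gt$spacing
  gm <- split_labels(gt)
  pm <- split_labels(pred)
  codes <- as.integer(names(gm))
  nms <- attr(gm, "tissue_names")

  rows <- vector("list", length(codes))
  for (i in seq_along(codes)) {
    code <- codes[i]
    a <- gm[[i]]
    b <- pm[[i]]
    exp_row <- expected[expected$label_code == code, , drop = FALSE]
    if (nrow(exp_row) != 1L)
      stop("expected-topology table has no entry for label ", code)
    gt_empty <- !any(a)
    pred_empty <- !any(b)

    if (gt_empty && pred_empty) {
      warning("label ", code, " empty in both maps; cell excluded from means")
      rows[[i]] <- data.frame(
        label_code = code, label_name = nms[i],
        dsc = NA_real_, hd95 = NA_real_, vs = NA_real_,
        b0 = NA_integer_, b1 = NA_integer_, b2 = NA_integer_,
        bne0 = NA_integer_, bne1 = NA_integer_, bne2 = NA_integer_,
        missing = FALSE, both_empty = TRUE, stringsAsFactors = FALSE)
      next
    }
    if (pred_empty) {
      rows[[i]] <- data.frame(
        label_code = code, label_name = nms[i],
        dsc = 0, hd95 = NA_real_, vs = 0,
        b0 = 0L, b1 = 0L, b2 = 0L,
        bne0 = NA_integer_, bne1 = NA_integer_, bne2 = NA_integer_,
        missing = TRUE, both_empty = FALSE, stringsAsFactors = FALSE)
      next
    }
    bn <- betti_numbers(b)
    bne <- setNames(abs(bn - c(exp_row$b0, exp_row$b1, exp_row$b2)),
                    c("bne0", "bne1", "bne2"))
    hd <- if (gt_empty) NA_real_ else hd95(a, b, spacing)
    rows[[i]] <- data.frame(
      label_code = code, label_name = nms[i],
      dsc = dice(a, b), hd95 = hd, vs = volume_similarity(a, b),
      b0 = bn[["b0"]], b1 = bn[["b1"]], b2 = bn[["b2"]],
      bne0 = bne[["bne0"]], bne1 = bne[["bne1"]], bne2 = bne[["bne2"]],
      missing = FALSE, both_empty = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a whole cohort into a score table
#'
#' Runs [evaluate_case()] for every (team, case) pair of a
#' [generate_cohort()] result and stacks the rows into the score table
#' consumed by the ranking module.
#'
#' @param cohort A `segtopo_cohort`.
#' @param expected Expected-topology table.
#' @return A data frame with columns `team`, `case_id` plus the
#'   [evaluate_case()] columns.
#' @export
evaluate_cohort <- function(cohort,
                            expected = expected_topology()) {
  stopifnot(inherits(cohort, "segtopo_cohort"))
  out <- list()
  for (tm in names(cohort$predictions)) {
    for (cid in names(cohort$cases)) {
      df <- evaluate_case(cohort$cases[[cid]],
                          cohort$predictions[[tm]][[cid]],
                          expected = expected)
      df <- data.frame(team = tm, case_id = cid, df,
                       stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
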