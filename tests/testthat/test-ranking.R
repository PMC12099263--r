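test_that("missing-label penalties fill cells with the worst-case rule", {
  tab <- make_score_table(c("X", "Y", "Z"), c("c1", "c2"), c(2L, 3L))
  # GM hd95 max over non-missing cells is 10mm; worst BNE0 is 7
  tab$hd95[tab$label_code == 2L] <- c(4, 10, 6, 5, 9, 8)
  tab$bne0[tab$label_code == 2L] <- c(0L, 7L, 1L, 2L, 3L, 1L)
  i <- which(tab$team == "X" & tab$case_id == "c1" & tab$label_code == 2L)
  tab$missing[i] <- TRUE
  tab$dsc[i] <- 0; tab$vs[i] <- 0
  tab$hd95[i] <- NA; tab$bne0[i] <- NA; tab$bne1[i] <- NA; tab$bne2[i] <- NA

  out <- apply_missing_penalties(tab)
  expect_identical(out$hd95[i], 20)      # 2 x max(10)
  expect_identical(out$bne0[i], 14)      # 2 x worst(7)
  expect_identical(out$dsc[i], 0)
  expect_identical(out$vs[i], 0)
  # untouched rows unchanged
  expect_identical(out$hd95[-i], tab$hd95[-i])

  # identity on tables without missing cells
  clean <- make_score_table("X", "c1", 1L)
  expect_identical(apply_missing_penalties(clean), clean)
})

test_that("label-case penalty scope restricts the pool to the same case", {
  tab <- make_score_table(c("X", "Y"), c("c1", "c2"), 2L)
  tab$hd95 <- c(NA, 3, 8, 5)  # X/c1 missing; same-case max is Y/c1 = 3
  tab$missing[1] <- TRUE
  tab$bne0[1] <- NA; tab$bne1[1] <- NA; tab$bne2[1] <- NA
  out_label <- apply_missing_penalties(tab, scope = "label")
  out_case <- apply_missing_penalties(tab, scope = "label_case")
  expect_identical(out_label$hd95[1], 16)  # 2 x 8 across cases
  expect_identical(out_case$hd95[1], 6)    # 2 x 3 within the case
})

test_that("a label missing from every submission is an explicit error", {
  tab <- make_score_table(c("X", "Y"), "c1", 5L)
  tab$missing <- TRUE
  tab$hd95 <- NA
  expect_error(apply_missing_penalties(tab), "every submission")
})

test_that("metric ranking means then ranks with direction and ties", {
  tab <- make_score_table(c("A", "B", "C"), c("c1", "c2"), 1L)
  tab$dsc <- c(0.9, 0.8, 0.7, 0.9, 0.8, 0.7)
  expect_identical(metric_ranking(tab, "dsc"),
                   c(A = 1, B = 2, C = 3))
  # lower-better direction
  tab$hd95 <- c(2, 3, 4, 2, 3, 4)
  expect_identical(metric_ranking(tab, "hd95"),
                   c(A = 1, B = 2, C = 3))
  # identical means share the mean of positions (fractional)
  tab$vs <- c(0.5, 0.5, 0.1, 0.5, 0.5, 0.1)
  expect_identical(metric_ranking(tab, "vs"),
                   c(A = 1.5, B = 1.5, C = 3))
  expect_error(metric_ranking(tab, "nope"), "unknown metric")
})

test_that("aggregate ranking uses tie-then-skip publication", {
  per_metric <- list(
    dsc = c(A = 1, B = 2, C = 3, D = 4),
    hd95 = c(A = 1, B = 3, C = 2, D = 4),
    vs = c(A = 1, B = 1, C = 3, D = 4)
  )
  # B mean 2.0, C mean ~2.67 -> order A, B, C, D
  agg <- aggregate_ranking(per_metric)
  expect_identical(as.integer(agg[c("A", "B", "C", "D")]), c(1L, 2L, 3L, 4L))

  # two teams tied on mean rank 2.0 share rank 2; the next team gets 4
  tied <- list(
    m1 = c(A = 1, B = 2, C = 2, D = 4),
    m2 = c(A = 1, B = 2, C = 2, D = 4),
    m3 = c(A = 1, B = 2, C = 2, D = 4)
  )
  agg2 <- aggregate_ranking(tied)
  expect_identical(as.integer(agg2[c("A", "B", "C", "D")]), c(1L, 2L, 2L, 4L))

  # permutation invariance
  perm <- lapply(per_metric, function(r) r[c("C", "A", "D", "B")])
  expect_identical(aggregate_ranking(perm)[names(agg)], agg,
                   ignore_attr = TRUE)
  expect_error(aggregate_ranking(list(a = c(A = 1), b = c(B = 1))),
               "different team sets")
})

test_that("BNE ranking aggregates the three dimensions", {
  tab <- make_score_table(c("A", "B", "C"), "c1", 1L)
  tab$bne0 <- c(0L, 1L, 2L)
  tab$bne1 <- c(0L, 1L, 2L)
  tab$bne2 <- c(0L, 2L, 1L)
  bb <- bne_ranking(tab)
  expect_identical(as.integer(bb$overall[c("A", "B", "C")]), c(1L, 2L, 3L))
  expect_identical(bb$per_dimension$bne2[c("A", "B", "C")],
                   c(A = 1, B = 3, C = 2))
  # best in two dimensions, mid in the third, can still win overall
  tab$bne0 <- c(0L, 1L, 2L); tab$bne1 <- c(0L, 1L, 2L); tab$bne2 <- c(1L, 0L, 2L)
  bb2 <- bne_ranking(tab)
  expect_identical(as.integer(bb2$overall[["A"]]), 1L)
  # value-averaging variant agrees on this unambiguous table
  bb3 <- bne_ranking(tab, method = "value")
  expect_identical(as.integer(bb3$overall[c("A", "B", "C")]), c(1L, 2L, 3L))
})

test_that("per-tissue BNE leaderboard ranks each label independently", {
  tab <- make_score_table(c("A", "B"), "c1", c(1L, 2L))
  # A topologically clean on label 1, B on label 2
  tab$bne0 <- c(0L, 3L, 3L, 0L)
  lb <- per_label_bne_ranking(tab)
  expect_identical(lb$`1`[lb$team == "A"], 1)
  expect_identical(lb$`2`[lb$team == "A"], 2)
  expect_identical(lb$average[lb$team == "A"], 1.5)
  expect_identical(lb$average[lb$team == "B"], 1.5)

  # a team with zero BNE everywhere is rank 1 for every tissue
  tab$bne0 <- c(0L, 1L, 0L, 2L)
  lb2 <- per_label_bne_ranking(tab)
  expect_true(all(lb2[lb2$team == "A", c("1", "2")] == 1))
  expect_identical(lb2$team[1], "A")
})

test_that("topology-integrative ranking blends four rankings equally", {
  r1 <- c(A = 1, B = 2); r2 <- r1; r3 <- r1
  expect_identical(as.integer(
    topology_integrative_ranking(r1, r2, r3, c(A = 1, B = 2))[["A"]]), 1L)
  # (5,5,5,1) mean 4.0 beats (4,4,4,8) mean 5.0
  five <- c(P = 5, Q = 4)
  tir <- topology_integrative_ranking(five, five, five, c(P = 1, Q = 8))
  expect_lt(tir[["P"]], tir[["Q"]])
  # degenerate case: BNE equal to the aggregate leaves the order unchanged
  pm <- list(dsc = c(A = 1, B = 2, C = 3), hd95 = c(A = 1, B = 2, C = 3),
             vs = c(A = 1, B = 2, C = 3))
  agg <- aggregate_ranking(pm)
  tir2 <- topology_integrative_ranking(pm$dsc, pm$hd95, pm$vs,
                                       attr(agg, "fractional"))
  expect_identical(as.integer(tir2[names(agg)]), as.integer(agg))
})

test_that("per-label ranking restricts the aggregate to one tissue", {
  tab <- make_score_table(c("A", "B"), "c1", c(1L, 2L))
  tab$dsc[tab$label_code == 1L] <- c(0.9, 0.5)
  tab$dsc[tab$label_code == 2L] <- c(0.5, 0.9)
  tab$hd95[tab$label_code == 1L] <- c(1, 3)
  tab$hd95[tab$label_code == 2L] <- c(3, 1)
  tab$vs[tab$label_code == 1L] <- c(0.9, 0.5)
  tab$vs[tab$label_code == 2L] <- c(0.5, 0.9)
  r1 <- per_label_ranking(tab, 1L)
  r2 <- per_label_ranking(tab, 2L)
  expect_identical(as.integer(r1[c("A", "B")]), c(1L, 2L))
  expect_identical(as.integer(r2[c("A", "B")]), c(2L, 1L))
  expect_error(per_label_ranking(tab, 9L), "no rows")
})

test_that("subset rankings recompute independently per group", {
  tab <- make_score_table(c("A", "B"), c("c1", "c2", "c3", "c4"), 1L)
  md <- data.frame(case_id = c("c1", "c2", "c3", "c4"),
                   site = c("s1", "s1", "s2", "s2"),
                   quality = c(3L, 3L, 1L, 1L),
                   pathological = c(FALSE, FALSE, TRUE, TRUE),
                   sr_method = "m", stringsAsFactors = FALSE)
  # A dominates site s1, B dominates site s2
  dom <- function(col, a_best) {
    tab[[col]][tab$team == "A" & tab$case_id %in% c("c1", "c2")] <<-
      if (a_best) 0.9 else 0.1
    tab[[col]][tab$team == "B" & tab$case_id %in% c("c1", "c2")] <<-
      if (a_best) 0.1 else 0.9
    tab[[col]][tab$team == "A" & tab$case_id %in% c("c3", "c4")] <<-
      if (a_best) 0.1 else 0.9
    tab[[col]][tab$team == "B" & tab$case_id %in% c("c3", "c4")] <<-
      if (a_best) 0.9 else 0.1
  }
  dom("dsc", TRUE); dom("vs", TRUE)
  tab$hd95[tab$team == "A"] <- c(1, 1, 9, 9)
  tab$hd95[tab$team == "B"] <- c(9, 9, 1, 1)

  bysite <- subset_ranking(tab, md, "site")
  expect_identical(as.integer(bysite$s1[c("A", "B")]), c(1L, 2L))
  expect_identical(as.integer(bysite$s2[c("A", "B")]), c(2L, 1L))

  # a single-value grouping reproduces the global ranking
  bymethod <- subset_ranking(tab, md, "sr_method")
  glob <- aggregate_ranking(list(dsc = metric_ranking(tab, "dsc"),
                                 hd95 = metric_ranking(tab, "hd95"),
                                 vs = metric_ranking(tab, "vs")))
  expect_identical(bymethod$m[names(glob)], glob, ignore_attr = TRUE)

  # quality grouping yields one leaderboard per observed rating
  byq <- subset_ranking(tab, md, "quality")
  expect_identical(sort(names(byq)), c("1", "3"))
})

test_that("rankings are invariant to positive scaling of HD95", {
  tab <- make_score_table(c("A", "B", "C"), c("c1", "c2"), c(1L, 2L))
  set.seed(41)
  tab$hd95 <- runif(nrow(tab), 1, 10)
  r1 <- metric_ranking(tab, "hd95")
  tab2 <- tab
  tab2$hd95 <- tab2$hd95 * 7.3
  expect_identical(metric_ranking(tab2, "hd95"), r1)
})

test_that("penalty filling never improves a team's mean on any metric", {
  set.seed(42)
  tab <- make_score_table(c("A", "B", "C"), paste0("c", 1:4), c(1L, 2L))
  tab$dsc <- runif(nrow(tab), 0.4, 0.9)
  tab$vs <- runif(nrow(tab), 0.5, 1)
  tab$hd95 <- runif(nrow(tab), 1, 5)
  for (k in c("bne0", "bne1", "bne2")) tab[[k]] <- sample(0:3, nrow(tab), TRUE)
  miss <- which(tab$team == "B" & tab$case_id == "c2" & tab$label_code == 1L)
  before <- apply_missing_penalties(tab)  # identity (no missing yet)
  tab$missing[miss] <- TRUE
  tab$dsc[miss] <- 0; tab$vs[miss] <- 0
  tab$hd95[miss] <- NA
  for (k in c("bne0", "bne1", "bne2")) tab[[k]][miss] <- NA
  after <- apply_missing_penalties(tab)
  for (m in c("dsc", "vs")) {
    expect_lte(mean(after[[m]][after$team == "B"]),
               mean(before[[m]][before$team == "B"]))
  }
  for (m in c("hd95", "bne0", "bne1", "bne2")) {
    expect_gte(mean(after[[m]][after$team == "B"]),
               mean(before[[m]][before$team == "B"]))
  }
})

test_that("fractional ranks agree with the mean-of-positions oracle", {
  set.seed(43)
  for (i in 1:20) {
    means <- sample(round(runif(6), 1), 6, replace = TRUE)
    tab <- make_score_table(paste0("t", 1:6), "c1", 1L)
    tab$hd95 <- means
    got <- metric_ranking(tab, "hd95")
    expect_equal(unname(got[paste0("t", 1:6)]),
                 oracle_fractional_ranks(means))
  }
})

test_that("bootstrap stability is seeded and detects dominance", {
  tab <- make_score_table(c("A", "B", "C"), paste0("c", 1:6), 1L)
  tab$dsc[tab$team == "A"] <- 0.95
  tab$dsc[tab$team == "B"] <- 0.8
  tab$dsc[tab$team == "C"] <- 0.6
  bs1 <- bootstrap_stability(tab, "dsc", replicates = 200, seed = 7)
  bs2 <- bootstrap_stability(tab, "dsc", replicates = 200, seed = 7)
  expect_identical(bs1$ranks, bs2$ranks)
  # a team strictly best on every case is rank 1 in all replicates
  expect_true(all(bs1$ranks[, "A"] == 1))
  # identical teams: uniformly tied ranks
  tied <- tab
  tied$dsc <- 0.5
  bst <- bootstrap_stability(tied, "dsc", replicates = 50, seed = 1)
  expect_true(all(bst$ranks == 2))
  expect_error(bootstrap_stability(tab, "dsc", replicates = 0), "replicates")
})

test_that("bootstrap distributions are stable across seeds", {
  set.seed(44)
  tab <- make_score_table(c("A", "B"), paste0("c", 1:10), 1L)
  tab$dsc <- runif(nrow(tab))
  f1 <- mean(bootstrap_stability(tab, "dsc", 400, seed = 1)$ranks[, "A"] == 1)
  f2 <- mean(bootstrap_stability(tab, "dsc", 400, seed = 2)$ranks[, "A"] == 1)
  expect_lt(abs(f1 - f2), 0.15)  # binomial error at n = 400
})

test_that("significance matrix flags dominant pairs and only those", {
  # team A better than B on all 20 cases by a margin -> significant;
  # exact signed-rank null: P(all 20 signs positive) = 2^-20
  tab <- make_score_table(c("A", "B"), paste0("c", 1:20), 1L)
  tab$dsc[tab$team == "A"] <- seq(0.80, 0.99, length.out = 20)
  tab$dsc[tab$team == "B"] <- seq(0.60, 0.79, length.out = 20)
  p <- significance_matrix(tab, "dsc")
  expect_lt(p["A", "B"], 0.05)
  expect_gt(p["B", "A"], 0.05)
  expect_true(is.na(p["A", "A"]))

  # all teams identical -> nothing significant
  same <- make_score_table(c("A", "B", "C"), paste0("c", 1:8), 1L)
  p2 <- significance_matrix(same, "dsc")
  expect_true(all(p2[!is.na(p2)] == 1))

  # fewer than 5 cases -> untestable
  tiny <- make_score_table(c("A", "B"), paste0("c", 1:3), 1L)
  expect_true(all(is.na(significance_matrix(tiny, "dsc"))))

  # direction flips for lower-better metrics
  tab$hd95[tab$team == "A"] <- 1
  tab$hd95[tab$team == "B"] <- 2 + seq(0, 1, length.out = 20)
  ph <- significance_matrix(tab, "hd95")
  expect_lt(ph["A", "B"], 0.05)
})

test_that("Holm adjustment never lowers p-values", {
  set.seed(45)
  tab <- make_score_table(paste0("t", 1:4), paste0("c", 1:8), 1L)
  tab$dsc <- runif(nrow(tab))
  padj <- significance_matrix(tab, "dsc")
  # recompute raw p-values and compare row-wise
  percase <- tapply(tab$dsc, list(tab$team, tab$case_id), mean)
  for (i in rownames(padj)) for (j in colnames(padj)) {
    if (i == j) next
    raw <- suppressWarnings(
      wilcox.test(percase[i, ], percase[j, ], paired = TRUE,
                  alternative = "greater")$p.value)
    expect_gte(padj[i, j], raw - 1e-12)
  }
})
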