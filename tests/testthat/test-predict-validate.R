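# prediction combination, validation reports, tuning grid

test_that("the convex combination honors its boundary identities", {
  expect_equal(combine_gi50(5.5, 4.2, 1), 5.5)
  expect_equal(combine_gi50(5.5, 4.2, 0), 4.2)
  expect_equal(combine_gi50(NA, 6.1, 0.7), 6.1)
  expect_equal(combine_gi50(6.0, 5.0, 0.5), 5.5)
  expect_error(combine_gi50(5, 5, 1.2), "S must lie")
  expect_error(combine_gi50(5, 5, -0.1), "S must lie")
})

test_that("the combined value never leaves the parent interval", {
  set.seed(3)
  fp <- runif(500, 3, 9); cl <- runif(500, 3, 9); S <- runif(500)
  g <- combine_gi50(fp, cl, S)
  expect_true(all(g >= pmin(fp, cl) - 1e-12))
  expect_true(all(g <= pmax(fp, cl) + 1e-12))
})

test_that("training compounds reproduce their experimental values exactly", {
  tr <- random_training(n = 25, d = 6, missing_rate = 0.25, seed = 61)
  model <- suppressWarnings(build_model(tr$desc, tr$act, cl_params(N = 6)))
  preds <- predict_batch(model$train_desc, model)
  expect_true(all(preds$S == 1))
  exp_m <- act_values(model$train_act)
  have <- !is.na(exp_m[cbind(match(preds$query_id, rownames(exp_m)),
                             match(preds$cell_line, colnames(exp_m)))])
  expect_equal(preds$gi50[have],
               exp_m[cbind(match(preds$query_id, rownames(exp_m)),
                           match(preds$cell_line, colnames(exp_m)))][have])
})

test_that("predict_batch emits one row per query and active cell line", {
  tr <- random_training(n = 15, d = 5, missing_rate = 0, seed = 71)
  model <- build_model(tr$desc, tr$act, cl_params(N = 5))
  q <- tr$desc[1:4, , drop = FALSE]
  p1 <- predict_batch(q, model)
  expect_equal(nrow(p1), 4L * ncol(tr$act))
  expect_identical(predict_batch(q, model), p1)   # deterministic
  expect_error(predict_batch(q[, 1:2, drop = FALSE], model),
               "lacks model descriptor")
})

test_that("where the similarity match lacks data the template value stands", {
  desc <- dm(rbind(c(1, 2), c(9, 9)), ids = c("near", "far"))
  a <- rbind(c(NA, 6.0), c(5.05, 7.0))
  act <- am(a, ids = c("near", "far"))
  model <- build_model(desc, act, cl_params(N = 2, G = "a"))
  p <- predict_batch(dm(rbind(q1 = c(1, 2)), ids = "q1"), model)
  r1 <- p[p$cell_line == "L01", ]
  expect_true(is.na(r1$gi50_fp))
  expect_equal(r1$gi50, r1$gi50_cl)
})

test_that("dtv aggregates match a hand computation with missing data", {
  # 3 compounds x 2 lines, one experimental value missing -> 5 pairs
  pred <- rbind(c(5.0, 6.0), c(4.5, 7.0), c(6.0, 6.5))
  rownames(pred) <- c("c1", "c2", "c3"); colnames(pred) <- c("L1", "L2")
  exp_ <- rbind(c(5.2, 6.0), c(4.0, NA), c(7.0, 6.0))
  act <- am(exp_, ids = c("c1", "c2", "c3"), lines = c("L1", "L2"),
            panels = c(L1 = "P1", L2 = "P2"))
  rep_ <- dtv_report(pred, act)
  expect_equal(rep_$n_pairs, 5L)
  # |DTV|: c1 (0.2, 0), c2 (0.5), c3 (1.0, 0.5)
  expect_equal(rep_$overall, mean(c(0.2, 0, 0.5, 1.0, 0.5)))
  expect_equal(unname(rep_$per_compound[c("c1", "c2", "c3")]),
               c(0.1, 0.5, 0.75))
  expect_equal(unname(rep_$per_cell_line[c("L1", "L2")]),
               c(mean(c(0.2, 0.5, 1.0)), 0.25))
  expect_equal(unname(rep_$per_panel[c("P1", "P2")]),
               c(mean(c(0.2, 0.5, 1.0)), 0.25))
  expect_equal(rep_$within1_fraction, 1)
  # aggregates recompute from the raw pairs
  expect_equal(rep_$overall, mean(rep_$pairs$dtv))
  expect_equal(rep_$within1_fraction, mean(rep_$pairs$dtv <= 1))
})

test_that("perfect predictions and single-pair cases behave as stated", {
  act <- am(matrix(c(5, 6), 1, 2), ids = "c1")
  perfect <- dtv_report(matrix(c(5, 6), 1, 2,
                               dimnames = list("c1", c("L01", "L02"))), act)
  expect_equal(perfect$overall, 0)
  expect_equal(perfect$within1_fraction, 1)
  one <- dtv_report(matrix(5.0, 1, 1, dimnames = list("c1", "L01")),
                    am(matrix(6.2, 1, 1), ids = "c1"))
  expect_equal(one$overall, 1.2)
  expect_equal(one$within1_fraction, 0)
  expect_error(dtv_report(matrix(5, 1, 1, dimnames = list("zz", "L01")),
                          act), "no \\(compound")
})

test_that("per-panel means are unweighted means of cell-line means", {
  set.seed(8)
  pred <- matrix(runif(12, 4, 8), 3, 4,
                 dimnames = list(c("c1", "c2", "c3"), sprintf("L%02d", 1:4)))
  a <- matrix(runif(12, 4, 8), 3, 4)
  a[2, 3] <- NA
  act <- am(a, ids = c("c1", "c2", "c3"), lines = sprintf("L%02d", 1:4),
            panels = setNames(c("P1", "P1", "P1", "P2"), sprintf("L%02d", 1:4)))
  rep_ <- dtv_report(pred, act)
  expect_equal(unname(rep_$per_panel["P1"]),
               mean(rep_$per_cell_line[c("L01", "L02", "L03")]))
})

test_that("the default grid enumerates 18 runs with run 1 at (240, 50, a)", {
  g <- default_tuning_grid()
  expect_equal(nrow(g), 18L)
  expect_equal(anyDuplicated(g[, c("N", "Z", "G")]), 0L)
  expect_equal(g$N[g$run_id == 1], 240L)
  expect_equal(g$Z[g$run_id == 1], 50)
  expect_identical(g$G[g$run_id == 1], "a")
  expect_setequal(unique(g$N), c(240L, 360L, 480L, 600L, 720L, 800L))
  expect_setequal(unique(g$G), c("a", "b", "c"))
})

test_that("tune evaluates every run and picks argmin mean deviation", {
  tr <- random_training(n = 30, d = 8, missing_rate = 0.1, seed = 81)
  vids <- rownames(tr$desc)[c(3, 9, 15, 21)]
  grid <- data.frame(run_id = 1:4, N = c(4L, 8L, 4L, 8L), Z = 50,
                     G = c("a", "a", "c", "c"), stringsAsFactors = FALSE)
  tuned <- suppressWarnings(tune(grid, tr$desc, tr$act, vids))
  expect_equal(nrow(tuned$runs), 4L)
  expect_false(anyNA(tuned$runs$mean_dtv))
  expect_equal(tuned$best_overall,
               tuned$runs$run_id[which.min(tuned$runs$mean_dtv)])
  expect_true(all(tuned$best_per_cell_line$run_id %in% grid$run_id))
  expect_true(all(tuned$best_per_panel$run_id %in% grid$run_id))
  # deterministic re-run
  tuned2 <- suppressWarnings(tune(grid, tr$desc, tr$act, vids))
  expect_identical(tuned$runs, tuned2$runs)
  # singleton grid is trivially best everywhere
  single <- suppressWarnings(tune(grid[2, ], tr$desc, tr$act, vids))
  expect_equal(single$best_overall, 2L)
  expect_true(all(single$best_per_panel$run_id == 2L))
  expect_error(tune(grid[0, ], tr$desc, tr$act, vids), "empty")
  expect_error(tune(grid, tr$desc, tr$act, "ghost"), "validation id")
})

test_that("fp-only report scores the transfer module alone", {
  tr <- random_training(n = 20, d = 6, missing_rate = 0.2, seed = 91)
  model <- suppressWarnings(build_model(tr$desc, tr$act, cl_params(N = 6)))
  vids <- rownames(tr$desc)[1:5]
  rep_ <- fp_only_report(model$train_desc[vids, , drop = FALSE], model,
                         model$train_act[vids, , drop = FALSE])
  # validation compounds sit in the training set: self-transfer, zero error
  expect_equal(rep_$overall, 0)
  expect_true(all(rep_$per_compound == 0))
})

test_that("the validation sample is reproducible from its seed", {
  ids <- sprintf("c%03d", 1:200)
  s1 <- validation_sample(ids, fraction = 0.05, seed = 42)
  s2 <- validation_sample(ids, fraction = 0.05, seed = 42)
  expect_identical(s1$ids, s2$ids)
  expect_length(s1$ids, 10L)
  expect_equal(s1$seed, 42)
})
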