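# activity binning, template construction, profile matching

test_that("bin layout: 42 bins, 40 regular of width 0.1 covering [4, 8]", {
  bins <- activity_bins()
  expect_equal(nrow(bins), 42L)
  regular <- bins[is.finite(bins$lower) & is.finite(bins$upper), ]
  expect_equal(nrow(regular), 40L)
  expect_equal(regular$upper - regular$lower, rep(0.1, 40))
  expect_equal(min(regular$lower), 4)
  expect_equal(max(regular$upper), 8)
  expect_equal(bins$assigned[bins$index == 0], 4)
  expect_equal(bins$assigned[bins$index == 41], 8)
  expect_equal(bins$assigned[bins$index == 14], 5.35)  # [5.3, 5.4) midpoint
})

test_that("assign_bin matches a brute-force scan over the bin edges", {
  expect_equal(assign_bin(5.25), 13L)
  expect_equal(assign_bin(3.2), 0L)
  expect_equal(assign_bin(8.0), 40L)        # 8.0 stays in the regular range
  expect_equal(assign_bin(8.0000001), 41L)
  set.seed(2)
  vals <- c(runif(200, 3, 9), seq(4, 8, by = 0.1), 3.999999, 7.95)
  expect_equal(assign_bin(vals),
               vapply(vals, bf_assign_bin, integer(1)))
  expect_error(assign_bin(c(5, NA)), "missing")
})

test_that("hand-binned toy set produces the expected member counts", {
  desc <- dm(matrix(runif(8, 1, 2), 4, 2))
  act <- am(matrix(c(4.05, 4.05, 7.2, 9.0), 4, 1), lines = "L1",
            panels = c(L1 = "P1"))
  tpl <- build_templates(desc, act, cl_params(N = 2))
  cnt <- tpl$counts$L1
  expect_equal(unname(cnt[c("1", "33", "41")]), c(2L, 1L, 1L))
  expect_equal(sum(cnt), 4L)
  expect_equal(sum(cnt[setdiff(names(cnt), c("1", "33", "41"))]), 0L)
})

test_that("member counts conserve the non-missing activities per cell line", {
  for (seed in 1:5) {
    tr <- random_training(n = 25, d = 5, missing_rate = 0.3, seed = seed)
    tpl <- suppressWarnings(build_templates(tr$desc, tr$act, cl_params(N = 5)))
    for (cl in names(tpl$counts))
      expect_equal(sum(tpl$counts[[cl]]),
                   sum(!is.na(act_values(tr$act)[, cl])))
  }
})

test_that("zero-variance templates get the floored sigma, mu exact", {
  desc <- dm(matrix(c(3, 3, 50, 50), 2, 2), descs = c("dA", "dB"))
  act <- am(matrix(c(5.0, 5.0), 2, 1), lines = "L1", panels = c(L1 = "P1"))
  tpl <- build_templates(desc, act, cl_params(N = 2))
  i <- as.character(assign_bin(5.0))
  expect_equal(tpl$mu$L1[i, "dA"], 3)
  expect_equal(tpl$sigma$L1[i, "dA"], 1e-6 * 3)   # floor 1e-6 * max(|mu|, 1)
  expect_equal(tpl$sigma$L1[i, "dB"], 1e-6 * 50)
  desc1 <- dm(matrix(0.2, 1, 1))
  act1 <- am(matrix(6, 1, 1), lines = "L1", panels = c(L1 = "P1"))
  tpl1 <- build_templates(desc1, act1, cl_params(N = 1))
  expect_equal(unname(tpl1$sigma$L1[as.character(assign_bin(6)), 1]), 1e-6)
})

test_that("template construction is invariant to training row order", {
  tr <- random_training(n = 20, d = 4, seed = 31)
  t1 <- suppressWarnings(build_templates(tr$desc, tr$act, cl_params(N = 4)))
  perm <- rev(seq_len(nrow(tr$desc)))
  t2 <- suppressWarnings(build_templates(tr$desc[perm, , drop = FALSE],
                                         tr$act[perm, , drop = FALSE],
                                         cl_params(N = 4)))
  for (cl in names(t1$mu)) {
    expect_equal(t1$mu[[cl]], t2$mu[[cl]])
    expect_equal(t1$sigma[[cl]], t2$sigma[[cl]])
  }
})

test_that("a cell line without any activity data is excluded with warning", {
  desc <- dm(matrix(runif(4), 2, 2))
  a <- cbind(c(5, 6), c(NA, NA))
  act <- am(a, lines = c("LIVE", "DEAD"),
            panels = c(LIVE = "P1", DEAD = "P1"))
  expect_warning(tpl <- build_templates(desc, act, cl_params(N = 2)), "DEAD")
  expect_identical(tpl$excluded, "DEAD")
  expect_false("DEAD" %in% names(tpl$mu))
})

test_that("match score modes agree with closed forms and hand counts", {
  mu <- c(a = 1, b = 2, c = 3, d = 4)
  sigma <- c(a = 0.1, b = 0.1, c = 0.1, d = 0.1)
  # query equal to mu scores 1 in every mode
  for (g in c("a", "b", "c"))
    expect_equal(template_match_score(mu, mu, sigma, G = g), 1)
  # mode a: 2 of 4 inside the mean +/- sd window
  q <- c(a = 1.05, b = 2.05, c = 3.5, d = 5)
  expect_equal(template_match_score(q, mu, sigma, G = "a"), 0.5)
  # mode b at one sd: exp(-1/2); mode c: exp(-1/8)
  q1 <- c(a = 1.1); m1 <- c(a = 1); s1 <- c(a = 0.1)
  expect_equal(template_match_score(q1, m1, s1, G = "b"), exp(-0.5))
  expect_equal(template_match_score(q1, m1, s1, G = "c"), exp(-1 / 8))
})

test_that("mode-a score equals the brute-force inside counter", {
  set.seed(7)
  for (rep in 1:50) {
    d <- sample(2:8, 1)
    nm <- sprintf("d%d", seq_len(d))
    mu <- setNames(runif(d, -2, 2), nm)
    sigma <- setNames(runif(d, 0.05, 1), nm)
    q <- setNames(runif(d, -3, 3), nm)
    q[runif(d) < 0.2] <- NA
    sel <- sample(nm, sample(seq_len(d), 1))
    got <- template_match_score(q, mu, sigma, selected = sel, G = "a")
    expect_equal(got, bf_score_a(q, mu, sigma, sel))
  }
})

test_that("modes b and c never reward moving a coordinate away from mu", {
  mu <- c(x = 0, y = 1); sigma <- c(x = 1, y = 2)
  for (g in c("b", "c")) {
    steps <- seq(0, 3, by = 0.25)
    scores <- vapply(steps, function(s)
      template_match_score(c(x = s, y = 1), mu, sigma, G = g), 0)
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("cl_predict returns the exhaustive-argmax template per cell line", {
  tr <- random_training(n = 40, d = 6, missing_rate = 0, seed = 41)
  params <- cl_params(N = 6, G = "b")
  tpl <- build_templates(tr$desc, tr$act, params)
  q <- unclass(tr$desc)[3, ]
  got <- cl_predict(q, tpl)
  for (i in seq_len(nrow(got))) {
    cl <- got$cell_line[i]
    sel <- tpl$selected[[cl]]
    scores <- vapply(1:42, function(b) {
      if (tpl$counts[[cl]][b] < 1) return(NA_real_)
      template_match_score(q, tpl$mu[[cl]][b, ], tpl$sigma[[cl]][b, ],
                           selected = sel, G = "b")
    }, 0)
    expect_equal(got$score[i], max(scores, na.rm = TRUE))
    expect_equal(got$gi50_cl[i], tpl$bins$assigned[got$bin[i] + 1L])
  }
})

test_that("score ties break toward more members, then the lower bin", {
  # two identical one-member templates at bins 10 and 20, plus a
  # two-member template at bin 30 with the same profile
  desc <- dm(matrix(c(1, 1, 1, 1), 4, 1), descs = "d1")
  act <- am(matrix(c(4.95, 5.95, 6.95, 6.95), 4, 1), lines = "L1",
            panels = c(L1 = "P1"))
  tpl <- build_templates(desc, act, cl_params(N = 1, G = "a"))
  got <- cl_predict(c(d1 = 1), tpl)
  expect_equal(got$bin, 30L)                 # member count 2 beats the ties
  # remove the two-member bin: lower bin index wins among equals
  tpl2 <- build_templates(desc[1:2, , drop = FALSE],
                          act[1:2, , drop = FALSE], cl_params(N = 1, G = "a"))
  expect_equal(cl_predict(c(d1 = 1), tpl2)$bin, 10L)
  # rerunning gives the identical result
  expect_identical(cl_predict(c(d1 = 1), tpl2), cl_predict(c(d1 = 1), tpl2))
})

test_that("a query at a template mean wins that bin outright", {
  tr <- random_training(n = 30, d = 5, missing_rate = 0, seed = 51)
  tpl <- build_templates(tr$desc, tr$act, cl_params(N = 5, G = "a"))
  cl <- names(tpl$mu)[1]
  live <- which(tpl$counts[[cl]] >= 1)
  b <- live[length(live) %/% 2 + 1]
  q <- tpl$mu[[cl]][b, ]
  got <- cl_predict(q, tpl)
  row <- got[got$cell_line == cl, ]
  expect_equal(row$score, 1)
})
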