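test_that("evaluate_case scores the seven structures plus their mean", {
  ph <- fixture_phantom("normal")
  row <- evaluate_case(ph$truth, ph$truth)
  expect_equal(as.numeric(row), rep(1, 8))
  expect_equal(names(row), c(structure_names(), "overall"))

  empty <- label_volume(array(0L, dim(ph$truth$data)), ph$truth$spacing)
  row0 <- evaluate_case(empty, ph$truth)
  expect_equal(as.numeric(row0[1:7]), rep(0, 7))

  # six structures perfect, PA 0.3 -> overall (6 + 0.3) / 7
  row2 <- c(rep(1, 6), 0.3)
  tab <- score_table(list(c(row2, mean(row2))))
  expect_equal(tab$overall, 0.9, tolerance = 1e-12)
})

test_that("summarize_scores gives column means and sample deviations", {
  rows <- list(c(0.8, rep(0.5, 6), mean(c(0.8, rep(0.5, 6)))),
               c(0.6, rep(0.5, 6), mean(c(0.6, rep(0.5, 6)))))
  tab <- score_table(rows)
  s <- summarize_scores(tab)
  expect_equal(s["LV", "mean"], 0.7)
  expect_equal(s["LV", "sd"], sd(c(0.8, 0.6)), tolerance = 1e-12)
  expect_equal(s["RV", "sd"], 0)
  one <- score_table(rows[1])
  s1 <- summarize_scores(one)
  expect_equal(s1["LV", "mean"], 0.8)
  expect_true(is.na(s1["LV", "sd"]))
  expect_error(summarize_scores(tab[0, ]), "empty")
})

test_that("paired_t_test matches the closed form and stats::t.test", {
  r <- paired_t_test(c(2, 3, 5), c(1, 2, 3))
  expect_equal(r$t, 4, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # antisymmetry
  r2 <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r2$t, -r$t)
  # degenerate pairing
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  # reference implementation on 50 random pairs
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    a <- runif(n); b <- runif(n)
    mine <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("score tables are validated and written as CSV", {
  expect_error(score_table(list(c(rep(0.5, 7), 0.9))), "overall")
  tab <- score_table(list(c(rep(0.5, 7), 0.5)), case_ids = "case1")
  path <- tempfile(fileext = ".csv")
  write_scores(tab, path, summary_path = sub("csv$", "summary.csv", path))
  got <- read.csv(path, row.names = 1)
  expect_equal(colnames(got), c(structure_names(), "overall"))
  expect_equal(got["case1", "Myo"], 0.5)
})
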