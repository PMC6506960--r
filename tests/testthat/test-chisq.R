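test_that("contingency tables stack per-sample rows of one initial state", {
  tabs <- spleen_transition_counts()
  ct <- build_contingency(tabs, "A")
  expect_equal(dim(ct), c(3, 4))
  expect_equal(unname(ct[1, ]), c(159513, 12082, 7505, 16928))
  expect_equal(unname(ct[2, ]), c(170787, 13663, 9638, 18661))
  expect_equal(unname(ct[3, ]), c(209282, 13179, 8953, 17408))
  expect_equal(rownames(ct), c("STL001", "STL002", "STL003"))

  expect_error(build_contingency(tabs[1], "A"), "at least 2")
  zero <- transition_table(matrix(c(rep(0, 4), rep(1, 12)), 4, byrow = TRUE),
                           "Z")
  expect_error(build_contingency(list(zero, tabs[[1]]), "A"), "Z")

  # identical tables stack into equal rows, and row sums are conserved
  ct2 <- build_contingency(list(tabs[[1]], tabs[[1]]), "B")
  expect_equal(ct2[1, ], ct2[2, ])
  expect_equal(unname(rowSums(ct2)), rep(sum(tabs$STL001$counts["B", ]), 2))
})

test_that("Pearson test matches the brute-force formula oracle", {
  r <- pearson_chi_square(matrix(c(10, 20, 30, 40), 2, byrow = TRUE))
  o <- chisq_oracle(matrix(c(10, 20, 30, 40), 2, byrow = TRUE))
  expect_equal(r$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(r$df, 1)

  set.seed(31)
  for (i in 1:200) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    m <- matrix(rpois(nr * nc, lambda = 20) + 1, nr, nc)
    r <- pearson_chi_square(m)
    o <- chisq_oracle(m)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(r$df, o$df)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("proportional rows give a zero statistic", {
  m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, byrow = TRUE)
  r <- pearson_chi_square(m)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  cc <- cell_contributions(m)
  expect_equal(max(abs(cc$cells)), 0, tolerance = 1e-12)
})

test_that("contribution decomposition is exact", {
  tabs <- spleen_transition_counts()
  for (st in meth_states()) {
    ct <- build_contingency(tabs, st)
    r <- pearson_chi_square(ct)
    cc <- cell_contributions(ct)
    expect_equal(sum(cc$cells), r$statistic, tolerance = 1e-9)
    expect_equal(sum(cc$by_sample), r$statistic, tolerance = 1e-9)
    expect_equal(sum(cc$by_terminal_state), r$statistic, tolerance = 1e-9)
  }
})

test_that("count scaling applies the stated rounding rules", {
  ct <- matrix(c(159513, 15, 24, 26), 2)
  expect_equal(scale_counts(ct, 10)[1, 1], 15951)  # half away from zero
  expect_equal(scale_counts(matrix(25, 1, 1), 10), matrix(3, 1, 1))
  expect_equal(scale_counts(matrix(25, 1, 1), 10, "floor"), matrix(2, 1, 1))
  expect_equal(scale_counts(ct, 1), ct)
  expect_error(scale_counts(ct, -1), "positive")

  # homogeneity: without rounding the statistic scales exactly as 1/n
  set.seed(37)
  m <- matrix(rpois(8, 1000), 2)
  for (d in c(10, 100, 7.5)) {
    expect_equal(pearson_chi_square(scale_counts(m, d, "none"))$statistic,
                 pearson_chi_square(m)$statistic / d, tolerance = 1e-12)
  }
})

test_that("sensitivity scan weakens significance as counts shrink", {
  tabs <- spleen_transition_counts()
  scan <- sensitivity_scan(tabs, "A")
  tab <- sensitivity_table(scan)
  expect_equal(tab$divisor, c(1, 10, 100, 1000))
  expect_equal(tab$statistic[1], 1323.14, tolerance = 1e-4)
  expect_true(all(diff(tab$p_value) >= 0))
  expect_gt(tab$p_value[4], 0.05)  # at /1000 the difference dissolves

  # synthetic three-sample data, unrounded: p non-decreasing by construction
  set.seed(41)
  syn <- lapply(1:3, function(i) {
    tr <- random_track(600, sample_id = paste0("S", i))
    count_transitions(build_state_pairs(tr), paste0("S", i))
  })
  tab2 <- sensitivity_table(sensitivity_scan(syn, "A", c(1, 10, 100), "none"))
  expect_true(all(diff(tab2$p_value) >= 0))
})

test_that("pairwise tests reproduce the omnibus machinery on row subsets", {
  tabs <- spleen_transition_counts()
  pw <- pairwise_chi_square(tabs, "A")
  expect_length(pw, 3)
  expect_named(pw, c("STL001.vs.STL002", "STL001.vs.STL003",
                     "STL002.vs.STL003"))
  ct <- build_contingency(tabs, "A")
  for (nm in names(pw)) {
    ids <- strsplit(nm, ".vs.", fixed = TRUE)[[1]]
    o <- chisq_oracle(ct[ids, ])
    expect_equal(pw[[nm]]$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(pw[[nm]]$df, 3)
  }

  ident <- pairwise_chi_square(list(tabs[[1]], tabs[[1]]), "D")
  expect_equal(ident[[1]]$statistic, 0, tolerance = 1e-9)
  expect_equal(ident[[1]]$p_value, 1)
})

test_that("degenerate scaled tables are flagged, not fatal", {
  small <- lapply(1:2, function(i)
    transition_table(matrix(c(3, 1, 1, 1), 4, 4)[1:4, 1:4] * 0 +
                       matrix(rep(c(3, 1, 1, 1), 4), 4, byrow = TRUE),
                     paste0("S", i)))
  scan <- sensitivity_scan(small, "A", c(1, 1000))
  expect_true(is.na(scan[["1000"]]$statistic))
  expect_true(scan[["1000"]]$flag_min_expected)
})
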