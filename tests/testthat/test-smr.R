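test_that("SMR segmentation finds maximal same-state runs", {
  tr <- track_from_states(c("A", "A", "A", "B", "D", "D"),
                          positions = c(10L, 12L, 20L, 30L, 40L, 44L))
  smr <- segment_smrs(tr)
  expect_equal(nrow(smr), 2)
  expect_equal(smr$state, c("A", "D"))
  expect_equal(smr$first_position, c(10L, 40L))
  expect_equal(smr$last_position, c(20L, 44L))
  expect_equal(smr$cg_count, c(3L, 2L))
  expect_equal(smr$length, c(10L, 4L))

  # NA breaks runs: D,NA,D yields two singletons, neither reportable
  expect_equal(nrow(segment_smrs(track_from_states(c("D", NA, "D")))), 0)
  # NA-transparent mode bridges them
  bridged <- segment_smrs(track_from_states(c("D", NA, "D")), na_breaks = FALSE)
  expect_equal(bridged$cg_count, 2L)

  # adjacent CGCG: the minimum reportable length is 2 bp
  cgcg <- track_from_states(c("D", "D"), positions = c(100L, 102L))
  expect_equal(segment_smrs(cgcg)$length, 2L)

  expect_error(segment_smrs(example_track()), "annotate")
})

test_that("segmentation agrees with the brute-force run-length oracle", {
  set.seed(43)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    states <- random_states(n, na_prob = 0.25)
    pos <- cumsum(sample(2:100, n, replace = TRUE))
    tr <- track_from_states(states, positions = pos)
    got <- as.data.frame(segment_smrs(tr))[, c("state", "first_position",
                                               "last_position", "cg_count",
                                               "length")]
    want <- smr_oracle(states, pos)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("SMRs are disjoint and cover exactly the long-enough runs", {
  set.seed(47)
  tr <- random_track(500, na_prob = 0.2)
  smr <- segment_smrs(tr, min_count = 2)
  # member sites of distinct SMRs never overlap
  if (nrow(smr) > 1)
    expect_true(all(smr$first_position[-1] > smr$last_position[-nrow(smr)]))
  # every site inside an SMR shares its state
  for (k in seq_len(nrow(smr))) {
    inside <- tr$position >= smr$first_position[k] &
      tr$position <= smr$last_position[k]
    expect_true(all(tr$state[inside] == smr$state[k]))
    # length equals the sum of member forward distances
    expect_equal(sum(tr$distance[inside][-sum(inside)]), smr$length[k])
  }
  # covered CG sites = all non-NA sites minus those in short runs
  r <- rle(ifelse(is.na(tr$state), "NA", tr$state))
  expect_equal(sum(smr$cg_count),
               sum(r$lengths[r$values != "NA" & r$lengths >= 2]))
})

test_that("six-number summaries trim one maximum and interpolate quartiles", {
  smr <- structure(data.frame(state = "A", chrom = "chr1",
                              first_position = c(1, 100, 200, 300),
                              last_position = c(2, 101, 201, 301),
                              cg_count = c(2, 2, 3, 10),
                              length = c(1, 1, 1, 1)),
                   class = c("smr_set", "data.frame"))
  s <- summarize_smrs(smr, "A", "count")
  expect_equal(unname(s[c("min", "median", "max", "n")]), c(2, 2, 3, 3))
  expect_equal(unname(s["mean"]), mean(c(2, 2, 3)), tolerance = 1e-12)

  # without trimming the maximum stays
  s2 <- summarize_smrs(smr, "A", "count", drop_largest = FALSE)
  expect_equal(unname(s2["max"]), 10)

  # a single SMR trims to the empty sentinel
  one <- smr[1, ]
  class(one) <- class(smr)
  expect_equal(unname(summarize_smrs(one, "A", "count")["n"]), 0)
  expect_true(is.na(summarize_smrs(one, "A", "count")["median"]))
  # no SMRs of the state: sentinel, not an error
  expect_equal(unname(summarize_smrs(smr, "B", "count")["n"]), 0)

  # oracle recomputation on a larger set: trimmed type-7 quantiles
  set.seed(53)
  tr <- random_track(800)
  sm <- segment_smrs(tr)
  for (st in unique(sm$state)) {
    x <- sort(sm$cg_count[sm$state == st])
    x <- x[-length(x)]
    if (length(x) == 0) next
    got <- summarize_smrs(sm, st, "count")
    expect_equal(unname(got[c("min", "q1", "median", "mean", "q3", "max")]),
                 unname(c(min(x), quantile(x, c(.25, .5, .75))[1],
                          median(x), mean(x), quantile(x, .75)[[1]], max(x))),
                 tolerance = 1e-12)
  }
})

test_that("the SMR report covers every sample-state-metric cell", {
  set.seed(59)
  smrs <- list(S1 = segment_smrs(random_track(300)),
               S2 = segment_smrs(random_track(300)))
  rep <- smr_report(smrs)
  expect_equal(nrow(rep), 2 * 4 * 2)
  expect_setequal(unique(rep$metric), c("count", "length"))

  # a track with only D runs reports sentinels for A, B, C
  allD <- list(D = segment_smrs(track_from_states(c(rep("D", 10), NA,
                                                    rep("D", 10)))))
  repD <- smr_report(allD)
  expect_true(all(repD$n[repD$state != "D"] == 0))
  expect_true(all(repD$n[repD$state == "D" & repD$metric == "count"] > 0))
})
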