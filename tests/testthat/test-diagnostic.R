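test_that("bin_of implements half-open fifths with a closed top", {
  expect_equal(bin_of(c(0, 0.19, 0.2, 0.39, 0.4, 0.6, 0.8, 0.99, 1)),
               c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L, 5L))
  expect_error(bin_of(1.1), "\\[0,1\\]")
})

test_that("round A1 excludes hard images and samples per cell", {
  tw <- data.frame(
    image_id = sprintf("i%02d", 1:12),
    class_label = rep(c("mirror", "glass"), each = 6),
    judgment = c("mirror", "mirror", "glass", "glass", "hard", "mirror",
                 "glass", "glass", "mirror", "mirror", "hard", "glass"))
  sel <- round_a1_select(tw, 2L, seed = 1L)
  expect_length(sel, 8L)
  expect_false(any(c("i05", "i11") %in% sel))       # hard excluded
  expect_identical(round_a1_select(tw, 2L, seed = 1L), sel)  # purity
  expect_identical(round_a1_select(tw, 0L), character(0))
  expect_error(round_a1_select(tw, 3L), "cell")
})

test_that("round A2 applies the min-ratings rule and conflict windows", {
  manifest <- data.frame(image_id = c("m1", "m2", "m3", "g1", "g2"),
                         class_label = c("mirror", "mirror", "mirror",
                                         "glass", "glass"))
  resp <- rbind(
    data.frame(image_id = "m1", value = c(1L, 1L, 2L)),   # mean 0.083 -> conflict
    data.frame(image_id = "m2", value = c(1L, 1L)),       # only 2 ratings
    data.frame(image_id = "m3", value = c(5L, 5L, 5L)),   # agrees
    data.frame(image_id = "g1", value = c(4L, 4L, 5L)),   # mean 0.83 -> conflict
    data.frame(image_id = "g2", value = c(1L, 2L, 1L)))   # agrees
  resp$observer_id <- "w"; resp$is_catch <- FALSE; resp$excluded <- FALSE
  sel <- round_a2_select(resp, manifest, min_ratings = 3L)
  expect_equal(sel$mirror_conflicts, "m1")
  expect_equal(sel$glass_conflicts, "g1")
  expect_length(sel$selected, 2L)
  # all-agreeing table yields empty selection
  agree <- resp[resp$image_id %in% c("m3", "g2"), ]
  expect_length(round_a2_select(agree, manifest)$selected, 0L)
})

test_that("round A3 boundary audit at mean exactly 0.5", {
  # mean 0.5: mirror selected (0.5 < 0.6), glass selected (0.5 >= 0.4)
  manifest <- data.frame(image_id = c("m", "g"),
                         class_label = c("mirror", "glass"))
  resp <- data.frame(image_id = rep(c("m", "g"), each = 30),
                     observer_id = rep(sprintf("o%d", 1:10), 6),
                     value = 3L)
  sel <- round_a3_select(resp, manifest)
  expect_setequal(sel$selected, c("m", "g"))
  # empty candidate set
  empty <- round_a3_select(resp[0, ], manifest)
  expect_length(empty$selected, 0L)
})

test_that("round B1 keeps images at the inclusive 6-vote boundary", {
  votes <- expand.grid(image_id = c("a", "b", "c"),
                       observer_id = sprintf("o%d", 1:10))
  votes$vote <- with(votes, ifelse(image_id == "a", TRUE,
                                   ifelse(image_id == "b",
                                          observer_id %in% sprintf("o%d", 1:6),
                                          FALSE)))
  kept <- round_b1_select(votes)
  expect_setequal(kept, c("a", "b"))   # 10 votes and exactly 6 votes kept
  expect_length(round_b1_select(within(votes, vote <- FALSE)), 0L)
  expect_error(round_b1_select(votes[-1, ]), "exactly 10")
})

test_that("round B2 samples consistent images per bin and names underfull bins", {
  manifest <- data.frame(image_id = sprintf("i%02d", 1:25),
                         a = rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 5))
  ratings <- rate_all(manifest, lab_panel(10L), seed = 3L, n_trials = 3L)
  sel <- round_b2_select(ratings, per_bin_quota = 3L, seed = 5L)
  expect_length(sel, 15L)
  s <- summarize_ratings(ratings)
  expect_equal(unname(table(s$bin[s$image_id %in% sel])), rep(3L, 5),
               ignore_attr = TRUE)
  expect_identical(round_b2_select(ratings, 0L), character(0))
  expect_error(round_b2_select(ratings, 6L), "bin 1")
})

test_that("consistency filter demands unanimity", {
  tab <- data.frame(image_id = rep(c("a", "b"), each = 10),
                    bin = c(rep(3L, 10), c(rep(3L, 9), 4L)))
  cons <- consistency_filter(tab, 10L)
  expect_true(cons[["a"]])
  expect_false(cons[["b"]])
  expect_error(consistency_filter(tab[-1, ], 10L), "exactly 10")
})

test_that("assembly certifies flatness and decorrelation on a balanced set", {
  world <- build_diagnostic_world(seed = 5L)
  set <- world$set
  expect_equal(set$n_total, 265L)
  expect_equal(set$n_renderings, 170L)
  expect_true(all(set$bin_counts == 17L))
  expect_lt(abs(set$decorrelation_r), 0.05)
  expect_equal(unname(table(set$members$component)[c("ambiguous", "illusory",
                                                     "veridical")]),
               c(95L, 102L, 68L), ignore_attr = TRUE)
  # flatness violation errors with the count table
  bad_summaries <- world$summaries
  expect_error(
    assemble_diagnostic(world$veridical$selected[-1],
                        setdiff(set$members$image_id[set$members$component ==
                                                       "illusory"], ""),
                        world$b$b2_selected, world$summaries, world$manifest),
    "flatness")
})

test_that("conflict selections never contain rating/label agreements", {
  w <- world_round_a2(seed = 3L)
  s <- w$summaries
  cls <- w$manifest$class_label[match(s$image_id, w$manifest$image_id)]
  mirror_sel <- s$mean_norm_rating[match(w$mirror_conflicts, s$image_id)]
  glass_sel <- s$mean_norm_rating[match(w$glass_conflicts, s$image_id)]
  expect_true(all(mirror_sel < 0.4))
  expect_true(all(glass_sel >= 0.6))
})
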