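noiseless <- function(id = "o") observer_profile(id, rating_noise_sd = 0,
                                                 lapse_rate = 0)

test_that("noiseless ratings bin the appearance into fifths", {
  obs <- noiseless()
  expect_equal(simulate_rating(0.05, obs, 1L), 1L)
  expect_equal(simulate_rating(0.99, obs, 1L), 5L)
  expect_equal(simulate_rating(1, obs, 1L), 5L)   # top bin closed
  # boundary 0.2 belongs to bin 2 (half-open convention)
  expect_equal(simulate_rating(0.2, obs, 1L), 2L)
  # determinism in the seed
  obs2 <- observer_profile("n", rating_noise_sd = 0.1, lapse_rate = 0.1)
  expect_identical(simulate_rating(0.5, obs2, 7L), simulate_rating(0.5, obs2, 7L))
})

test_that("noisy rating distribution matches the normal-CDF closed form", {
  sigma <- 0.05
  obs <- observer_profile("n", rating_noise_sd = sigma, lapse_rate = 0)
  n <- 10000L
  r <- vapply(seq_len(n), function(i) simulate_rating(0.5, obs, i), integer(1))
  p_hat <- mean(r == 3L)
  p_true <- pnorm((0.6 - 0.5) / sigma) - pnorm((0.4 - 0.5) / sigma)
  mc_sd <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * mc_sd)
})

test_that("three-way judgment follows the 0.5 threshold and the hard rate", {
  always_hard <- observer_profile("h", p_hard = 1)
  expect_true(all(vapply(1:20, function(i)
    simulate_threeway(0.7, always_hard, i), character(1)) == "hard"))
  obs <- noiseless()
  expect_equal(simulate_threeway(0.7, obs, 1L), "mirror")
  expect_equal(simulate_threeway(0.5, obs, 1L), "mirror")  # boundary to mirror
  expect_equal(simulate_threeway(0.49, obs, 1L), "glass")
  # planted hard rate recovered within 3 MC sd
  p <- 0.029
  obsh <- observer_profile("h", rating_noise_sd = 0, p_hard = p)
  n <- 100000L
  hard <- vapply(seq_len(n), function(i)
    simulate_threeway(0.9, obsh, i) == "hard", logical(1))
  expect_lt(abs(mean(hard) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("recognizability votes are Bernoulli in the planted probability", {
  obs <- noiseless()
  expect_true(all(vapply(1:20, function(i)
    simulate_recognizability(1, obs, i), logical(1))))
  expect_false(any(vapply(1:20, function(i)
    simulate_recognizability(0, obs, i), logical(1))))
  n <- 5000L
  v <- vapply(seq_len(n), function(i)
    simulate_recognizability(0.6, obs, i), logical(1))
  expect_lt(abs(mean(v) - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("crowd sessions assign balanced blocks and apply the catch rule", {
  ds <- generate_dataset(49L, master_seed = 5L, render = FALSE)  # 98 images
  workers <- lapply(1:4, function(i)
    observer_profile(sprintf("w%d", i), rating_noise_sd = 0, lapse_rate = 0))
  sess <- simulate_crowd_session(ds$manifest, workers, seed = 9L)
  expect_true(all(sess$workers$accepted))
  per_worker <- table(sess$responses$observer_id[!sess$responses$is_catch])
  expect_true(all(per_worker == 98L))
  # 4 workers x 98 over 98 images = 4 ratings per image
  cnt <- table(sess$responses$image_id[!sess$responses$is_catch])
  expect_true(all(cnt == 4L))
  expect_error(simulate_crowd_session(ds$manifest[1:10, ], workers),
               "fewer images")
})

test_that("fully lapsing workers are rejected at the closed-form rate", {
  # a lapsing rating is uniform on 1..5; the glass catch (a = 0) passes
  # with probability 2/5, the mirror catch (a = 1) with 3/5
  p_pass <- (2 / 5) * (3 / 5)
  ds <- generate_dataset(49L, master_seed = 5L, render = FALSE)
  workers <- lapply(1:1000, function(i)
    observer_profile(sprintf("w%d", i), lapse_rate = 1))
  sess <- simulate_crowd_session(ds$manifest, workers, seed = 2L)
  rej <- mean(!sess$workers$accepted)
  expect_lt(abs(rej - (1 - p_pass)), 3 * sqrt(p_pass * (1 - p_pass) / 1000))
  # rejected workers' test ratings are flagged excluded
  bad <- sess$workers$observer_id[!sess$workers$accepted][1]
  expect_true(all(sess$responses$excluded[sess$responses$observer_id == bad]))
})

test_that("rating summaries respect bins and the consistency rule", {
  resp <- data.frame(
    image_id = rep(c("a", "b"), each = 3),
    observer_id = rep(c("o1", "o2", "o3"), 2),
    value = c(3L, 3L, 3L, 2L, 3L, 3L))
  s <- summarize_ratings(resp)
  expect_equal(s$mean_norm_rating[s$image_id == "a"], 0.5)
  expect_equal(s$bin[s$image_id == "a"], 3L)
  expect_true(s$consistent[s$image_id == "a"])
  expect_false(s$consistent[s$image_id == "b"])
})

test_that("noiseless observers are perfectly consistent (10/10 by construction)", {
  ds <- generate_dataset(10L, master_seed = 6L, render = FALSE)
  panel <- lab_panel(10L, sigma = 0, lapse = 0)
  ratings <- rate_all(ds$manifest, panel, seed = 13L)
  s <- summarize_ratings(ratings)
  expect_true(all(s$consistent))
  expect_true(all(s$n_ratings == 10L))
})

test_that("high-contrast appearance batches give a bimodal rating distribution", {
  mix <- strong_mix()
  ds <- generate_dataset(100L, mix, master_seed = 8L, render = FALSE)
  obs <- observer_profile("o", rating_noise_sd = 0.05, lapse_rate = 0)
  r <- vapply(seq_len(nrow(ds$manifest)), function(i)
    simulate_rating(ds$manifest$a[i], obs, i), integer(1))
  outer_mass <- mean(r %in% c(1L, 5L))
  expect_gt(outer_mass, 0.5)
})
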