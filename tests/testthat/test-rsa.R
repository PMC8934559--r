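test_that("build_rdm is forced arithmetic on score differences", {
  expect_equal(build_rdm(c(0, 1))$mat, matrix(c(0, 1, 1, 0), 2),
               ignore_attr = TRUE)
  expect_true(all(build_rdm(rep(0.3, 4))$mat == 0))
  m <- build_rdm(c(0.2, 0.5, 0.9))$mat
  expect_equal(sort(m[upper.tri(m)]), c(0.3, 0.4, 0.7))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  # translation invariance of the RDM
  expect_equal(build_rdm(c(0.2, 0.5, 0.9) + 0.05)$mat, m, ignore_attr = TRUE)
  expect_error(build_rdm(0.4), "at least 2")
})

test_that("CDM entries match a brute-force pairwise correlation oracle", {
  s1 <- c(0.1, 0.4, 0.8, 0.3)
  s2 <- c(0.2, 0.5, 0.7, 0.1)
  s3 <- c(0.9, 0.2, 0.4, 0.6)
  rdms <- list(a = build_rdm(s1, source = "a"), b = build_rdm(s2, source = "b"),
               c = build_rdm(s3, source = "c"))
  cdm <- build_cdm(rdms, n_random_controls = 0L)
  ut <- function(s) { m <- abs(outer(s, s, `-`)); m[upper.tri(m)] }
  expect_equal(cdm$mat["a", "b"], 1 - cor(ut(s1), ut(s2)))
  expect_equal(cdm$mat["a", "c"], 1 - cor(ut(s1), ut(s3)))
  expect_true(all(cdm$mat >= 0 & cdm$mat <= 2))
  # scale invariance: rdm vs 2*rdm correlate perfectly
  double <- rdms$a; double$mat <- 2 * double$mat; double$source <- "a2"
  cdm2 <- build_cdm(list(a = rdms$a, a2 = double), n_random_controls = 0L)
  expect_equal(cdm2$mat["a", "a2"], 0)
  # mismatched orderings rejected
  bad <- build_rdm(s1, ids = c("x", "y", "z", "w"))
  expect_error(build_cdm(list(rdms$a, bad)), "orderings")
})

test_that("random control RDMs sit farther from a structured source", {
  ds <- strong_dataset(30L)
  scores <- pmin(pmax(ds$manifest$a, 0), 1)
  noisy <- pmin(pmax(scores + withr::with_seed(2L, rnorm(60, 0, 0.05)), 0), 1)
  rdms <- list(human = build_rdm(scores, source = "human"),
               model = build_rdm(noisy, source = "model"))
  cdm <- build_cdm(rdms, n_random_controls = 10L, seed = 4L)
  to_human <- cdm$mat["human", ]
  d_model <- to_human[["model"]]
  d_random <- to_human[grepl("^random", names(to_human))]
  expect_true(all(d_random > d_model))
})

test_that("MDS reproduces planar configurations exactly", {
  set.seed(6)
  pts <- cbind(runif(6), runif(6))
  d <- as.matrix(dist(pts))
  emb <- mds_embed(d, n_dims = 2L)
  expect_equal(as.matrix(dist(emb$coords)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(emb$explained_var, 1.0, tolerance = 1e-8)
  # equilateral for three equidistant sources
  eq <- matrix(1, 3, 3); diag(eq) <- 0
  emb3 <- mds_embed(eq, n_dims = 2L)
  dd <- dist(emb3$coords)
  expect_lt(diff(range(dd)), 1e-10)
  # explained variance nondecreasing in dims; truncation notices
  e1 <- mds_embed(d, 1L)$explained_var
  e2 <- mds_embed(d, 2L)$explained_var
  expect_lte(e1, e2 + 1e-12)
  expect_message(mds_embed(eq, 3L), "truncat")
})

test_that("noise ceiling matches trivial and analytic oracles", {
  ratings <- matrix(rep(seq(0, 1, length.out = 50), 4), nrow = 4,
                    byrow = TRUE)
  expect_equal(noise_ceiling(ratings)$mean, 1.0)
  # independent observers: ceiling near zero
  ind <- withr::with_seed(8L, matrix(runif(10 * 1000), nrow = 10))
  expect_lt(abs(noise_ceiling(ind)$mean), 0.1)
  # signal+noise closed form: r = v_s / sqrt((v_s+v_n)(v_s+v_n/(m-1)))
  v_s <- 0.04; v_n <- 0.01; m <- 10L; n_img <- 400L
  sim <- withr::with_seed(9L, {
    s <- rnorm(n_img, 0, sqrt(v_s))
    t(sapply(seq_len(m), function(i) s + rnorm(n_img, 0, sqrt(v_n))))
  })
  r_pred <- v_s / sqrt((v_s + v_n) * (v_s + v_n / (m - 1)))
  nc <- noise_ceiling(sim)
  mc_sd <- sd(nc$per_observer) / sqrt(m)
  expect_lt(abs(nc$mean - r_pred), 3 * mc_sd + 0.01)
  expect_error(noise_ceiling(ratings[1:2, ]), "at least 3")
  expect_error(noise_ceiling(matrix(1, 3, 10)), "zero-variance")
})

test_that("layerwise dissimilarity agrees with the direct final-stage oracle", {
  fx <- trained_gap_cnn()
  idx <- 1:20
  x <- fx$x[, , , idx]
  ratings <- pmin(pmax(fx$ds$manifest$a[idx], 0), 1)
  ld <- layerwise_dissimilarity(fx$model, x, ratings)
  scores <- predict_cnn(fx$model, x)
  hum <- build_rdm(ratings)
  out <- build_rdm(scores)
  direct <- 1 - cor(hum$mat[upper.tri(hum$mat)], out$mat[upper.tri(out$mat)])
  expect_equal(ld$dissimilarity[ld$stage == "output"], direct,
               tolerance = 1e-10)
  # permutation invariance of the input stage
  perm <- c(5:20, 1:4)
  ld2 <- layerwise_dissimilarity(fx$model, x[, , , perm], ratings[perm])
  expect_equal(ld2$dissimilarity[ld2$stage == "input"],
               ld$dissimilarity[ld$stage == "input"], tolerance = 1e-10)
  # a trained model's output stage is closer to the ratings than an
  # untrained clone's
  raw <- build_cnn(fx$model$spec, seed = 123L)
  ld_raw <- layerwise_dissimilarity(raw, x, ratings)
  expect_lt(ld$dissimilarity[ld$stage == "output"],
            ld_raw$dissimilarity[ld_raw$stage == "output"])
  expect_error(layerwise_dissimilarity(fx$model, x, ratings, stages = "nope"),
               "unknown stages")
})
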