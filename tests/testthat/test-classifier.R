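toy_class_model <- function(mean, cov, ridge = 0) {
  list(label = "male", mean = mean, cov = cov, n = 10L, ridge = ridge)
}

test_that("training computes per-class unbiased moments and class sizes", {
  model <- cached_default_model()
  ns <- vapply(model$classes, function(cm) cm$n, 0L)
  expect_equal(unname(ns[c("hermaphrodite", "male", "larva")]), c(46L, 46L, 39L))
  expect_equal(model$feature_order, c("length_um", "thickness_um", "r1", "r2"))

  # hand-computed covariance on a 4-point configuration; the two flat
  # feature dimensions force the ridge path
  base <- data.frame(class = "hermaphrodite",
                     length_um = c(0, 2, 0, 2), thickness_um = c(0, 0, 2, 2),
                     r1 = 0.1, r2 = 0.1)
  filler <- do.call(rbind, lapply(c("male", "larva"), function(cl)
    data.frame(class = cl, length_um = c(10, 11, 12, 13, 14) + 100,
               thickness_um = c(5, 6, 7, 8, 9), r1 = seq(0.2, 0.4, by = 0.05),
               r2 = seq(0.5, 0.7, by = 0.05))))
  m <- fit_training(rbind(base, base[1:1, ], filler))
  cm <- m$classes$hermaphrodite
  expect_equal(unname(cm$mean[1:2]), c(0.8, 0.8), tolerance = 1e-12)
  # unbiased covariance of {0,2,0,2,0} x {0,0,2,2,0}: var 4.8/4, cov 0.8/4
  expect_equal(unname(cm$cov[1, 1]), 1.2, tolerance = 1e-12)
  expect_equal(unname(cm$cov[2, 2]), 1.2, tolerance = 1e-12)
  expect_equal(unname(cm$cov[1, 2]), 0.2, tolerance = 1e-12)
  expect_gt(cm$ridge, 0)
  # distance from the degenerate class's own mean is still exactly 0
  expect_equal(mahalanobis_distance(cm$mean, cm), 0)
})

test_that("training is order-independent and validates its input", {
  tab <- default_training_table()
  m1 <- fit_training(tab)
  m2 <- fit_training(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(m1, m2)

  expect_error(fit_training(tab[tab$class != "larva", ]), "larva")
  small <- tab[c(which(tab$class == "hermaphrodite")[1:3],
                 which(tab$class == "male"), which(tab$class == "larva")), ]
  expect_error(fit_training(small), "hermaphrodite")
  bad <- tab; bad$r2[5] <- NaN
  expect_error(fit_training(bad), "non-finite")
})

test_that("identical records in one class are handled by regularisation", {
  same <- data.frame(class = "male", length_um = 800, thickness_um = 45,
                     r1 = 0.5, r2 = 0.8)[rep(1, 8), ]
  other <- data.frame(
    class = rep(c("hermaphrodite", "larva"), each = 5),
    length_um = c(1000:1004, 400:404), thickness_um = c(55:59, 16:20),
    r1 = rep(c(0.32, 0.45), each = 5) + (1:5) / 100,
    r2 = rep(c(0.48, 0.65), each = 5) + (1:5) / 100)
  m <- fit_training(rbind(same, other))
  expect_gt(m$classes$male$ridge, 0)
  cl <- classify(c(800, 45, 0.5, 0.8), m)
  expect_equal(cl$label, "male")
  expect_equal(unname(cl$distances[["male"]]), 0)
})

test_that("mahalanobis distance matches hand-computed and library oracles", {
  # identity covariance reduces to Euclidean distance
  cm <- toy_class_model(rep(0, 4), diag(4))
  x <- c(3, 4, 0, 0)
  expect_equal(mahalanobis_distance(x, cm), 5)
  expect_equal(mahalanobis_distance(rep(0, 4), cm), 0)

  # 2-D worked example embedded in 4-D: mu = 0, Sigma = diag(4,1),
  # x = (2,1) gives sqrt(4/4 + 1) = sqrt(2)
  cm2 <- toy_class_model(rep(0, 4), diag(c(4, 1, 1, 1)))
  expect_equal(mahalanobis_distance(c(2, 1, 0, 0), cm2), sqrt(2),
               tolerance = 1e-12)

  # ridge enters the quadratic form
  cm3 <- toy_class_model(rep(0, 4), diag(4), ridge = 1)
  expect_equal(mahalanobis_distance(c(2, 0, 0, 0), cm3), sqrt(4 / 2),
               tolerance = 1e-12)

  expect_error(mahalanobis_distance(c(1, NA, 0, 0), cm), "non-finite")

  # random SPD oracle against stats::mahalanobis
  set.seed(42)
  for (i in 1:200) {
    a <- matrix(rnorm(16), 4)
    sigma <- crossprod(a) + diag(4) * 0.05
    mu <- rnorm(4); x <- rnorm(4, sd = 3)
    got <- mahalanobis_distance(x, toy_class_model(mu, sigma))
    ref <- sqrt(stats::mahalanobis(x, mu, sigma))
    expect_lt(abs(got - ref) / max(ref, 1e-12), 1e-10)
  }
})

test_that("classification picks the nearest class and flags exact ties", {
  model <- cached_default_model()
  for (cl in c("hermaphrodite", "male", "larva")) {
    res <- classify(model$classes[[cl]]$mean, model)
    expect_equal(res$label, cl)
    expect_equal(unname(res$distances[[cl]]), 0)
    expect_gte(res$margin, 0)
  }

  # two identical class models tie exactly; fixed order wins
  tied <- model
  tied$classes$male <- tied$classes$hermaphrodite
  tied$classes$male$label <- "male"
  res <- classify(tied$classes$hermaphrodite$mean, tied)
  expect_true(res$tie)
  expect_equal(res$label, "hermaphrodite")
  expect_equal(res$margin, 0)
})

test_that("classify agrees with a brute-force argmin over explicit inverses", {
  model <- cached_default_model()
  set.seed(7)
  agree <- 0
  for (i in 1:100) {
    cl <- sample(names(model$classes), 1)
    cm <- model$classes[[cl]]
    x <- as.numeric(cm$mean) + as.numeric(chol(cm$cov) %*% rnorm(4))
    got <- classify(x, model)$label
    brute <- names(which.min(vapply(model$classes, function(k) {
      d <- x - k$mean
      drop(t(d) %*% solve(k$cov + k$ridge * diag(4)) %*% d)
    }, 0)))
    agree <- agree + (got == brute)
  }
  expect_gte(agree, 95)
})

test_that("classification is invariant under a common feature rescaling", {
  tab <- default_training_table()
  model <- cached_default_model()
  scale <- c(2, 0.5, 10, 10)
  tab2 <- tab
  tab2[, 2:5] <- sweep(tab2[, 2:5], 2, scale, "*")
  model2 <- fit_training(tab2)
  set.seed(3)
  idx <- sample(nrow(tab), 25)
  for (i in idx) {
    x <- as.numeric(tab[i, 2:5])
    expect_equal(classify(x, model)$label,
                 classify(x * scale, model2)$label)
  }
})

test_that("plate-level aggregation counts classes and rejections", {
  model <- cached_default_model()
  empty <- classify_plate(features_table(list()), model)
  expect_equal(sum(empty$counts), 0)
  expect_true(is.na(empty$male_percentage))

  mk <- function(cl, id) {
    f <- cached_default_model()$classes[[cl]]$mean
    data.frame(region_id = id, length_um = f[1], thickness_um = f[2],
               r1 = f[3], r2 = f[4], status = "ok")
  }
  feats <- rbind(mk("male", 1), mk("male", 2), mk("male", 3),
                 mk("hermaphrodite", 4), mk("larva", 5), mk("larva", 6),
                 data.frame(region_id = 7, length_um = NA, thickness_um = NA,
                            r1 = NA, r2 = NA, status = "branched"))
  rep <- classify_plate(feats, model)
  expect_equal(unname(rep$counts), c(1L, 3L, 2L))
  expect_equal(rep$male_percentage, 75)
  expect_equal(unname(rep$rejected[["branched"]]), 1L)
  expect_equal(nrow(rep$worms), 6)
})

test_that("model JSON round-trips through the versioned schema", {
  model <- cached_default_model()
  path <- tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  x <- c(850, 47, 0.5, 0.75)
  for (cl in names(model$classes)) {
    expect_equal(mahalanobis_distance(x, back$classes[[cl]]),
                 mahalanobis_distance(x, model$classes[[cl]]),
                 tolerance = 1e-10)
  }
  expect_equal(vapply(back$classes, function(cm) cm$n, 0L),
               vapply(model$classes, function(cm) cm$n, 0L))
})
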