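test_that("disc averaging is the per-channel arithmetic mean", {
  df <- data.frame(specimen_id = "s1", disc = 1:3,
                   R = c(10, 30, 20), G = c(20, 20, 20),
                   B = c(30, 10, 20))
  p <- average_discs(df)
  expect_equal(unlist(p[1, c("R", "G", "B")]), c(R = 20, G = 20, B = 20))

  one <- average_discs(data.frame(specimen_id = "s", disc = 1,
                                  R = 5, G = 6, B = 7))
  expect_equal(unlist(one[1, c("R", "G", "B")]), c(R = 5, G = 6, B = 7))

  set.seed(2)
  n <- 40
  df <- data.frame(specimen_id = rep(sprintf("s%d", 1:10), each = 4),
                   disc = rep(1:4, 10),
                   R = runif(n, 0, 255), G = runif(n, 0, 255),
                   B = runif(n, 0, 255))
  p <- average_discs(df)
  for (i in 1:10) {
    rows <- df[df$specimen_id == sprintf("s%d", i), ]
    expect_equal(p$R[p$specimen_id == sprintf("s%d", i)],
                 sum(rows$R) / nrow(rows))
  }

  df$G[3] <- NA
  expect_error(average_discs(df), "missing G")
  expect_error(average_discs(data.frame(specimen_id = "s", R = 1, B = 1)),
               "missing column")
  expect_error(average_discs(data.frame(specimen_id = "s", disc = 1,
                                        R = 300, G = 0, B = 0)),
               "out of")
})

test_that("HSV conversion follows the hexcone convention and round-trips", {
  expect_equal(as.numeric(rgb_to_hsv(255, 0, 0)), c(0, 1, 1))
  expect_equal(as.numeric(rgb_to_hsv(0, 255, 0)), c(120, 1, 1))
  expect_equal(as.numeric(rgb_to_hsv(0, 0, 255)), c(240, 1, 1))
  grey <- rgb_to_hsv(128, 128, 128)
  expect_equal(unname(grey[, c("H", "S")]), c(0, 0))
  expect_error(rgb_to_hsv(-1, 0, 0), "\\[0, 255\\]")

  set.seed(8)
  h <- runif(1000, 0, 359.99); s <- runif(1000); v <- runif(1000)
  rgb <- hsv_to_rgb(h, s, v)
  back <- rgb_to_hsv(rgb[, "R"], rgb[, "G"], rgb[, "B"])
  chroma <- s * v > 1e-8     # hue undefined at zero chroma
  expect_lt(max(abs(back[chroma, "H"] - h[chroma])), 1e-9)
  expect_lt(max(abs(back[v > 1e-8, "S"] - s[v > 1e-8])), 1e-9)
  expect_lt(max(abs(back[, "V"] - v)), 1e-9)
})

test_that("colour distances are Euclidean in the chosen space", {
  df <- data.frame(specimen_id = c("a", "b"), disc = 1,
                   R = c(0, 3), G = c(0, 4), B = c(0, 0))
  p <- average_discs(df)
  expect_equal(as.numeric(colour_distance_matrix(p, "RGB")), 5)
  expect_equal(as.numeric(stats::dist(rbind(unlist(p[1, c("H", "S", "V")]),
                                            unlist(p[2, c("H", "S", "V")])))),
               as.numeric(colour_distance_matrix(p, "HSV")))

  set.seed(4)
  p <- average_discs(data.frame(
    specimen_id = rep(sprintf("s%d", 1:6), each = 3), disc = 1:3,
    R = runif(18, 0, 255), G = runif(18, 0, 255), B = runif(18, 0, 255)))
  d <- as.matrix(colour_distance_matrix(p, "RGB"))
  for (i in 1:6) for (j in 1:6)
    expect_equal(d[i, j], sqrt(sum((unlist(p[i, c("R", "G", "B")]) -
                                    unlist(p[j, c("R", "G", "B")]))^2)))
})

test_that("NMDS embeds exactly embeddable distances at near-zero stress", {
  set.seed(10)
  pts <- matrix(rnorm(24), ncol = 2)
  d <- stats::dist(pts)
  ord <- nmds_ordination(d, n_starts = 3, seed = 1)
  expect_lt(ord$stress, 1e-6)
  expect_equal(unname(colMeans(ord$points)), c(0, 0), tolerance = 1e-8)

  expect_error(nmds_ordination(stats::dist(matrix(0, 4, 2))),
               "degenerate")

  # planted clusters separate in the ordination (positive silhouette)
  mu <- rbind(c(0, 0, 0), c(30, 30, 30))
  x <- rbind(matrix(rnorm(30, mu[1, ], 3), ncol = 3, byrow = TRUE),
             matrix(rnorm(30, mu[2, ], 3), ncol = 3, byrow = TRUE))
  grp <- rep(1:2, each = 10)
  ord <- nmds_ordination(stats::dist(x), n_starts = 5, seed = 2)
  dd <- as.matrix(stats::dist(ord$points))
  sil <- vapply(seq_len(20), function(i) {
    a <- mean(dd[i, grp == grp[i]][-which(which(grp == grp[i]) == i)])
    b <- mean(dd[i, grp != grp[i]])
    (b - a) / max(a, b)
  }, 1)
  expect_gt(mean(sil), 0)
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on univariate data", {
  set.seed(21)
  for (rep in 1:5) {
    y <- rnorm(24, mean = rep(c(0, 0.5, 1), each = 8))
    g <- factor(rep(letters[1:3], each = 8))
    pv <- permanova(stats::dist(y), g, n_permutations = 99, seed = rep)
    f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pv$pseudo_F, f_aov, tolerance = 1e-9)
    expect_equal(unname(pv$df), c(2L, 21L))
  }
})

test_that("PERMANOVA matches vegan's adonis2 statistic and behaves at the null", {
  set.seed(33)
  x <- matrix(rnorm(60), ncol = 3)
  g <- factor(rep(c("a", "b"), each = 10))
  d <- stats::dist(x)
  pv <- permanova(d, g, n_permutations = 199, seed = 1)
  av <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(pv$pseudo_F, av$F[1], tolerance = 1e-9)
  expect_gte(pv$p_value, 1 / 200)
  expect_lte(pv$p_value, 1)

  # identical point clouds in both groups: no separation signal
  x2 <- rbind(x[1:10, ], x[1:10, ])
  pv2 <- permanova(stats::dist(x2), g, n_permutations = 199, seed = 1)
  expect_lt(pv2$pseudo_F, 1e-6)
  expect_gt(pv2$p_value, 0.9)
})

test_that("PERMANOVA is invariant under consistent relabelling of points", {
  set.seed(42)
  x <- matrix(rnorm(45), ncol = 3)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  d <- as.matrix(stats::dist(x))
  perm <- sample(15)
  p1 <- permanova(stats::as.dist(d), g, n_permutations = 99, seed = 5)
  p2 <- permanova(stats::as.dist(d[perm, perm]), g[perm],
                  n_permutations = 99, seed = 5)
  expect_equal(p1$pseudo_F, p2$pseudo_F, tolerance = 1e-12)

  expect_error(permanova(stats::as.dist(d), g, n_permutations = 10,
                         seed = 1), "at least 99")
  expect_error(permanova(stats::as.dist(d), g[1:10], seed = 1),
               "does not match")
  expect_error(permanova(stats::as.dist(d), rep("a", 15),
                         n_permutations = 99, seed = 1),
               "at least two groups")
  expect_error(permanova(stats::as.dist(d), g, n_permutations = 99),
               "seed")
})
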