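test_that("min-max normalization maps training range to [0,1] and clips", {
  x <- cbind(a = c(0, 10), b = c(5, 5))
  p <- minmax_fit(x)
  expect_equal(unname(minmax_apply(p, x)[, "a"]), c(0, 1))
  expect_equal(unname(minmax_apply(p, x)[, "b"]), c(0, 0))  # constant -> 0
  out <- minmax_apply(p, cbind(a = c(-5, 20), b = c(7, 3)))
  expect_equal(unname(out[, "a"]), c(0, 1))                 # clipped
})

test_that("crisp membership initialization is one-hot and row-stochastic", {
  u <- init_memberships(c("A", "B"))
  expect_equal(unname(u), rbind(c(1, 0), c(0, 1)))
  u2 <- init_memberships(factor(rep("A", 4), levels = c("A", "B")))
  expect_true(all(u2[, "A"] == 1))
  expect_equal(rowSums(u2), rep(1, 4))
  expect_error(init_memberships(c("A"), scheme = "keller"), "scheme")
})

test_that("membership aggregation follows the distance-weighting formula", {
  # k=1: inherit the single neighbour's crisp row
  f1 <- fknn(matrix(c(0, 5), 2, 1), c("A", "B"), k = 1, scale = FALSE)
  r1 <- fknn_membership(f1, matrix(0.4))
  expect_equal(unname(r1$memberships[1, ]), c(1, 0))

  # k=2 equidistant crisp neighbours of different classes -> (0.5, 0.5)
  f2 <- fknn(matrix(c(-1, 1), 2, 1), c("A", "B"), k = 2, m = 2,
             scale = FALSE)
  r2 <- fknn_membership(f2, matrix(0))
  expect_equal(unname(r2$memberships[1, ]), c(0.5, 0.5))

  # k=3, distances {1,2,4}, classes {A,A,B}, m=2: weights 1, 1/4, 1/16
  f3 <- fknn(matrix(c(1, 2, 4), 3, 1), c("A", "A", "B"), k = 3, m = 2,
             scale = FALSE)
  r3 <- fknn_membership(f3, matrix(0))
  expect_equal(unname(r3$memberships[1, ]),
               c(1.25 / 1.3125, 0.0625 / 1.3125))
  expect_equal(unname(r3$distances[1, ]), c(1, 2, 4))
  # against a direct evaluation of the weighting formula
  expect_equal(unname(r3$memberships[1, ]),
               unname(oracle_membership(diag(2)[c(1, 1, 2), ], c(1, 2, 4), 2)))
})

test_that("zero-distance queries inherit the exact-match membership rows", {
  f <- fknn(matrix(c(0, 0, 3), 3, 1), c("A", "B", "B"), k = 3, m = 2,
            scale = FALSE)
  r <- fknn_membership(f, matrix(0))
  expect_equal(unname(r$memberships[1, ]), c(0.5, 0.5))  # mean of two matches
})

test_that("prediction takes the membership argmax with lowest-index ties", {
  f <- fknn(matrix(c(-1, 1), 2, 1), c("B", "A"), k = 2, m = 2, scale = FALSE)
  # memberships (0.5, 0.5): tie resolved to the first class level, "A"
  expect_equal(as.character(predict(f, matrix(0))), "A")
})

test_that("equidistant neighbourhoods reduce to majority vote", {
  # 6 training points all at distance 1 from the origin query (3-D corners)
  x <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  y <- c("A", "A", "A", "A", "B", "B")
  f <- fknn(x, y, k = 6, m = 2, scale = FALSE)
  r <- fknn_membership(f, matrix(0, 1, 3))
  # equal weights: memberships equal class prevalences
  expect_equal(unname(r$memberships[1, ]), c(4 / 6, 2 / 6))
  expect_equal(as.character(r$class), "A")  # the majority class
})

test_that("membership rows sum to one and are scale-invariant in distance", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(c("A", "B", "C"), 40, TRUE)
    f <- fknn(x, y, k = 5, m = 1.7, scale = FALSE)
    q <- matrix(rnorm(6 * 3), 6, 3)
    u <- fknn_membership(f, q)$memberships
    expect_equal(rowSums(u), rep(1, 6), tolerance = 1e-12)
    # multiplying every coordinate (hence every distance) by c > 0
    f2 <- fknn(3.7 * x, y, k = 5, m = 1.7, scale = FALSE)
    u2 <- fknn_membership(f2, 3.7 * q)$memberships
    expect_equal(u, u2, tolerance = 1e-9)
  }
})

test_that("invalid parameters are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fknn(x, letters[1:5], m = 1), "m must be")
  expect_error(fknn(x, letters[1:5], k = 6), "k must be")
})

test_that("models survive a JSON round-trip", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  y <- sample(c("A", "B"), 20, TRUE)
  f <- fknn(x, y, k = 3)
  path <- withr::local_tempfile(fileext = ".json")
  fknn_to_json(f, path)
  g <- fknn_from_json(path)
  q <- matrix(rnorm(15), 5, 3)
  expect_equal(predict(f, q, type = "membership"),
               predict(g, q, type = "membership"), tolerance = 1e-9)
})
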