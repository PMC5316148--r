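test_that("crosstab partitions paired labels into the four cells", {
  s <- c("unhealthy", "unhealthy", "healthy", "healthy", "unhealthy")
  r <- c("unhealthy", "healthy", "unhealthy", "healthy", "unhealthy")
  t <- crosstab(s, r)
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 1, 1))
  expect_equal(attr(t, "n"), 5)
  # concordant-only input leaves the off-diagonal empty
  t2 <- crosstab(rep(c("healthy", "unhealthy"), 2), rep(c("healthy", "unhealthy"), 2))
  expect_equal(c(t2$b, t2$c), c(0, 0))
  expect_error(crosstab(c("healthy"), c("fat")), "labels")
  expect_error(crosstab(character(0), character(0)), "non-empty")
  # counts always sum to the number of pairs
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    s <- sample(c("healthy", "unhealthy"), n, TRUE)
    r <- sample(c("healthy", "unhealthy"), n, TRUE)
    t <- crosstab(s, r)
    expect_equal(t$a + t$b + t$c + t$d, n)
  }
})

test_that("percent agreement reproduces the published 2x2 arithmetic", {
  rep <- percent_agreement(two_by_two(59, 18, 0, 91))
  expect_equal(rep$overall, 100 * 150 / 168)
  expect_equal(round(rep$overall, 2), 89.29)
  expect_equal(rep$positive, 100)
  expect_equal(round(rep$negative, 2), 83.49)
  expect_equal(unname(rep$presentation), c(89, 100, 83))
  expect_equal(unname(rep$cell_pct["a"]), 100 * 59 / 168)
})

test_that("degenerate tables give the boundary values or NA", {
  perfect <- percent_agreement(two_by_two(10, 0, 0, 10))
  expect_equal(c(perfect$overall, perfect$positive, perfect$negative),
               c(100, 100, 100))
  discord <- percent_agreement(two_by_two(0, 5, 5, 0))
  expect_equal(c(discord$overall, discord$positive, discord$negative),
               c(0, 0, 0))
  # empty denominators are undefined, not zero
  no_pos <- percent_agreement(two_by_two(0, 3, 0, 7))
  expect_true(is.na(no_pos$positive))
  expect_false(is.na(no_pos$negative))
  expect_error(two_by_two(-1, 0, 0, 2), "non-negative")
  expect_error(two_by_two(0, 0, 0, 0), "at least one")
})

test_that("overall agreement is the count-weighted mix of positive and negative", {
  set.seed(31)
  for (i in 1:50) {
    t <- two_by_two(sample(0:30, 1), sample(0:30, 1),
                    sample(0:30, 1), sample(1:30, 1))
    rep <- percent_agreement(t)
    n <- rep$n
    pos_part <- if (is.na(rep$positive)) 0 else rep$positive * (t$a + t$c)
    neg_part <- if (is.na(rep$negative)) 0 else rep$negative * (t$b + t$d)
    expect_equal(rep$overall, (pos_part + neg_part) / n)
    # swapping method roles mirrors b and c and swaps nothing else
    sw <- percent_agreement(two_by_two(t$a, t$c, t$b, t$d))
    expect_equal(sw$overall, rep$overall)
    if (t$a + t$b > 0) {
      expect_equal(sw$positive, 100 * t$a / (t$a + t$b))
    } else {
      expect_true(is.na(sw$positive))
    }
  }
})

test_that("kappa matches the closed form on a hand-checked table", {
  # po = 150/168; pe = (77*59 + 91*109)/168^2; kappa = (po-pe)/(1-pe)
  t <- two_by_two(59, 18, 0, 91)
  po <- 150 / 168
  pe <- (77 * 59 + 91 * 109) / 168^2
  expect_equal(cohen_kappa(t), (po - pe) / (1 - pe))
  expect_true(is.na(cohen_kappa(two_by_two(5, 0, 0, 0))))
})
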