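test_that("DNM index matches hand evaluation and its conventions", {
  # two nodes with SDs 1 and 4 and one edge with |rho| = 0.5:
  # sqrt(1*4) * 0.5 = 1
  n <- 400
  t_idx <- seq_len(n)
  x <- rep(c(-1, 1), length.out = n)          # SD ~ 1
  dat <- array(0, c(1, 2, n))
  dat[1, 1, ] <- x
  dat[1, 2, ] <- 4 * x * c(rbind(1, 1, 1, -1)) # break perfect correlation
  # construct exactly: use uncorrelated-ish parts; easier to check by parts
  ce <- make_corrected(dat)
  sds <- node_fluctuation(ce)
  rho <- edge_correlation(ce, rbind(c(1, 2)))
  net <- dnmnet(c(1, 2), rbind(c(1, 2)))
  expect_equal(dnm_index(ce, net), sqrt(prod(sds)) * rho, tolerance = 1e-12)

  # empty edge set: edge factor is 1; single node with SD 2 gives 2
  y <- rep(c(-2, 2), 50)
  d1 <- array(y, c(1, 1, 100))
  sd1 <- sd(d1[1, 1, ])
  expect_equal(dnm_index(make_corrected(d1), dnmnet(1)), sd1)
  # constant signals give 0 (with the zero-variance correlation warning)
  expect_warning(
    dnm0 <- dnm_index(make_corrected(array(3, c(2, 2, 10))),
                      dnmnet(c(1, 2), rbind(c(1, 2)))), "zero-variance")
  expect_equal(dnm0, 0)
  expect_error(dnm_index(ce, dnmnet(integer(0))), "no nodes")
})

test_that("DNM index follows the exact hand example through controlled SDs and rho", {
  # build series with exact sample SDs {1, 4} and |rho| = 0.5
  a <- c(1, -1, 1, -1) / sqrt(4 / 3) # sample SD exactly 1
  b <- c(1, 1, -1, -1) / sqrt(4 / 3)
  x1 <- a                            # SD 1
  x2 <- 4 * (a + b) / sqrt(2)        # SD 4, cor(x1,x2) = 1/sqrt(2)... use direct
  # direct construction: cor(a, a+ c*b) = 1/sqrt(1+c^2); c = sqrt(3) -> 0.5
  x2 <- (a + sqrt(3) * b)
  x2 <- 4 * x2 / sd(x2)
  dat <- array(0, c(1, 2, 4))
  dat[1, 1, ] <- x1; dat[1, 2, ] <- x2
  ce <- make_corrected(dat)
  expect_equal(unname(node_fluctuation(ce)), c(1, 4), tolerance = 1e-12)
  expect_equal(unname(edge_correlation(ce, rbind(c(1, 2)),
                                       demean_epochs = FALSE)), 0.5,
               tolerance = 1e-12)
  net <- dnmnet(c(1, 2), rbind(c(1, 2)))
  expect_equal(dnm_index(ce, net, demean_epochs = FALSE), 1.0,
               tolerance = 1e-12)
})

test_that("DNM index scales linearly with the signal", {
  set.seed(61)
  dat <- array(rnorm(5 * 4 * 50), c(5, 4, 50))
  ce <- make_corrected(dat)
  ce3 <- make_corrected(3 * dat)
  net <- dnmnet(c(1, 2, 4), rbind(c(1, 2), c(2, 4)))
  expect_equal(dnm_index(ce3, net), 3 * dnm_index(ce, net), tolerance = 1e-10)
})

test_that("Gaussian MI matches the closed form and degenerate contracts", {
  set.seed(62)
  # independent series: MI near 0
  x <- matrix(rnorm(10000), 4)
  y <- matrix(rnorm(10000), 4)
  expect_lt(gaussian_mi(x, y, delta_t = 20), 0.005)
  # exact linear lagged dependence (y_{t+10} == x_t): clipped, finite, large
  s <- rnorm(990)
  mi_lin <- gaussian_mi(s, c(rnorm(10), s[1:980]), delta_t = 20,
                        sampling_rate = 500)
  expect_true(is.finite(mi_lin))
  expect_gt(mi_lin, 10)
  # zero-variance input warns and returns 0
  expect_warning(mi0 <- gaussian_mi(rep(1, 100), rnorm(100)), "zero-variance")
  expect_equal(mi0, 0)
})

test_that("lagged bivariate Gaussian MI matches -0.5 log(1-rho^2) at rho 0.2/0.5/0.8", {
  set.seed(63)
  lag <- 10; n <- 100000 # 20 ms at 500 Hz
  for (rho in c(0.2, 0.5, 0.8)) {
    e <- rnorm(n)
    y <- numeric(n)
    y[seq_len(lag)] <- rnorm(lag)
    y[(lag + 1):n] <- rho * e[seq_len(n - lag)] +
      sqrt(1 - rho^2) * rnorm(n - lag)
    mi <- gaussian_mi(e, y, delta_t = 20, sampling_rate = 500)
    expect_lt(abs(mi - (-0.5 * log(1 - rho^2))), 0.02)
  }
})

test_that("distribution entropy matches hand evaluation and conventions", {
  # multiset {1,1,2}: -(0.25 ln 0.25 * 2 + 0.5 ln 0.5) / ln 3
  expect_equal(distribution_entropy(c(1, 1, 2)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)) / log(3),
               tolerance = 1e-12)
  expect_equal(distribution_entropy(c(1, 1, 2)), 0.946, tolerance = 1e-3)
  # all equal: maximal uniformity
  expect_equal(distribution_entropy(rep(0.3, 12)), 1)
  # single nonzero MI: zero entropy
  expect_equal(distribution_entropy(c(0, 0, 0.7)), 0)
  # all-zero MI: convention 1 with a warning
  expect_warning(de0 <- distribution_entropy(c(0, 0, 0)), "zero")
  expect_equal(de0, 1)
  mi_mat <- matrix(0.2, 3, 3); diag(mi_mat) <- 0
  expect_equal(distribution_entropy(mi_mat), 1)
  expect_error(distribution_entropy(matrix(0.1, 1, 1)), ">= 2 nodes")
})

test_that("network entropy matches hand evaluation and bounds", {
  # uniform outgoing MI over n nodes: log(n-1)
  for (n in c(3, 5, 9)) {
    mi <- matrix(1, n, n); diag(mi) <- 0
    expect_equal(network_entropy(mi), log(n - 1), tolerance = 1e-12)
  }
  # n = 2: single outgoing edge per node, entropy 0
  mi2 <- matrix(c(0, 0.4, 0.9, 0), 2, 2)
  expect_equal(network_entropy(mi2), 0)
  # node with outgoing {1,3}: -(0.25 ln 0.25 + 0.75 ln 0.75) = 0.5623
  mi3 <- matrix(0, 3, 3)
  mi3[1, 2] <- 1; mi3[1, 3] <- 3
  mi3[2, 1] <- 1; mi3[2, 3] <- 1
  mi3[3, 1] <- 2; mi3[3, 2] <- 2
  h1 <- -(0.25 * log(0.25) + 0.75 * log(0.75))
  expect_equal(network_entropy(mi3), (h1 + log(2) + log(2)) / 3,
               tolerance = 1e-12)
  expect_equal(h1, 0.5623, tolerance = 1e-4)
  # all-zero outgoing row contributes 0 with a warning
  mi4 <- mi3; mi4[2, ] <- 0
  expect_warning(ne4 <- network_entropy(mi4), "all-zero outgoing")
  expect_equal(ne4, (h1 + 0 + log(2)) / 3, tolerance = 1e-12)
})

test_that("entropy measures are invariant to rescaling all MI values", {
  set.seed(64)
  mi <- matrix(rexp(36), 6, 6); diag(mi) <- 0
  expect_equal(distribution_entropy(5.7 * mi), distribution_entropy(mi),
               tolerance = 1e-12)
  expect_equal(network_entropy(5.7 * mi), network_entropy(mi),
               tolerance = 1e-12)
})

test_that("CTE agrees with the closed-form partial-correlation oracle on 2 channels", {
  set.seed(65)
  # 2-channel VAR: x drives y at lag 1; delta_t of one sample
  A <- rbind(c(0.5, 0), c(0.4, 0.3))
  z <- matrix(0, 2, 6000)
  for (t in 2:6000) z[, t] <- A %*% z[, t - 1] + rnorm(2)
  ce <- make_corrected(aperm(array(z, c(2, 6000, 1)), c(3, 1, 2)),
                       sampling_rate = 500)
  cte <- conditional_transfer_entropy(ce, delta_t = 2, demean_epochs = FALSE)
  # oracle: residualise x_t and y_{t+1} on y_t by least squares
  xt <- z[1, 1:5999]; yt <- z[2, 1:5999]; yl <- z[2, 2:6000]
  r_oracle <- resid_partial_cor(xt, yl, cbind(yt))
  expect_equal(cte[1, 2], -0.5 * log(1 - r_oracle^2), tolerance = 1e-6)
  expect_equal(diag(cte), c(0, 0), ignore_attr = TRUE)
})

test_that("CTE separates direct from indirect links in a chain VAR", {
  # x -> y -> z chain at lag 1, no direct x -> z link
  reps <- sapply(1:5, function(s) {
    set.seed(70 + s)
    A <- rbind(c(0.4, 0, 0), c(0.5, 0.3, 0), c(0, 0.5, 0.3))
    z <- matrix(0, 3, 4000)
    for (t in 2:4000) z[, t] <- A %*% z[, t - 1] + rnorm(3)
    ce <- make_corrected(aperm(array(z, c(3, 4000, 1)), c(3, 1, 2)))
    cte <- conditional_transfer_entropy(ce, delta_t = 2,
                                        demean_epochs = FALSE)
    c(direct = cte[1, 2], indirect = cte[1, 3])
  })
  expect_gt(median(reps["direct", ]), median(reps["indirect", ]))
  expect_lt(median(reps["indirect", ]), 0.01)
})

test_that("CTE is within the null band for independent channels and needs enough samples", {
  set.seed(66)
  vals <- sapply(1:5, function(s) {
    dat <- array(rnorm(10 * 4 * 260), c(10, 4, 260))
    cte <- conditional_transfer_entropy(make_corrected(dat), delta_t = 20)
    max(cte)
  })
  expect_lt(median(vals), 0.01)
  small <- make_corrected(array(rnorm(1 * 4 * 20), c(1, 4, 20)))
  expect_error(conditional_transfer_entropy(small, delta_t = 20),
               "required")
})

test_that("CTE is invariant under channel rescaling and metrics assemble per subject", {
  set.seed(67)
  dat <- array(rnorm(8 * 4 * 120), c(8, 4, 120))
  ce <- make_corrected(dat)
  ce_scaled <- make_corrected(dat * 7)
  expect_equal(conditional_transfer_entropy(ce, 20),
               conditional_transfer_entropy(ce_scaled, 20), tolerance = 1e-9)
  net <- dnmnet(1:3, rbind(c(1, 2)))
  cm <- criticality_metrics(ce, net, delta_t = 20)
  expect_s3_class(cm, "criticality_metrics")
  expect_gte(cm$distribution_entropy, 0)
  expect_lte(cm$distribution_entropy, 1)
  expect_lte(cm$network_entropy, log(length(net$nodes) - 1) + 1e-12)
  expect_true(all(diag(cm$cte_matrix) == 0))
  expect_true(all(cm$cte_matrix >= 0))
})

test_that("group comparison uses the documented contrast directions", {
  set.seed(68)
  vals <- c(rnorm(10, 5), rnorm(8, 3), rnorm(9, 3))
  groups <- rep(c("HC", "UHR", "PD"), c(10, 8, 9))
  gc <- group_compare(vals, groups)
  expect_equal(gc$alternative, c("greater", "greater", "two.sided"))
  expect_lt(gc$p[1], 0.01) # HC > UHR planted
  expect_lt(gc$p[2], 0.01) # HC > PD planted
  expect_gt(gc$p[3], 0.05) # UHR ~ PD
  # oracle equivalence at small n: one-sided p equals exact enumeration
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(rank_sum_test(x, y, "greater")$p_value,
               enum_rank_sum_p(x, y, "greater"), tolerance = 1e-12)
  expect_error(group_compare(vals[1:5], groups), "align")
})

test_that("group-mean CTE averages matrices entrywise", {
  m1 <- matrix(1, 3, 3); diag(m1) <- 0
  m2 <- matrix(3, 3, 3); diag(m2) <- 0
  gm <- group_mean_cte(list(m1, m2), c("PD", "PD"), "PD")
  expect_equal(gm$mean, (m1 + m2) / 2)
  expect_equal(gm$n_subjects, 2)
  one <- group_mean_cte(list(m1, m2), c("PD", "HC"), "HC")
  expect_equal(one$mean, m2)
  zero <- group_mean_cte(list(m1 * 0), "PD", "PD")
  expect_true(all(zero$mean == 0))
  expect_error(group_mean_cte(list(m1), "PD", "HC"), "no subjects")
})
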