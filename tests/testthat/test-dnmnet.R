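test_that("node fluctuation matches hand and closed-form values", {
  # samples {0, 2} on one channel: sample SD = sqrt(2)
  dat <- array(0, c(1, 2, 2))
  dat[1, 1, ] <- c(0, 2)
  expect_equal(unname(node_fluctuation(make_corrected(dat))),
               c(sqrt(2), 0))
  # constant data has zero SD
  expect_true(all(node_fluctuation(make_corrected(array(5, c(2, 3, 10)))) == 0))
  # AR(1) channel gamma=0.9, sigma=1: stationary SD 1/sqrt(1-0.81)
  m <- make_linear_model(2, 1, 0.9, design = "diagonal",
                         direct_coupling = 0, noise_sd = 1)
  z <- simulate_difference_process(m, 40000, seed = 51)
  ce <- make_corrected(aperm(array(z, c(2, 40000, 1)), c(3, 1, 2)))
  expect_equal(unname(node_fluctuation(ce)[1]), 2.294, tolerance = 0.05 * 2.294)
})

test_that("edge correlation is exact on linear dependence and small under independence", {
  set.seed(52)
  x <- rnorm(500)
  dat <- array(0, c(1, 3, 500))
  dat[1, 1, ] <- x
  dat[1, 2, ] <- 2 * x
  dat[1, 3, ] <- rnorm(500)
  cm <- edge_correlation(make_corrected(dat))
  expect_equal(cm[1, 2], 1, tolerance = 1e-12)
  # independent 10k-sample series: |rho| below the Fisher-z 0.05 bound
  big <- array(rnorm(2 * 10000), c(1, 2, 10000))
  expect_lt(edge_correlation(make_corrected(big))[1, 2], 0.05)
  # zero-variance channel recorded as 0 with a warning
  dat0 <- array(rnorm(30), c(1, 3, 10)); dat0[1, 2, ] <- 1
  expect_warning(cm0 <- edge_correlation(make_corrected(dat0)),
                 "zero-variance")
  expect_equal(cm0[1, 2], 0)
})

test_that("coupled DNM pairs correlate more strongly than uncoupled pairs", {
  meds <- sapply(1:5, function(s) {
    set.seed(s)
    m <- make_linear_model(6, 1:3, 0.95, direct_coupling = 0, noise_sd = 1)
    z <- dnmcrit:::sim_z_segments(m, 150, 15)
    ce <- make_corrected(aperm(z, c(3, 1, 2)))
    cm <- edge_correlation(ce)
    c(coupled = cm[1, 2], uncoupled = cm[4, 5])
  })
  expect_gt(median(meds["coupled", ]), median(meds["uncoupled", ]))
})

test_that("node selection recovers the planted block and rejects nulls", {
  study <- model_study(15, 16, 1:4, n_epochs = 25, epoch_len = 120, seed = 53)
  sel <- select_nodes(study, alpha = 1e-3)
  expect_gte(length(intersect(sel$nodes, 1:4)), 3)
  expect_lte(length(setdiff(sel$nodes, 1:4)), 1)

  # identical data relabelled: exchangeable null, nothing selected
  hc <- study[grepl("HC", names(study))]
  null_study <- hc
  for (i in 8:14) null_study[[i]]$group <- "PD"
  expect_length(select_nodes(null_study, alpha = 1e-3)$nodes, 0)

  # monotonicity in alpha
  sel_loose <- select_nodes(study, alpha = 0.05)
  expect_true(all(sel$nodes %in% sel_loose$nodes))
  expect_error(select_nodes(hc), "need >= 2 subjects")
})

test_that("paired-t node option uses within-subject standard/corrected pairing", {
  gs <- default_group_specs(); gs$n <- c(4L, 0L, 4L); gs <- gs[gs$n > 0, ]
  cfg <- sim_config(n_channels = 8, n_stimuli = 150, dnm_members = 1:3,
                    groups = gs, seed = 54)
  pp <- preprocess_study(generate_study(cfg))
  sel <- select_nodes(pp$epoch_sets, test = "paired_t", alpha = 0.01)
  # corrected epochs on DNM channels carry the near-critical dynamics on
  # top of sensor noise, so their SD exceeds the standard-epoch SD
  expect_true(all(1:3 %in% sel$nodes))
  expect_error(select_nodes(pp$corrected, test = "paired_t"), "epoch_set")
})

test_that("edge selection concentrates in the planted block with a working reverse screen", {
  study <- model_study(15, 12, 1:4, n_epochs = 25, epoch_len = 120, seed = 55)
  es <- select_edges(study, alpha = 0.005)
  expect_gt(nrow(es$edges), 0)
  in_block <- es$edges[, 1] %in% 1:4 & es$edges[, 2] %in% 1:4
  expect_gte(mean(in_block), 0.8)

  # reverse-planted: stable group gets the strong correlations
  rev_study <- model_study(15, 12, 1:4, gamma_hc = 0.6, gamma_pd = 0.97,
                           direct_hc = 0.65, direct_pd = 0.1,
                           n_epochs = 25, epoch_len = 120, seed = 56)
  es_rev <- select_edges(rev_study, alpha = 0.005)
  expect_equal(nrow(es_rev$edges), 0)
  expect_gte(nrow(es_rev$decreasing), 1)
})

test_that("DNMnet composition is deterministic and monotone in its thresholds", {
  study <- model_study(10, 10, 1:3, n_epochs = 20, epoch_len = 100, seed = 57)
  net1 <- build_dnmnet(study, node_alpha = 1e-3, edge_alpha = 0.005)
  net2 <- build_dnmnet(study, node_alpha = 1e-3, edge_alpha = 0.005)
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$edges, net2$edges)
  expect_true(net1$direction_checked)

  loose <- build_dnmnet(study, node_alpha = 0.05, edge_alpha = 0.05)
  expect_true(all(net1$nodes %in% loose$nodes))
  if (nrow(net1$edges) > 0) {
    key <- function(e) paste(e[, 1], e[, 2])
    expect_true(all(key(net1$edges) %in% key(loose$edges)))
  }

  # alpha = 0 is unreachable by any adjusted p: empty network
  empty <- build_dnmnet(study, node_alpha = 0, edge_alpha = 0)
  expect_length(empty$nodes, 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("DNMnet JSON serialisation round-trips", {
  net <- dnmnet(c(3, 1, 7), rbind(c(1, 3), c(3, 7)))
  f <- withr::local_tempfile(fileext = ".json")
  write_dnmnet(net, f)
  back <- read_dnmnet(f)
  expect_equal(back$nodes, c(1L, 3L, 7L))
  expect_equal(back$edges, rbind(c(1, 3), c(3, 7)))
})
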