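# The synthetic multi-omics generator: reproducibility, censoring
# calibration, missing-modality structure and the latent risk signal.

test_that("fixed seeds give identical datasets; presets are well-formed", {
  a <- simulate_multiomics(sim_config(n_patients = 50, seed = 5))
  b <- simulate_multiomics(sim_config(n_patients = 50, seed = 5))
  expect_identical(a$data$omics, b$data$omics)
  expect_identical(a$truth, b$truth)
  d <- simulate_multiomics(sim_config(n_patients = 50, seed = 6))
  expect_false(identical(a$data$omics$mRNA, d$data$omics$mRNA))

  tiny <- make_fixture("tiny")
  expect_equal(n_patients(tiny$data), 20L)
  expect_equal(length(tiny$data$omics), 3L)  # + clinical = 4 modalities
  # at least one patient per single-modality-missing pattern
  av <- tiny$data$availability
  for (mod in c("mRNA", "miRNA", "CNV")) {
    expect_true(any(av[, mod] == 0))
  }
  expect_error(make_fixture("nope"), "unknown fixture preset")
})

test_that("omics are nonnegative with heterogeneous variances; zero rows match mask", {
  sim <- simulate_multiomics(sim_config(n_patients = 120, seed = 2,
                                        missing_rate = c(mRNA = 0.2,
                                                         miRNA = 0.1)))
  for (mod in names(sim$data$omics)) {
    X <- sim$data$omics[[mod]]
    av <- sim$data$availability[, mod] == 1
    expect_true(all(X >= 0))
    v <- apply(X[av, ], 2, var)
    expect_gt(max(v) / max(min(v), 1e-12), 10)  # spread of feature scales
    expect_true(all(X[!av, ] == 0))
    expect_true(mean(!av) > 0)
  }
})

test_that("censoring calibration hits the requested rate within 0.05", {
  for (target in c(0.2, 0.4)) {
    sim <- simulate_multiomics(sim_config(n_patients = 600,
                                          censoring_rate = target,
                                          seed = 9))
    expect_lt(abs(sim$achieved_censoring - target), 0.05)
  }
  # zero censoring: every patient an event
  sim0 <- simulate_multiomics(sim_config(n_patients = 100,
                                         censoring_rate = 0, seed = 3))
  expect_true(all(sim0$data$survival$event == 1))
})

test_that("low noise, uncensored: event-time ranks track the true risk", {
  sim <- simulate_multiomics(sim_config(
    n_patients = 500, censoring_rate = 0, noise_sd = 0.05,
    risk_coef = 4, seed = 14))
  # strong hazard differences make time ordering follow risk ordering
  tau <- cor(sim$truth$risk, -sim$data$survival$time, method = "kendall")
  expect_gt(tau, 0.7)
  oc <- c_index(sim$truth$risk, sim$data$survival$time,
                sim$data$survival$event)$c_index
  expect_gt(oc, 0.85)
})

test_that("the signal lives where signal_split puts it", {
  sim <- simulate_multiomics(sim_config(
    n_patients = 300, censoring_rate = 0,
    signal_split = c(mRNA = 1),
    missing_rate = c(mRNA = 0, miRNA = 0), seed = 21))
  time <- sim$data$survival$time; event <- sim$data$survival$event
  # a model-free per-patient score: mean of the standardized informative
  # direction is unknown, so use correlation of each feature with risk and
  # aggregate the top features
  score_from <- function(X) {
    cors <- suppressWarnings(cor(log(pmax(X, 1e-9)), sim$truth$risk))
    cors[is.na(cors)] <- 0
    top <- order(abs(cors), decreasing = TRUE)[1:20]
    as.vector(scale(log(pmax(X[, top], 1e-9))) %*% sign(cors[top]))
  }
  c_mrna <- c_index(score_from(sim$data$omics$mRNA), time, event)$c_index
  expect_gt(c_mrna, 0.6)
  # permuting mRNA across patients destroys the association
  perm <- local({ set.seed(1); sample(nrow(sim$data$omics$mRNA)) })
  c_perm <- c_index(score_from(sim$data$omics$mRNA)[perm], time,
                    event)$c_index
  expect_lt(abs(c_perm - 0.5), 0.08)
  # miRNA carries no signal share here
  c_mir <- c_index(score_from(sim$data$omics$miRNA), time, event)$c_index
  expect_lt(abs(c_mir - 0.5), 0.1)
})

test_that("null preset carries no prognostic signal", {
  nl <- make_fixture("null")
  expect_true(all(nl$truth$risk == 0))
  # any fixed score is uninformative; a random score concentrates near 0.5
  set.seed(8)
  cs <- replicate(50, c_index(rnorm(n_patients(nl$data)),
                              nl$data$survival$time,
                              nl$data$survival$event)$c_index)
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})
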