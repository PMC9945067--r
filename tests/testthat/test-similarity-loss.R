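# Cross-modal similarity loss: closed forms, brute-force oracle agreement,
# invariances, matched-pairing contract and analytic gradients.

test_that("similarity closed forms", {
  set.seed(1)
  v <- rnorm(6)
  A <- cbind(v, v)
  expect_equal(cross_patient_sim(A, A), 2)      # 2 modalities, cosine 1 each
  expect_equal(within_patient_sim(A), 1)        # single pair, cosine 1
  A4 <- cbind(v, v, v, v)
  expect_equal(within_patient_sim(A4), 6)       # C(4,2) pairs
  # orthogonal representations
  O <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Oy <- cbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(cross_patient_sim(O, Oy), 0)
  expect_equal(within_patient_sim(O), 0)
  # collapse: all four vectors identical -> hinge of 0.2 + 2 - 1 = 1.2
  expect_equal(pair_loss(A, A, margin = 0.2), 1.2)
  # well-separated: own modalities aligned, patients orthogonal -> 0
  expect_equal(pair_loss(O * 0 + cbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                         cbind(c(0, 1, 0, 0), c(0, 1, 0, 0)),
                         margin = 0.2), 0)
})

test_that("similarity terms match the loop-based oracle on random input", {
  set.seed(33)
  for (rep in 1:25) {
    m <- sample(3:8, 1); n <- sample(2:4, 1)
    Ax <- rand_repr(m, n); Ay <- rand_repr(m, n)
    expect_equal(cross_patient_sim(Ax, Ay), oracle_cross_sim(Ax, Ay),
                 tolerance = 1e-6)
    expect_equal(within_patient_sim(Ax), oracle_within_sim(Ax),
                 tolerance = 1e-6)
    expect_equal(pair_loss(Ax, Ay, 0.2), oracle_pair_loss(Ax, Ay, 0.2),
                 tolerance = 1e-6)
  }
})

test_that("pair loss is symmetric, nonnegative and cosine-scale invariant", {
  set.seed(9)
  for (rep in 1:20) {
    Ax <- rand_repr(5, 3); Ay <- rand_repr(5, 3)
    lx <- pair_loss(Ax, Ay); ly <- pair_loss(Ay, Ax)
    expect_equal(lx, ly)
    expect_gte(lx, 0)
    # positive per-column rescaling never changes any cosine
    sc <- runif(3, 0.1, 7)
    Ax_s <- sweep(Ax, 2, sc, "*")
    expect_equal(pair_loss(Ax_s, Ay), lx, tolerance = 1e-10)
  }
})

test_that("zero-norm (unavailable) modalities are skipped, not NaN", {
  set.seed(5)
  Ax <- rand_repr(4, 3); Ay <- rand_repr(4, 3)
  Ax[, 2] <- 0  # patient x lacks modality 2
  expect_false(is.nan(cross_patient_sim(Ax, Ay)))
  expect_equal(cross_patient_sim(Ax, Ay),
               oracle_cosine(Ax[, 1], Ay[, 1]) +
                 oracle_cosine(Ax[, 3], Ay[, 3]), tolerance = 1e-12)
  expect_equal(within_patient_sim(Ax),
               oracle_cosine(Ax[, 1], Ax[, 3]), tolerance = 1e-12)
})

test_that("batch loss pairs exactly floor(B/2) disjoint couples", {
  set.seed(21)
  batch <- lapply(1:7, function(i) rand_repr(6, 2))
  res <- batch_similarity_loss(batch, pairing_seed = 4)
  expect_equal(attr(res, "n_pairs"), 3L)           # odd leftover unpaired
  pairs <- attr(res, "pairs")
  expect_equal(length(unique(as.vector(pairs))), 6L)  # disjoint
  # batch of 4: exactly 2 pair terms, never the C(4,2) = 6 of all-pairs
  res4 <- batch_similarity_loss(batch[1:4], pairing_seed = 4)
  expect_equal(attr(res4, "n_pairs"), 2L)
  expect_equal(oracle_all_pairs_loss(batch[1:4], 0.2)$n_terms, 6L)
  # determinism and sensitivity to the pairing seed
  expect_equal(as.numeric(batch_similarity_loss(batch, pairing_seed = 4)),
               as.numeric(res))
  # batch of 2: only one possible pairing, so it equals both pair_loss and
  # the all-pairs oracle
  two <- batch[1:2]
  expect_equal(as.numeric(batch_similarity_loss(two, pairing_seed = 1)),
               oracle_all_pairs_loss(two, 0.2)$loss)
  expect_warning(r1 <- batch_similarity_loss(batch[1]), "batch size < 2")
  expect_equal(as.numeric(r1), 0)
})

test_that("collapsed batch of two reproduces the analytic hinge value", {
  v <- rnorm(8)
  A <- cbind(v, v)
  expect_equal(as.numeric(batch_similarity_loss(list(A, A), margin = 0.2,
                                                pairing_seed = 1)), 1.2)
})

test_that("mean reduction divides the summed pair terms by their count", {
  set.seed(13)
  batch <- lapply(1:6, function(i) rand_repr(5, 2))
  s <- batch_similarity_loss(batch, pairing_seed = 2, reduction = "sum")
  m <- batch_similarity_loss(batch, pairing_seed = 2, reduction = "mean")
  expect_equal(as.numeric(m), as.numeric(s) / 3)
})

test_that("analytic pair-loss gradient matches central finite differences", {
  set.seed(99)
  for (rep in 1:5) {
    Ax <- rand_repr(4, 2); Ay <- rand_repr(4, 2)
    g <- coxfuse:::pair_loss_grad(Ax, Ay, margin = 0.6)
    if (g$loss == 0) next
    eps <- 1e-6
    for (target in c("x", "y")) {
      M <- if (target == "x") Ax else Ay
      num <- M * 0
      for (i in seq_len(nrow(M))) {
        for (j in seq_len(ncol(M))) {
          Mp <- M; Mp[i, j] <- M[i, j] + eps
          Mm <- M; Mm[i, j] <- M[i, j] - eps
          num[i, j] <- if (target == "x") {
            (pair_loss(Mp, Ay, 0.6) - pair_loss(Mm, Ay, 0.6)) / (2 * eps)
          } else {
            (pair_loss(Ax, Mp, 0.6) - pair_loss(Ax, Mm, 0.6)) / (2 * eps)
          }
        }
      }
      ana <- if (target == "x") g$dAx else g$dAy
      expect_lt(max(abs(ana - num)), 1e-4)
    }
  }
})
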