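# Attention fusion: scores, row-stochastic softmax weights, convex fusion
# and the forced-uniform variant.

test_that("attention scores are tanh(W_j alpha_j) and bounded", {
  m <- 5; n <- 3
  A <- rand_repr(m, n)
  W <- lapply(1:n, function(j) matrix(rnorm(m * m), m, m))
  S <- attention_scores(W, A)
  # explicit loop oracle
  for (j in 1:n) {
    sj <- numeric(m)
    for (i in 1:m) sj[i] <- tanh(sum(W[[j]][i, ] * A[, j]))
    expect_equal(S[, j], sj, tolerance = 1e-6)
  }
  expect_true(all(abs(S) < 1))
  # zero weights or zero representation give zero scores
  W0 <- lapply(1:n, function(j) matrix(0, m, m))
  expect_true(all(attention_scores(W0, A) == 0))
  expect_true(all(attention_scores(W, A * 0) == 0))
  # array form is accepted
  Warr <- array(0, c(n, m, m))
  for (j in 1:n) Warr[j, , ] <- W[[j]]
  expect_equal(attention_scores(Warr, A), S)
})

test_that("softmax weights are row-stochastic with known closed forms", {
  # equal scores -> uniform 1/n
  S <- matrix(1, 4, 3)
  P <- attention_weights(S)
  expect_true(all(abs(P - 1 / 3) < 1e-12))
  # n = 2, scores (1, 1 + ln 3) -> weights (0.25, 0.75)
  P2 <- attention_weights(matrix(c(1, 1 + log(3)), 1, 2))
  expect_equal(as.vector(P2), c(0.25, 0.75), tolerance = 1e-12)
  # random scores: rows sum to 1, all entries in (0,1)
  set.seed(2)
  Pr <- attention_weights(matrix(rnorm(40), 10, 4))
  expect_equal(rowSums(Pr), rep(1, 10), tolerance = 1e-9)
  expect_true(all(Pr > 0 & Pr < 1))
  # stability under large scores (max-shift): no overflow
  Pb <- attention_weights(matrix(c(1000, 999), 1, 2))
  expect_equal(rowSums(Pb), 1, tolerance = 1e-9)
})

test_that("masking drops missing modalities and renormalizes", {
  S <- matrix(rnorm(12), 4, 3)
  P <- attention_weights(S, available = c(TRUE, FALSE, TRUE))
  expect_true(all(P[, 2] == 0))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  expect_error(attention_weights(S, available = c(FALSE, FALSE, FALSE)),
               "no available modality")
})

test_that("fusion is the attention-weighted row sum with convex output", {
  set.seed(8)
  m <- 6; n <- 3
  A <- rand_repr(m, n)
  P <- attention_weights(matrix(rnorm(m * n), m, n))
  cv <- fuse(P, A)
  # double-loop oracle
  oracle <- numeric(m)
  for (i in 1:m) for (j in 1:n) oracle[i] <- oracle[i] + P[i, j] * A[i, j]
  expect_equal(cv, oracle, tolerance = 1e-6)
  # convexity: each c_i within the row range of A
  expect_true(all(cv >= apply(A, 1, min) - 1e-12))
  expect_true(all(cv <= apply(A, 1, max) + 1e-12))
  # one-hot column selects that modality exactly
  P1 <- matrix(0, m, n); P1[, 2] <- 1
  expect_equal(fuse(P1, A), A[, 2])
  # linearity in A for fixed P
  A2 <- rand_repr(m, n)
  expect_equal(fuse(P, 2 * A + A2), 2 * fuse(P, A) + fuse(P, A2),
               tolerance = 1e-12)
})

test_that("uniform fusion equals the row mean and the all-ones-score path", {
  set.seed(4)
  A <- rand_repr(5, 4)
  expect_equal(fuse_uniform(A), rowMeans(A))
  # consistency with softmax of constant scores
  expect_equal(fuse_uniform(A),
               fuse(attention_weights(matrix(1, 5, 4)), A),
               tolerance = 1e-12)
  # invariant to modality order
  perm <- c(3, 1, 4, 2)
  expect_equal(fuse_uniform(A[, perm]), fuse_uniform(A))
  # restricted to available modalities
  A[, 2] <- 0
  expect_equal(fuse_uniform(A), rowMeans(A[, c(1, 3, 4)]))
})

test_that("batched attention backward matches finite differences", {
  set.seed(17)
  B <- 3; m <- 4; n <- 2
  Rlist <- lapply(1:n, function(j) matrix(rnorm(B * m), B, m))
  W <- lapply(1:n, function(j) matrix(rnorm(m * m, sd = 0.5), m, m))
  avail <- matrix(1, B, n); avail[2, 2] <- 0
  Rlist[[2]][2, ] <- 0
  loss_of <- function(Rl, Wl) {
    fw <- coxfuse:::att_forward(Rl, Wl, avail)
    sum(sin(fw$C))  # arbitrary smooth downstream loss
  }
  fw <- coxfuse:::att_forward(Rlist, W, avail)
  dC <- cos(fw$C)
  bw <- coxfuse:::att_backward(dC, fw, Rlist, W)
  eps <- 1e-6
  for (j in 1:n) {
    numR <- Rlist[[j]] * 0
    for (k in seq_along(numR)) {
      Rp <- Rlist; Rp[[j]][k] <- Rp[[j]][k] + eps
      Rm <- Rlist; Rm[[j]][k] <- Rm[[j]][k] - eps
      numR[k] <- (loss_of(Rp, W) - loss_of(Rm, W)) / (2 * eps)
    }
    expect_lt(max(abs(bw$dR[[j]] - numR)), 1e-5)
    numW <- W[[j]] * 0
    for (k in seq_along(numW)) {
      Wp <- W; Wp[[j]][k] <- Wp[[j]][k] + eps
      Wm <- W; Wm[[j]][k] <- Wm[[j]][k] - eps
      numW[k] <- (loss_of(Rlist, Wp) - loss_of(Rlist, Wm)) / (2 * eps)
    }
    expect_lt(max(abs(bw$dW[[j]] - numW)), 1e-5)
  }
})
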