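# Independent brute-force oracles (explicit loops, no shared code with the
# implementation) and small fixture builders used across the test files.

oracle_cosine <- function(u, v) {
  num <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  if (nu == 0 || nv == 0) return(0)
  num / (sqrt(nu) * sqrt(nv))
}

oracle_cross_sim <- function(Ax, Ay) {
  s <- 0
  for (j in seq_len(ncol(Ax))) s <- s + oracle_cosine(Ax[, j], Ay[, j])
  s
}

oracle_within_sim <- function(Ax) {
  s <- 0
  n <- ncol(Ax)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) s <- s + oracle_cosine(Ax[, i], Ax[, j])
    }
  }
  s
}

oracle_pair_loss <- function(Ax, Ay, margin) {
  max(0, margin + oracle_cross_sim(Ax, Ay) -
        0.5 * oracle_within_sim(Ax) - 0.5 * oracle_within_sim(Ay))
}

# The all-pairs contrastive variant (every unordered patient pair in the
# batch): the quadratic-cost alternative the matched-pairing loss avoids.
oracle_all_pairs_loss <- function(A_list, margin) {
  B <- length(A_list)
  s <- 0; n_terms <- 0
  for (x in seq_len(B)) {
    for (y in seq_len(B)) {
      if (x < y) {
        s <- s + oracle_pair_loss(A_list[[x]], A_list[[y]], margin)
        n_terms <- n_terms + 1
      }
    }
  }
  list(loss = s, n_terms = n_terms)
}

oracle_cox_npll <- function(h, time, event) {
  n_ev <- sum(event == 1)
  total <- 0
  for (i in seq_along(h)) {
    if (event[i] == 1) {
      denom <- 0
      for (j in seq_along(h)) {
        if (time[j] >= time[i]) denom <- denom + exp(h[j])
      }
      total <- total + (h[i] - log(denom))
    }
  }
  -total / n_ev
}

# Exhaustive enumeration of the concordance definition over ordered pairs.
oracle_c_index <- function(h, time, event, ties = "half") {
  num <- 0; den <- 0
  for (i in seq_along(h)) {
    for (j in seq_along(h)) {
      if (i != j && time[i] > time[j] && event[j] == 1) {
        den <- den + 1
        if (h[i] < h[j]) num <- num + 1
        else if (ties == "half" && h[i] == h[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) NaN else num / den
}

# random m x n representation matrix with unit-scale entries
rand_repr <- function(m, n) matrix(stats::rnorm(m * n), m, n)

# cached tiny fixture: cheap enough to rebuild but shared for convenience
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("tiny")
    cache
  }
})

# small fast training configuration for structural tests
fast_config <- function(...) {
  synthetic_config(m = 16L, hazard_hidden = c(8L, 4L), batch_size = 16L,
                   epochs = 3L, patience = 3L,
                   encoders = list(mRNA = list(hidden = 16L),
                                   miRNA = list(hidden = 16L),
                                   CNV = list(hidden = 16L)),
                   ...)
}
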