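# The unsupervised cross-modal similarity loss with random in-batch pairing.
# For a patient x with modality representations alpha_1(x), ..., alpha_n(x)
# (the columns of an m x n representation matrix A):
#   sim(x, y)  = sum_i cos(alpha_i(x), alpha_i(y))          (same modality,
#                                                            two patients)
#   sim(x, x)  = sum_{i<j} cos(alpha_i(x), alpha_j(x))      (two modalities,
#                                                            one patient)
#   L(x, y)    = max{0, M + sim(x,y) - sim(x,x)/2 - sim(y,y)/2}
#   Lsim       = sum over randomly matched disjoint pairs of L(x, y).
# Pairing is a seeded random permutation matching consecutive patients, so a
# batch of size B contributes floor(B/2) pair terms (not all C(B,2) pairs).
# Modalities with availability 0 (zero-norm columns, whose cosine is
# undefined) are skipped in every sum.

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# d cos(u,v) / du and /dv
cosine_grad <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    return(list(c = 0, du = u * 0, dv = v * 0))
  }
  cs <- sum(u * v) / (nu * nv)
  list(c = cs, du = v / (nu * nv) - cs * u / nu^2,
       dv = u / (nu * nv) - cs * v / nv^2)
}

avail_from_matrix <- function(A) colSums(A^2) > 0

#' Cross-patient modality similarity
#'
#' Sum over modalities of the cosine similarity between the two patients'
#' representations of the same modality. Modalities where either patient is
#' unavailable (zero-norm column) contribute 0.
#'
#' @param Ax,Ay m x n representation matrices (columns are modalities).
#' @param available_x,available_y optional logical availability flags of
#'   length n; default: a modality counts as available iff its column has
#'   nonzero norm.
#' @return A single real number.
#' @export
cross_patient_sim <- function(Ax, Ay, available_x = NULL, available_y = NULL) {
  stopifnot(identical(dim(Ax), dim(Ay)))
  ax <- available_x %||% avail_from_matrix(Ax)
  ay <- available_y %||% avail_from_matrix(Ay)
  s <- 0
  for (j in which(ax & ay)) s <- s + cosine_sim(Ax[, j], Ay[, j])
  s
}

#' Within-patient modality similarity
#'
#' Sum over unordered modality pairs i < j of the cosine similarity between
#' a patient's own representations of modalities i and j. Pairs involving an
#' unavailable modality contribute 0.
#'
#' @param Ax m x n representation matrix.
#' @param available optional logical availability flags of length n.
#' @return A single real number.
#' @export
within_patient_sim <- function(Ax, available = NULL) {
  av <- available %||% avail_from_matrix(Ax)
  n <- ncol(Ax)
  s <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (!av[i]) next
      for (j in seq((i + 1), n)) {
        if (av[j]) s <- s + cosine_sim(Ax[, i], Ax[, j])
      }
    }
  }
  s
}

#' Margin-based pair loss between two patients
#'
#' Hinge of margin + cross-patient similarity minus the mean of the two
#' within-patient similarities; always nonnegative. Minimizing it pulls a
#' patient's own modalities together and pushes different patients' same-
#' modality representations apart.
#'
#' @param Ax,Ay m x n representation matrices.
#' @param margin hinge margin M (default 0.2).
#' @param available_x,available_y optional availability flags.
#' @return Nonnegative real.
#' @export
pair_loss <- function(Ax, Ay, margin = 0.2,
                      available_x = NULL, available_y = NULL) {
  stopifnot(margin >= 0)
  max(0, margin + cross_patient_sim(Ax, Ay, available_x, available_y) -
        0.5 * within_patient_sim(Ax, available_x) -
        0.5 * within_patient_sim(Ay, available_y))
}

#' Batch similarity loss with random matched pairing
#'
#' Applies a seeded random permutation to the batch, matches consecutive
#' disjoint pairs (1st with 2nd, 3rd with 4th, ...) and sums [pair_loss()]
#' over the matched pairs only; an odd leftover patient contributes 0.
#'
#' @param A list of m x n representation matrices, or an m x n x B array.
#' @param margin hinge margin M (default 0.2).
#' @param pairing_seed integer seed for the pairing permutation.
#' @param reduction `"sum"` (as defined) or `"mean"` over pair terms.
#' @return The loss, with attributes `n_pairs` (number of pair terms
#'   evaluated, floor(B/2)) and `pairs` (the matched index pairs).
#' @export
batch_similarity_loss <- function(A, margin = 0.2, pairing_seed = 1L,
                                  reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.array(A) && length(dim(A)) == 3) {
    A <- lapply(seq_len(dim(A)[3]), function(b) A[, , b])
  }
  B <- length(A)
  if (B < 2) {
    warning("batch_similarity_loss: batch size < 2, returning 0")
    return(structure(0, n_pairs = 0L, pairs = matrix(integer(), 0, 2)))
  }
  perm <- local_seed(pairing_seed, sample.int(B))
  np <- B %/% 2L
  pairs <- matrix(perm[seq_len(2L * np)], ncol = 2, byrow = TRUE)
  terms <- apply(pairs, 1, function(p) pair_loss(A[[p[1]]], A[[p[2]]], margin))
  loss <- if (reduction == "mean") mean(terms) else sum(terms)
  structure(loss, n_pairs = np, pairs = pairs)
}

# ---- batched training-path version with analytic gradients ----------------

# Representations as the training loop carries them: Rlist[[j]] is B x m for
# modality j; avail is B x n. `pairs` is a 2-column matrix of matched batch
# indices. Returns the loss and dL/dRlist (same shapes).
sim_loss_batch <- function(Rlist, avail, margin, pairs,
                           reduction = "sum", want_grad = TRUE) {
  n <- length(Rlist)
  B <- nrow(avail)
  dR <- if (want_grad) lapply(Rlist, function(R) R * 0) else NULL
  np <- nrow(pairs)
  total <- 0
  scale <- if (reduction == "mean" && np > 0) 1 / np else 1
  for (r in seq_len(np)) {
    x <- pairs[r, 1]; y <- pairs[r, 2]
    ax <- avail[x, ] == 1; ay <- avail[y, ] == 1
    # forward: collect cosine terms and their gradients
    val <- margin
    contribs <- list()
    for (j in which(ax & ay)) {
      g <- cosine_grad(Rlist[[j]][x, ], Rlist[[j]][y, ])
      val <- val + g$c
      contribs[[length(contribs) + 1]] <-
        list(w = 1, jx = j, px = x, du = g$du, jy = j, py = y, dv = g$dv)
    }
    for (p in list(list(i = x, av = ax), list(i = y, av = ay))) {
      if (n >= 2) {
        for (i in seq_len(n - 1)) {
          if (!p$av[i]) next
          for (j in seq((i + 1), n)) {
            if (!p$av[j]) next
            g <- cosine_grad(Rlist[[i]][p$i, ], Rlist[[j]][p$i, ])
            val <- val - 0.5 * g$c
            contribs[[length(contribs) + 1]] <-
              list(w = -0.5, jx = i, px = p$i, du = g$du,
                   jy = j, py = p$i, dv = g$dv)
          }
        }
      }
    }
    if (val > 0) {
      total <- total + val
      if (want_grad) {
        for (cb in contribs) {
          dR[[cb$jx]][cb$px, ] <- dR[[cb$jx]][cb$px, ] + scale * cb$w * cb$du
          dR[[cb$jy]][cb$py, ] <- dR[[cb$jy]][cb$py, ] + scale * cb$w * cb$dv
        }
      }
    }
  }
  list(loss = total * scale, n_pairs = np, dR = dR)
}

# Analytic gradient of pair_loss with respect to both representation
# matrices; used by the finite-difference gradient tests.
pair_loss_grad <- function(Ax, Ay, margin = 0.2) {
  Rlist <- lapply(seq_len(ncol(Ax)), function(j) rbind(Ax[, j], Ay[, j]))
  avail <- rbind(as.numeric(avail_from_matrix(Ax)),
                 as.numeric(avail_from_matrix(Ay)))
  res <- sim_loss_batch(Rlist, avail, margin, pairs = matrix(c(1L, 2L), 1))
  dAx <- sapply(res$dR, function(d) d[1, ])
  dAy <- sapply(res$dR, function(d) d[2, ])
  list(loss = res$loss, dAx = matrix(dAx, nrow(Ax)), dAy = matrix(dAy, nrow(Ay)))
}
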