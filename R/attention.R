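# Attention-based fusion of the n modality representations into one fused
# vector c of length m. Per modality j, a score vector s_j = tanh(W_j alpha_j)
# is computed from a learned tensor W (n stacked m x m matrices); the softmax
# across modalities of each feature row of (s_1 ... s_n) gives a
# row-stochastic attention matrix P, and c_i = sum_j p_ij * a_ij. Missing
# modalities are (by default) masked out of the softmax so their weight is
# exactly zero and the remaining weights renormalize.

as_W_list <- function(W, n = NULL) {
  if (is.array(W) && length(dim(W)) == 3) {
    W <- lapply(seq_len(dim(W)[1]), function(j) W[j, , ])
  }
  stopifnot(is.list(W))
  if (!is.null(n) && length(W) != n) stop("attention tensor has wrong modality count")
  W
}

#' Attention scores s_j = tanh(W_j alpha_j)
#'
#' @param W attention weights: a list of n m x m matrices, or an n x m x m
#'   array.
#' @param A m x n representation matrix for one patient.
#' @return m x n score matrix with entries in (-1, 1).
#' @export
attention_scores <- function(W, A) {
  W <- as_W_list(W, ncol(A))
  S <- sapply(seq_along(W), function(j) tanh(W[[j]] %*% A[, j]))
  matrix(S, nrow(A), ncol(A))
}

#' Row-wise softmax attention weights
#'
#' Applies the softmax across modalities to each feature row of the score
#' matrix (with max-subtraction for numerical stability). Unavailable
#' modalities can be masked out, receiving weight exactly 0.
#'
#' @param S m x n score matrix.
#' @param available optional logical flags of length n; masked-out columns
#'   get zero weight and the rest renormalize. At least one modality must be
#'   available.
#' @return m x n attention matrix whose rows sum to 1.
#' @export
attention_weights <- function(S, available = NULL) {
  av <- available %||% rep(TRUE, ncol(S))
  if (!any(av)) stop("attention_weights: no available modality")
  S_av <- S[, av, drop = FALSE]
  mx <- apply(S_av, 1, max)
  E <- exp(S_av - mx)
  P <- matrix(0, nrow(S), ncol(S))
  P[, av] <- E / rowSums(E)
  P
}

#' Fuse a representation matrix with attention weights
#'
#' @param P m x n attention matrix (rows sum to 1).
#' @param A m x n representation matrix.
#' @return Fused vector c of length m with `c_i = sum_j P[i,j] * A[i,j]`.
#' @export
fuse <- function(P, A) {
  stopifnot(identical(dim(P), dim(A)))
  rowSums(P * A)
}

#' Uniform (attention-free) fusion
#'
#' Equivalent to forcing every score vector s_j to the all-ones vector, so
#' the softmax distributes weight evenly over the available modalities: the
#' fused vector is the row-wise mean of the available columns of A. This is
#' the fusion used by the unsupervised-only model variant.
#'
#' @param A m x n representation matrix.
#' @param available optional logical availability flags.
#' @return Fused vector of length m.
#' @export
fuse_uniform <- function(A, available = NULL) {
  av <- available %||% avail_from_matrix(A)
  if (!any(av)) return(rep(0, nrow(A)))
  rowMeans(A[, av, drop = FALSE])
}

# ---- batched training-path version ----------------------------------------

# Rlist[[j]]: B x m representations; avail: B x n; Wlist: n matrices m x m.
# mode "uniform" forces even weights over available modalities. When
# mask_missing is FALSE, zero columns enter the softmax like the zero-row
# imputation convention would imply (strict parity mode).
att_forward <- function(Rlist, Wlist, avail, mode = "attention",
                        mask_missing = TRUE) {
  n <- length(Rlist); B <- nrow(avail); m <- ncol(Rlist[[1]])
  eff_avail <- if (mask_missing) avail else matrix(1, B, n)
  if (mode == "uniform") {
    denom <- rowSums(eff_avail)
    denom[denom == 0] <- 1
    Plist <- lapply(seq_len(n), function(j) {
      matrix(eff_avail[, j] / denom, B, m)
    })
    Slist <- NULL
  } else {
    Slist <- lapply(seq_len(n), function(j) tanh(Rlist[[j]] %*% t(Wlist[[j]])))
    M <- matrix(-Inf, B, m)
    for (j in seq_len(n)) {
      rows <- eff_avail[, j] == 1
      if (any(rows)) M[rows, ] <- pmax(M[rows, , drop = FALSE],
                                       Slist[[j]][rows, , drop = FALSE])
    }
    M[!is.finite(M)] <- 0  # rows with no available modality
    Z <- matrix(0, B, m)
    Elist <- vector("list", n)
    for (j in seq_len(n)) {
      E <- exp(Slist[[j]] - M)
      E[eff_avail[, j] == 0, ] <- 0
      Elist[[j]] <- E
      Z <- Z + E
    }
    Z[Z == 0] <- 1
    Plist <- lapply(Elist, function(E) E / Z)
  }
  C <- matrix(0, B, m)
  for (j in seq_len(n)) C <- C + Plist[[j]] * Rlist[[j]]
  list(C = C, Plist = Plist, Slist = Slist)
}

# Backward pass: dC is B x m. Returns gradient contributions for the
# representations and the attention tensor.
att_backward <- function(dC, fw, Rlist, Wlist, mode = "attention") {
  n <- length(Rlist)
  dR <- vector("list", n)
  dW <- NULL
  # direct path through c = sum_j P_j * R_j
  for (j in seq_len(n)) dR[[j]] <- fw$Plist[[j]] * dC
  if (mode == "attention") {
    dW <- vector("list", n)
    G <- lapply(seq_len(n), function(j) dC * Rlist[[j]])   # dL/dP_j
    Tm <- Reduce(`+`, lapply(seq_len(n), function(j) fw$Plist[[j]] * G[[j]]))
    for (j in seq_len(n)) {
      dS <- fw$Plist[[j]] * (G[[j]] - Tm)        # softmax backward
      dZ <- dS * (1 - fw$Slist[[j]]^2)           # tanh backward
      dW[[j]] <- crossprod(dZ, Rlist[[j]])
      dR[[j]] <- dR[[j]] + dZ %*% Wlist[[j]]
    }
  }
  list(dR = dR, dW = dW)
}
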