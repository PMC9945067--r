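# Non-linear Cox hazard head and the averaged negative partial
# log-likelihood. The hazard head is a two-hidden-layer ReLU network ending
# in a single linear node; its scalar output h(x) is a log-relative-risk
# score. The partial likelihood compares each event patient's risk with the
# risk set {j : T_j >= T_i} (inclusive Breslow-style handling of ties),
# which keeps the loss invariant to adding a constant to all scores.

#' Averaged negative Cox partial log-likelihood
#'
#' `Lsur = -(1/N) * sum over events i of [ h_i - log sum_{j: T_j >= T_i} exp(h_j) ]`
#' with N the number of event (non-censored) patients. Risk sets are
#' inclusive (`T_j >= T_i`, patient i itself included), so tied event times
#' appear in each other's risk sets.
#'
#' @param h numeric vector of risk scores.
#' @param time observed event/censoring times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return The loss (a nonnegative real). With no events in the batch the
#'   loss is defined as 0 and a warning is raised (gradient-free batch).
#' @export
cox_npll <- function(h, time, event) {
  stopifnot(length(h) == length(time), length(h) == length(event),
            all(is.finite(h)))
  ev <- which(event == 1)
  if (length(ev) == 0) {
    warning("cox_npll: no events in batch, loss defined as 0")
    return(0)
  }
  hm <- h - max(h)  # shift-invariant, numerically stable
  eh <- exp(hm)
  ll <- vapply(ev, function(i) {
    hm[i] - log(sum(eh[time >= time[i]]))
  }, numeric(1))
  -mean(ll)
}

#' Gradient of [cox_npll()] with respect to the risk scores
#'
#' @inheritParams cox_npll
#' @return Numeric vector `d Lsur / d h` of the same length as `h`.
#' @export
cox_npll_grad <- function(h, time, event) {
  ev <- which(event == 1)
  n_ev <- length(ev)
  if (n_ev == 0) return(h * 0)
  hm <- h - max(h)
  eh <- exp(hm)
  # M[k, i] = 1 if patient k is in the risk set of event i
  M <- outer(time, time[ev], ">=")
  denom <- as.vector(crossprod(M, eh))
  contrib <- eh * as.vector(M %*% (1 / denom))
  (contrib - (event == 1)) / n_ev
}

#' Combined training objective
#'
#' `L = Lsur + lambda * Lsim`: the Cox loss plus the weighted cross-modal
#' similarity loss. `lambda = 0` recovers the fusion-only model variant.
#'
#' @param lsur Cox partial-likelihood loss.
#' @param lsim similarity loss.
#' @param lambda nonnegative balance factor (default 0.3).
#' @return The combined loss.
#' @export
combined_loss <- function(lsur, lsim, lambda = 0.3) {
  stopifnot(lambda >= 0)
  lsur + lambda * lsim
}

# ---- hazard head (internal) ------------------------------------------------

init_hazard <- function(m, hidden) {
  stopifnot(length(hidden) == 2)
  list(W1 = he_init(m, hidden[1]), b1 = rep(0, hidden[1]),
       W2 = he_init(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
       W3 = glorot_init(hidden[2], 1), b3 = 0)
}

hazard_forward <- function(par, C) {
  l1 <- nn_linear_fwd(C, par$W1, par$b1); r1 <- nn_relu_fwd(l1$out)
  l2 <- nn_linear_fwd(r1$out, par$W2, par$b2); r2 <- nn_relu_fwd(l2$out)
  l3 <- nn_linear_fwd(r2$out, par$W3, par$b3)
  list(h = as.vector(l3$out), cache = list(l1 = l1, r1 = r1, l2 = l2,
                                           r2 = r2, l3 = l3))
}

hazard_backward <- function(dh, cache, par) {
  d3 <- nn_linear_bwd(matrix(dh, ncol = 1), cache$l3, par$W3)
  d2r <- nn_relu_bwd(d3$dX, cache$r2)
  d2 <- nn_linear_bwd(d2r, cache$l2, par$W2)
  d1r <- nn_relu_bwd(d2$dX, cache$r1)
  d1 <- nn_linear_bwd(d1r, cache$l1, par$W1)
  list(dC = d1$dX,
       dpar = list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db,
                   W3 = d3$dW, b3 = d3$db))
}
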