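# Model fitting: minimizes L = Lsur + lambda * Lsim by minibatch Adam over
# the encoder, attention and hazard-head parameters, with early stopping on
# validation C-index. Risk sets for the Cox loss are formed within each
# minibatch (standard practice for neural Cox models), so the batch size
# should be large enough for stable risk sets; validation metrics use the
# full validation set.

#' Fit a multimodal neural Cox survival model
#'
#' Trains modality-specific encoders, attention fusion and a non-linear Cox
#' hazard head end to end on a [multimodal_dataset]. Preprocessing (variance
#' filtering, min-max scaling, clinical vocabularies) is fitted on the
#' training split and frozen. Training minimizes the averaged negative Cox
#' partial log-likelihood plus `lambda` times the cross-modal similarity
#' loss, and keeps the parameters of the epoch with the best validation
#' C-index.
#'
#' @param data a [multimodal_dataset].
#' @param config a [coxfuse_config()].
#' @param split optional list with `train`, `val`, `test` index vectors;
#'   default: a seeded split in `config$split` fractions.
#' @param epochs optional override of `config$epochs`; `epochs = 0` returns
#'   the initialized, untrained model (useful for inspecting the
#'   architecture).
#' @param verbose print per-epoch metrics.
#' @return An object of class `coxfuse` with, among others, `history`
#'   (per-epoch losses and validation C-index), `best_epoch`, and the frozen
#'   preprocessing state. Use [predict.coxfuse()] for risk scores,
#'   [summary.coxfuse()] for split-wise concordance, [plot.coxfuse()] for
#'   training curves.
#' @export
coxfuse <- function(data, config = coxfuse_config(), split = NULL,
                    epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "multimodal_dataset"),
            inherits(config, "coxfuse_config"))
  cl <- match.call()
  n <- n_patients(data)
  split <- split %||% split_dataset(n, config$split, config$seed)
  stopifnot(all(c("train", "val", "test") %in% names(split)))

  prep <- fit_preprocessor(data, config, split$train)
  proc <- apply_preprocessor(prep, data)
  meta <- build_meta(prep, proc, config)
  params <- init_model_params(meta, config$seed)
  n_epochs <- as.integer(epochs %||% config$epochs)

  model <- structure(
    list(params = params, meta = meta, prep = prep, proc = proc,
         config = config, split = split, history = NULL,
         best_epoch = 0L, call = cl),
    class = "coxfuse"
  )
  if (n_epochs == 0) return(model)

  model$params <- NULL  # filled with the best parameters below
  train_idx <- split$train
  state <- adam_init(params)
  best <- list(c = -Inf, params = params, epoch = 0L)
  wait <- 0L
  pair_counter <- 0L
  hist <- vector("list", n_epochs)

  eval_metrics <- function(params, idx) {
    if (!length(idx)) return(list(lsur = NA_real_, c = NA_real_))
    fw <- model_repr_forward(params, meta, proc, idx, training = FALSE)
    att <- att_forward(fw$Rlist, params$att$W, fw$avail,
                       mode = config$fusion,
                       mask_missing = config$mask_missing)
    h <- hazard_forward(params$haz, att$C)$h
    lsur <- if (any(proc$event[idx] == 1)) {
      cox_npll(h, proc$time[idx], proc$event[idx])
    } else NA_real_
    ci <- c_index(h, proc$time[idx], proc$event[idx])
    list(lsur = lsur, c = ci$c_index)
  }

  local_seed(config$seed + 1L, {
    for (ep in seq_len(n_epochs)) {
      order_ep <- sample(train_idx)
      starts <- seq(1, length(order_ep), by = config$batch_size)
      lsur_ep <- 0; lsim_ep <- 0; nb <- 0L
      for (s in starts) {
        idx_b <- order_ep[s:min(s + config$batch_size - 1, length(order_ep))]
        if (length(idx_b) < 2) next
        B <- length(idx_b)
        fw <- model_repr_forward(params, meta, proc, idx_b, training = TRUE)
        params <- fw$params
        att <- att_forward(fw$Rlist, params$att$W, fw$avail,
                           mode = config$fusion,
                           mask_missing = config$mask_missing)
        hz <- hazard_forward(params$haz, att$C)
        tb <- proc$time[idx_b]; eb <- proc$event[idx_b]
        if (any(eb == 1)) {
          lsur <- cox_npll(hz$h, tb, eb)
          dh <- cox_npll_grad(hz$h, tb, eb)
        } else {
          lsur <- 0; dh <- hz$h * 0
        }
        sim <- if (config$lambda > 0) {
          pair_counter <- pair_counter + 1L
          perm <- local_seed(config$pairing_seed + pair_counter,
                             sample.int(B))
          np <- B %/% 2L
          prs <- matrix(perm[seq_len(2L * np)], ncol = 2, byrow = TRUE)
          sim_loss_batch(fw$Rlist, fw$avail, config$margin, prs,
                         reduction = config$pair_reduction)
        } else list(loss = 0, dR = NULL)
        loss <- combined_loss(lsur, sim$loss, config$lambda)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged at epoch %d (non-finite loss); lower the learning rate or batch size", ep))
        }
        hzb <- hazard_backward(dh, hz$cache, params$haz)
        attb <- att_backward(hzb$dC, att, fw$Rlist, params$att$W,
                             mode = config$fusion)
        dR <- attb$dR
        names(dR) <- names(fw$Rlist)
        if (!is.null(sim$dR)) {
          for (j in seq_along(dR)) {
            dR[[j]] <- dR[[j]] + config$lambda * sim$dR[[j]]
          }
        }
        genc <- model_repr_backward(dR, fw, params, meta)
        grads <- list(enc = genc, att = list(W = attb$dW), haz = hzb$dpar)
        upd <- adam_step(params, grads, state, config$lr)
        params <- upd$params; state <- upd$state
        lsur_ep <- lsur_ep + lsur; lsim_ep <- lsim_ep + sim$loss
        nb <- nb + 1L
      }
      val <- eval_metrics(params, split$val)
      hist[[ep]] <- data.frame(
        epoch = ep, lsur_train = lsur_ep / max(nb, 1),
        lsim_train = lsim_ep / max(nb, 1),
        lsur_val = val$lsur, cindex_val = val$c
      )
      if (verbose) {
        message(sprintf(
          "epoch %3d  Lsur %.4f  Lsim %.4f  val Lsur %.4f  val C %.4f",
          ep, lsur_ep / max(nb, 1), lsim_ep / max(nb, 1),
          val$lsur, val$c))
      }
      if (length(split$val)) {
        if (is.finite(val$c) && val$c > best$c + 1e-6) {
          best <- list(c = val$c, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      } else {
        best <- list(c = NA_real_, params = params, epoch = ep)
      }
    }
  })

  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}

# eval-mode forward to risk scores / fused vectors on preprocessed arrays
model_predict_proc <- function(object, proc, idx = NULL) {
  idx <- idx %||% seq_along(proc$patient_ids)
  fw <- model_repr_forward(object$params, object$meta, proc, idx,
                           training = FALSE)
  att <- att_forward(fw$Rlist, object$params$att$W, fw$avail,
                     mode = object$config$fusion,
                     mask_missing = object$config$mask_missing)
  h <- hazard_forward(object$params$haz, att$C)$h
  list(h = h, C = att$C, Rlist = fw$Rlist, Plist = att$Plist,
       avail = fw$avail, ids = proc$patient_ids[idx])
}

#' Predict from a fitted multimodal survival model
#'
#' @param object a fitted [coxfuse()] model.
#' @param newdata optional [multimodal_dataset]; default: the data the model
#'   was fitted on. New data are passed through the frozen preprocessing
#'   (selected features, training-split scalers, vocabularies with unseen
#'   categories mapped to the reserved unknown code).
#' @param type `"risk"` (log-relative-risk scores; higher = earlier expected
#'   event), `"fused"` (patients x m fused vectors), `"representation"`
#'   (patients x m x modality array of encoder outputs) or `"attention"`
#'   (patients x m x modality array of softmax weights).
#' @param ... ignored.
#' @return A named vector (`risk`), matrix (`fused`) or 3-d array.
#' @export
predict.coxfuse <- function(object, newdata = NULL,
                            type = c("risk", "fused", "representation",
                                     "attention"), ...) {
  type <- match.arg(type)
  proc <- if (is.null(newdata)) object$proc else
    apply_preprocessor(object$prep, newdata)
  out <- model_predict_proc(object, proc)
  mods <- object$meta$modalities
  stack <- function(lst) {
    arr <- array(unlist(lst), dim = c(length(out$ids), object$meta$m,
                                      length(mods)),
                 dimnames = list(out$ids, NULL, mods))
    arr
  }
  switch(type,
         risk = stats::setNames(out$h, out$ids),
         fused = { rownames(out$C) <- out$ids; out$C },
         representation = stack(out$Rlist),
         attention = stack(out$Plist))
}

#' @export
print.coxfuse <- function(x, ...) {
  cat("Multimodal neural Cox model (coxfuse)\n")
  cat("  modalities:", paste(x$meta$modalities, collapse = ", "), "\n")
  cat(sprintf("  representation length m = %d, fusion = %s, lambda = %g, margin = %g\n",
              x$meta$m, x$config$fusion, x$config$lambda, x$config$margin))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs (best validation C-index %.3f at epoch %d)\n",
                nrow(x$history), max(x$history$cindex_val, na.rm = TRUE),
                x$best_epoch))
  } else {
    cat("  untrained (initialized parameters)\n")
  }
  invisible(x)
}

#' Summarize a fitted model: concordance by data split
#'
#' @param object a fitted [coxfuse()] model.
#' @param ... ignored.
#' @return Invisibly, a list with the per-split [c_index()] results.
#' @export
summary.coxfuse <- function(object, ...) {
  print(object)
  out <- list()
  for (sp in c("train", "val", "test")) {
    idx <- object$split[[sp]]
    if (!length(idx)) next
    pr <- model_predict_proc(object, object$proc, idx)
    out[[sp]] <- c_index(pr$h, object$proc$time[idx],
                         object$proc$event[idx])
    cat(sprintf("  %-5s C-index %.4f  (%d patients, %d comparable pairs)\n",
                sp, out[[sp]]$c_index, length(idx),
                out[[sp]]$n_comparable))
  }
  invisible(out)
}

#' Plot training curves of a fitted model
#'
#' Left panel: training and validation Cox loss by epoch. Right panel:
#' validation C-index with the selected (best) epoch marked.
#'
#' @param x a fitted [coxfuse()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coxfuse <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model is untrained; nothing to plot")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$lsur_train, type = "l", xlab = "epoch",
                 ylab = "Cox loss", main = "Partial-likelihood loss", ...)
  graphics::lines(h$epoch, h$lsur_val, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  graphics::plot(h$epoch, h$cindex_val, type = "l", xlab = "epoch",
                 ylab = "validation C-index", main = "Model selection", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
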