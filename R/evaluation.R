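# Evaluation: the censored concordance index, PCA projection of learned
# representations, and cross-validated model evaluation.

#' Censored concordance index
#'
#' Over all ordered patient pairs (i, j), a pair is comparable when
#' `T_i > T_j` and patient j's event was observed (`E_j = 1`); it is
#' concordant when the earlier-event patient carries the higher risk score
#' (`h_i < h_j`). The C-index is the fraction of comparable pairs that are
#' concordant: 0.5 is random ordering, 1 perfect. Pairs with tied times are
#' not comparable (the inequality is strict); tied risk scores count 1/2 by
#' default (`ties = "half"`, Harrell's convention) or 0 under the literal
#' strict-inequality definition (`ties = "strict"`).
#'
#' @param h numeric risk scores (higher = higher risk).
#' @param time observed times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param ties `"half"` or `"strict"`.
#' @return A list of class `concordance_result` with `c_index`,
#'   `n_comparable` and `n_concordant` (fractional under half-tie
#'   counting). With zero comparable pairs `c_index` is `NaN` (warning).
#' @export
c_index <- function(h, time, event, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  stopifnot(length(h) >= 2, length(h) == length(time),
            length(h) == length(event))
  comp <- outer(time, time, ">") & matrix(event == 1, length(h),
                                          length(h), byrow = TRUE)
  n_comp <- sum(comp)
  if (n_comp == 0) {
    warning("c_index: no comparable pairs; returning NaN")
    return(structure(list(c_index = NaN, n_comparable = 0L,
                          n_concordant = 0), class = "concordance_result"))
  }
  lower <- outer(h, h, "<")
  n_conc <- sum(comp & lower)
  if (ties == "half") {
    n_conc <- n_conc + 0.5 * sum(comp & outer(h, h, "=="))
  }
  structure(list(c_index = n_conc / n_comp, n_comparable = n_comp,
                 n_concordant = n_conc), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.4f  (%s concordant of %d comparable pairs)\n",
              x$c_index, format(x$n_concordant), x$n_comparable))
  invisible(x)
}

#' Project representation vectors to 2-D by PCA
#'
#' Mean-centered principal-component projection onto the top components,
#' with each component's sign fixed so that its largest-magnitude loading is
#' positive (reproducible orientation). Used to visualize how the
#' cross-modal similarity loss arranges the per-modality representation
#' vectors.
#'
#' @param vectors numeric matrix, observations x features (e.g. stacked
#'   length-m representation vectors).
#' @param dims number of components (default 2).
#' @return A list with `coords` (observations x dims), `explained`
#'   (variance fractions per kept component) and `rotation`.
#' @export
project_pca <- function(vectors, dims = 2L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < max(3, dims)) {
    stop("project_pca: need at least ", max(3, dims), " vectors")
  }
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  dims <- min(dims, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(dims), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  coords <- sweep(pc$x[, seq_len(dims), drop = FALSE], 2, flip, "*")
  ev <- pc$sdev^2
  list(coords = coords, explained = ev[seq_len(dims)] / sum(ev),
       rotation = rot)
}

#' Plot per-modality representations in PCA space
#'
#' Pools the representation vectors of all patients and modalities, projects
#' them to 2-D with [project_pca()] and draws one color per modality.
#'
#' @param object a fitted [coxfuse()] model.
#' @param data optional [multimodal_dataset] (default: training data).
#' @param modalities modalities to include (default: all the model's).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [project_pca()] result with a `modality` label
#'   vector attached.
#' @export
plot_representations <- function(object, data = NULL, modalities = NULL,
                                 ...) {
  arr <- predict(object, newdata = data, type = "representation")
  mods <- modalities %||% dimnames(arr)[[3]]
  proc <- if (is.null(data)) object$proc else
    apply_preprocessor(object$prep, data)
  vecs <- NULL; labs <- character()
  for (mod in mods) {
    keep <- proc$availability[, mod] == 1
    vecs <- rbind(vecs, arr[keep, , mod])
    labs <- c(labs, rep(mod, sum(keep)))
  }
  pr <- project_pca(vecs, 2L)
  cols <- seq_along(mods)[match(labs, mods)]
  graphics::plot(pr$coords, col = cols, pch = 16, cex = 0.6,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * pr$explained[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * pr$explained[2]), ...)
  graphics::legend("topright", legend = mods, col = seq_along(mods),
                   pch = 16, bty = "n")
  pr$modality <- labs
  invisible(pr)
}

#' Cross-validated evaluation of the model
#'
#' Trains one model per fold from [make_folds()] and reports the test-fold
#' concordance of each, with mean and standard deviation. A failing fold is
#' recorded as `NA` with a warning and excluded from the mean.
#'
#' @param data a [multimodal_dataset].
#' @param config a [coxfuse_config()].
#' @param n_folds number of folds (default: `config$n_folds`).
#' @param seed fold-assignment seed (default: `config$seed`).
#' @param verbose print per-fold progress.
#' @return A data frame of class `coxfuse_cv` with one row per fold and
#'   attributes `mean` and `sd`.
#' @export
evaluate_cv <- function(data, config = coxfuse_config(), n_folds = NULL,
                        seed = NULL, verbose = FALSE) {
  n_folds <- n_folds %||% config$n_folds
  seed <- seed %||% config$seed
  folds <- make_folds(n_patients(data), n_folds, seed)
  res <- lapply(seq_along(folds), function(k) {
    ci <- tryCatch({
      fit <- coxfuse(data, config, split = folds[[k]])
      pr <- model_predict_proc(fit, fit$proc, folds[[k]]$test)
      c_index(pr$h, fit$proc$time[folds[[k]]$test],
              fit$proc$event[folds[[k]]$test])$c_index
    }, error = function(e) {
      warning(sprintf("fold %d failed: %s", k, conditionMessage(e)))
      NA_real_
    })
    if (verbose) message(sprintf("fold %d: C-index %.4f", k, ci))
    data.frame(fold = k, c_index = ci)
  })
  out <- do.call(rbind, res)
  attr(out, "mean") <- mean(out$c_index, na.rm = TRUE)
  attr(out, "sd") <- stats::sd(out$c_index, na.rm = TRUE)
  class(out) <- c("coxfuse_cv", "data.frame")
  out
}

#' @export
print.coxfuse_cv <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean C-index %.4f (sd %.4f)\n", attr(x, "mean"),
              attr(x, "sd")))
  invisible(x)
}
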