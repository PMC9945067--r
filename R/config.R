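# Model/run configuration. Every constant of the method is a configurable
# default here, never hard-coded elsewhere: similarity margin M = 0.2,
# combined-loss weight lambda = 0.3, representation length m = 128, variance
# thresholds 7 (mRNA) and 0.2 (CNV), a 60-20-20 split and 5-fold CV.

#' Model and training configuration
#'
#' Collects every tunable of the pipeline with its default. The object
#' serializes losslessly to and from YAML via [write_config()] /
#' [read_config()].
#'
#' @param modalities modalities the model consumes (subset of the data's).
#' @param m representation length per modality (default 128).
#' @param margin similarity-loss hinge margin M (default 0.2).
#' @param lambda combined-loss weight on the similarity term (default 0.3);
#'   0 disables the unsupervised loss (fusion-only variant).
#' @param fusion `"attention"` or `"uniform"` (forced even weights, the
#'   unsupervised-only variant).
#' @param mask_missing mask missing modalities out of the attention softmax
#'   (recommended); `FALSE` lets zero columns compete for weight.
#' @param pair_reduction reduction over matched pair terms: `"sum"` (as the
#'   loss is defined) or `"mean"` (batch-size-invariant tuning).
#' @param dropout dropout rate on the clinical embedding concatenation.
#' @param encoders optional per-modality overrides, e.g.
#'   `list(mRNA = list(hidden = c(512, 256)))`, and
#'   `clinical = list(embedding_dims = ...)`.
#' @param hazard_hidden the two hidden-layer sizes of the hazard head.
#' @param lr,batch_size,epochs,patience Adam learning rate, minibatch size,
#'   maximum epochs, and early-stopping patience on validation C-index.
#' @param seed global seed (initialization, shuffling, dropout).
#' @param pairing_seed seed of the pairing permutation stream (default:
#'   derived from `seed`).
#' @param variance_thresholds named vector of per-modality variance cutoffs
#'   applied before scaling; modalities not named are not filtered.
#' @param variance_scope `"cohort"` (variance over all available patients)
#'   or `"train"` (training patients only, leakage-free; recommended).
#' @param sample_variance use n-1 instead of n in the variance filter.
#' @param split train/validation/test fractions.
#' @param n_folds folds for [evaluate_cv()].
#' @return An object of class `coxfuse_config`.
#' @export
coxfuse_config <- function(modalities = c("clinical", "mRNA", "miRNA", "CNV"),
                           m = 128L,
                           margin = 0.2,
                           lambda = 0.3,
                           fusion = c("attention", "uniform"),
                           mask_missing = TRUE,
                           pair_reduction = c("sum", "mean"),
                           dropout = 0.3,
                           encoders = list(),
                           hazard_hidden = c(64L, 32L),
                           lr = 1e-3,
                           batch_size = 128L,
                           epochs = 100L,
                           patience = 10L,
                           seed = 1L,
                           pairing_seed = NULL,
                           variance_thresholds = c(mRNA = 7, CNV = 0.2),
                           variance_scope = c("cohort", "train"),
                           sample_variance = FALSE,
                           split = c(0.6, 0.2, 0.2),
                           n_folds = 5L) {
  fusion <- match.arg(fusion)
  pair_reduction <- match.arg(pair_reduction)
  variance_scope <- match.arg(variance_scope)
  stopifnot(m >= 1, margin >= 0, lambda >= 0, dropout >= 0, dropout < 1,
            lr > 0, batch_size >= 2, epochs >= 0, patience >= 1,
            length(hazard_hidden) == 2, all(hazard_hidden >= 1),
            length(split) == 3)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (!is.null(names(variance_thresholds)) || length(variance_thresholds) == 0) {
    variance_thresholds <- as.list(variance_thresholds)
  }
  stopifnot(all(unlist(variance_thresholds) >= 0))
  structure(list(
    modalities = as.character(modalities), m = as.integer(m),
    margin = as.numeric(margin), lambda = as.numeric(lambda),
    fusion = fusion, mask_missing = isTRUE(mask_missing),
    pair_reduction = pair_reduction, dropout = as.numeric(dropout),
    encoders = encoders, hazard_hidden = as.integer(hazard_hidden),
    lr = as.numeric(lr), batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed),
    pairing_seed = as.integer(pairing_seed %||% (as.integer(seed) + 777L)),
    variance_thresholds = variance_thresholds,
    variance_scope = variance_scope,
    sample_variance = isTRUE(sample_variance),
    split = as.numeric(split), n_folds = as.integer(n_folds)
  ), class = "coxfuse_config")
}

#' @export
print.coxfuse_config <- function(x, ...) {
  cat("coxfuse model configuration\n")
  cat("  modalities:", paste(x$modalities, collapse = ", "), "\n")
  cat(sprintf("  m = %d, margin M = %g, lambda = %g, fusion = %s\n",
              x$m, x$margin, x$lambda, x$fusion))
  cat(sprintf("  optimizer: Adam lr %g, batch %d, <= %d epochs, patience %d\n",
              x$lr, x$batch_size, x$epochs, x$patience))
  cat(sprintf("  split %s, %d folds, seed %d\n",
              paste(x$split, collapse = "-"), x$n_folds, x$seed))
  invisible(x)
}

#' Write a configuration to a YAML file
#' @param config a `coxfuse_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "coxfuse_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#' @param path YAML file written by [write_config()] (unknown keys are a
#'   hard error).
#' @return A `coxfuse_config`.
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(coxfuse_config))
  extra <- setdiff(names(lst), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "))
  }
  do.call(coxfuse_config, lst)
}
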