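# Feature selection, scaling and split/cross-validation machinery.
# Order of operations mirrors the training pipeline: variance filtering on
# raw values first, then min-max scaling to [0,1]. Zero-imputed rows of
# missing modalities are placeholders, not measurements, so they are
# excluded from both the variance computation and scaler fitting, and are
# re-zeroed after scaling.

#' Variance-threshold feature filter
#'
#' Keeps the features whose variance, computed over the patients for which
#' the modality is available, strictly exceeds `threshold`. The population
#' (1/N) variance is the default; ties at the threshold are dropped.
#'
#' @param X numeric matrix, patients x features.
#' @param threshold nonnegative variance cutoff.
#' @param available optional logical/0-1 vector marking rows that are real
#'   measurements; zero-imputed missing-modality rows should be `FALSE`.
#' @param sample_variance use the n-1 denominator instead of n.
#' @return The column-subsetted matrix (feature order preserved). If every
#'   feature is removed a warning is raised and a zero-column matrix
#'   returned.
#' @export
variance_filter <- function(X, threshold, available = NULL,
                            sample_variance = FALSE) {
  stopifnot(is.numeric(threshold), threshold >= 0 || is.infinite(threshold))
  X <- as.matrix(X)
  rows <- if (is.null(available)) seq_len(nrow(X)) else which(as.logical(available))
  if (length(rows) == 0 || ncol(X) == 0) {
    keep <- logical(ncol(X))
  } else {
    Xs <- X[rows, , drop = FALSE]
    mu <- colMeans(Xs)
    ss <- colSums(sweep(Xs, 2, mu)^2)
    denom <- if (sample_variance) max(length(rows) - 1, 1) else length(rows)
    v <- ss / denom
    keep <- v > threshold
  }
  if (!any(keep) && ncol(X) > 0) {
    warning("variance_filter: no features exceed threshold ", threshold)
  }
  X[, keep, drop = FALSE]
}

#' Fit a min-max scaler on training patients
#'
#' Stores per-feature minima and maxima over the training rows (optionally
#' restricted to rows where the modality is available), for later use with
#' [apply_minmax()].
#'
#' @param X numeric matrix or vector (a vector is treated as one feature).
#' @param train_idx indices of training patients (defaults to all rows).
#' @param available optional availability flags over all rows of `X`.
#' @return An object of class `minmax_scaler` with fields `min` and `max`.
#' @export
fit_minmax <- function(X, train_idx = NULL, available = NULL) {
  X <- as.matrix(X)
  rows <- train_idx %||% seq_len(nrow(X))
  if (!is.null(available)) rows <- intersect(rows, which(as.logical(available)))
  if (length(rows) == 0) stop("fit_minmax: no available training rows")
  Xs <- X[rows, , drop = FALSE]
  structure(
    list(min = apply(Xs, 2, min), max = apply(Xs, 2, max)),
    class = "minmax_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature through (x - min) / (max - min). Constant features
#' (max == min) map to 0; out-of-range values are clipped to \[0,1\];
#' zero-imputed missing-modality rows are re-zeroed after scaling.
#'
#' @param scaler a `minmax_scaler` from [fit_minmax()].
#' @param X matrix or vector with the same feature count as the scaler.
#' @param available optional availability flags; rows with flag 0 are set to
#'   the all-zero vector after scaling.
#' @return The scaled matrix, all cells in \[0,1\].
#' @export
apply_minmax <- function(scaler, X, available = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$min)) {
    stop("apply_minmax: column count does not match scaler")
  }
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min)
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  if (any(const)) out[, const] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (!is.null(available)) out[!as.logical(available), ] <- 0
  out
}

#' Seeded train/validation/test split
#'
#' Shuffles patients with a fixed seed and partitions them in the given
#' fractions (default 60-20-20). Partition sizes are within 1 of
#' `fraction * N` and the three sets are disjoint and exhaustive.
#'
#' @param n number of patients, or a `multimodal_dataset`.
#' @param fractions length-3 vector summing to 1.
#' @param seed integer RNG seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (inherits(n, "multimodal_dataset")) n <- n_patients(n)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1")
  }
  if (n < 5) stop("need at least 5 patients to split")
  sizes <- apportion(n, fractions)
  perm <- local_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1])]),
       val = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Cross-validation folds with inner train/validation splits
#'
#' Partitions patients into `n_folds` test folds (each patient is tested
#' exactly once); within each fold the remaining patients are re-split
#' 75/25 into train/validation, preserving the overall 60-20-20 proportions
#' at 5 folds.
#'
#' @param n number of patients, or a `multimodal_dataset`.
#' @param n_folds number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return List of `n_folds` lists, each with `train`, `val`, `test` indices.
#' @export
make_folds <- function(n, n_folds = 5L, seed = 1L) {
  if (inherits(n, "multimodal_dataset")) n <- n_patients(n)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > n) stop("more folds than patients")
  perm <- local_seed(seed, sample.int(n))
  fold_id <- rep(seq_len(n_folds), length.out = n)
  lapply(seq_len(n_folds), function(k) {
    test <- sort(perm[fold_id == k])
    rest <- sort(perm[fold_id != k])
    sizes <- apportion(length(rest), c(0.75, 0.25))
    inner <- local_seed(seed + 1000L + k, sample.int(length(rest)))
    list(train = sort(rest[inner[seq_len(sizes[1])]]),
         val = sort(rest[inner[sizes[1] + seq_len(sizes[2])]]),
         test = test)
  })
}

# ---- fitted preprocessing pipeline (internal) ------------------------------

# Fit the full preprocessing state on the training split of a dataset:
# variance filtering per omics modality (cohort- or train-scoped), min-max
# scalers fitted on training patients only, and clinical category
# vocabularies frozen on the training split with a reserved "unknown" code
# for categories first seen at validation/test time.
fit_preprocessor <- function(ds, config, train_idx) {
  mods <- intersect(modality_names(ds), config$modalities)
  if (!length(mods)) stop("no configured modality present in the data")
  omods <- setdiff(mods, "clinical")

  kept <- list(); scalers <- list()
  for (mod in omods) {
    X <- ds$omics[[mod]]
    av <- ds$availability[, mod] == 1
    thr <- config$variance_thresholds[[mod]] %||% NA_real_
    if (!is.na(thr)) {
      rows <- if (config$variance_scope == "train") {
        intersect(train_idx, which(av))
      } else {
        which(av)
      }
      flag <- logical(nrow(X)); flag[rows] <- TRUE
      X <- variance_filter(X, thr, available = flag,
                           sample_variance = isTRUE(config$sample_variance))
    }
    kept[[mod]] <- colnames(X)
    scalers[[mod]] <- fit_minmax(X, train_idx, available = av)
  }
  age_scaler <- fit_minmax(ds$clinical$age, train_idx)
  vocabs <- lapply(CLIN_CATEGORICAL, function(cc) {
    sort(unique(ds$clinical[[cc]][train_idx]))
  })
  names(vocabs) <- CLIN_CATEGORICAL
  structure(
    list(modalities = mods, kept = kept, scalers = scalers,
         age_scaler = age_scaler, vocabs = vocabs),
    class = "coxfuse_prep"
  )
}

# Apply a fitted preprocessor, returning the numeric arrays consumed by the
# encoders: scaled omics matrices, integer category codes (vocab size + 1 is
# the unknown slot), scaled age, availability and survival vectors.
apply_preprocessor <- function(prep, ds) {
  omods <- setdiff(prep$modalities, "clinical")
  omics <- list()
  for (mod in omods) {
    if (!mod %in% names(ds$omics)) stop("dataset lacks modality ", mod)
    X <- ds$omics[[mod]]
    miss <- setdiff(prep$kept[[mod]], colnames(X))
    if (length(miss)) {
      stop("dataset lacks ", length(miss), " selected ", mod, " feature(s)")
    }
    X <- X[, prep$kept[[mod]], drop = FALSE]
    av <- ds$availability[, mod] == 1
    omics[[mod]] <- apply_minmax(prep$scalers[[mod]], X, available = av)
  }
  codes <- sapply(CLIN_CATEGORICAL, function(cc) {
    idx <- match(ds$clinical[[cc]], prep$vocabs[[cc]])
    idx[is.na(idx)] <- length(prep$vocabs[[cc]]) + 1L  # unknown slot
    idx
  })
  codes <- matrix(as.integer(codes), nrow = n_patients(ds),
                  dimnames = list(NULL, CLIN_CATEGORICAL))
  list(
    omics = omics,
    clin_codes = codes,
    age = as.vector(apply_minmax(prep$age_scaler, ds$clinical$age)),
    availability = ds$availability[, prep$modalities, drop = FALSE],
    time = ds$survival$time,
    event = ds$survival$event,
    patient_ids = ds$patient_ids
  )
}
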