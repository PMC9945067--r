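# Core containers and delimited-text readers/writers for multimodal
# survival data. A dataset holds, for one cohort of patients:
#   * a clinical table (cancer type, gender, race, histological type, age),
#   * any subset of numeric omics matrices (mRNA, miRNA, CNV, ...),
#   * a per-patient modality availability mask,
#   * right-censored survival labels (time, event).
# Missing modalities are stored both as all-zero rows (the training-time
# convention) and as zeros in the availability mask; the mask is
# authoritative, so loss code can skip zero-norm vectors whose cosine
# similarity would otherwise be undefined.

CLIN_CATEGORICAL <- c("cancer_type", "gender", "race", "histological_type")
CLIN_CONTINUOUS <- "age"
CLIN_COLUMNS <- c(CLIN_CATEGORICAL, CLIN_CONTINUOUS)

#' Assemble a multimodal survival dataset
#'
#' Bundles a clinical table, omics matrices, survival labels and a modality
#' availability mask into a single aligned object. All components must refer
#' to the same patients; omics rows for unavailable modalities are forced to
#' all-zero vectors so that the mask and the zero-row convention always agree.
#'
#' @param clinical data frame with columns `patient_id`, `cancer_type`,
#'   `gender`, `race`, `histological_type` (categorical) and `age` (numeric).
#' @param omics named list of numeric matrices (patients x features) with
#'   patient IDs as row names, in the same order as `clinical`.
#' @param survival data frame with columns `patient_id`, `time` (nonnegative)
#'   and `event` (0 = right-censored, 1 = event observed).
#' @param availability optional 0/1 matrix (patients x modalities) with one
#'   column per omics modality plus a leading `clinical` column. If omitted it
#'   is derived: a patient is unavailable in a modality iff their omics row is
#'   the all-zero vector.
#' @return An object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(clinical, omics = list(), survival,
                               availability = NULL) {
  stopifnot(is.data.frame(clinical), is.data.frame(survival), is.list(omics))
  if (!"patient_id" %in% names(clinical)) {
    stop("clinical table must have a 'patient_id' column")
  }
  missing_cols <- setdiff(CLIN_COLUMNS, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(clinical$patient_id)
  if (anyDuplicated(ids)) {
    stop("duplicate patient IDs in clinical table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(c("patient_id", "time", "event") %in% names(survival))) {
    stop("survival table needs columns patient_id, time, event")
  }
  surv <- survival[match(ids, as.character(survival$patient_id)), , drop = FALSE]
  if (anyNA(surv$patient_id)) {
    stop("survival table does not cover all clinical patients")
  }
  surv$time <- as.numeric(surv$time)
  surv$event <- as.numeric(surv$event)
  if (any(!is.finite(surv$time)) || any(surv$time < 0)) {
    stop("survival times must be finite and >= 0")
  }
  if (!is_binary01(surv$event)) stop("event indicator must be 0 or 1")

  clin <- clinical[, CLIN_COLUMNS, drop = FALSE]
  for (cc in CLIN_CATEGORICAL) clin[[cc]] <- as.character(clin[[cc]])
  clin[[CLIN_CONTINUOUS]] <- as.numeric(clin[[CLIN_CONTINUOUS]])
  rownames(clin) <- NULL

  n <- length(ids)
  omics <- lapply(omics, function(X) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (n == 0) {
      return(matrix(X, 0, ncol(X), dimnames = list(character(0), colnames(X))))
    }
    if (nrow(X) != n || !identical(rownames(X), ids)) {
      if (is.null(rownames(X))) stop("omics matrices need patient row names")
      idx <- match(ids, rownames(X))
      if (anyNA(idx)) stop("omics matrix does not cover all patients; use read_dataset() for partial modalities")
      X <- X[idx, , drop = FALSE]
    }
    X
  })

  mods <- c("clinical", names(omics))
  if (is.null(availability)) {
    availability <- matrix(1, n, length(mods), dimnames = list(ids, mods))
    for (mod in names(omics)) {
      zero_row <- rowSums(abs(omics[[mod]])) == 0 & ncol(omics[[mod]]) > 0
      availability[zero_row, mod] <- 0
    }
  } else {
    availability <- as.matrix(availability)
    if (!"clinical" %in% colnames(availability)) {
      availability <- cbind(clinical = 1, availability)
    }
    availability <- availability[, mods, drop = FALSE]
    storage.mode(availability) <- "double"
    rownames(availability) <- ids
  }
  if (!is_binary01(availability)) stop("availability mask must be 0/1")
  # the mask is authoritative: enforce the zero-row convention
  for (mod in names(omics)) {
    off <- availability[, mod] == 0
    if (any(off) && ncol(omics[[mod]]) > 0) omics[[mod]][off, ] <- 0
  }

  structure(
    list(patient_ids = ids, clinical = clin, omics = omics,
         availability = availability,
         survival = data.frame(patient_id = ids, time = surv$time,
                               event = surv$event)),
    class = "multimodal_dataset"
  )
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  n <- length(x$patient_ids)
  cat("Multimodal survival dataset\n")
  cat(sprintf("  %d patients, %d events (%.1f%% censored)\n", n,
              sum(x$survival$event),
              100 * mean(1 - x$survival$event)))
  cat("  clinical: 4 categorical + 1 continuous variable\n")
  for (mod in names(x$omics)) {
    cat(sprintf("  %s: %d features, %.1f%% missing-modality patients\n",
                mod, ncol(x$omics[[mod]]),
                100 * mean(x$availability[, mod] == 0)))
  }
  invisible(x)
}

#' Number of patients in a dataset
#' @param ds a `multimodal_dataset`.
#' @return Integer patient count.
#' @export
n_patients <- function(ds) length(ds$patient_ids)

#' Modality names of a dataset
#' @param ds a `multimodal_dataset`.
#' @param omics_only if `TRUE`, drop the leading "clinical" entry.
#' @return Character vector of modality names in column order.
#' @export
modality_names <- function(ds, omics_only = FALSE) {
  mods <- colnames(ds$availability)
  if (omics_only) setdiff(mods, "clinical") else mods
}

#' Subset a multimodal dataset by patients
#' @param x a `multimodal_dataset`.
#' @param i patient index vector (positions into `x$patient_ids`).
#' @param ... ignored.
#' @return The subsetted `multimodal_dataset`.
#' @export
`[.multimodal_dataset` <- function(x, i, ...) {
  clin <- x$clinical[i, , drop = FALSE]
  clin <- cbind(patient_id = x$patient_ids[i], clin)
  multimodal_dataset(
    clinical = clin,
    omics = lapply(x$omics, function(X) X[i, , drop = FALSE]),
    survival = x$survival[i, , drop = FALSE],
    availability = x$availability[i, , drop = FALSE]
  )
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
}

# Convert the non-ID columns of a just-read table to numeric, with a hard
# error naming file/row/column for any non-numeric cell.
to_numeric_matrix <- function(df, path) {
  ids <- df[[1]]
  if (ncol(df) < 2) {
    return(matrix(0, length(ids), 0, dimnames = list(ids, NULL)))
  }
  M <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(M), nrow(M), ncol(M)))
  bad <- which(is.na(num) & !(M %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value %s in %s (row %d [%s], column '%s')",
                 dQuote(M[bad[1, 1], bad[1, 2]]), path, bad[1, 1],
                 ids[bad[1, 1]], colnames(M)[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(M))
  num
}

#' Read a multimodal dataset from delimited text files
#'
#' Files are TSV by default; a `.csv` extension switches to comma-separated.
#' Every file needs a header row and a patient-ID first column. Patients are
#' joined inner on clinical and survival (patients absent from either are
#' dropped, with a message giving the count) and left-outer on each omics
#' file: a patient missing from an omics file gets availability 0 and an
#' all-zero feature row for that modality.
#'
#' @param clinical_path path to the clinical table.
#' @param omics_paths named character vector or list, modality name -> path.
#' @param survival_path path to the survival table (patient_id, time, event).
#' @param availability_path optional path to an explicit 0/1 availability
#'   table; when given it overrides the mask derived from missing rows.
#' @return A `multimodal_dataset`.
#' @export
read_dataset <- function(clinical_path, omics_paths = c(),
                         survival_path, availability_path = NULL) {
  clin_df <- read_delim_auto(clinical_path)
  names(clin_df)[1] <- "patient_id"
  if (anyDuplicated(clin_df$patient_id)) {
    stop("duplicate patient IDs in ", clinical_path)
  }
  surv_df <- read_delim_auto(survival_path)
  names(surv_df)[1] <- "patient_id"
  if (anyDuplicated(surv_df$patient_id)) {
    stop("duplicate patient IDs in ", survival_path)
  }
  ids <- intersect(clin_df$patient_id, surv_df$patient_id)
  dropped <- (nrow(clin_df) - length(ids)) + (nrow(surv_df) - length(ids))
  if (dropped > 0) {
    message(sprintf("read_dataset: dropped %d patient record(s) absent from clinical or survival table", dropped))
  }
  clin_df <- clin_df[match(ids, clin_df$patient_id), , drop = FALSE]
  clin_df$age <- as.numeric(clin_df$age)
  surv_df <- surv_df[match(ids, surv_df$patient_id), , drop = FALSE]
  surv_df$time <- as.numeric(surv_df$time)
  surv_df$event <- as.numeric(surv_df$event)

  omics <- list()
  avail <- matrix(1, length(ids), 1 + length(omics_paths),
                  dimnames = list(ids, c("clinical", names(omics_paths))))
  for (mod in names(omics_paths)) {
    df <- read_delim_auto(omics_paths[[mod]])
    if (anyDuplicated(df[[1]])) {
      stop("duplicate patient IDs in ", omics_paths[[mod]])
    }
    M <- to_numeric_matrix(df, omics_paths[[mod]])
    X <- matrix(0, length(ids), ncol(M), dimnames = list(ids, colnames(M)))
    idx <- match(ids, rownames(M))
    present <- !is.na(idx)
    if (any(present)) X[present, ] <- M[idx[present], , drop = FALSE]
    avail[!present, mod] <- 0
    omics[[mod]] <- X
  }
  if (!is.null(availability_path)) {
    adf <- read_delim_auto(availability_path)
    A <- to_numeric_matrix(adf, availability_path)
    idx <- match(ids, rownames(A))
    if (anyNA(idx)) stop("availability file does not cover all patients")
    keep <- intersect(colnames(avail), colnames(A))
    avail[, keep] <- A[idx, keep, drop = FALSE]
  }
  multimodal_dataset(clinical = clin_df, omics = omics, survival = surv_df,
                     availability = avail)
}

#' Write a multimodal dataset as delimited text files
#'
#' Writes one TSV per component: `clinical.tsv`, one `<modality>.tsv` per
#' omics matrix, `survival.tsv` (patient_id, time, event) and
#' `availability.tsv`. Numeric values are written at full precision so a
#' write/read round trip is bit-exact for finite values.
#'
#' @param ds a `multimodal_dataset`.
#' @param out_dir output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  write_tsv <- function(df, path) {
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) stop("failed writing ", path, ": ",
                                conditionMessage(e)))
    invisible(ok)
  }
  paths <- c()
  clin <- cbind(patient_id = ds$patient_ids, ds$clinical)
  clin$age <- fmt_full(ds$clinical$age)
  p <- file.path(out_dir, "clinical.tsv"); write_tsv(clin, p)
  paths["clinical"] <- p
  for (mod in names(ds$omics)) {
    X <- ds$omics[[mod]]
    df <- data.frame(patient_id = ds$patient_ids, stringsAsFactors = FALSE)
    if (ncol(X) > 0) {
      chr <- matrix(fmt_full(X), nrow(X), ncol(X), dimnames = dimnames(X))
      df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE))
    }
    p <- file.path(out_dir, paste0(mod, ".tsv")); write_tsv(df, p)
    paths[mod] <- p
  }
  surv <- data.frame(patient_id = ds$patient_ids,
                     time = fmt_full(ds$survival$time),
                     event = ds$survival$event)
  p <- file.path(out_dir, "survival.tsv"); write_tsv(surv, p)
  paths["survival"] <- p
  av <- cbind(data.frame(patient_id = ds$patient_ids),
              as.data.frame(ds$availability))
  p <- file.path(out_dir, "availability.tsv"); write_tsv(av, p)
  paths["availability"] <- p
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' Convenience wrapper locating the standard file names in a directory.
#'
#' @param dir directory produced by [write_dataset()].
#' @return A `multimodal_dataset`.
#' @export
read_dataset_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  base <- sub("\\.tsv$", "", basename(files))
  special <- c("clinical", "survival", "availability")
  omics <- files[!base %in% special]
  names(omics) <- base[!base %in% special]
  avail <- file.path(dir, "availability.tsv")
  if (file.exists(avail)) {
    # restore the original modality order from the availability header
    hdr <- names(read_delim_auto(avail))[-1]
    omics <- omics[intersect(hdr, names(omics))]
  }
  read_dataset(
    clinical_path = file.path(dir, "clinical.tsv"),
    omics_paths = omics,
    survival_path = file.path(dir, "survival.tsv"),
    availability_path = if (file.exists(avail)) avail else NULL
  )
}
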