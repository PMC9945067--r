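# Modality-specific encoders mapping raw inputs to fixed-length (m)
# representation vectors, whose column-wise concatenation per patient forms
# the representation matrix A (m x n modalities).
#   * clinical: one embedding per categorical variable, dropout on the
#     concatenated embeddings, batch-normalized age, then a single fully
#     connected projection to length m;
#   * omics (mRNA/miRNA/CNV): 2-4 stacked fully connected layers, each
#     followed by batch normalization and ReLU, ending at length m.
# Unavailable modalities bypass the encoder entirely and emit exact zero
# columns: zero-imputed rows are placeholders, and skipping them keeps
# batch-norm statistics clean and lets the losses mask missing modalities.

# Hidden sizes scale with the input width when not configured explicitly;
# total layer count (hidden + final) stays within 2..4.
default_hidden <- function(width) {
  if (width > 2000) c(1024, 512)
  else if (width > 500) c(512, 256)
  else c(256)
}

default_emb_dim <- function(vocab_size) {
  max(2L, min(32L, as.integer(ceiling(vocab_size / 2))))
}

build_meta <- function(prep, proc, config) {
  mods <- prep$modalities
  omods <- setdiff(mods, "clinical")
  enc_cfg <- config$encoders %||% list()
  hidden <- lapply(omods, function(mod) {
    h <- enc_cfg[[mod]]$hidden %||% default_hidden(ncol(proc$omics[[mod]]))
    if (length(h) < 1 || length(h) > 3) {
      stop("encoder for ", mod, " must have 2-4 layers (1-3 hidden sizes)")
    }
    h
  })
  names(hidden) <- omods
  vocab_sizes <- vapply(prep$vocabs, length, integer(1))
  emb_dims <- vapply(CLIN_CATEGORICAL, function(cc) {
    as.integer(enc_cfg$clinical$embedding_dims[[cc]] %||%
                 default_emb_dim(vocab_sizes[[cc]]))
  }, integer(1))
  list(modalities = mods, omics_mods = omods, m = config$m,
       widths = vapply(omods, function(mod) ncol(proc$omics[[mod]]),
                       integer(1)),
       hidden = hidden, vocab_sizes = vocab_sizes, emb_dims = emb_dims,
       dropout = config$dropout, hazard_hidden = config$hazard_hidden)
}

init_model_params <- function(meta, seed) {
  local_seed(seed, {
    enc <- list()
    if ("clinical" %in% meta$modalities) {
      emb <- lapply(seq_along(CLIN_CATEGORICAL), function(k) {
        # +1 row: reserved "unknown" code for unseen categories
        matrix(stats::rnorm((meta$vocab_sizes[k] + 1) * meta$emb_dims[k],
                            sd = 0.05),
               meta$vocab_sizes[k] + 1, meta$emb_dims[k])
      })
      names(emb) <- CLIN_CATEGORICAL
      d_in <- sum(meta$emb_dims) + 1L
      enc$clinical <- list(emb = emb, bn_age = new_bn_par(1),
                           W = glorot_init(d_in, meta$m), b = rep(0, meta$m))
    }
    for (mod in meta$omics_mods) {
      sizes <- c(meta$widths[[mod]], meta$hidden[[mod]], meta$m)
      layers <- lapply(seq_len(length(sizes) - 1), function(l) {
        c(list(W = he_init(sizes[l], sizes[l + 1]),
               b = rep(0, sizes[l + 1])),
          new_bn_par(sizes[l + 1]))
      })
      enc[[mod]] <- list(layers = layers)
    }
    att <- list(W = lapply(seq_along(meta$modalities),
                           function(j) glorot_init(meta$m, meta$m)))
    haz <- init_hazard(meta$m, meta$hazard_hidden)
    list(enc = enc, att = att, haz = haz)
  })
}

# ---- clinical encoder ------------------------------------------------------

enc_clinical_fwd <- function(par, codes, age, dropout, training) {
  Elist <- lapply(seq_along(CLIN_CATEGORICAL), function(k) {
    nn_embedding_fwd(codes[, k], par$emb[[k]])
  })
  Ecat <- do.call(cbind, Elist)
  drop <- nn_dropout_fwd(Ecat, dropout, training)
  bn <- nn_bn_fwd(matrix(age, ncol = 1), par$bn_age, training)
  par$bn_age <- bn$par
  X <- cbind(drop$out, bn$out)
  lin <- nn_linear_fwd(X, par$W, par$b)
  list(out = lin$out, par = par,
       cache = list(codes = codes, drop = drop, bn = bn$cache, lin = lin,
                    d_emb = ncol(Ecat)))
}

enc_clinical_bwd <- function(dY, cache, par) {
  dlin <- nn_linear_bwd(dY, cache$lin, par$W)
  de <- cache$d_emb
  dEcat <- nn_dropout_bwd(dlin$dX[, seq_len(de), drop = FALSE], cache$drop)
  dbn <- nn_bn_bwd(dlin$dX[, de + 1, drop = FALSE], cache$bn, par$bn_age)
  off <- 0L
  demb <- vector("list", length(CLIN_CATEGORICAL))
  for (k in seq_along(CLIN_CATEGORICAL)) {
    dk <- ncol(par$emb[[k]])
    demb[[k]] <- nn_embedding_bwd(dEcat[, off + seq_len(dk), drop = FALSE],
                                  cache$codes[, k], nrow(par$emb[[k]]))
    off <- off + dk
  }
  names(demb) <- CLIN_CATEGORICAL
  list(emb = demb,
       bn_age = list(gamma = dbn$dgamma, beta = dbn$dbeta),
       W = dlin$dW, b = dlin$db)
}

# ---- omics encoder ---------------------------------------------------------

enc_omics_fwd <- function(par, X, training) {
  caches <- vector("list", length(par$layers))
  H <- X
  for (l in seq_along(par$layers)) {
    lay <- par$layers[[l]]
    lin <- nn_linear_fwd(H, lay$W, lay$b)
    bn <- nn_bn_fwd(lin$out, lay, training)
    par$layers[[l]][c("run_mean", "run_var")] <-
      bn$par[c("run_mean", "run_var")]
    act <- nn_relu_fwd(bn$out)
    caches[[l]] <- list(lin = lin, bn = bn$cache, act = act)
    H <- act$out
  }
  list(out = H, par = par, cache = caches)
}

enc_omics_bwd <- function(dY, cache, par) {
  grads <- vector("list", length(par$layers))
  d <- dY
  for (l in rev(seq_along(par$layers))) {
    lay <- par$layers[[l]]
    d <- nn_relu_bwd(d, cache[[l]]$act)
    dbn <- nn_bn_bwd(d, cache[[l]]$bn, lay)
    dlin <- nn_linear_bwd(dbn$dX, cache[[l]]$lin, lay$W)
    grads[[l]] <- list(W = dlin$dW, b = dlin$db,
                       gamma = dbn$dgamma, beta = dbn$dbeta)
    d <- dlin$dX
  }
  list(layers = grads)
}

# ---- full representation forward/backward ----------------------------------

# proc: preprocessed arrays from apply_preprocessor(); idx: batch indices.
# Returns per-modality B x m representations (zero rows for unavailable
# modalities), caches for the backward pass, and params with updated
# batch-norm running statistics.
model_repr_forward <- function(params, meta, proc, idx, training) {
  B <- length(idx)
  avail <- proc$availability[idx, meta$modalities, drop = FALSE]
  Rlist <- vector("list", length(meta$modalities))
  names(Rlist) <- meta$modalities
  caches <- list()
  for (mod in meta$modalities) {
    R <- matrix(0, B, meta$m)
    rows <- which(avail[, mod] == 1)
    if (length(rows)) {
      if (mod == "clinical") {
        fw <- enc_clinical_fwd(params$enc$clinical,
                               proc$clin_codes[idx[rows], , drop = FALSE],
                               proc$age[idx[rows]], meta$dropout, training)
        params$enc$clinical <- fw$par
      } else {
        fw <- enc_omics_fwd(params$enc[[mod]],
                            proc$omics[[mod]][idx[rows], , drop = FALSE],
                            training)
        params$enc[[mod]] <- fw$par
      }
      R[rows, ] <- fw$out
      caches[[mod]] <- list(rows = rows, cache = fw$cache)
    }
    Rlist[[mod]] <- R
  }
  list(Rlist = Rlist, avail = avail, caches = caches, params = params)
}

model_repr_backward <- function(dRlist, fw, params, meta) {
  genc <- list()
  for (mod in meta$modalities) {
    cc <- fw$caches[[mod]]
    if (is.null(cc)) next
    dY <- dRlist[[mod]][cc$rows, , drop = FALSE]
    genc[[mod]] <- if (mod == "clinical") {
      enc_clinical_bwd(dY, cc$cache, params$enc$clinical)
    } else {
      enc_omics_bwd(dY, cc$cache, params$enc[[mod]])
    }
  }
  genc
}

#' Encode one modality of a dataset with a fitted model
#'
#' Runs the modality's encoder in evaluation mode (dropout off,
#' batch-normalization using running statistics) and returns the
#' representation vectors. Rows for patients lacking the modality are
#' all-zero.
#'
#' @param object a fitted [coxfuse()] model.
#' @param data a `multimodal_dataset` (default: the training data).
#' @param modality modality name (e.g. `"clinical"`, `"mRNA"`).
#' @return Numeric matrix, patients x m.
#' @export
encode_modality <- function(object, data = NULL, modality) {
  stopifnot(inherits(object, "coxfuse"))
  if (!modality %in% object$meta$modalities) {
    stop("model has no encoder for modality ", modality)
  }
  proc <- if (is.null(data)) object$proc else
    apply_preprocessor(object$prep, data)
  fw <- model_repr_forward(object$params, object$meta, proc,
                           seq_along(proc$patient_ids), training = FALSE)
  out <- fw$Rlist[[modality]]
  rownames(out) <- proc$patient_ids
  out
}
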