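# Synthetic multimodal survival-data generator. It emulates the structure
# the method assumes — several nonnegative omics matrices with
# heterogeneous feature variances, a clinical table, a shared latent risk
# signal distributed across modalities in configurable proportions,
# proportional-hazards (exponential) event times, independent uniform
# right-censoring calibrated to a target rate, and per-patient missing
# modalities — without imitating any real cohort at the distributional
# level (no count models, no batch effects).

#' Configuration of the synthetic data generator
#'
#' @param n_patients cohort size.
#' @param modality_widths named integer vector of feature counts per omics
#'   modality.
#' @param latent_dim total latent factors: 1 risk factor plus
#'   `latent_dim - 1` nuisance factors shared within modalities.
#' @param signal_split named fractions of the latent risk signal carried by
#'   each modality (may include `clinical`); must sum to 1. A modality's
#'   informative features load on the risk factor with weight
#'   `sqrt(share)`, so shares partition the squared signal amplitude.
#' @param noise_sd standard deviation of the feature-level Gaussian noise
#'   added on the latent scale (features are exponentiated afterwards, so
#'   omics values are lognormal and nonnegative).
#' @param informative_frac fraction of each omics modality's features
#'   carrying the risk factor.
#' @param censoring_rate target fraction of right-censored patients; an
#'   independent uniform censoring time is calibrated to achieve it.
#' @param missing_rate named per-modality probabilities that a patient lacks
#'   the modality entirely (zero row + availability 0).
#' @param baseline_hazard exponential baseline event rate (per time unit).
#' @param risk_coef slope of the true log-hazard in the latent risk factor.
#' @param seed integer seed; fixed seed gives byte-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 600L,
                       modality_widths = c(mRNA = 240L, miRNA = 100L),
                       latent_dim = 4L,
                       signal_split = c(clinical = 0.3, mRNA = 0.5,
                                        miRNA = 0.2),
                       noise_sd = 0.5,
                       informative_frac = 0.3,
                       censoring_rate = 0.3,
                       missing_rate = c(mRNA = 0.05, miRNA = 0.05),
                       baseline_hazard = 0.02,
                       risk_coef = 1.5,
                       seed = 1L) {
  stopifnot(n_patients >= 2, latent_dim >= 2, noise_sd > 0,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, informative_frac > 0,
            all(unlist(missing_rate) >= 0), all(unlist(missing_rate) < 1))
  if (abs(sum(signal_split) - 1) > 1e-9) {
    stop("signal_split must sum to 1")
  }
  unknown <- setdiff(names(signal_split),
                     c("clinical", names(modality_widths)))
  if (length(unknown)) stop("signal_split names unknown: ",
                            paste(unknown, collapse = ", "))
  structure(list(
    n_patients = as.integer(n_patients),
    modality_widths = modality_widths, latent_dim = as.integer(latent_dim),
    signal_split = signal_split, noise_sd = noise_sd,
    informative_frac = informative_frac, censoring_rate = censoring_rate,
    missing_rate = missing_rate, baseline_hazard = baseline_hazard,
    risk_coef = risk_coef, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multimodal survival dataset
#'
#' Draws a latent risk factor z per patient plus nuisance factors; each
#' omics modality is a lognormal feature matrix whose informative features
#' load on z with amplitude `sqrt(signal_split)`, with per-feature scales
#' drawn log-uniformly (so the variance filter has non-trivial behavior).
#' The clinical table carries its share of signal through age and the
#' cancer-type category. The true log-hazard is `risk_coef * z`; event
#' times are exponential with rate `baseline_hazard * exp(log-hazard)`,
#' censoring is independent uniform calibrated to the target rate, and
#' missing modalities are applied as zero rows with availability 0.
#'
#' @param cfg a [sim_config()].
#' @return A list with `data` (a [multimodal_dataset]), `truth` (data frame
#'   of patient ID, latent factor `z` and true log-hazard `risk`) and
#'   `achieved_censoring`.
#' @export
simulate_multiomics <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    n <- cfg$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    z <- stats::rnorm(n)
    Q <- matrix(stats::rnorm(n * (cfg$latent_dim - 1)), n)

    share <- function(mod) {
      s <- cfg$signal_split
      if (mod %in% names(s)) s[[mod]] else 0
    }
    omics <- list()
    for (mod in names(cfg$modality_widths)) {
      d <- cfg$modality_widths[[mod]]
      sdf <- exp(stats::runif(d, log(0.5), log(2)))      # feature scales
      n_inf <- max(1L, round(cfg$informative_frac * d))
      inf <- sample.int(d, n_inf)
      load_z <- numeric(d)
      load_z[inf] <- sqrt(share(mod)) * stats::runif(n_inf, 0.8, 1.2)
      load_q <- matrix(0, cfg$latent_dim - 1, d)
      which_q <- sample.int(cfg$latent_dim - 1, d, replace = TRUE)
      load_q[cbind(which_q, seq_len(d))] <- stats::runif(d, 0.3, 0.8)
      raw <- outer(z, load_z) + Q %*% load_q +
        matrix(stats::rnorm(n * d, sd = cfg$noise_sd), n)
      X <- exp(sweep(raw, 2, sdf, "*"))
      dimnames(X) <- list(ids, sprintf("%s_f%04d", mod, seq_len(d)))
      omics[[mod]] <- X
    }

    a_c <- sqrt(share("clinical"))
    age_lat <- a_c * z + stats::rnorm(n, sd = cfg$noise_sd)
    age <- pmin(pmax(round(58 + 11 * age_lat), 25), 90)
    type_lat <- a_c * z + stats::rnorm(n, sd = cfg$noise_sd)
    type_breaks <- stats::quantile(type_lat, probs = seq(0, 1, by = 0.2))
    cancer_type <- paste0("T", as.integer(cut(type_lat, type_breaks,
                                              include.lowest = TRUE)))
    clinical <- data.frame(
      patient_id = ids,
      cancer_type = cancer_type,
      gender = sample(c("female", "male"), n, replace = TRUE),
      race = sample(c("asian", "black", "white", "other"), n,
                    replace = TRUE),
      histological_type = sample(paste0("H", 1:5), n, replace = TRUE),
      age = age,
      stringsAsFactors = FALSE
    )

    risk <- cfg$risk_coef * z
    rate <- cfg$baseline_hazard * exp(risk)
    t_event <- stats::rexp(n, rate)
    if (cfg$censoring_rate > 0) {
      # with C ~ U(0, cmax), P(censor | T) = min(T, cmax) / cmax
      f <- function(cmax) mean(pmin(t_event, cmax) / cmax) -
        cfg$censoring_rate
      cmax <- tryCatch(
        stats::uniroot(f, lower = min(t_event) * 1e-3,
                       upper = max(t_event) * 1e3)$root,
        error = function(e) max(t_event))
      cens <- stats::runif(n, 0, cmax)
    } else {
      cens <- rep(Inf, n)
    }
    event <- as.numeric(t_event <= cens)
    time <- pmin(t_event, cens)
    achieved <- mean(event == 0)
    if (abs(achieved - cfg$censoring_rate) > 0.05 && n >= 100) {
      warning(sprintf(
        "censoring calibration achieved %.2f (target %.2f)", achieved,
        cfg$censoring_rate))
    }

    avail <- matrix(1, n, 1 + length(omics),
                    dimnames = list(ids, c("clinical", names(omics))))
    for (mod in names(omics)) {
      rate_m <- cfg$missing_rate[[mod]]
      if (!is.null(rate_m) && rate_m > 0) {
        miss <- stats::runif(n) < rate_m
        if (all(miss)) miss[1] <- FALSE
        avail[miss, mod] <- 0
        omics[[mod]][miss, ] <- 0
      }
    }

    ds <- multimodal_dataset(
      clinical = clinical, omics = omics,
      survival = data.frame(patient_id = ids, time = time, event = event),
      availability = avail
    )
    list(data = ds,
         truth = data.frame(patient_id = ids, z = z, risk = risk),
         achieved_censoring = achieved)
  })
}

#' Canned synthetic datasets used across examples and tests
#'
#' Deterministic presets of [simulate_multiomics()]:
#' \describe{
#'   \item{tiny}{20 patients, all four modalities (including CNV), small
#'     feature counts, with at least one patient per single-modality-missing
#'     pattern. For fast structural tests.}
#'   \item{default}{600 patients, clinical + mRNA + miRNA with signal split
#'     0.3/0.5/0.2, 30\% censoring. The standard end-to-end benchmark.}
#'   \item{null}{300 patients with `risk_coef = 0`: the log-hazard is
#'     constant, so any model's expected C-index is 0.5.}
#' }
#'
#' @param name preset id: `"tiny"`, `"default"` or `"null"`.
#' @return As [simulate_multiomics()]: list with `data`, `truth` and
#'   `achieved_censoring`.
#' @export
make_fixture <- function(name = c("tiny", "default", "null")) {
  if (!is.character(name) || !name[1] %in% c("tiny", "default", "null")) {
    stop("unknown fixture preset: ", name[1])
  }
  name <- match.arg(name)
  if (name == "tiny") {
    cfg <- sim_config(
      n_patients = 20L,
      modality_widths = c(mRNA = 30L, miRNA = 15L, CNV = 20L),
      signal_split = c(clinical = 0.3, mRNA = 0.4, miRNA = 0.2, CNV = 0.1),
      missing_rate = c(mRNA = 0, miRNA = 0, CNV = 0),
      censoring_rate = 0.25, seed = 101L
    )
    sim <- simulate_multiomics(cfg)
    # force one patient per single-modality-missing pattern, plus one
    # patient missing two modalities
    ds <- sim$data
    pat <- list(c("mRNA"), c("miRNA"), c("CNV"), c("mRNA", "CNV"))
    for (k in seq_along(pat)) {
      for (mod in pat[[k]]) {
        ds$availability[k, mod] <- 0
        ds$omics[[mod]][k, ] <- 0
      }
    }
    sim$data <- multimodal_dataset(
      clinical = cbind(patient_id = ds$patient_ids, ds$clinical),
      omics = ds$omics, survival = ds$survival,
      availability = ds$availability)
    sim
  } else if (name == "default") {
    simulate_multiomics(sim_config(seed = 20240601L))
  } else {
    simulate_multiomics(sim_config(
      n_patients = 300L, risk_coef = 0, seed = 7L,
      signal_split = c(clinical = 0.3, mRNA = 0.5, miRNA = 0.2)))
  }
}
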