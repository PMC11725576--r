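# Synthetic multimodal cohort generator.
#
# Emulates the statistical structure the benchmarking pipeline assumes: four
# per-patient feature blocks (clinical, radiomics, pathomics, rna) driven by
# modality-specific latent factors, a log-linear hazard on those latents,
# exponential OS/PFS with administrative + dropout censoring, block-wise
# modality missingness and within-block missing cells.

#' Default modality availability pattern counts
#'
#' Counts over the 8 availability patterns with clinical always present,
#' chosen to reproduce the per-modality totals of the emulated cohort:
#' 317 clinical, 201 radiomics, 236 pathomics, 134 rna, and 80 patients with
#' all four modalities. The full Venn decomposition is not published, so the
#' intermediate cells are a fixed plausible choice consistent with those
#' margins.
#'
#' @return Named integer vector over availability patterns; names are
#'   `"+"`-separated modality subsets (clinical always included).
#' @export
default_pattern_counts <- function() {
  c("clinical"                        = 10L,
    "clinical+radiomics"              = 37L,
    "clinical+pathomics"              = 76L,
    "clinical+rna"                    = 10L,
    "clinical+radiomics+pathomics"    = 60L,
    "clinical+radiomics+rna"          = 24L,
    "clinical+pathomics+rna"          = 20L,
    "clinical+radiomics+pathomics+rna" = 80L)
}

#' Missingness specification
#'
#' @param mode `"exact_counts"` (deterministic pattern frequencies) or
#'   `"bernoulli"` (patterns sampled with the given probabilities).
#' @param pattern_counts Named integer vector of patients per availability
#'   pattern (`exact_counts` mode); names as in [default_pattern_counts()].
#' @param pattern_probs Named probability vector over patterns
#'   (`bernoulli` mode); must sum to 1.
#' @param within_block_na_rate Fraction of cells set to `NA` inside available
#'   blocks (missing measurements within an otherwise collected modality).
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(mode = c("exact_counts", "bernoulli"),
                             pattern_counts = default_pattern_counts(),
                             pattern_probs = NULL,
                             within_block_na_rate = 0.02) {
  mode <- match.arg(mode)
  stopifnot(within_block_na_rate >= 0, within_block_na_rate <= 1)
  if (mode == "bernoulli") {
    if (is.null(pattern_probs))
      pattern_probs <- pattern_counts / sum(pattern_counts)
    if (abs(sum(pattern_probs) - 1) > 1e-8)
      stop("pattern_probs must sum to 1")
  }
  structure(list(mode = mode, pattern_counts = pattern_counts,
                 pattern_probs = pattern_probs,
                 within_block_na_rate = within_block_na_rate),
            class = "missingness_spec")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study cohort: 317 patients, feature blocks of
#' 30 (clinical) / 30 (radiomics) / 134 (pathomics) / 34 (rna) features,
#' median OS around 756 days and median PFS around 296 days for a baseline
#' patient, administrative censoring at five years plus uniform dropout.
#'
#' @param n_patients Cohort size.
#' @param block_schema Named integer vector, features per modality.
#' @param latent_dims Named integer vector, latent factors per modality; the
#'   first latent of each modality carries the prognostic signal.
#' @param effect_sizes Named numeric vector, log-hazard coefficient of each
#'   modality's risk latent.
#' @param baseline_hazard_os,baseline_hazard_pfs Exponential baseline hazards
#'   (events per day). Defaults give medians of 756 / 296 days at zero risk.
#' @param censoring_window Administrative censoring horizon in days.
#' @param dropout_rate Probability that a patient drops out at a uniform
#'   time before the administrative window.
#' @param feature_noise_sd Gaussian noise added on top of latent loadings.
#' @param categorical_fraction Fraction of clinical features emitted as
#'   binary indicators.
#' @param missingness A [missingness_spec()]; `NULL` for a fully observed
#'   cohort.
#' @param seed Master seed; sub-seeds for cohort, missingness and lesions are
#'   derived from it so experiments can share cross-validation schemes.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 317L,
                          block_schema = c(clinical = 30L, radiomics = 30L,
                                           pathomics = 134L, rna = 34L),
                          latent_dims = c(clinical = 2L, radiomics = 2L,
                                          pathomics = 4L, rna = 2L),
                          effect_sizes = c(clinical = 0.5, radiomics = 0.4,
                                           pathomics = 0.3, rna = 0.6),
                          baseline_hazard_os = log(2) / 756,
                          baseline_hazard_pfs = log(2) / 296,
                          censoring_window = 1825,
                          dropout_rate = 0.35,
                          feature_noise_sd = 1,
                          categorical_fraction = 0.3,
                          missingness = missingness_spec(),
                          seed = 1L) {
  stopifnot(n_patients > 0, all(block_schema > 0), all(latent_dims > 0),
            all(is.finite(effect_sizes)),
            censoring_window > 0,
            dropout_rate >= 0, dropout_rate <= 1,
            feature_noise_sd >= 0,
            categorical_fraction >= 0, categorical_fraction <= 1)
  if (baseline_hazard_os <= 0 || baseline_hazard_pfs <= 0)
    stop("baseline hazards must be positive")
  mods <- names(block_schema)
  stopifnot(!is.null(mods), setequal(names(latent_dims), mods),
            setequal(names(effect_sizes), mods))
  structure(list(n_patients = as.integer(n_patients),
                 block_schema = block_schema[mods],
                 latent_dims = latent_dims[mods],
                 effect_sizes = effect_sizes[mods],
                 baseline_hazard_os = baseline_hazard_os,
                 baseline_hazard_pfs = baseline_hazard_pfs,
                 censoring_window = censoring_window,
                 dropout_rate = dropout_rate,
                 feature_noise_sd = feature_noise_sd,
                 categorical_fraction = categorical_fraction,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Derive a reproducible sub-seed < 2^31 from a master seed and a purpose tag.
sub_seed <- function(seed, purpose) {
  offs <- c(cohort = 11L, missingness = 29L, lesions = 47L, cv = 83L,
            permutation = 131L, bootstrap = 173L)
  stopifnot(purpose %in% names(offs))
  (as.integer(seed) %% 1000003L) * 2011L + offs[[purpose]]
}

#' Generate a synthetic multimodal cohort
#'
#' Draws per-patient latent factors for each modality, emits feature blocks
#' as random linear loadings of those latents plus Gaussian noise (a fraction
#' of clinical features binarized), and simulates right-censored OS and PFS
#' from an exponential model with log-hazard `sum_k beta_k * z_k1` where
#' `z_k1` is modality k's first latent. Block-wise missingness is applied per
#' the config's [missingness_spec()].
#'
#' @param config A [cohort_config()].
#' @return A list with elements
#'   \describe{
#'     \item{data}{`multimodal_dataset`: `patient_ids`, `blocks` (named list
#'       of patients x features matrices, `NA` where missing),
#'       `availability` (logical patients x modalities matrix).}
#'     \item{outcomes}{Data frame with `patient_id`, `os_time`, `os_event`,
#'       `pfs_time`, `pfs_event`, `label_1y_death`, `label_6m_progression`
#'       (binary labels are `NA` when the patient is excluded because of
#'       censoring before the horizon).}
#'     \item{latents}{Named list of latent matrices (for oracle checks).}
#'     \item{risk}{True log-hazard per patient.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  mods <- names(config$block_schema)
  set.seed(sub_seed(config$seed, "cohort"))

  ids <- sprintf("P%04d", seq_len(n))
  latents <- list()
  blocks <- list()
  risk <- numeric(n)
  for (k in mods) {
    d <- config$latent_dims[[k]]
    p <- config$block_schema[[k]]
    z <- matrix(stats::rnorm(n * d), n, d)
    load <- matrix(stats::rnorm(d * p, sd = 1), d, p)
    x <- z %*% load +
      matrix(stats::rnorm(n * p, sd = config$feature_noise_sd), n, p)
    colnames(x) <- feature_names_for(k, p)
    if (k == "clinical" && config$categorical_fraction > 0) {
      n_cat <- floor(p * config$categorical_fraction)
      if (n_cat > 0) {
        idx <- seq(p - n_cat + 1L, p)
        x[, idx] <- (x[, idx] > 0) + 0
      }
    }
    latents[[k]] <- z
    blocks[[k]] <- x
    risk <- risk + config$effect_sizes[[k]] * z[, 1]
  }

  os_time_raw <- stats::rexp(n, rate = config$baseline_hazard_os * exp(risk))
  pfs_time_raw <- stats::rexp(n, rate = config$baseline_hazard_pfs * exp(risk))
  dropout <- ifelse(stats::runif(n) < config$dropout_rate,
                    stats::runif(n, 0, config$censoring_window),
                    config$censoring_window)
  cens <- pmin(dropout, config$censoring_window)
  os_time <- pmin(os_time_raw, cens)
  os_event <- as.integer(os_time_raw <= cens)
  pfs_time <- pmin(pfs_time_raw, cens)
  pfs_event <- as.integer(pfs_time_raw <= cens)
  # guard against zero-duration follow-up
  os_time <- pmax(os_time, 1)
  pfs_time <- pmax(pfs_time, 1)

  outcomes <- data.frame(
    patient_id = ids,
    os_time = os_time, os_event = os_event,
    pfs_time = pfs_time, pfs_event = pfs_event,
    stringsAsFactors = FALSE)
  outcomes$label_1y_death <-
    derive_binary_labels(os_time, os_event, horizon = 365)
  outcomes$label_6m_progression <-
    derive_binary_labels(pfs_time, pfs_event, horizon = 183)

  avail <- matrix(TRUE, n, length(mods), dimnames = list(ids, mods))
  data <- structure(list(patient_ids = ids, blocks = blocks,
                         availability = avail),
                    class = "multimodal_dataset")
  if (!is.null(config$missingness))
    data <- apply_missingness(data, config$missingness,
                              seed = sub_seed(config$seed, "missingness"))
  list(data = data, outcomes = outcomes, latents = latents, risk = risk)
}

# Feature names; a few named sentinels make interpretation demos readable.
feature_names_for <- function(modality, p) {
  sentinels <- switch(modality,
    clinical = c("albumin_like", "ecog_like", "ldh_like"),
    rna = c("dc_abundance_like", "cd8_abundance_like", "tmb_like"),
    character(0))
  base <- sprintf("%s_f%03d", modality, seq_len(p))
  k <- min(length(sentinels), p)
  if (k > 0) base[seq_len(k)] <- sentinels[seq_len(k)]
  base
}

#' Derive binary outcome labels from censored times
#'
#' Event before the horizon maps to 1; follow-up beyond the horizon maps
#' to 0; censoring before the horizon excludes the patient (`NA`).
#'
#' @param time Follow-up times in days.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param horizon Horizon in days (365 for 1-year death, 183 for 6-month
#'   progression).
#' @return Integer vector with values 0, 1 or `NA` (excluded).
#' @export
derive_binary_labels <- function(time, event, horizon) {
  stopifnot(horizon > 0, length(time) == length(event))
  if (any(time <= 0, na.rm = TRUE)) stop("times must be positive")
  label <- ifelse(time <= horizon & event == 1, 1L,
           ifelse(time > horizon, 0L, NA_integer_))
  as.integer(label)
}

#' Apply block-wise modality missingness
#'
#' Sets the availability mask according to the spec's pattern frequencies and
#' blanks every cell of unavailable blocks; additionally scatters `NA` cells
#' inside available blocks at `within_block_na_rate`.
#'
#' @param data A `multimodal_dataset`.
#' @param spec A [missingness_spec()].
#' @param seed Integer seed controlling pattern assignment and cell-level
#'   missingness.
#' @return The dataset with updated `availability` and `NA`-filled blocks.
#' @export
apply_missingness <- function(data, spec, seed = 1L) {
  stopifnot(inherits(data, "multimodal_dataset"),
            inherits(spec, "missingness_spec"))
  n <- length(data$patient_ids)
  mods <- colnames(data$availability)
  set.seed(as.integer(seed))

  pat_names <- names(if (spec$mode == "exact_counts") spec$pattern_counts
                     else spec$pattern_probs)
  if (spec$mode == "exact_counts") {
    counts <- spec$pattern_counts
    if (sum(counts) != n)
      stop("pattern counts must sum to n_patients")
    assignment <- rep(pat_names, times = counts)
    assignment <- sample(assignment)          # which patient gets which pattern
  } else {
    assignment <- sample(pat_names, n, replace = TRUE,
                         prob = spec$pattern_probs)
  }

  avail <- matrix(FALSE, n, length(mods),
                  dimnames = list(data$patient_ids, mods))
  for (i in seq_len(n)) {
    present <- strsplit(assignment[i], "+", fixed = TRUE)[[1]]
    bad <- setdiff(present, mods)
    if (length(bad)) stop("unknown modality in pattern: ", bad[1])
    avail[i, present] <- TRUE
  }

  for (k in mods) {
    blk <- data$blocks[[k]]
    blk[!avail[, k], ] <- NA
    if (spec$within_block_na_rate > 0) {
      obs <- which(avail[, k])
      if (length(obs)) {
        cells <- matrix(stats::runif(length(obs) * ncol(blk)) <
                          spec$within_block_na_rate,
                        length(obs), ncol(blk))
        blk[obs, ][cells] <- NA
      }
    }
    data$blocks[[k]] <- blk
  }
  data$availability <- avail
  data
}

#' Patients with a complete multimodal profile
#'
#' @param data A `multimodal_dataset`.
#' @return Character vector of patient ids with every modality available.
#' @export
complete_profile_ids <- function(data) {
  data$patient_ids[rowSums(data$availability) == ncol(data$availability)]
}

#' Generate a per-lesion PET cohort
#'
#' Simulates the lesion-level input of the radiomics aggregation module:
#' Poisson lesion counts per anatomical region, lognormal metabolic volumes,
#' SUVmax values bounded below by the 2.5 SUV segmentation threshold,
#' centroids in a body-sized box, occasional diffuse-disease flags, plus
#' per-patient healthy-organ reference uptake (liver, spleen SUVmean) and
#' body surface area.
#'
#' @param n_patients Number of patients.
#' @param region_intensity Named vector of expected lesion counts per region;
#'   defaults cover the TNM-inspired partition used by
#'   [assemble_radiomics()].
#' @param diffuse_prob Probability that a lesion is flagged as diffuse
#'   (lymphangitic-spread-like, excluded from volume features).
#' @param seed Integer seed.
#' @return A list with `lesions` (data frame: `patient_id`, `lesion_id`,
#'   `suv_max`, `volume_ml`, `x_mm`, `y_mm`, `z_mm`, `region`, `diffuse`) and
#'   `rois` (data frame: `patient_id`, `liver_suvmean`, `spleen_suvmean`,
#'   `bsa_m2`).
#' @export
generate_lesion_cohort <- function(n_patients,
                                   region_intensity = c(
                                     primary_ipsilateral_lung = 1.5,
                                     contralateral_lung = 0.5,
                                     subdiaphragmatic_nodes = 0.4,
                                     supradiaphragmatic_nodes = 0.6,
                                     pleura = 0.3,
                                     liver = 0.3,
                                     bones = 0.5,
                                     adrenal_gland = 0.2,
                                     other = 0.2),
                                   diffuse_prob = 0.05,
                                   seed = 1L) {
  stopifnot(n_patients > 0, all(region_intensity >= 0),
            diffuse_prob >= 0, diffuse_prob <= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("P%04d", seq_len(n_patients))
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    counts <- stats::rpois(length(region_intensity), region_intensity)
    total <- sum(counts)
    if (total == 0) { rows[[i]] <- NULL; next }
    region <- rep(names(region_intensity), counts)
    rows[[i]] <- data.frame(
      patient_id = ids[i],
      lesion_id = sprintf("%s_L%02d", ids[i], seq_len(total)),
      suv_max = 2.5 + stats::rlnorm(total, meanlog = 1.2, sdlog = 0.6),
      volume_ml = stats::rlnorm(total, meanlog = 1.5, sdlog = 1),
      x_mm = stats::runif(total, -250, 250),
      y_mm = stats::runif(total, -150, 150),
      z_mm = stats::runif(total, 0, 1000),
      region = region,
      diffuse = stats::runif(total) < diffuse_prob,
      stringsAsFactors = FALSE)
  }
  lesions <- do.call(rbind, rows)
  if (is.null(lesions))
    lesions <- data.frame(patient_id = character(), lesion_id = character(),
                          suv_max = numeric(), volume_ml = numeric(),
                          x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                          region = character(), diffuse = logical())
  rois <- data.frame(
    patient_id = ids,
    liver_suvmean = pmax(0.5, stats::rnorm(n_patients, 2.2, 0.35)),
    spleen_suvmean = pmax(0.4, stats::rnorm(n_patients, 1.9, 0.3)),
    bsa_m2 = pmax(1.2, stats::rnorm(n_patients, 1.8, 0.2)),
    stringsAsFactors = FALSE)
  list(lesions = lesions, rois = rois)
}

#' Write a multimodal cohort to delimited files
#'
#' One CSV per feature block (`patient_id` + features, empty cell = missing),
#' plus `outcomes.csv` and `availability.csv`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (k in names(cohort$data$blocks)) {
    df <- data.frame(patient_id = cohort$data$patient_ids,
                     cohort$data$blocks[[k]], check.names = FALSE)
    f <- file.path(dir, paste0(k, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  f <- file.path(dir, "outcomes.csv")
  utils::write.csv(cohort$outcomes, f, row.names = FALSE, na = "")
  files <- c(files, f)
  av <- data.frame(patient_id = cohort$data$patient_ids,
                   cohort$data$availability + 0, check.names = FALSE)
  f <- file.path(dir, "availability.csv")
  utils::write.csv(av, f, row.names = FALSE)
  invisible(c(files, f))
}

#' Read a multimodal cohort written by [write_cohort()]
#'
#' @param dir Directory containing the block CSVs, `outcomes.csv` and
#'   `availability.csv`.
#' @param modalities Block file names to read (without extension).
#' @return A list with `data` (`multimodal_dataset`) and `outcomes`.
#' @export
read_cohort <- function(dir, modalities = c("clinical", "radiomics",
                                            "pathomics", "rna")) {
  blocks <- list()
  for (k in modalities) {
    df <- utils::read.csv(file.path(dir, paste0(k, ".csv")),
                          check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- NULL
    blocks[[k]] <- m
  }
  av <- utils::read.csv(file.path(dir, "availability.csv"),
                        check.names = FALSE)
  avail <- as.matrix(av[, -1, drop = FALSE]) > 0
  rownames(avail) <- av$patient_id
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"))
  data <- structure(list(patient_ids = av$patient_id, blocks = blocks,
                         availability = avail),
                    class = "multimodal_dataset")
  list(data = data, outcomes = outcomes)
}
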