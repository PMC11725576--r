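# Whole-body PET radiomics aggregation.
#
# Turns a per-lesion table (SUVmax, metabolic volume, centroid, anatomical
# region, diffuse flag) into 30 whole-body features: healthy-organ reference
# uptake, total metabolic tumor volume (TMTV), invaded-organ count,
# standardized Dmax, the quartile dispersion of centroid distances, and per
# TNM-inspired stage group the TMTV plus mean/sd/max of SUVmax. Volume
# features are log(x+1)-transformed. Diffuse-flagged lesions (lymphangitic
# spread and similar, whose segmentation is unreliable) are excluded from all
# volume- and distance-derived features but kept for SUVmax statistics.

# Anatomical regions recognised in the lesion table.
radiomics_regions <- c("primary_ipsilateral_lung", "contralateral_lung",
                       "subdiaphragmatic_nodes", "supradiaphragmatic_nodes",
                       "pleura", "liver", "bones", "adrenal_gland", "other")

#' Stage-group partition of anatomical regions
#'
#' Six groups inspired by TNM staging: T (primary tumor and ipsilateral lung
#' metastases), N (nodal stations), M1a (intrathoracic metastatic spread),
#' M1b/M1c (extrathoracic organ groups) and a catch-all. Together with the
#' six whole-body features this yields the fixed 30-feature set
#' (6 + 6 groups x 4 statistics). The mapping is configurable because the
#' region-to-stage assignment is a modelling choice.
#'
#' @return Named list mapping group name to a character vector of regions.
#' @export
default_stage_groups <- function() {
  list(T = "primary_ipsilateral_lung",
       N = c("subdiaphragmatic_nodes", "supradiaphragmatic_nodes"),
       M1a = c("contralateral_lung", "pleura"),
       M1b = c("liver", "adrenal_gland"),
       M1c = "bones",
       other = "other")
}

check_lesions <- function(lesions) {
  need <- c("suv_max", "volume_ml", "x_mm", "y_mm", "z_mm", "region",
            "diffuse")
  missing <- setdiff(need, names(lesions))
  if (length(missing)) stop("lesion table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(lesions) && any(lesions$suv_max < 2.5))
    stop("SUVmax below the 2.5 SUV segmentation threshold")
  if (nrow(lesions) && any(lesions$volume_ml < 0))
    stop("negative metabolic volume")
  invisible(lesions)
}

#' Total metabolic tumor volume
#'
#' Sum of metabolic volumes over non-diffuse lesions, in ml.
#'
#' @param lesions Per-lesion data frame for one patient.
#' @return TMTV in ml (0 for an empty lesion list).
#' @export
compute_tmtv <- function(lesions) {
  check_lesions(lesions)
  if (!nrow(lesions)) return(0)
  sum(lesions$volume_ml[!lesions$diffuse])
}

#' Standardized Dmax
#'
#' Largest Euclidean distance between two non-diffuse lesion centroids,
#' normalized by body surface area. A tumor-dissemination measure.
#'
#' @param lesions Per-lesion data frame for one patient.
#' @param bsa Body surface area in m^2 (> 0).
#' @return Dmax / BSA in mm per m^2; 0 with fewer than two lesions.
#' @export
standardized_dmax <- function(lesions, bsa) {
  check_lesions(lesions)
  if (!is.finite(bsa) || bsa <= 0) stop("bsa must be positive")
  keep <- lesions[!lesions$diffuse, , drop = FALSE]
  if (nrow(keep) < 2) return(0)
  xyz <- as.matrix(keep[, c("x_mm", "y_mm", "z_mm")])
  max(stats::dist(xyz)) / bsa
}

#' Quartile dispersion of centroid distances
#'
#' Coefficient of quartile dispersion (Q3 - Q1) / (Q3 + Q1) of the distances
#' between each non-diffuse lesion centroid and the unweighted global
#' centroid, with linear-interpolation quartiles.
#'
#' @param lesions Per-lesion data frame for one patient.
#' @return Dimensionless dispersion in [0, 1]; 0 with fewer than two lesions
#'   or when Q1 + Q3 = 0.
#' @export
quartile_dispersion <- function(lesions) {
  check_lesions(lesions)
  keep <- lesions[!lesions$diffuse, , drop = FALSE]
  if (nrow(keep) < 2) return(0)
  xyz <- as.matrix(keep[, c("x_mm", "y_mm", "z_mm")])
  ctr <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  if (sum(q) == 0) return(0)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Invaded-organ count
#'
#' Number of distinct organ categories containing at least one lesion; the
#' two lung regions count as one "lungs" category, the two nodal stations
#' count separately.
#'
#' @param lesions Per-lesion data frame for one patient.
#' @return Integer count in 0..8.
#' @export
invaded_organ_count <- function(lesions) {
  check_lesions(lesions)
  if (!nrow(lesions)) return(0L)
  organ <- ifelse(lesions$region %in%
                    c("primary_ipsilateral_lung", "contralateral_lung"),
                  "lungs", lesions$region)
  length(unique(organ))
}

#' Stage-group volume and SUVmax statistics
#'
#' Restricted to the lesions of one stage group: TMTV over non-diffuse
#' lesions, and the mean, population standard deviation and maximum of
#' SUVmax over all lesions of the group (diffuse included, since SUVmax
#' does not depend on segmentation quality). An empty group maps to zeros.
#'
#' @param lesions Per-lesion data frame for one patient.
#' @param group Stage-group name.
#' @param groups Region partition, see [default_stage_groups()].
#' @return Named numeric vector `c(tmtv, suv_mean, suv_sd, suv_max)`.
#' @export
stage_group_features <- function(lesions, group,
                                 groups = default_stage_groups()) {
  check_lesions(lesions)
  if (!group %in% names(groups)) stop("unknown stage group: ", group)
  sub <- lesions[lesions$region %in% groups[[group]], , drop = FALSE]
  if (!nrow(sub))
    return(c(tmtv = 0, suv_mean = 0, suv_sd = 0, suv_max = 0))
  suv <- sub$suv_max
  c(tmtv = sum(sub$volume_ml[!sub$diffuse]),
    suv_mean = mean(suv),
    suv_sd = sqrt(mean((suv - mean(suv))^2)),  # population sd; 0 for n = 1
    suv_max = max(suv))
}

#' Assemble the 30 whole-body radiomic features for one patient
#'
#' @param lesions Per-lesion data frame for one patient (possibly empty).
#' @param liver_suvmean,spleen_suvmean Healthy-organ reference SUVmean
#'   (`NA` if the ROI is unavailable).
#' @param bsa Body surface area in m^2.
#' @param groups Stage-group partition.
#' @return Named numeric vector of exactly 30 features in a fixed order;
#'   metabolic-volume features are log(x+1)-transformed.
#' @export
assemble_radiomics <- function(lesions, liver_suvmean, spleen_suvmean, bsa,
                               groups = default_stage_groups()) {
  check_lesions(lesions)
  out <- c(liver_suvmean = as.numeric(liver_suvmean),
           spleen_suvmean = as.numeric(spleen_suvmean),
           tmtv_log = log1p(compute_tmtv(lesions)),
           n_invaded_organs = as.numeric(invaded_organ_count(lesions)),
           dmax_std = standardized_dmax(lesions, bsa),
           quartile_dispersion = quartile_dispersion(lesions))
  for (g in names(groups)) {
    f <- stage_group_features(lesions, g, groups)
    f[["tmtv"]] <- log1p(f[["tmtv"]])
    names(f) <- paste0(g, "_", c("tmtv_log", "suvmax_mean", "suvmax_sd",
                                 "suvmax_max"))
    out <- c(out, f)
  }
  stopifnot(length(out) == 30L)
  out
}

#' Radiomic feature table for a lesion cohort
#'
#' Applies [assemble_radiomics()] per patient of a lesion cohort.
#'
#' @param lesions Lesion table for all patients (column `patient_id`).
#' @param rois Healthy-ROI table (`patient_id`, `liver_suvmean`,
#'   `spleen_suvmean`, `bsa_m2`).
#' @param groups Stage-group partition.
#' @return Data frame: `patient_id` + 30 feature columns.
#' @export
radiomics_feature_table <- function(lesions, rois,
                                    groups = default_stage_groups()) {
  stopifnot(all(c("patient_id", "liver_suvmean", "spleen_suvmean",
                  "bsa_m2") %in% names(rois)))
  feats <- t(vapply(seq_len(nrow(rois)), function(i) {
    pid <- rois$patient_id[i]
    les <- lesions[lesions$patient_id == pid, , drop = FALSE]
    assemble_radiomics(les, rois$liver_suvmean[i], rois$spleen_suvmean[i],
                       rois$bsa_m2[i], groups)
  }, numeric(30)))
  data.frame(patient_id = rois$patient_id, feats, check.names = FALSE,
             stringsAsFactors = FALSE)
}
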