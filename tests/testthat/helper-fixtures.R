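# Shared fixtures and independent oracles used across the test files.

# Lesion table rows built directly, all SUVmax above the 2.5 threshold.
make_lesions <- function(volumes = numeric(0), suv = NULL, regions = NULL,
                         centroids = NULL, diffuse = NULL) {
  n <- length(volumes)
  if (is.null(suv)) suv <- rep(5, n)
  if (is.null(regions)) regions <- rep("primary_ipsilateral_lung", n)
  if (is.null(centroids)) centroids <- matrix(0, n, 3)
  if (is.null(diffuse)) diffuse <- rep(FALSE, n)
  data.frame(patient_id = rep("P1", n),
             lesion_id = sprintf("L%02d", seq_len(n)),
             suv_max = suv, volume_ml = volumes,
             x_mm = centroids[, 1], y_mm = centroids[, 2],
             z_mm = centroids[, 3],
             region = regions, diffuse = diffuse,
             stringsAsFactors = FALSE)
}

# O(n^2) pair-counting oracle for the AUC (probability interpretation).
brute_auc <- function(pred, labels) {
  pos <- pred[labels == 1]; neg <- pred[labels == 0]
  num <- 0
  for (p in pos) for (q in neg)
    num <- num + (p > q) + 0.5 * (p == q)
  num / (length(pos) * length(neg))
}

# O(n^2) concordant-pair oracle for censoring-free survival data.
brute_cindex <- function(pred, time) {
  num <- den <- 0
  n <- length(pred)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j]) {
      den <- den + 1
      num <- num + (pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j])
    }
  }
  num / den
}

# Exact Shapley values by enumeration over all player permutations:
# independent of the subset-enumeration route used by the package.
brute_shapley <- function(preds, baseline = 0.5) {
  players <- names(preds)
  K <- length(players)
  v <- function(S) if (!length(S)) baseline else mean(preds[S])
  perms <- if (K == 1) list(players) else {
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(character(0), players)
    out
  }
  phi <- stats::setNames(numeric(K), players)
  for (perm in perms) {
    prev <- v(character(0))
    S <- character(0)
    for (p in perm) {
      S <- c(S, p)
      cur <- v(S)
      phi[p] <- phi[p] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(perms)
}

# Survival cohort with two risk regimes split at the score's q-quantile.
two_regime_cohort <- function(n = 200, q = 0.5, seed = 110, hr = 6) {
  set.seed(seed)
  score <- runif(n)
  high <- score > quantile(score, q)
  rate <- ifelse(high, hr * 0.002, 0.002)
  t <- rexp(n, rate)
  cns <- runif(n, 500, 3000)
  list(score = score, time = pmin(t, cns), event = as.integer(t <= cns),
       high = high)
}

# Small fully observed multimodal cohort for learner/fusion tests.
small_cohort <- function(n = 150, betas = c(clinical = 0.6, radiomics = 0.6,
                                            pathomics = 0.6, rna = 0.6),
                         seed = 10) {
  cohort_config(
    n_patients = n,
    block_schema = c(clinical = 8L, radiomics = 8L, pathomics = 12L,
                     rna = 8L),
    latent_dims = c(clinical = 1L, radiomics = 1L, pathomics = 2L,
                    rna = 1L),
    effect_sizes = betas,
    missingness = NULL, seed = seed) |> generate_cohort()
}
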