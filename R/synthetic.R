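# Deterministic generators emulating the three pipeline inputs: multi-
# origin batch fingerprints, Box-Behnken response columns, and LC-MS
# feature sets with known parent/modification labels.

#' Configuration for the fingerprint generator
#'
#' Defaults emulate the fingerprint study conditions: 15 batches from
#' several growing origins, 11 consensus peaks, retention-time jitter well
#' inside the 0.1 min matching window, and moderate multiplicative area
#' noise.
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param n_origins number of origins (> 0).
#' @param batches_per_origin batches per origin (> 0).
#' @param n_peaks archetype peaks per fingerprint (> 0).
#' @param rt_jitter_sd SD of the Gaussian retention-time jitter, minutes.
#' @param area_noise_cv coefficient of variation of the lognormal
#'   multiplicative area noise (areas stay positive, as chromatographic
#'   areas must).
#' @param dropout_prob probability that a peak is missing from a batch
#'   (in \[0, 1)); applied before alignment so common-peak detection is
#'   exercised.
#' @return validated list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, n_origins = 3L, batches_per_origin = 5L,
                         n_peaks = 11L, rt_jitter_sd = 0.01,
                         area_noise_cv = 0.05, dropout_prob = 0) {
  if (n_origins < 1 || batches_per_origin < 1 || n_peaks < 1)
    stop("counts must be positive", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)", call. = FALSE)
  if (rt_jitter_sd < 0 || area_noise_cv < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  structure(list(seed = as.integer(seed), n_origins = as.integer(n_origins),
                 batches_per_origin = as.integer(batches_per_origin),
                 n_peaks = as.integer(n_peaks),
                 rt_jitter_sd = rt_jitter_sd,
                 area_noise_cv = area_noise_cv,
                 dropout_prob = dropout_prob),
            class = "synth_config")
}

# lognormal sdlog such that the coefficient of variation equals cv
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate multi-origin batch fingerprints
#'
#' Each origin gets an archetype area vector (lognormal peak areas times
#' an origin amplitude); each batch is the archetype perturbed by
#' multiplicative lognormal noise with the requested coefficient of
#' variation, Gaussian retention-time jitter, and Bernoulli peak dropout.
#' Archetype peaks are spaced 1.5 min apart so distinct peaks never fall
#' into one 0.1 min matching window.
#'
#' @param cfg a [synth_config()].
#' @return list with `tables` (list of [peak_table()]), `origin` (named
#'   ground-truth origin per sample), `archetypes` (origins x peaks area
#'   matrix), `amplitudes` (per-origin scale factors) and `peak_rts`.
#' @export
make_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  rts <- seq(5, by = 1.5, length.out = cfg$n_peaks)
  amplitudes <- stats::rlnorm(cfg$n_origins, meanlog = 0, sdlog = 0.3)
  shape <- matrix(stats::rlnorm(cfg$n_origins * cfg$n_peaks,
                                meanlog = log(500), sdlog = 0.8),
                  nrow = cfg$n_origins)
  archetypes <- shape * amplitudes
  tables <- list()
  origin <- character(0)
  sdlog <- cv_to_sdlog(cfg$area_noise_cv)
  for (o in seq_len(cfg$n_origins)) {
    for (b in seq_len(cfg$batches_per_origin)) {
      id <- sprintf("O%d-B%d", o, b)
      noise <- if (cfg$area_noise_cv > 0)
        stats::rlnorm(cfg$n_peaks, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, cfg$n_peaks)
      jitter <- if (cfg$rt_jitter_sd > 0)
        stats::rnorm(cfg$n_peaks, 0, cfg$rt_jitter_sd)
      else rep(0, cfg$n_peaks)
      keep <- if (cfg$dropout_prob > 0)
        stats::runif(cfg$n_peaks) >= cfg$dropout_prob
      else rep(TRUE, cfg$n_peaks)
      if (!any(keep)) keep[1] <- TRUE  # a table must hold >= 1 peak
      tables[[id]] <- peak_table(id, (rts + jitter)[keep],
                                 (archetypes[o, ] * noise)[keep])
      origin[id] <- sprintf("O%d", o)
    }
  }
  list(tables = tables, origin = origin, archetypes = archetypes,
       amplitudes = amplitudes, peak_rts = rts)
}

#' Write generated fingerprints to disk
#'
#' Long-form CSV of all peak tables plus a JSON sidecar carrying the
#' ground-truth origin labels and generator configuration.
#'
#' @param fp a [make_fingerprints()] result.
#' @param csv_path output CSV (columns `sample_id`, `rt_min`, `area`).
#' @param truth_path optional JSON sidecar path.
#' @param cfg the generating [synth_config()], stored in the sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_fingerprints <- function(fp, csv_path, truth_path = NULL, cfg = NULL) {
  long <- do.call(rbind, fp$tables)
  utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(list(origin = as.list(fp$origin),
                              config = unclass(cfg)),
                         truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' True response surface for the Box-Behnken generator
#'
#' @param beta0 intercept.
#' @param linear,interaction,quadratic coefficient triples, interactions
#'   in (x1 x2, x1 x3, x2 x3) order.
#' @param noise_sd run-to-run Gaussian noise SD (>= 0).
#' @return list of class `"true_surface"` whose `beta` slot matches the
#'   [fit_quadratic()] coefficient naming.
#' @export
true_surface <- function(beta0, linear, interaction, quadratic,
                         noise_sd = 0) {
  stopifnot(length(linear) == 3, length(interaction) == 3,
            length(quadratic) == 3, noise_sd >= 0)
  beta <- c(beta0, linear, interaction, quadratic)
  names(beta) <- c("b0", "b1", "b2", "b3", "b12", "b13", "b23",
                   "b11", "b22", "b33")
  structure(list(beta = beta, noise_sd = noise_sd),
            class = "true_surface")
}

#' Simulate response values on a Box-Behnken design
#'
#' `y_i = f(x_i) + N(0, noise_sd)` with `f` the true quadratic surface
#' evaluated at the coded design points.
#'
#' @param surface a [true_surface()].
#' @param design a [bbd_design()] (coded levels in -1/0/+1).
#' @param seed integer seed for the noise draws.
#' @return numeric response vector, one value per design run.
#' @export
make_bbd_responses <- function(surface, design, seed = 1L) {
  stopifnot(inherits(surface, "true_surface"))
  X <- coded_matrix(design)
  if (!all(X %in% c(-1, 0, 1)))
    stop("design must have coded levels in {-1, 0, +1}", call. = FALSE)
  mu <- eval_quadratic(surface$beta, X)
  if (surface$noise_sd == 0) return(mu)
  set.seed(seed)
  mu + stats::rnorm(nrow(X), 0, surface$noise_sd)
}

#' Generate an LC-MS feature set with known annotations
#'
#' Draws features at the theoretical m/z of random parent x
#' modification-multiset x adduct combinations and perturbs them by
#' Gaussian ppm noise. Truth combinations are sampled only from the
#' *identifiable* candidates: (i) where several combinations share one
#' ion formula (hence one exact mass), only the one the annotator would
#' rank first (fewest modifications, then parent name) is used as a truth
#' label, so zero-noise recovery is exact by construction; and (ii)
#' candidates whose exact mass lies within `min_separation_ppm` of
#' another distinct candidate mass in the same ion mode are excluded,
#' so the benchmark measures noise tolerance rather than inherent
#' isobaric ambiguity of the search space.
#'
#' @param parents named list/vector of parent formulas.
#' @param rules modification library, see [modification_rules()].
#' @param max_depth maximum modifications per combination (>= 1).
#' @param ppm_noise_sd SD of the Gaussian m/z perturbation, in ppm.
#' @param n number of features to draw.
#' @param seed integer seed.
#' @param min_separation_ppm identifiability margin: truth candidates
#'   must be at least this far (ppm) from every other distinct candidate
#'   mass in the same mode. Default 20, twice the default search
#'   tolerance of [annotate_features()].
#' @return list with `features` (data frame `id`, `mz`, `ion_mode`) and
#'   `truth` (data frame `id`, `parent`, `modifications`, `adduct`,
#'   `formula`, `true_mz`).
#' @export
make_feature_set <- function(parents, rules = modification_rules(),
                             max_depth = 3, ppm_noise_sd = 0, n = 100,
                             seed = 1L, min_separation_ppm = 20) {
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (is.character(parents)) parents <- as.list(parents)
  if (!length(parents)) stop("parents must be non-empty", call. = FALSE)
  cand <- candidate_table(parents, rules, max_depth)
  # identifiability margin: distance to the nearest distinct candidate
  # mass in the same ion mode (any combination, canonical or not)
  sep_ok <- rep(TRUE, nrow(cand))
  for (mode in unique(cand$ion_mode)) {
    idx <- which(cand$ion_mode == mode)
    mz <- sort(unique(round(cand$calc_mz[idx], 5)))
    gap_ppm <- diff(mz) / mz[-length(mz)] * 1e6
    near <- mz[c(gap_ppm < min_separation_ppm, FALSE) |
                 c(FALSE, gap_ppm < min_separation_ppm)]
    sep_ok[idx] <- !(round(cand$calc_mz[idx], 5) %in% near)
  }
  cand <- cand[sep_ok, , drop = FALSE]
  # canonical representative per exact ion mass within a mode: several
  # combinations can share one m/z exactly (shared ion formula, or a
  # formic-acid adduct isobaric with the deprotonated CH2O2-shifted
  # formula); keep the one the annotator ranks first at that mass
  key <- paste(cand$ion_mode, sprintf("%.5f", cand$calc_mz))
  cand <- cand[order(key, cand$n_mods, cand$parent, cand$adduct),
               , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$ion_mode,
                                 sprintf("%.5f", cand$calc_mz))),
               , drop = FALSE]
  cand <- cand[order(cand$calc_mz), , drop = FALSE]
  if (!nrow(cand))
    stop("no identifiable candidates under min_separation_ppm",
         call. = FALSE)
  set.seed(seed)
  pick <- sample.int(nrow(cand), n, replace = TRUE)
  truth <- cand[pick, , drop = FALSE]
  noise <- if (ppm_noise_sd > 0) stats::rnorm(n, 0, ppm_noise_sd) else
    rep(0, n)
  mz <- truth$calc_mz * (1 + noise * 1e-6)
  ids <- sprintf("F%04d", seq_len(n))
  list(features = data.frame(id = ids, mz = mz,
                             ion_mode = truth$ion_mode,
                             stringsAsFactors = FALSE),
       truth = data.frame(id = ids, parent = truth$parent,
                          modifications = truth$mods,
                          adduct = truth$adduct, formula = truth$formula,
                          true_mz = truth$calc_mz,
                          stringsAsFactors = FALSE))
}

#' Parent compounds observed in plasma
#'
#' The packaged parent-compound panel (name, molecular formula) used as
#' the default search space for metabolite annotation.
#'
#' @return named character vector of formulas.
#' @export
plasma_parents <- function() {
  d <- utils::read.csv(herbqc_example("plasma_parents.csv"),
                       stringsAsFactors = FALSE)
  stats::setNames(d$formula, d$name)
}
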