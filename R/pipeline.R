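# End-to-end orchestration: quality screening, extraction optimization,
# and annotation runs, each writing CSV/JSON outputs plus a reproducibility
# manifest.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

write_manifest <- function(out_dir, stage, params, inputs) {
  checksums <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("herbqc")),
                   parameters = params,
                   input_md5 = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the batch-quality screening stage
#'
#' Peak alignment, similarity report against the median reference
#' fingerprint, autoscaling, correlation-matrix PCA, comprehensive-score
#' ranking, and hierarchical clustering, with all outputs written to
#' `out_dir`: `fingerprint_matrix.csv`, `similarity.csv`, `ranking.csv`,
#' `dendrogram.nwk` and `manifest.json`.
#'
#' @param peak_csv CSV of stacked peak tables (`sample_id`, `rt_min`,
#'   `area`).
#' @param out_dir output directory (created if missing).
#' @param rt_window alignment window half-width in minutes.
#' @param eigen_threshold PCA retention threshold.
#' @param k number of flat clusters for the dendrogram cut (default: not
#'   cut).
#' @param linkage,metric clustering settings, see [hca()].
#' @param similarity_method see [similarity()].
#' @return invisibly, a list with the fingerprint matrix, similarity
#'   report, PCA, ranking and clustering.
#' @export
run_quality <- function(peak_csv, out_dir, rt_window = 0.1,
                        eigen_threshold = 0.99, k = NULL,
                        linkage = "ward", metric = "euclidean",
                        similarity_method = "cosine") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- with_stage("read", read_peak_tables(peak_csv))
  m <- with_stage("align", match_peaks(tables, window = rt_window))
  sim <- with_stage("similarity",
                    similarity_report(m, method = similarity_method))
  # degenerate case: all batches identical (every common-peak column has
  # zero variance) -- PCA is undefined, the ranking is trivial (all
  # comprehensive scores 0, stable id order) and all samples form one
  # cluster
  degenerate <- all(apply(m$areas[, m$common_mask, drop = FALSE], 2,
                          stats::sd) == 0)
  if (degenerate) {
    p <- NULL
    ids <- sort(m$sample_ids)
    ranking <- data.frame(sample_id = ids, comprehensive_score = 0,
                          rank = seq_along(ids), stringsAsFactors = FALSE)
    cl <- list(hclust = stats::hclust(stats::dist(m$areas), "ward.D2"))
    if (!is.null(k)) cl$labels <- stats::cutree(cl$hclust, k = k)
  } else {
    p <- with_stage("pca", pca_fingerprint(m, eigen_threshold))
    ranking <- with_stage("ranking", comprehensive_scores(p))
    cl <- with_stage("hca", hca(m, k = k, linkage = linkage,
                                metric = metric))
  }
  write_fingerprint_matrix(m, file.path(out_dir, "fingerprint_matrix.csv"))
  utils::write.csv(sim, file.path(out_dir, "similarity.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)
  dendrogram_newick(cl, file.path(out_dir, "dendrogram.nwk"))
  write_manifest(out_dir, "quality",
                 list(rt_window = rt_window,
                      eigen_threshold = eigen_threshold,
                      k = k, linkage = linkage, metric = metric,
                      similarity_method = similarity_method),
                 list(peak_csv = peak_csv))
  invisible(list(matrix = m, similarity = sim, pca = p,
                 ranking = ranking, hca = cl))
}

#' Run the extraction-optimization stage
#'
#' Reads a Box-Behnken run table, obtains the overall-desirability
#' response (either a precomputed `od_col`, or computed from
#' `response_cols` via per-response linear desirability and their
#' geometric mean), fits the coded-unit quadratic, and maximizes it over
#' the design cube. Writes `model.json` (coefficients, ANOVA, optimum)
#' and two contour grids to `out_dir`.
#'
#' The run table may carry coded levels (columns `x1`, `x2`, `x3`) or
#' actual levels (columns matching the factor names, or `X1`, `X2`, `X3`),
#' which are auto-coded via `factors`.
#'
#' @param run_csv run-table CSV.
#' @param out_dir output directory.
#' @param od_col name of a precomputed overall-desirability column, if
#'   present (default `"OD"`); set `NULL` to force computation from
#'   `response_cols`.
#' @param response_cols response column names used when `od_col` is
#'   absent.
#' @param bounds `"observed"` (per-response min/max over the design) or a
#'   list of `c(ymin, ymax)` per response.
#' @param factors list of three [factor_spec()]s
#'   (default [extraction_factors()]).
#' @return invisibly, a list with the design, response, fitted
#'   `quadratic_model` and `rsm_optimum`.
#' @export
run_rsm <- function(run_csv, out_dir, od_col = "OD",
                    response_cols = NULL, bounds = "observed",
                    factors = extraction_factors()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- with_stage("read", utils::read.csv(run_csv, check.names = FALSE))
  d <- with_stage("code", {
    if (!all(c("x1", "x2", "x3") %in% names(d))) {
      actual_cols <- vapply(factors, `[[`, character(1), "name")
      if (!all(actual_cols %in% names(d))) actual_cols <- c("X1", "X2", "X3")
      if (!all(actual_cols %in% names(d)))
        stop("run table needs coded x1..x3 or actual-unit factor columns")
      for (j in 1:3)
        d[[paste0("x", j)]] <-
          (d[[actual_cols[j]]] - factors[[j]]$center) / factors[[j]]$step
    }
    d
  })
  y <- with_stage("desirability", {
    if (!is.null(od_col) && od_col %in% names(d)) {
      d[[od_col]]
    } else {
      if (is.null(response_cols))
        stop("no OD column found and no response_cols given")
      dmat <- sapply(seq_along(response_cols), function(i) {
        yi <- d[[response_cols[i]]]
        if (identical(bounds, "observed")) desirability(yi)
        else desirability(yi, bounds[[i]][1], bounds[[i]][2])
      })
      overall_desirability(dmat)
    }
  })
  attr(d, "factors") <- factors
  model <- with_stage("fit", fit_quadratic(d, y))
  opt <- with_stage("optimize", optimize_quadratic(model, factors))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         r_squared = model$r_squared,
         anova = model$anova,
         optimum = list(coded = opt$coded,
                        actual = as.list(opt$actual),
                        predicted = opt$predicted)),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(surface_grid(model, c(1, 2), factors = factors),
                   file.path(out_dir, "contour_x1_x2.csv"),
                   row.names = FALSE)
  utils::write.csv(surface_grid(model, c(1, 3), factors = factors),
                   file.path(out_dir, "contour_x1_x3.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "rsm",
                 list(od_col = od_col, response_cols = response_cols,
                      bounds = if (is.character(bounds)) bounds
                               else "supplied"),
                 list(run_csv = run_csv))
  invisible(list(design = d, response = y, model = model, optimum = opt))
}

#' Run the mass-annotation stage
#'
#' For a compound table (`id`, `formula`, `adduct`, `measured_mz`) writes
#' the theoretical m/z and ppm error per row; for a feature list plus a
#' parent panel writes biotransformation annotations. Either input may be
#' omitted. An empty feature list yields an empty (but well-formed)
#' annotation report.
#'
#' @param out_dir output directory.
#' @param compound_csv optional compound table CSV.
#' @param feature_csv optional feature list CSV (`id`, `mz`, `ion_mode`).
#' @param parent_csv optional parent panel CSV (`name`, `formula`);
#'   defaults to the packaged plasma parent panel when features are given.
#' @param tol_ppm,max_depth see [annotate_features()].
#' @return invisibly, a list with the computed tables.
#' @export
run_annotation <- function(out_dir, compound_csv = NULL,
                           feature_csv = NULL, parent_csv = NULL,
                           tol_ppm = 10, max_depth = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (!is.null(compound_csv)) {
    comp <- with_stage("read", utils::read.csv(compound_csv,
                                               stringsAsFactors = FALSE))
    out$masses <- with_stage("masses", {
      comp$calc_mz <- mapply(function(f, a) ion_mz(f, a),
                             comp$formula, comp$adduct)
      comp$ppm <- ppm_error(comp$measured_mz, comp$calc_mz)
      comp
    })
    utils::write.csv(out$masses, file.path(out_dir, "calculated_masses.csv"),
                     row.names = FALSE)
  }
  if (!is.null(feature_csv)) {
    feats <- with_stage("read", utils::read.csv(feature_csv,
                                                stringsAsFactors = FALSE))
    parents <- with_stage("read", {
      if (is.null(parent_csv)) plasma_parents()
      else {
        pd <- utils::read.csv(parent_csv, stringsAsFactors = FALSE)
        stats::setNames(pd$formula, pd$name)
      }
    })
    out$annotations <- with_stage("annotate",
      annotate_features(feats, as.list(parents), tol_ppm = tol_ppm,
                        max_depth = max_depth))
    utils::write.csv(out$annotations,
                     file.path(out_dir, "annotations.csv"),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "annotation",
                 list(tol_ppm = tol_ppm, max_depth = max_depth),
                 Filter(Negate(is.null),
                        list(compound_csv = compound_csv,
                             feature_csv = feature_csv,
                             parent_csv = parent_csv)))
  invisible(out)
}
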