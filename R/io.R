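#' Write a cohort to delimited text files
#'
#' Writes one TSV per subject (T rows x N node columns, header = node ids), a
#' `manifest.csv` (`subject_id`, `path`, `group`) and, when present, the
#' planted-edge annotation as `edge_truth.csv`.
#'
#' @param cohort Cohort tibble (`subject_id`, `group`, `series`).
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$subject_id, ".tsv"))
  for (s in seq_along(paths)) {
    readr::write_tsv(tibble::as_tibble(cohort$series[[s]]), paths[s],
                     progress = FALSE)
  }
  manifest <- tibble::tibble(subject_id = cohort$subject_id,
                             path = basename(paths),
                             group = as.character(cohort$group))
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path, progress = FALSE)
  truth <- attr(cohort, "edge_truth")
  if (!is.null(truth))
    readr::write_csv(truth, file.path(dir, "edge_truth.csv"), progress = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path CSV with columns `subject_id`, `path` (relative to
#'   the manifest's directory, or absolute), `group` (values `patient` /
#'   `control`).
#' @param tr_seconds Sampling interval metadata to attach.
#' @return Cohort tibble in manifest order; all subjects are validated to
#'   share the same T and N.
#' @export
read_cohort <- function(manifest_path, tr_seconds = 2) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(manifest)))
    abort("manifest must have columns subject_id, path, group.",
          class = "dynfc_schema_error")
  bad <- setdiff(unique(manifest$group), c("patient", "control"))
  if (length(bad) > 0L)
    abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
          class = "dynfc_schema_error")
  base <- dirname(manifest_path)
  series <- lapply(seq_len(nrow(manifest)), function(s) {
    p <- manifest$path[s]
    if (!file.exists(p)) p <- file.path(base, p)
    as.matrix(readr::read_tsv(p, show_col_types = FALSE, progress = FALSE))
  })
  dims <- vapply(series, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    off <- which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])[1L]
    abort(sprintf("subject %s has dimensions %d x %d; expected %d x %d.",
                  manifest$subject_id[off], dims[1L, off], dims[2L, off],
                  dims[1L, 1L], dims[2L, 1L]),
          class = "dynfc_dimension_mismatch")
  }
  if (anyNA(unlist(series)))
    abort("time-series tables must not contain missing values.",
          class = "dynfc_schema_error")
  out <- tibble::tibble(
    subject_id = manifest$subject_id,
    group = factor(manifest$group, levels = c("control", "patient")),
    series = series
  )
  attr(out, "tr_seconds") <- tr_seconds
  truth_path <- file.path(base, "edge_truth.csv")
  if (file.exists(truth_path))
    attr(out, "edge_truth") <- readr::read_csv(truth_path,
                                               show_col_types = FALSE,
                                               progress = FALSE)
  class(out) <- c("dynfc_cohort", class(out))
  out
}

#' Read atlas labels
#'
#' @param path Delimited text file with columns `node_id`, `network` and
#'   optionally MNI coordinates `x`, `y`, `z`.
#' @return Label tibble.
#' @export
read_atlas_labels <- function(path) {
  labels <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("node_id", "network") %in% names(labels)))
    abort("atlas labels need columns node_id, network.",
          class = "dynfc_schema_error")
  labels
}

#' Write / read a connectivity matrix with sidecar metadata
#'
#' The matrix is stored as TSV with the node ids as header; a JSON sidecar
#' (`<path>.json`) records the kind, window specification and GSR flag.
#'
#' @param mat `dynfc_conn` matrix.
#' @param path Output TSV path.
#' @param window Optional [window_spec()] used to produce `mat`.
#' @param gsr Whether global-signal regression was applied upstream.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(mat, path, window = NULL, gsr = FALSE) {
  readr::write_tsv(tibble::as_tibble(unclass(mat)[, , drop = FALSE]), path,
                   progress = FALSE)
  meta <- list(kind = attr(mat, "kind") %||% "static",
               gsr = gsr, sd_denominator = "K-1")
  if (!is.null(window))
    meta$window <- list(length = window$length, step = window$step,
                        taper = window$taper)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  m <- as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                 progress = FALSE))
  rownames(m) <- colnames(m)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(m, kind = meta$kind, class = c("dynfc_conn", "matrix", "array"))
}

#' Run the complete fingerprinting pipeline
#'
#' For each requested connectivity kind: (optional global-signal regression)
#' -> connectivity -> edge features -> LOOCV classification -> metrics / ROC /
#' AUC -> optional label-permutation test -> discriminative-network anatomy.
#' Writes, per kind, a JSON report, a per-subject score TSV, a signed edge
#' CSV and a hub/fingerprint CSV.  Outputs are identical under identical
#' inputs and seed.
#'
#' @param cohort Cohort tibble, or path to a cohort manifest
#'   ([read_cohort()]).
#' @param out_dir Output directory.
#' @param kinds Connectivity kinds to run, subset of
#'   `c("dynamic", "static")`.
#' @param window [window_spec()] for the dynamic kind.
#' @param gsr Apply global-signal regression to every subject first.
#' @param cost,selection_threshold,nested,positive_class Classifier settings
#'   (see [classify_loocv()]).
#' @param n_permutations Label permutations for the significance test
#'   (0 skips it).
#' @param seed Seed for the permutation test.
#' @param atlas Atlas label tibble; defaults to [toy_atlas_labels()].
#' @param top_k Hub count for the network fingerprints.
#' @return Invisibly, a named list (per kind) with `report`
#'   (`dynfc_loocv`), `networks` and `anatomy` (per-sign hubs/fingerprints).
#' @export
run_pipeline <- function(cohort, out_dir,
                         kinds = c("dynamic", "static"),
                         window = window_spec(), gsr = FALSE,
                         cost = 1, selection_threshold = 0.01, nested = TRUE,
                         positive_class = "patient",
                         n_permutations = 0L, seed = 1L,
                         atlas = NULL, top_k = 25L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  kinds <- match.arg(kinds, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_nodes <- ncol(cohort$series[[1L]])
  if (is.null(atlas)) atlas <- toy_atlas_labels(n_nodes)

  results <- list()
  for (kind in kinds) {
    message(sprintf("[%s] connectivity (gsr=%s, taper=%s, w=%d, s=%d, sd denominator=K-1)",
                    kind, gsr, window$taper, window$length, window$step))
    conn <- compute_connectivity(cohort, kind, window, gsr)
    feats <- edge_features(conn)
    message(sprintf("[%s] LOOCV (C=%g, p<%g, %s selection)", kind, cost,
                    selection_threshold,
                    if (nested) "nested per-fold" else "pre-CV"))
    report <- classify_loocv(feats, cost, selection_threshold, nested,
                             positive_class)
    if (n_permutations > 0L) {
      message(sprintf("[%s] permutation test (B=%d, corrected estimator)",
                      kind, n_permutations))
      report <- permutation_test(feats, report, n_permutations, seed)
    }
    nets <- discriminative_networks(feats, cost, selection_threshold,
                                    positive_class)
    anatomy <- lapply(list(positive = nets$positive, negative = nets$negative),
                      function(e) {
                        if (nrow(e) == 0L) NULL
                        else node_degree_fingerprint(e, atlas, top_k)
                      })

    g <- glance(report)
    json <- list(
      kind = kind,
      parameters = list(gsr = gsr, cost = cost,
                        selection_threshold = selection_threshold,
                        nested_selection = nested,
                        window = list(length = window$length,
                                      step = window$step,
                                      taper = window$taper),
                        sd_denominator = "K-1",
                        permutation_estimator = "corrected",
                        n_permutations = n_permutations, seed = seed),
      confusion = as.list(report$confusion),
      metrics = list(accuracy = g$accuracy, sensitivity = g$sensitivity,
                     specificity = g$specificity, auc = g$auc),
      roc = report$roc,
      permutation_p = if (n_permutations > 0L) report$permutation$p else NULL,
      networks = list(n_positive = nrow(nets$positive),
                      n_negative = nrow(nets$negative),
                      n_zero = nets$n_zero),
      fingerprints = lapply(anatomy, function(a) if (is.null(a)) NULL
                            else a$fingerprint)
    )
    jsonlite::write_json(json, file.path(out_dir, sprintf("report_%s.json", kind)),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
    readr::write_tsv(tidy(report),
                     file.path(out_dir, sprintf("scores_%s.tsv", kind)),
                     progress = FALSE)
    readr::write_csv(tidy(nets),
                     file.path(out_dir, sprintf("edges_%s.csv", kind)),
                     progress = FALSE)
    hubs <- dplyr::bind_rows(lapply(names(anatomy), function(sgn) {
      a <- anatomy[[sgn]]
      if (is.null(a)) NULL else dplyr::mutate(a$hubs, sign = sgn)
    }))
    readr::write_csv(hubs, file.path(out_dir, sprintf("hubs_%s.csv", kind)),
                     progress = FALSE)
    results[[kind]] <- list(report = report, networks = nets,
                            anatomy = anatomy)
  }
  invisible(results)
}
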