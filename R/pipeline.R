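#' Write a synthetic dataset and its generating truth to disk
#'
#' Produces `data.csv` (wide person-by-item table with the group column) and
#' `truth.json` (generating trait values, per-group item parameters and
#' per-item DIF labels, labelled synthetic).
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- simulate_responses(spec)
  df <- as.data.frame(out$data)
  data_path <- file.path(dir, "data.csv")
  utils::write.csv(df, data_path, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- list(synthetic = TRUE,
                dif_labels = setNames(as.list(out$truth$dif_labels),
                                      out$data$item_ids),
                theta = out$truth$theta,
                params_by_group = lapply(out$truth$params_by_group, function(p)
                  list(a = p$a, b = apply(p$b, 1L, identity, simplify = FALSE))),
                spec = list(n_per_group = spec$n_per_group,
                            n_items = spec$n_items,
                            n_categories = spec$n_categories,
                            impact = spec$impact, trait_sd = spec$trait_sd,
                            seed = spec$seed))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, truth = truth_path))
}

#' Run the full reproduction pipeline
#'
#' Computes the three standard outputs on one dataset: the per-subgroup
#' reliability/CFA index table, the per-item DIF report from the iterative
#' hybrid analysis, and the with/without-uniform-DIF group comparison.
#' When `out_dir` is given, writes `indices.csv`, `dif_report.csv`,
#' `group_comparison.csv`, the flagged-item curves (`dif_curves.csv`) and a
#' run manifest (`manifest.json`: config snapshot, input checksums, package
#' version, seed, per-stage timings, output list).
#'
#' @param data a [response_matrix].
#' @param config a [dif_config].
#' @param out_dir optional output directory.
#' @param input_paths optional named character vector of input files to
#'   checksum into the manifest.
#' @return list with `indices`, `dif` (the [dif_olr] fit), `comparison`,
#'   `curves`, and `manifest`.
#' @export
run_full_analysis <- function(data, config = dif_config(), out_dir = NULL,
                              input_paths = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  if (!is.null(config$seed)) set.seed(config$seed)
  timing <- list()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    list(value = value, seconds = proc.time()[["elapsed"]] - t0)
  }
  st <- tic(psychometric_table(data))
  indices <- st$value; timing$psychometrics <- st$seconds
  st <- tic(dif_olr(data, config))
  fit <- st$value; timing$dif <- st$seconds
  st <- tic(compare_with_without_dif(fit))
  comparison <- st$value; timing$comparison <- st$seconds
  curves <- suppressMessages(export_dif_curves(fit))

  manifest <- list(package = "difolr",
                   version = as.character(utils::packageVersion("difolr")),
                   config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   seed = config$seed,
                   inputs = if (!is.null(input_paths))
                     as.list(tools::md5sum(input_paths)),
                   timing_seconds = timing,
                   outputs = character(0))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(indices = file.path(out_dir, "indices.csv"),
               dif_report = file.path(out_dir, "dif_report.csv"),
               comparison = file.path(out_dir, "group_comparison.csv"),
               curves = file.path(out_dir, "dif_curves.csv"),
               manifest = file.path(out_dir, "manifest.json"))
    utils::write.csv(indices, paths[["indices"]], row.names = FALSE)
    write_dif_report(fit, paths[["dif_report"]])
    utils::write.csv(comparison, paths[["comparison"]], row.names = FALSE)
    utils::write.csv(curves, paths[["curves"]], row.names = FALSE)
    manifest$outputs <- unname(paths)
    # manifest written atomically: full temp file then rename
    tmp <- paste0(paths[["manifest"]], ".tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    file.rename(tmp, paths[["manifest"]])
  }
  list(indices = indices, dif = fit, comparison = comparison,
       curves = curves, manifest = manifest)
}
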