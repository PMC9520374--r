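# End-to-end orchestration and configuration.

.PIPELINE_DEFAULTS <- list(
  features = NULL, msms = NULL, probes = NULL,
  registry = NULL, characteristic_ions = NULL,
  out_dir = NULL,
  polarity = "positive",
  ppm = 15, rt_window_s = 12, min_fragment_intensity = 100,
  similarity_threshold = 0.7, min_matched_peaks = 6,
  precursor_merge_tol_da = 0.01, fragment_tol_da = 0.02,
  max_neighbors = 50, max_component = 500, max_depth = 3,
  seed = 1
)

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default (15 ppm mass accuracy, 12 s
#' RT window, fragment intensity floor 100, similarity threshold 0.7, >= 6
#' matched fragments, 0.01 Da precursor / 0.02 Da fragment tolerance, 50
#' neighbors and 500 nodes per component, propagation depth 3) plus input
#' paths and polarity. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults (see `pathprobe:::.PIPELINE_DEFAULTS`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, over, keep.null = TRUE)
  for (k in c("ppm", "similarity_threshold", "precursor_merge_tol_da",
              "fragment_tol_da"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config '", k, "' must be positive")
  for (k in c("min_fragment_intensity", "rt_window_s"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stop("config '", k, "' must be >= 0")
  for (k in c("min_matched_peaks", "max_neighbors", "max_component", "max_depth"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1)
      stop("config '", k, "' must be >= 1")
  if (!cfg$polarity %in% c("positive", "negative"))
    stop("config 'polarity' must be 'positive' or 'negative'")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML keys mirror [pipeline_config()] arguments; explicit `overrides`
#' (e.g. from CLI flags) take precedence over the file.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals <- utils::modifyList(vals, overrides, keep.null = TRUE)
  do.call(pipeline_config, vals)
}

#' Run the full screening-and-annotation pipeline
#'
#' Executes screen -> network -> cluster filter -> annotate and writes
#' `modified.tsv`, `net.graphml`, `edges.tsv`, `clusters.tsv`,
#' `annotations.tsv` and `summary.json` to the run directory. Re-running with
#' identical inputs and config reproduces identical outputs.
#'
#' Inputs may be given as paths in the config (`features` CSV, `msms` MGF,
#' `probes` MGF, `registry` CSV) or passed directly as in-memory objects via
#' the corresponding arguments.
#'
#' @param config A `pipeline_config`.
#' @param features,spectra,probes,registry Optional in-memory inputs
#'   overriding the config paths.
#' @return Invisibly, a list with the stage outputs (`screen`, `network`,
#'   `clusters`, `evidence`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config, features = NULL, spectra = NULL,
                         probes = NULL, registry = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config 'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[pathprobe:%s] %s", stage, sprintf(...)))
  }

  if (is.null(registry))
    registry <- load_modification_registry(
      if (is.null(config$registry)) default_registry_path() else config$registry)
  if (is.null(features)) {
    if (is.null(config$features)) stop("screen: no feature table given")
    features <- read_feature_table(config$features)
  }
  if (is.null(spectra)) {
    if (is.null(config$msms)) stop("screen: no MS/MS file given")
    spectra <- read_mgf(config$msms, default_polarity = config$polarity)
  }
  if (is.null(probes)) {
    probes <- if (is.null(config$probes)) list()
              else read_mgf(config$probes, default_polarity = config$polarity)
  }
  char_ions <- if (is.null(config$characteristic_ions)) load_characteristic_ions()
               else load_characteristic_ions(config$characteristic_ions)

  # -- screen ---------------------------------------------------------------
  scr <- tryCatch(
    screen_modified_metabolome(features, spectra, registry,
                               tol_ppm = config$ppm,
                               rt_window_s = config$rt_window_s,
                               min_fragment_intensity = config$min_fragment_intensity),
    error = function(e) stop("screen: ", conditionMessage(e)))
  log_stage("screen", "%d features -> %d modified metabolites",
            nrow(features), length(scr$metabolites))
  utils::write.table(modified_metabolome_table(scr$metabolites),
                     file.path(out_dir, "modified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- network --------------------------------------------------------------
  mod_spectra <- lapply(scr$metabolites, `[[`, "spectrum")
  hits <- stats::setNames(lapply(scr$metabolites, `[[`, "hits"),
                          vapply(mod_spectra, `[[`, character(1), "id"))
  net <- tryCatch(
    build_network(mod_spectra, probes,
                  threshold = config$similarity_threshold,
                  min_matched = config$min_matched_peaks,
                  precursor_merge_tol_da = config$precursor_merge_tol_da,
                  fragment_tol_da = config$fragment_tol_da,
                  max_neighbors = config$max_neighbors,
                  max_component = config$max_component,
                  hits = hits),
    error = function(e) stop("network: ", conditionMessage(e)))
  log_stage("network", "%d nodes, %d edges, %d components",
            nrow(net$nodes), nrow(net$edges), length(unique(net$components)))

  # -- cluster filter -------------------------------------------------------
  modified_ids <- vapply(mod_spectra, `[[`, character(1), "id")
  clusters <- filter_pathway_clusters(net, modified_ids, registry)
  cluster_members <- unlist(lapply(clusters, `[[`, "members"))
  candidates <- intersect(cluster_members,
                          net$nodes$id[net$nodes$kind == "experimental"])
  log_stage("filter", "%d qualifying cluster(s), %d candidate metabolite(s)",
            length(clusters), length(candidates))
  cl_df <- do.call(rbind, lapply(clusters, function(cl) data.frame(
    component = cl$component, qualification = cl$qualification,
    n_members = length(cl$members), probes = paste(cl$probes, collapse = ";"),
    specific_modifications = paste(cl$specific_modifications, collapse = ";"),
    members = paste(cl$members, collapse = ";"), stringsAsFactors = FALSE)))
  if (is.null(cl_df))
    cl_df <- data.frame(component = character(0), qualification = character(0),
                        n_members = integer(0), probes = character(0),
                        specific_modifications = character(0),
                        members = character(0))
  utils::write.table(cl_df, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- annotate -------------------------------------------------------------
  seed_ids <- sort(net$nodes$id[net$nodes$kind == "probe"])
  evidence <- tryCatch(
    propagate(net, seed_ids, registry, tol_ppm = config$ppm,
              max_depth = config$max_depth,
              min_fragment_intensity = config$min_fragment_intensity),
    error = function(e) stop("annotate: ", conditionMessage(e)))
  names(evidence) <- vapply(evidence, `[[`, character(1), "node")
  # de-novo for qualifying seedless clusters
  for (cl in clusters) {
    has_seed <- any(cl$members %in% seed_ids)
    if (has_seed || cl$qualification != "specific-modification-only") next
    for (e in de_novo_annotate(cl, net, registry, char_ions,
                               tol_ppm = config$ppm))
      if (evidence[[e$node]]$status == "unannotated") evidence[[e$node]] <- e
  }
  # fragment-level assignments for propagated candidates
  for (id in candidates) {
    e <- evidence[[id]]
    if (e$status == "propagated" && is.null(e$fragment_assignments)) {
      e$fragment_assignments <- annotate_fragments(net$spectra[[id]], registry,
                                                   char_ions,
                                                   tol_ppm = config$ppm)
      evidence[[id]] <- e
    }
  }
  evidence <- unname(evidence)
  export_annotations(evidence, net, file.path(out_dir, "annotations.tsv"))
  write_network_graphml(net, file.path(out_dir, "net.graphml"),
                        edge_tsv = file.path(out_dir, "edges.tsv"),
                        node_attrs = annotation_table(evidence)[
                          , c("id", "status", "seed", "chain")])

  status <- vapply(evidence, `[[`, character(1), "status")
  node_id <- vapply(evidence, `[[`, character(1), "node")
  status_counts <- as.list(table(status[node_id %in% candidates]))
  summary <- list(
    n_features = nrow(features),
    n_spectra = length(spectra),
    n_modified_metabolites = length(scr$metabolites),
    n_modification_types_observed = scr$summary$n_types_observed,
    frac_multi_type = scr$summary$frac_multi_type,
    n_network_nodes = nrow(net$nodes),
    n_network_edges = nrow(net$edges),
    n_qualifying_clusters = length(clusters),
    n_candidates = length(candidates),
    annotations_by_status = status_counts,
    params = unclass(config)[setdiff(names(config),
                                     c("features", "msms", "probes", "registry",
                                       "characteristic_ions", "out_dir"))]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", "annotations: %s",
            paste(names(status_counts), unlist(status_counts),
                  sep = "=", collapse = ", "))
  invisible(list(screen = scr, network = net, clusters = clusters,
                 evidence = evidence, summary = summary, out_dir = out_dir))
}
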