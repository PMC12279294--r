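#' Pipeline configuration
#'
#' Bundles every tunable of the prepare workflow. The defaults are the
#' production operating point: truncate to the first 100 generative models,
#' cluster to 20 centers with complete linkage on H3 loop RMSD, merge with
#' the light chain, and drop assemblies with more than one backbone clash at
#' 63% of the vdW radii sum.
#'
#' @param regions a [region_definition()] or path to a YAML region config.
#' @param loop loop driving the clustering (default `"H3"`).
#' @param plddt_threshold triage threshold (default 80).
#' @param n_models ensemble truncation size (default 100).
#' @param k_clusters cluster count (default 20).
#' @param linkage linkage strategy (default `"complete"`).
#' @param clash_fraction clash threshold fraction (default 0.63).
#' @param max_clashes maximum tolerated backbone clashes (default 1).
#' @param radii element radii table.
#' @param heavy_id,light_id chain ids of the merged assembly.
#' @param atom_set backbone atoms for the loop metric.
#' @param seed seed recorded in the manifest (geometry and clustering are
#'   deterministic; the seed only governs fixture generation and shuffles).
#' @param preset `"default"` or `"af2-baseline"` (the 25-model, 5-cluster
#'   reduction used for AF2 prediction sets).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(regions = NULL, loop = "H3",
                            plddt_threshold = 80, n_models = 100,
                            k_clusters = 20, linkage = "complete",
                            clash_fraction = 0.63, max_clashes = 1,
                            radii = default_vdw_radii(),
                            heavy_id = "H", light_id = "L",
                            atom_set = BACKBONE_ATOMS, seed = 1,
                            preset = c("default", "af2-baseline")) {
  preset <- match.arg(preset)
  if (preset == "af2-baseline") {
    if (missing(n_models)) n_models <- 25
    if (missing(k_clusters)) k_clusters <- 5
  }
  if (is.character(regions)) regions <- read_region_config(regions)
  structure(
    list(regions = regions, loop = loop, plddt_threshold = plddt_threshold,
         n_models = as.integer(n_models), k_clusters = as.integer(k_clusters),
         linkage = match.arg(linkage, LINKAGES),
         clash_fraction = clash_fraction, max_clashes = max_clashes,
         radii = validate_radii(radii), heavy_id = heavy_id,
         light_id = light_id, atom_set = atom_set, seed = as.integer(seed),
         preset = preset),
    class = "pipeline_config"
  )
}

config_snapshot <- function(config) {
  list(loop = config$loop, plddt_threshold = config$plddt_threshold,
       n_models = config$n_models, k_clusters = config$k_clusters,
       linkage = config$linkage, clash_fraction = config$clash_fraction,
       max_clashes = config$max_clashes, heavy_id = config$heavy_id,
       light_id = config$light_id, atom_set = config$atom_set,
       seed = config$seed, preset = config$preset,
       radii = as.list(config$radii))
}

input_hash <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    "in-memory"
  }
}

#' Prepare a clustered, clash-filtered docking ensemble
#'
#' The end-to-end reduction workflow: truncate the heavy-chain ensemble to
#' the first `n_models` members, cluster to `k_clusters` medoid centers on
#' framework-aligned loop RMSD, merge each center with the light chain, drop
#' assemblies with more than `max_clashes` backbone clashes between the two
#' chains, and write the surviving multi-model PDB plus a manifest and TSV
#' logs. Energy minimization is an external step (the manifest records
#' `minimization: "external"`); wire the output to your docking suite's
#' refinement module.
#'
#' @param heavy_ensemble `ab_ensemble` or path to a multi-model PDB of
#'   heavy-chain models.
#' @param light_model `ab_structure` or path to the light-chain PDB.
#' @param config a [pipeline_config()]; its `regions` must be set.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `ensemble` (the surviving assemblies),
#'   `manifest`, `clash`, `clusters` and `paths`.
#' @export
run_prepare <- function(heavy_ensemble, light_model, config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config")
  }
  if (is.null(config$regions)) stop("config$regions must be set")
  heavy_hash <- input_hash(heavy_ensemble)
  light_hash <- input_hash(light_model)
  if (is.character(heavy_ensemble)) {
    heavy_ensemble <- read_ensemble(heavy_ensemble)
  }
  if (is.character(light_model)) light_model <- read_structure(light_model)
  n_input <- length(heavy_ensemble$members)
  if (n_input < config$k_clusters) {
    stop("stage reduce: ensemble size ", n_input, " < k_clusters = ",
         config$k_clusters)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n_trunc <- min(config$n_models, n_input)
  truncated <- heavy_ensemble[seq_len(n_trunc)]
  reduced <- reduce_ensemble(truncated, config$regions, config$loop,
                             k = config$k_clusters, linkage = config$linkage,
                             atom_set = config$atom_set)
  asg <- attr(reduced, "assignment")
  message("reduce: ", n_trunc, " -> ", length(reduced$members),
          " centers; cluster sizes: ", paste(asg$sizes, collapse = ", "))

  merged <- lapply(reduced$members, function(h) {
    merge_chains(h, light_model, heavy_id = config$heavy_id,
                 light_id = config$light_id)
  })
  assemblies <- new_ensemble(merged, labels = reduced$labels)
  filt <- filter_clashed(assemblies, radii = config$radii,
                         fraction = config$clash_fraction,
                         max_clashes = config$max_clashes,
                         chain_pair = c(config$heavy_id, config$light_id))
  n_kept <- sum(filt$kept)
  if (n_kept == 0L) {
    stop("stage clash-filter: no models survive max_clashes = ",
         config$max_clashes)
  }
  message("clash filter: ", length(filt$kept), " -> ", n_kept, " models")

  paths <- list(
    ensemble = file.path(out_dir, "prepared_ensemble.pdb"),
    manifest = file.path(out_dir, "manifest.json"),
    clusters = file.path(out_dir, "clusters.tsv"),
    clash = file.path(out_dir, "clash_report.tsv")
  )
  write_ensemble(filt$ensemble, paths$ensemble)

  clusters_df <- data.frame(
    member = truncated$labels,
    cluster = unname(asg$membership[truncated$labels]),
    is_center = truncated$labels %in% asg$centers,
    stringsAsFactors = FALSE
  )
  utils::write.table(clusters_df, paths$clusters, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clash_df <- data.frame(
    member = names(filt$kept),
    clash_count = vapply(filt$reports, `[[`, integer(1), "count"),
    kept = unname(filt$kept),
    stringsAsFactors = FALSE
  )
  utils::write.table(clash_df, paths$clash, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    tool = "cdrclust",
    version = as.character(utils::packageVersion("cdrclust")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_snapshot(config),
    inputs = list(heavy_ensemble = heavy_hash, light_model = light_hash),
    counts = list(input = n_input, truncated = n_trunc,
                  clustered = length(reduced$members),
                  merged = length(assemblies$members), filtered = n_kept),
    cluster_sizes = as.integer(asg$sizes),
    minimization = "external"
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(ensemble = filt$ensemble, manifest = manifest,
                 clash = clash_df, clusters = clusters_df, paths = paths))
}

#' Summarise a prepared run per model
#'
#' Collates, for every surviving model of a [run_prepare()] result: loop
#' mean pLDDT, confidence class at the configured threshold, source cluster,
#' and clash count; with a reference structure, adds framework-aligned loop
#' RMSD and reports the best-center RMSD as an attribute.
#'
#' @param prepared result of [run_prepare()].
#' @param config the [pipeline_config()] used for the run.
#' @param reference optional heavy-chain `ab_structure` to score against.
#' @return data.frame, one row per surviving model; attribute
#'   `best_center_rmsd` when `reference` is given.
#' @export
run_report <- function(prepared, config, reference = NULL) {
  ens <- prepared$ensemble
  if (is.null(ens)) stop("prepared run has no surviving ensemble")
  plddt <- vapply(ens$members, loop_mean_plddt, numeric(1),
                  regions = hchain_regions(config), loop = config$loop)
  cl <- prepared$clusters
  out <- data.frame(
    model = ens$labels,
    loop_mean_plddt = plddt,
    confidence = ifelse(plddt >= config$plddt_threshold, "confident",
                        "difficult"),
    cluster = cl$cluster[match(ens$labels, cl$member)],
    clash_count = prepared$clash$clash_count[
      match(ens$labels, prepared$clash$member)],
    stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    # assemblies carry the heavy chain as config$heavy_id; relabel the
    # reference's heavy chain to match so atom pairing lines up
    ref_chain <- if (config$regions$chain %in% chain_ids(reference)) {
      config$regions$chain
    } else {
      chain_ids(reference)[1]
    }
    ref_use <- get_chain(reference, ref_chain)
    ref_use$atoms$chain <- config$heavy_id
    out$loop_rmsd <- vapply(ens$members, function(m) {
      loop_rmsd(m, ref_use, hchain_regions(config), config$loop,
                config$atom_set)
    }, numeric(1))
    attr(out, "best_center_rmsd") <- min(out$loop_rmsd)
  }
  rownames(out) <- NULL
  out
}

# the merged assemblies carry the heavy chain under config$heavy_id; remap
# the region definition onto that chain id
hchain_regions <- function(config) {
  r <- config$regions
  region_definition(config$heavy_id, r$framework, r$loops)
}
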