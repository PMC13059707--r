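#' Assemble a pipeline run configuration
#'
#' Stage parameters default to the study's stated values: rarefaction depth
#' 28,000; prevalence threshold 0.30; network thresholds |r| > 0.5 and
#' p < 0.05; tree-cut PERMANOVA 9,999 permutations at alpha 0.001; pairwise
#' subject-stratified PERMANOVA 999 permutations; PROTEST 999 permutations.
#'
#' @param scenario a [scenario_config()] to simulate, or `NULL` when reading
#'   from files.
#' @param counts_path,metadata_path,chem_path input TSV paths, used when
#'   `scenario` is `NULL`; `chem_path` may be `NULL` (the chemistry stages
#'   are then skipped).
#' @param out_dir output directory for all artifacts.
#' @param depth,min_prevalence,r_threshold,p_threshold,tree_n_perm,
#'   tree_alpha,pairwise_n_perm,protest_n_perm stage parameters.
#' @param seed master seed; stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = NULL, counts_path = NULL,
                       metadata_path = NULL, chem_path = NULL,
                       out_dir = tempfile("guildflow_run_"),
                       depth = 28000, min_prevalence = 0.30,
                       r_threshold = 0.5, p_threshold = 0.05,
                       tree_n_perm = 9999, tree_alpha = 0.001,
                       pairwise_n_perm = 999, protest_n_perm = 999,
                       seed = 1L) {
  if (is.null(scenario) && (is.null(counts_path) || is.null(metadata_path)))
    stop("provide either a scenario or counts_path + metadata_path")
  structure(list(scenario = scenario, counts_path = counts_path,
                 metadata_path = metadata_path, chem_path = chem_path,
                 out_dir = out_dir, depth = depth,
                 min_prevalence = min_prevalence, r_threshold = r_threshold,
                 p_threshold = p_threshold, tree_n_perm = tree_n_perm,
                 tree_alpha = tree_alpha, pairwise_n_perm = pairwise_n_perm,
                 protest_n_perm = protest_n_perm, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full guild-inference pipeline
#'
#' Executes simulate/read -> rarefy -> prevalence filter -> rmcorr ->
#' network + Ward tree + sequential-PERMANOVA guilds -> ordination and
#' stratified PERMANOVA -> Procrustes -> treatment/SCFA/chemistry models,
#' writing every intermediate artifact as TSV under `config$out_dir` and a
#' JSON manifest (parameters, seeds, per-stage dimensions, file checksums)
#' sufficient to reproduce the run bit for bit.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_community(config$scenario))
    counts <- sim$counts; meta <- sim$metadata; chem <- sim$chem
    truth <- sim$truth
    write_count_table(counts, out("counts_raw.tsv"))
    write_metadata(meta, out("metadata.tsv"))
    write_chem(chem, out("chem.tsv"))
    write_guild_assignment(truth$feature_guild, out("true_guilds.tsv"))
  } else {
    counts <- stage("read", read_count_table(config$counts_path))
    meta <- stage("read", validate_metadata(read_metadata(config$metadata_path),
                                            counts))
    chem <- if (is.null(config$chem_path)) NULL
            else stage("read", validate_chem(read_chem(config$chem_path), counts))
    if (is.null(chem))
      message("no chemistry table provided: SCFA/pH stages will be skipped")
  }

  rare <- stage("rarefy", rarefy(counts, depth = config$depth,
                                 seed = config$seed + 1L))
  prev <- stage("prevalence_filter",
                prevalence_filter(rare, min_prevalence = config$min_prevalence))
  write_count_table(prev, out("counts_prevalent.tsv"))
  rel_all <- to_relative(rare)
  rel <- to_relative(prev)
  logrel <- log_transform(rel)

  meta_r <- meta[match(rownames(rare), meta$sample_id), ]
  rm <- stage("rmcorr", rmcorr_matrix(logrel, subject = meta_r$donor))
  write_rmcorr(rm, out("rmcorr.tsv"))

  net <- stage("network", build_network(rm, rel,
                                        r_threshold = config$r_threshold,
                                        p_threshold = config$p_threshold))
  write_network(net, out("network_edges.tsv"), out("network.graphml"))
  dmat <- correlation_distance(rm)
  tree <- stage("ward_tree", ward_tree(dmat))
  write_tree_newick(tree, out("tree.nwk"))
  ga <- stage("tree_cut",
              cut_tree_permanova(tree, dmat, n_perm = config$tree_n_perm,
                                 alpha = config$tree_alpha,
                                 seed = config$seed + 100L, abund = rel))
  write_guild_assignment(ga, out("guild_assignment.tsv"))
  gt <- stage("aggregate", aggregate_guilds(rel, ga))
  utils::write.table(data.frame(sample_id = rownames(gt), gt,
                                check.names = FALSE),
                     out("guild_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  d_asv <- bray_curtis(rel_all)
  d_cag <- bray_curtis(gt)
  ord_asv <- stage("apcoa", apcoa(d_asv, meta_r$donor))
  ord_cag <- stage("apcoa", apcoa(d_cag, meta_r$donor))
  write_ordination(ord_asv, out("apcoa_asv.tsv"))
  write_ordination(ord_cag, out("apcoa_cag.tsv"))
  pw <- stage("pairwise_permanova",
              pairwise_permanova(d_cag, meta_r$treatment,
                                 n_perm = config$pairwise_n_perm,
                                 strata = meta_r$donor,
                                 seed = config$seed + 200L))
  utils::write.table(pw, out("pairwise_permanova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pro <- stage("procrustes",
               procrustes_protest(ord_asv, ord_cag,
                                  n_perm = config$protest_n_perm,
                                  seed = config$seed + 300L))

  assoc_trt <- stage("guild_treatment", fit_guild_treatment(gt, meta))
  utils::write.table(assoc_trt, out("association_treatment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  assoc_scfa <- NULL; chem_tests <- NULL
  if (!is.null(chem)) {
    assoc_scfa <- stage("guild_scfa", fit_guild_scfa(gt, chem, meta))
    utils::write.table(assoc_scfa, out("association_scfa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    chem_tests <- do.call(rbind, lapply(
      c("pH", "acetate", "propionate", "butyrate"), function(v) {
        ct <- stage("chem_treatment", fit_chem_treatment(chem, meta, v))
        cbind(response = v, ct)
      }))
    utils::write.table(chem_tests, out("chem_contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  files <- list.files(config$out_dir, pattern = "\\.(tsv|nwk|graphml)$",
                      full.names = TRUE)
  manifest <- list(
    parameters = config[setdiff(names(config),
                                c("scenario", "counts_path", "metadata_path",
                                  "chem_path", "out_dir"))],
    simulated = !is.null(config$scenario),
    n_samples_input = nrow(counts),
    n_features_input = ncol(counts),
    n_samples_rarefied = nrow(rare),
    dropped_samples = attr(rare, "dropped_samples"),
    n_features_prevalent = ncol(prev),
    prevalence_coverage = attr(prev, "coverage"),
    n_network_edges = nrow(net$edges),
    n_guilds = length(unique(ga$assignment)),
    procrustes = list(m2 = pro$m2, correlation = pro$correlation, p = pro$p),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, counts = counts, metadata = meta,
                 chem = chem, truth = truth, rarefied = rare,
                 prevalent = prev, rel = rel, rmcorr = rm, network = net,
                 tree = tree, guilds = ga, guild_table = gt,
                 ordination_asv = ord_asv, ordination_cag = ord_cag,
                 pairwise = pw, procrustes = pro,
                 association_treatment = assoc_trt,
                 association_scfa = assoc_scfa, chem_contrasts = chem_tests))
}
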