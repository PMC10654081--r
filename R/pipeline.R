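#' Build and validate a pipeline run configuration
#'
#' Exactly one of `paths` (input files: `table`, `tree`, `taxonomy`,
#' `metadata`) or `scenario` (a [scenario_config()]) must be supplied.
#' Stage parameters default to the package-wide defaults.
#'
#' @param paths named list of input file paths, or `NULL`.
#' @param scenario `scenario_config`, or `NULL`.
#' @param out_dir output directory (created if absent).
#' @param stages character subset of
#'   `c("diversity", "assembly", "network", "biomarkers")`.
#' @param params named list of per-stage parameter overrides
#'   (`rarefy_depth`, `n_null`, `rho_threshold`, `alpha`,
#'   `robustness_step`, `robustness_reps`, `cv_folds`, `cv_repeats`,
#'   `lda_threshold`, `n_perm`).
#' @param seed integer seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(paths = NULL, scenario = NULL, out_dir = "pitmudr_out",
                       stages = c("diversity", "assembly", "network",
                                  "biomarkers"),
                       params = list(), seed = 1L) {
  if (is.null(paths) == is.null(scenario))
    stop("exactly one of `paths` or `scenario` must be given")
  if (!is.null(paths)) {
    need <- c("table", "tree", "taxonomy", "metadata")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths missing: ", paste(miss, collapse = ", "))
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent)) stop("input file(s) not found: ",
                             paste(absent, collapse = ", "))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  defaults <- list(rarefy_depth = 10000, n_null = 999, rho_threshold = 0.7,
                   alpha = 0.01, min_prevalence = 0.2, min_mean_ra = 1e-4,
                   robustness_step = 0.05, robustness_reps = 100,
                   cv_folds = 10, cv_repeats = 5, n_trees = 500,
                   lda_threshold = 4, lefse_alpha = 0.05, n_boot = 30,
                   n_perm = 999)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(paths = paths, scenario = scenario, out_dir = out_dir,
                 stages = stages, params = defaults, seed = seed),
            class = "run_config")
}

#' Read a YAML run configuration file
#'
#' Flat key-value file with optional `paths:`, `scenario:` and `params:`
#' sections mirroring the [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen <- if (!is.null(y$scenario)) do.call(scenario_config, y$scenario)
  run_config(paths = y$paths, scenario = scen,
             out_dir = y$out_dir %||% "pitmudr_out",
             stages = y$stages %||% c("diversity", "assembly", "network",
                                      "biomarkers"),
             params = y$params %||% list(), seed = y$seed %||% 1L)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (ingest/simulate, rarefy, diversity, assembly, network, biomarkers),
#' writes every artifact as TSV/GraphML/JSON under the configured output
#' directory, and returns (and writes) a manifest listing each output with
#' the parameters and seed. Identical config and seed give byte-identical
#' tabular outputs.
#'
#' @param config `run_config`.
#' @param dry_run validate and plan only; write nothing.
#' @return manifest list (invisibly the same content as `manifest.json`).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  if (dry_run) {
    .log_stage("plan", "stages:", paste(config$stages, collapse = ", "))
    return(invisible(list(stages = config$stages, params = p,
                          seed = config$seed, dry_run = TRUE)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  emit <- function(name) files <<- c(files, name)

  if (!is.null(config$scenario)) {
    .log_stage("simulate", "seed", config$scenario$seed)
    tree <- simulate_tree(config$scenario)
    sim <- simulate_communities(tree, config$scenario)
    table <- sim$table; frame <- sim$frame
    taxonomy <- simulate_taxonomy(tree)
    write_community(table, out("otu_table.tsv"));        emit("otu_table.tsv")
    ape::write.tree(tree, out("tree.nwk"));              emit("tree.nwk")
    write.table(taxonomy, out("taxonomy.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE);                      emit("taxonomy.tsv")
    write.table(frame, out("metadata.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE);                      emit("metadata.tsv")
    jsonlite::write_json(list(regimes = as.list(sim$truth$regimes),
                              clades = sim$truth$clades),
                         out("ground_truth.json"), auto_unbox = TRUE)
    emit("ground_truth.json")
  } else {
    .log_stage("ingest", config$paths$table)
    table <- read_community(config$paths$table)
    tree <- ape::read.tree(config$paths$tree)
    taxonomy <- read_taxonomy(config$paths$taxonomy)
    frame <- read_sample_frame(config$paths$metadata, table)
  }

  .log_stage("rarefy", "depth", p$rarefy_depth)
  rar <- rarefy(table, depth = min(p$rarefy_depth, min(colSums(table$counts))),
                seed = config$seed)
  frame <- frame[frame$sample_id %in% sample_ids(rar), , drop = FALSE]
  rel <- to_relative(rar)

  if ("diversity" %in% config$stages) {
    .log_stage("diversity")
    alpha <- alpha_indices(rar)
    write.table(alpha, out("alpha.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("alpha.tsv")
    bc <- bray_curtis(rel)
    write_pairwise(bc, out("bray_curtis.tsv")); emit("bray_curtis.tsv")
    mt <- match_tree(rel, tree)
    wu <- weighted_unifrac(mt$table, mt$tree)
    write_pairwise(wu, out("weighted_unifrac.tsv")); emit("weighted_unifrac.tsv")
    ord <- nmds(wu, seed = config$seed)
    nm <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates)
    write.table(nm, out("nmds.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("nmds.tsv")
    jsonlite::write_json(list(stress = ord$stress), out("nmds_stress.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("nmds_stress.json")
    pm <- permanova(wu, frame, n_perm = p$n_perm, seed = config$seed)
    write.table(pm, out("permanova.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("permanova.tsv")
  }

  if ("assembly" %in% config$stages) {
    .log_stage("assembly", "n_null", p$n_null)
    mt <- match_tree(rel, tree)
    bn <- beta_nti(mt$table, mt$tree, n_null = p$n_null, seed = config$seed,
                   frame = frame)
    write.table(bn, out("beta_nti_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("beta_nti_pairs.tsv")
    fr <- assembly_fractions(bn)
    write.table(fr, out("assembly_fractions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("assembly_fractions.tsv")
  }

  if ("network" %in% config$stages) {
    for (g in levels(droplevels(frame$age_group))) {
      sub <- frame$sample_id[frame$age_group == g]
      if (length(sub) < 5) next
      .log_stage("network", g)
      tab_g <- community_table(rel$counts[, sub, drop = FALSE],
                               is_relative = TRUE)
      filt <- filter_prevalence(tab_g, p$min_prevalence, p$min_mean_ra)
      edges <- correlation_screen(filt, p$rho_threshold, p$alpha)
      net <- build_network(edges, table = filt, taxonomy = taxonomy)
      if (igraph::ecount(net) == 0) next
      write_network(net, out(sprintf("network_%s.graphml", g)),
                    out(sprintf("network_%s_edges.tsv", g)))
      emit(sprintf("network_%s.graphml", g))
      emit(sprintf("network_%s_edges.tsv", g))
      topo <- topology(net, seed = config$seed)
      write.table(topo, out(sprintf("topology_%s.tsv", g)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(sprintf("topology_%s.tsv", g))
      if (igraph::vcount(net) >= 5) {
        rb <- robustness(net, step = p$robustness_step,
                         n_reps = p$robustness_reps, seed = config$seed)
        write.table(data.frame(removal_fraction = rb$removal_fractions,
                               mean_remaining = rb$mean, sd = rb$sd),
                    out(sprintf("robustness_%s.tsv", g)), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit(sprintf("robustness_%s.tsv", g))
      }
    }
  }

  if ("biomarkers" %in% config$stages) {
    .log_stage("biomarkers")
    filt <- filter_prevalence(rel, p$min_prevalence, p$min_mean_ra)
    rf <- rf_select(filt, frame, n_trees = p$n_trees, folds = p$cv_folds,
                    repeats = p$cv_repeats, seed = config$seed)
    write.table(rf$cv_error_curve, out("rf_cv_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE); emit("rf_cv_curve.tsv")
    write.table(data.frame(taxon = names(rf$importances),
                           importance = rf$importances,
                           selected = names(rf$importances) %in%
                             rf$selected_taxa),
                out("rf_importances.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("rf_importances.tsv")
    genus <- aggregate_taxa(rel, taxonomy, "genus")
    lf <- lefse(genus, frame, alpha = p$lefse_alpha,
                lda_threshold = p$lda_threshold, n_boot = p$n_boot,
                seed = config$seed)
    write.table(lf, out("lefse.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE); emit("lefse.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pitmudr")),
    seed = config$seed, stages = config$stages, params = p,
    outputs = lapply(files, function(f)
      list(file = f, md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  .log_stage("done", length(files), "artifact(s)")
  invisible(manifest)
}
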