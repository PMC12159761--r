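#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a list. Fills defaults (rarefaction depth
#' 34,234; network thresholds `|rho| > 0.8`, `p_adj < 0.05`; stage seeds),
#' checks that every referenced input file exists, and returns a
#' normalised config that [run_pipeline()] (and a second
#' `validate_config()` call) accepts unchanged.
#'
#' @param config YAML path or list.
#' @return object of class `pipeline_config` (a normalised list).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  if (!is.list(config)) stop("config must be a YAML file or a list")

  defaults <- list(
    table = NULL, metadata = NULL, tree = NULL, plspm_spec = NULL,
    out_dir = "micronetstab_out",
    rarefy_depth = 34234L,
    rho_min = 0.8, alpha = 0.05,
    min_prevalence = 0, min_mean_relabund = 0,
    group_col = "group", groups = NULL,
    n_permutations = 999L,
    n_null = 200L, n_repetitions = 100L,
    pooled_network = FALSE,
    n_boot = 200L,
    seed = 7L,
    simulate = NULL,
    stages = c("diversity", "network", "stability")
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(config)) cfg[nm] <- list(config[[nm]])  # keeps NULLs
  cfg$stages <- unlist(cfg$stages)

  if (is.null(cfg$simulate)) {
    for (f in c("table", "metadata")) {
      if (is.null(cfg[[f]])) stop("config field '", f, "' is required (or set 'simulate')")
      if (!file.exists(cfg[[f]])) stop("config field '", f, "': no such file ", cfg[[f]])
    }
    for (f in c("tree", "plspm_spec"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("config field '", f, "': no such file ", cfg[[f]])
  }
  cfg$rarefy_depth <- as.integer(cfg$rarefy_depth)
  if (cfg$rarefy_depth < 1L) stop("rarefy_depth must be positive")
  if (cfg$rho_min <= 0 || cfg$rho_min >= 1) stop("rho_min must lie in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  cfg$seed <- as.integer(cfg$seed)
  cfg$stages <- match.arg(cfg$stages,
                          c("diversity", "network", "stability", "plspm"),
                          several.ok = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Read a PLS-PM model specification from YAML
#'
#' Expects keys `blocks` (latent -> manifest list), `paths` (list of
#' `from`/`to` pairs), and optionally `modes` and `scheme`.
#'
#' @param path YAML file.
#' @return a [plspm_spec()].
#' @export
read_plspm_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$blocks) || is.null(y$paths))
    stop("PLS-PM spec needs 'blocks' and 'paths'")
  blocks <- lapply(y$blocks, as.character)
  lat <- names(blocks)
  P <- matrix(FALSE, length(lat), length(lat), dimnames = list(lat, lat))
  for (p in y$paths) {
    if (!all(c(p$from, p$to) %in% lat))
      stop("path references unknown latent: ", p$from, " -> ", p$to)
    P[p$to, p$from] <- TRUE
  }
  plspm_spec(blocks, P,
             modes = if (is.null(y$modes)) "A" else unlist(y$modes),
             scheme = if (is.null(y$scheme)) "path" else y$scheme)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, then diversity, network, stability and
#' PLS-PM stages, writing every stage's outputs under `out_dir` and a JSON
#' run manifest recording parameters, seeds and output paths. Reruns with
#' the same config produce identical numeric outputs.
#'
#' @param config a [validate_config()]-acceptable config.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "micronetstab",
                   parameters = unclass(cfg)[c("rarefy_depth", "rho_min",
                                               "alpha", "n_permutations",
                                               "n_null", "n_repetitions",
                                               "seed")],
                   stages = list())
  outp <- function(...) file.path(cfg$out_dir, paste0(...))

  if (!is.null(cfg$simulate)) {
    sim <- .stage("simulate", {
      sc <- do.call(synth_config, cfg$simulate)
      com <- generate_community(sc)
      md <- generate_metadata(sc, com$truth, com$metadata_groups)
      md$sample_id <- colnames(com$table)
      tr <- generate_tree(rownames(com$table), seed = sc$seed)
      write_asv_table(com$table, outp("table.tsv"))
      write_metadata(md, outp("metadata.tsv"))
      ape::write.tree(tr, outp("tree.nwk"))
      write_results(list(module_assignment = as.list(com$truth$module_assignment),
                         effect_logfc = com$truth$effect_logfc,
                         true_paths = com$truth$true_paths),
                    outp("ground_truth.json"), format = "json")
      list(table = com$table, metadata = md, tree = tr)
    })
    counts <- sim$table; metadata <- sim$metadata; tree <- sim$tree
    manifest$stages$simulate <- list(outputs = c("table.tsv", "metadata.tsv",
                                                 "tree.nwk", "ground_truth.json"))
  } else {
    counts <- .stage("load", read_asv_table(cfg$table))
    metadata <- .stage("load", read_metadata(cfg$metadata,
                                             group_col = cfg$group_col))
    metadata <- .stage("load", match_metadata(counts, metadata))
    tree <- if (!is.null(cfg$tree)) .stage("load", read_tree(cfg$tree)) else NULL
  }
  groups <- droplevels(factor(metadata$group))

  rar <- .stage("diversity", {
    depth <- min(cfg$rarefy_depth, min(colSums(counts)))
    rarefy_counts(counts, depth, seed = cfg$seed)
  })

  if ("diversity" %in% cfg$stages) {
    .stage("diversity", {
      alpha <- alpha_diversity(rar, tree)
      write_results(alpha, outp("alpha_diversity.tsv"), "tsv")
      dm <- bray_curtis(rar)
      ord <- pcoa(dm)
      coords <- data.frame(sample_id = rownames(ord$points), ord$points,
                           stringsAsFactors = FALSE)
      write_results(coords, outp("pcoa_coordinates.tsv"), "tsv")
      pm <- permanova(dm, groups, n_permutations = cfg$n_permutations,
                      seed = cfg$seed)
      pw <- pairwise_permanova(dm, groups,
                               n_permutations = cfg$n_permutations,
                               seed = cfg$seed)
      write_results(list(overall = unclass(pm)[c("pseudo_F", "R2", "p_value",
                                                 "n_permutations", "seed")],
                         pairwise = pw,
                         proportion_explained = ord$proportion_explained),
                    outp("beta_diversity.json"), "json")
      manifest$stages$diversity <- list(
        depth = min(cfg$rarefy_depth, min(colSums(counts))),
        outputs = c("alpha_diversity.tsv", "pcoa_coordinates.tsv",
                    "beta_diversity.json"))
    })
  }

  nets <- NULL
  if (any(c("network", "stability") %in% cfg$stages)) {
    nets <- .stage("network", {
      split_samples <- if (cfg$pooled_network) list(pooled = colnames(rar))
        else split(colnames(rar), groups)
      metrics <- list()
      nl <- list()
      for (gname in names(split_samples)) {
        sub <- rar[, split_samples[[gname]], drop = FALSE]
        sub <- filter_taxa(sub, cfg$min_prevalence, cfg$min_mean_relabund)
        corr <- spearman_matrix(sub)
        rel <- sweep(sub, 2, colSums(sub), "/")
        net <- build_network(corr, rho_min = cfg$rho_min, alpha = cfg$alpha,
                             abundances = rowMeans(rel))
        write_network(net, outp("network_", gname, ".graphml"), "graphml")
        write_network(net, outp("network_", gname, ".edges.tsv"), "edgelist")
        if (igraph::vcount(net$graph) > 0) {
          tm <- topology(net, community_seed = cfg$seed)
          metrics[[gname]] <- data.frame(network = gname,
                                         as.data.frame(tm),
                                         stringsAsFactors = FALSE)
        }
        nl[[gname]] <- list(net = net, table = sub)
      }
      if (length(metrics))
        write_results(do.call(rbind, metrics), outp("topology_metrics.tsv"), "tsv")
      manifest$stages$network <- list(
        networks = names(split_samples),
        outputs = c(paste0("network_", names(split_samples), ".graphml"),
                    "topology_metrics.tsv"))
      nl
    })
  }

  if ("stability" %in% cfg$stages) {
    .stage("stability", {
      report <- list()
      coh_rows <- list()
      for (gname in names(nets)) {
        tab <- nets[[gname]]$table
        net <- nets[[gname]]$net
        coh <- cohesion(tab, null_model = "taxa_shuffle",
                        n_null = cfg$n_null, seed = cfg$seed)
        sr <- stability_ratio(coh)
        coh_rows[[gname]] <- data.frame(network = gname, coh$samples,
                                        ratio = sr$samples$ratio,
                                        stringsAsFactors = FALSE)
        entry <- list(stability_ratio_mean = sr$mean,
                      stability_ratio_se = sr$se)
        if (igraph::vcount(net$graph) >= 3 && igraph::ecount(net$graph) > 0) {
          rb_r <- robustness(net, "random", n_repetitions = cfg$n_repetitions,
                             seed = cfg$seed)
          rb_t <- robustness(net, "degree", n_repetitions = cfg$n_repetitions,
                             seed = cfg$seed)
          write_results(data.frame(network = gname, strategy = "random",
                                   rb_r$curve),
                        outp("robustness_", gname, "_random.tsv"), "tsv")
          write_results(data.frame(network = gname, strategy = "degree",
                                   rb_t$curve),
                        outp("robustness_", gname, "_degree.tsv"), "tsv")
          vul <- vulnerability(net)
          entry <- c(entry, list(robustness_random_half = rb_r$at_half,
                                 robustness_targeted_half = rb_t$at_half,
                                 vulnerability = vul$vulnerability,
                                 complexity = complexity(net)))
        }
        report[[gname]] <- entry
      }
      write_results(do.call(rbind, coh_rows), outp("cohesion.tsv"), "tsv")
      write_results(report, outp("stability_report.json"), "json")
      manifest$stages$stability <- list(
        outputs = c("cohesion.tsv", "stability_report.json"))
    })
  }

  if ("plspm" %in% cfg$stages) {
    .stage("plspm", {
      if (is.null(cfg$plspm_spec))
        stop("plspm stage requires config field 'plspm_spec'")
      spec <- read_plspm_spec(cfg$plspm_spec)
      model <- fit_plspm(metadata, spec)
      paths <- bootstrap_paths(model, metadata, spec, n_boot = cfg$n_boot,
                               seed = cfg$seed)
      write_results(paths, outp("plspm_paths.tsv"), "tsv")
      write_results(list(gof = model$gof, r_squared = as.list(model$r_squared),
                         iterations = model$iterations, n = model$n),
                    outp("plspm_model.json"), "json")
      manifest$stages$plspm <- list(
        outputs = c("plspm_paths.tsv", "plspm_model.json"))
    })
  }

  write_results(manifest, outp("manifest.json"), "json")
  invisible(manifest)
}
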