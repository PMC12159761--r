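#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the generative model behind [generate_community()],
#' [generate_metadata()] and [generate_tree()]. The defaults emulate a
#' three-treatment field trial (control, conventional film residue,
#' biodegradable film residue) with six replicate plots per treatment and
#' sequencing depths comfortably above a 34,234-read rarefaction depth.
#'
#' Counts are generated as log-normal relative abundances with a planted
#' block-correlation structure on latent Gaussian factors, multiplied by
#' treatment effects for a random subset of taxa, then sampled as negative
#' binomial draws at a sample-specific library size. Correlation is imposed
#' on the latent scale because rank correlations survive the monotone
#' exponential map, so planted modules remain recoverable by Spearman-based
#' network inference.
#'
#' @param n_taxa number of taxa (ASVs). The field study scale (~6,268 ASVs)
#'   is a valid but slow configuration; desk-scale defaults are smaller.
#' @param n_samples_per_group replicates per treatment group.
#' @param groups ordered character vector of treatment labels; the first is
#'   the reference (no treatment effect).
#' @param n_modules number of planted correlation blocks.
#' @param rho_in latent within-module correlation, in `[0, 1)`.
#' @param rho_out latent between-module correlation, in `[0, rho_in]`.
#' @param depth_mean,depth_cv mean and coefficient of variation of the
#'   log-normal library-size distribution.
#' @param dispersion negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson sampling.
#' @param effect_taxa_frac fraction of taxa given a treatment shift in each
#'   non-reference group.
#' @param effect_logfc magnitude of the treatment log-fold-change (natural
#'   log); signs are randomised per taxon.
#' @param base_sd standard deviation of taxon baseline log-abundances
#'   (controls rank-abundance skew).
#' @param latent_sd scale of the block-structured latent factor on the log
#'   abundance (controls how strongly modules correlate in counts).
#' @param path_coefficients lower-triangular matrix of true inner-model
#'   coefficients among the latent variables `treatment`, `soil`,
#'   `community`, `plant`; see [default_true_paths()].
#' @param meta_noise_sd measurement noise added to each metadata manifest on
#'   top of its latent score.
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_taxa = 150,
                         n_samples_per_group = 6,
                         groups = c("CK", "M", "bioM"),
                         n_modules = 4,
                         rho_in = 0.7,
                         rho_out = 0.2,
                         depth_mean = 5e4,
                         depth_cv = 0.3,
                         dispersion = 0.5,
                         effect_taxa_frac = 0.2,
                         effect_logfc = 1,
                         base_sd = 1.5,
                         latent_sd = 1,
                         path_coefficients = default_true_paths(),
                         meta_noise_sd = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_taxa = as.integer(n_taxa),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = as.character(groups),
    n_modules = as.integer(n_modules),
    rho_in = rho_in, rho_out = rho_out,
    depth_mean = depth_mean, depth_cv = depth_cv,
    dispersion = dispersion,
    effect_taxa_frac = effect_taxa_frac,
    effect_logfc = effect_logfc,
    base_sd = base_sd, latent_sd = latent_sd,
    path_coefficients = path_coefficients,
    meta_noise_sd = meta_noise_sd,
    seed = as.integer(seed)
  )
  nums <- unlist(cfg[c("rho_in", "rho_out", "depth_mean", "depth_cv",
                       "dispersion", "effect_taxa_frac", "effect_logfc",
                       "base_sd", "latent_sd", "meta_noise_sd")])
  if (any(!is.finite(nums)))
    stop("synth_config: all numeric parameters must be finite")
  if (cfg$n_taxa < 1L || cfg$n_samples_per_group < 1L || cfg$n_modules < 1L)
    stop("synth_config: n_taxa, n_samples_per_group and n_modules must be positive")
  if (cfg$n_taxa < cfg$n_modules)
    stop("synth_config: n_taxa must be >= n_modules")
  if (cfg$rho_in < 0 || cfg$rho_in >= 1)
    stop("synth_config: rho_in must lie in [0, 1)")
  if (cfg$rho_out < 0 || cfg$rho_out > cfg$rho_in)
    stop("synth_config: rho_out must lie in [0, rho_in]")
  if (cfg$effect_taxa_frac < 0 || cfg$effect_taxa_frac > 1)
    stop("synth_config: effect_taxa_frac must lie in [0, 1]")
  if (cfg$dispersion < 0) stop("synth_config: dispersion must be >= 0")
  if (anyDuplicated(cfg$groups)) stop("synth_config: duplicate group labels")
  if (!is.matrix(path_coefficients) ||
      nrow(path_coefficients) != ncol(path_coefficients))
    stop("synth_config: path_coefficients must be a square matrix")
  if (any(path_coefficients[upper.tri(path_coefficients, diag = TRUE)] != 0))
    stop("synth_config: path_coefficients must be strictly lower-triangular (acyclic)")
  class(cfg) <- "synth_config"
  cfg
}

#' Default true inner-model path coefficients
#'
#' A lower-triangular (acyclic) coefficient matrix among four latent
#' variables: the treatment score, a soil-property latent, a community
#' structure latent, and a plant-performance latent. Entry `[j, k]` is the
#' coefficient of latent `k` in the structural equation of latent `j`.
#'
#' @return a 4x4 named numeric matrix.
#' @export
default_true_paths <- function() {
  lat <- c("treatment", "soil", "community", "plant")
  P <- matrix(0, 4, 4, dimnames = list(lat, lat))
  P["soil", "treatment"] <- 0.6
  P["community", "treatment"] <- 0.5
  P["community", "soil"] <- 0.4
  P["plant", "soil"] <- 0.4
  P["plant", "community"] <- 0.5
  P
}

#' Generate a synthetic ASV count table with planted structure
#'
#' Draws per-sample latent Gaussian factors with block correlation
#' (`rho_in` within planted modules, `rho_out` between), exponentiates the
#' taxon-level latent log-abundances to relative abundances, multiplies in
#' treatment effects for a random subset of taxa in each non-reference
#' group, and samples negative-binomial counts at log-normally distributed
#' library sizes. Zero inflation arises naturally from the sampling model.
#'
#' @param config a [synth_config()].
#' @return a list with components:
#'   \describe{
#'     \item{table}{integer count matrix, taxa x samples, with taxon and
#'       sample identifiers as dimnames.}
#'     \item{metadata_groups}{factor of treatment labels per sample.}
#'     \item{truth}{ground truth: `module_assignment` (named integer vector,
#'       one module per taxon), `effect_logfc` (list per non-reference group
#'       of named signed log-fold-changes), `true_paths` (the inner-model
#'       coefficient matrix).}
#'   }
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nt <- config$n_taxa
  ng <- length(config$groups)
  n <- ng * config$n_samples_per_group

  taxa <- sprintf("ASV_%04d", seq_len(nt))
  grp <- factor(rep(config$groups, each = config$n_samples_per_group),
                levels = config$groups)
  samples <- paste0(rep(config$groups, each = config$n_samples_per_group),
                    "_", rep(seq_len(config$n_samples_per_group), ng))

  module <- rep(seq_len(config$n_modules), length.out = nt)
  module <- sort(module)
  names(module) <- taxa

  # block-correlated latent factors: shared + module + idiosyncratic
  g_fac <- rnorm(n)
  m_fac <- matrix(rnorm(config$n_modules * n), config$n_modules, n)
  eps <- matrix(rnorm(nt * n), nt, n)
  z <- sqrt(config$rho_out) * matrix(g_fac, nt, n, byrow = TRUE) +
    sqrt(config$rho_in - config$rho_out) * m_fac[module, , drop = FALSE] +
    sqrt(1 - config$rho_in) * eps

  mu <- rnorm(nt, 0, config$base_sd)
  logab <- mu + config$latent_sd * z

  n_eff <- ceiling(config$effect_taxa_frac * nt)
  effects <- list()
  if (ng > 1) {
    for (gl in config$groups[-1]) {
      idx <- sample.int(nt, n_eff)
      lfc <- sample(c(-1, 1), n_eff, replace = TRUE) * config$effect_logfc
      names(lfc) <- taxa[idx]
      effects[[gl]] <- lfc
      logab[idx, grp == gl] <- logab[idx, grp == gl] + lfc
    }
  }

  rel <- exp(logab)
  rel <- sweep(rel, 2, colSums(rel), "/")

  sdlog <- sqrt(log(1 + config$depth_cv^2))
  meanlog <- log(config$depth_mean) - sdlog^2 / 2
  depth <- round(rlnorm(n, meanlog, sdlog))

  mu_counts <- sweep(rel, 2, depth, "*")
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  counts <- matrix(rnbinom(nt * n, mu = as.vector(mu_counts), size = size),
                   nt, n, dimnames = list(taxa, samples))
  storage.mode(counts) <- "integer"

  list(
    table = counts,
    metadata_groups = grp,
    truth = list(module_assignment = module,
                 effect_logfc = effects,
                 true_paths = config$path_coefficients)
  )
}

#' Generate sample metadata from a known path model
#'
#' Latent scores are built recursively along the acyclic `true_paths`
#' matrix: the treatment latent is the standardised numeric treatment
#' score, and each downstream latent is the coefficient-weighted sum of its
#' predecessors plus Gaussian noise calibrated so each latent has unit
#' variance (hence coefficients are standardised path coefficients).
#' Manifest columns are latent scores plus `meta_noise_sd` measurement
#' noise: nine soil covariates (pH, SMC, NH4, NO3, IN, DOC, DON, TC, TN)
#' from the soil latent, two community-structure summaries from the
#' community latent, and biomass/yield from the plant latent.
#'
#' @param config a [synth_config()].
#' @param truth the `truth` component returned by [generate_community()]
#'   (supplies `true_paths`); may be `NULL` to use the config's matrix.
#' @param groups optional factor of per-sample treatments; defaults to the
#'   design implied by `config`.
#' @return a `data.frame` with `sample_id`, `group`, the latent treatment
#'   score and the manifest columns described above.
#' @export
generate_metadata <- function(config, truth = NULL, groups = NULL) {
  stopifnot(inherits(config, "synth_config"))
  paths <- if (is.null(truth)) config$path_coefficients else truth$true_paths
  if (is.null(groups)) {
    groups <- factor(rep(config$groups, each = config$n_samples_per_group),
                     levels = config$groups)
  }
  n <- length(groups)
  if (n < 2L) stop("generate_metadata: need at least 2 samples")
  set.seed(config$seed + 1L)

  lat_names <- rownames(paths)
  L <- matrix(0, n, length(lat_names), dimnames = list(NULL, lat_names))
  trt <- as.numeric(groups)
  L[, 1] <- as.vector(scale(trt))
  for (j in seq_along(lat_names)[-1]) {
    b <- paths[j, seq_len(j - 1)]
    eta <- L[, seq_len(j - 1), drop = FALSE] %*% b
    resid_sd <- sqrt(max(0, 1 - stats::var(as.vector(eta))))
    L[, j] <- eta + rnorm(n, 0, resid_sd)
  }

  manifest <- function(latent, cols) {
    m <- sapply(seq_along(cols), function(i)
      L[, latent] + rnorm(n, 0, config$meta_noise_sd))
    colnames(m) <- cols
    m
  }
  blocks <- list(soil = c("pH", "SMC", "NH4", "NO3", "IN", "DOC", "DON",
                          "TC", "TN"),
                 community = c("comm_axis1", "comm_axis2"),
                 plant = c("biomass", "yield"))
  blocks <- blocks[intersect(names(blocks), lat_names)]
  mans <- do.call(cbind, lapply(names(blocks),
                                function(b) manifest(b, blocks[[b]])))

  sample_ids <- paste0(as.character(groups), "_",
                       stats::ave(seq_len(n), groups, FUN = seq_along))
  out <- data.frame(sample_id = sample_ids,
                    group = groups,
                    treatment = L[, "treatment"],
                    mans,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(out[, -(1:2)]))))
    stop("generate_metadata: non-finite values produced")
  out
}

#' Generate a random bifurcating phylogeny over given taxa
#'
#' Random binary topology with independent unit-exponential branch lengths,
#' for exercising Faith's phylogenetic diversity; no attempt to model real
#' 16S divergence.
#'
#' @param taxa character vector of unique tip labels.
#' @param seed integer RNG seed.
#' @return an [ape::rtree()]-style `phylo` object with `length(taxa)` tips
#'   and `length(taxa) - 1` internal nodes.
#' @export
generate_tree <- function(taxa, seed = 1L) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("generate_tree: duplicate taxon identifiers")
  if (length(taxa) < 2L) stop("generate_tree: need at least 2 taxa")
  set.seed(seed)
  tr <- ape::rtree(length(taxa), tip.label = taxa)
  tr$edge.length <- rexp(nrow(tr$edge))
  tr
}
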