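# Synthetic compositional gene-abundance data with known ground truth.
#
# Latent model: each planted module m has one standard-normal factor per
# sample; a member gene loads on it with sqrt(within_module_rho) (sign
# flipped for a negative_fraction of members), so any two positively loaded
# members have latent correlation within_module_rho and the implied latent
# covariance is positive semi-definite by construction. Hub genes
# additionally load on every other module's factor. Latent log-abundances
# are exponentiated to expected fractions and counts drawn by multinomial
# sampling at lognormal library sizes, reproducing the compositional
# closure that SparCC is designed to undo.

.CAZY_CLASSES <- c("GT", "GH", "PL", "CE", "AA", "CBM")

.CHEM_PROPERTIES <- c("pH", "OlsenP", "TotalC", "TotalN", "CN_ratio",
                      "AMN_TN", "Moisture", "CEC", "Ca", "Mg", "Na", "K")

# per-property affine scaling to field-realistic ranges (center, spread);
# affine maps leave all correlations untouched
.CHEM_SCALE <- list(
  pH = c(5.8, 0.4), OlsenP = c(25, 10), TotalC = c(5, 1.5),
  TotalN = c(0.4, 0.1), CN_ratio = c(12, 2), AMN_TN = c(0.05, 0.015),
  Moisture = c(30, 8), CEC = c(18, 4), Ca = c(8, 2.5), Mg = c(1.5, 0.5),
  Na = c(0.15, 0.05), K = c(0.6, 0.2))

.default_chemistry_loadings <- function(n_modules) {
  pairs <- list(c("pH", "Ca"), c("OlsenP", "TotalC"), c("TotalN", "CN_ratio"),
                c("Moisture", "CEC"), c("Mg", "K"))
  out <- vector("list", n_modules)
  names(out) <- paste0("M", seq_len(n_modules))
  for (m in seq_len(n_modules)) {
    props <- pairs[[(m - 1L) %% length(pairs) + 1L]]
    coef <- c(0.9, if (m %% 2 == 0) -0.9 else 0.9)
    out[[m]] <- setNames(coef, props)
  }
  out
}

#' Configuration for the synthetic data generator
#'
#' Defaults mirror the scale of a multi-land-use soil metagenomic survey:
#' five land-use groups of 15 samples each and 120 CAZy gene families, with
#' four planted correlation modules, a moderate fraction of negative
#' associations, and lognormal library-size variation. The default
#' within-module correlation is strong (0.85): with 15 samples per group
#' and a Benjamini-Hochberg correction spanning all gene pairs, weaker
#' planted signals are not detectable at 1000 permutations, so a strong
#' default keeps the planted structure recoverable end-to-end at the
#' survey's sample size.
#'
#' @param n_samples_per_group samples per group.
#' @param groups character vector of group labels.
#' @param n_genes total number of gene families.
#' @param module_sizes integer vector of planted module sizes;
#'   \code{sum(module_sizes) <= n_genes}.
#' @param within_module_rho latent correlation between two (positively
#'   loaded) genes of the same module; scalar or one value per module,
#'   each in (0, 1). Negative associations are planted via
#'   \code{negative_fraction}.
#' @param negative_fraction proportion of each module's genes given a
#'   negative loading, so their links to the rest of the module are negative.
#' @param hub_count number of module genes whose loading on their own module
#'   factor is raised to \code{sqrt(0.95)}, so they correlate more strongly
#'   with each member than ordinary members do with one another (planted
#'   core-periphery hubs, assigned one per module, cycling).
#' @param library_size_mean,library_size_cv mean and coefficient of
#'   variation of the lognormal per-sample sequencing depth.
#' @param chemistry_loadings named list mapping module label (\code{"M1"},
#'   ...) to a named numeric vector of per-property linear coefficients on
#'   that module's latent factor. Default ties each module to two soil
#'   properties at coefficient 0.9.
#' @param noise_sd SD of the independent noise added to each chemistry
#'   property (the latent factors have SD 1).
#' @param seed integer seed; identical configurations generate bit-identical
#'   data.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_samples_per_group = 15,
                             groups = c("exotic_forest", "native_forest",
                                        "dryland_pasture", "irrigated_pasture",
                                        "regenerating_bush"),
                             n_genes = 120,
                             module_sizes = c(15L, 12L, 10L, 8L),
                             within_module_rho = 0.85,
                             negative_fraction = 0.25,
                             hub_count = 3,
                             library_size_mean = 2e4,
                             library_size_cv = 0.25,
                             chemistry_loadings = NULL,
                             noise_sd = 0.3,
                             seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              groups = as.character(groups),
              n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              within_module_rho = within_module_rho,
              negative_fraction = negative_fraction,
              hub_count = as.integer(hub_count),
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              chemistry_loadings = chemistry_loadings,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (is.null(cfg$chemistry_loadings))
    cfg$chemistry_loadings <- .default_chemistry_loadings(length(module_sizes))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param config a \code{synthetic_config} to validate.
#' @export
validate_synthetic_config <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with(config, {
    if (n_samples_per_group < 1) stop("n_samples_per_group must be positive")
    if (length(groups) < 1 || anyDuplicated(groups)) stop("groups must be distinct, nonempty")
    if (any(module_sizes < 1)) stop("all module sizes must be positive")
    if (sum(module_sizes) > n_genes)
      stop("sum(module_sizes) exceeds n_genes")
    if (!length(within_module_rho) %in% c(1L, length(module_sizes)))
      stop("within_module_rho must be scalar or one value per module")
    if (any(within_module_rho <= 0 | within_module_rho >= 1))
      stop("within_module_rho must lie in (0, 1); negative associations are ",
           "planted via negative_fraction")
    if (negative_fraction < 0 || negative_fraction > 1)
      stop("negative_fraction must lie in [0, 1]")
    if (hub_count < 0 || hub_count > sum(module_sizes))
      stop("hub_count must lie in [0, sum(module_sizes)]")
    if (library_size_mean <= 0 || library_size_cv <= 0)
      stop("library size parameters must be positive")
    if (noise_sd <= 0) stop("noise_sd must be positive")
  })
  invisible(config)
}

# CAZy-style gene IDs cycling GT, GH, PL, CE, AA, CBM with per-class counters
.make_gene_ids <- function(n_genes) {
  classes <- rep_len(.CAZY_CLASSES, n_genes)
  idx <- stats::ave(seq_len(n_genes), classes, FUN = seq_along)
  data.frame(gene_id = paste0(classes, idx),
             family = paste0(classes, idx),
             enzyme_class = classes,
             stringsAsFactors = FALSE)
}

# genes x modules loading matrix; rows with all-zero loadings are
# module-free background genes
.build_loadings <- function(config) {
  G <- config$n_genes
  sizes <- config$module_sizes
  M <- length(sizes)
  lambda <- matrix(0, G, M)
  assignment <- rep(NA_character_, G)
  sign_vec <- rep(1, G)
  rho_m <- rep_len(config$within_module_rho, M)
  start <- 1L
  for (m in seq_len(M)) {
    members <- start:(start + sizes[m] - 1L)
    assignment[members] <- paste0("M", m)
    n_neg <- floor(config$negative_fraction * sizes[m])
    if (n_neg > 0) sign_vec[members[(sizes[m] - n_neg + 1L):sizes[m]]] <- -1
    lambda[members, m] <- sqrt(rho_m[m])
    start <- start + sizes[m]
  }
  # hubs: the first member of each module (cycling over modules, then over
  # deeper members) has its loading raised to sqrt(0.95), so it correlates
  # more strongly with every module member than ordinary members do with
  # each other -- a planted core-periphery hub
  hubs <- integer(0)
  if (config$hub_count > 0) {
    firsts <- cumsum(c(1L, sizes[-M]))
    hubs <- unique(vapply(seq_len(config$hub_count) - 1L, function(i) {
      m <- i %% M + 1L
      min(firsts[m] + i %/% M, firsts[m] + sizes[m] - 1L)
    }, integer(1)))
    for (h in hubs) {
      own <- match(assignment[h], paste0("M", seq_len(M)))
      lambda[h, own] <- sqrt(0.95)
    }
  }
  lambda <- lambda * sign_vec
  list(lambda = lambda, assignment = assignment, sign = sign_vec,
       hub_idx = hubs)
}

#' Generate a synthetic multi-group dataset with known ground truth
#'
#' Draws per-group compositional count tables with planted correlation
#' modules, planted hub genes, a tunable fraction of negative associations,
#' lognormal library-size variation, and soil-chemistry covariates linearly
#' tied to the planted module factors. Every downstream stage of the
#' pipeline can be checked against the returned ground truth.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return A list of class \code{synthetic_dataset} with elements
#'   \describe{
#'     \item{abundance}{an \code{\link{abundance_table}} over all groups}
#'     \item{chemistry}{samples x properties numeric matrix}
#'     \item{annotation}{data.frame with \code{gene_id}, \code{family},
#'       \code{enzyme_class}}
#'     \item{truth}{class \code{ground_truth}: \code{basis_correlation}
#'       (genes x genes latent correlation matrix), \code{module_assignment}
#'       (named character; \code{NA} for background genes),
#'       \code{latent_factors} (samples x modules), \code{hub_genes}}
#'   }
#' @examples
#' d <- generate_dataset(synthetic_config(n_samples_per_group = 5, seed = 42))
#' d$abundance
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  ids <- .make_gene_ids(G)
  load <- .build_loadings(config)
  lambda <- load$lambda
  uniq <- 1 - rowSums(lambda^2)
  basis_cor <- tcrossprod(lambda) + diag(uniq)
  dimnames(basis_cor) <- list(ids$gene_id, ids$gene_id)
  # defensive PSD check per planted block (cannot fire for the factor
  # construction, but guards future covariance plumbing)
  for (m in unique(stats::na.omit(load$assignment))) {
    block <- basis_cor[load$assignment %in% m, load$assignment %in% m, drop = FALSE]
    ev <- eigen(block, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("requested covariance for module ", m, " is not positive ",
           "semi-definite (min eigenvalue ", signif(min(ev), 3), ")")
  }

  n_tot <- config$n_samples_per_group * length(config$groups)
  sample_ids <- unlist(lapply(config$groups, function(g)
    paste0(g, "_", seq_len(config$n_samples_per_group))))
  group <- setNames(rep(config$groups, each = config$n_samples_per_group),
                    sample_ids)
  M <- length(config$module_sizes)
  factors <- matrix(rnorm(n_tot * M), n_tot, M,
                    dimnames = list(sample_ids, paste0("M", seq_len(M))))
  eps <- matrix(rnorm(n_tot * G), n_tot, G)
  z <- factors %*% t(lambda) + eps %*% diag(sqrt(uniq))
  # gene baselines span ~3 log-units so abundance ranks vary between genes
  mu <- rnorm(G, 0, 1)
  log_abund <- sweep(z, 2, mu, "+")
  expfrac <- exp(log_abund)
  expfrac <- expfrac / rowSums(expfrac)

  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  lib <- round(exp(rnorm(n_tot, log(config$library_size_mean) - sdlog^2 / 2,
                         sdlog)))
  counts <- t(vapply(seq_len(n_tot),
                     function(s) as.numeric(rmultinom(1, lib[s], expfrac[s, ])),
                     numeric(G)))
  dimnames(counts) <- list(sample_ids, ids$gene_id)

  chem_raw <- matrix(rnorm(n_tot * length(.CHEM_PROPERTIES), 0, config$noise_sd),
                     n_tot, length(.CHEM_PROPERTIES),
                     dimnames = list(sample_ids, .CHEM_PROPERTIES))
  for (m in names(config$chemistry_loadings)) {
    coefs <- config$chemistry_loadings[[m]]
    bad <- setdiff(names(coefs), .CHEM_PROPERTIES)
    if (length(bad) > 0)
      stop("unknown chemistry properties in loadings for ", m, ": ",
           paste(bad, collapse = ", "))
    mi <- match(m, colnames(factors))
    if (is.na(mi)) stop("chemistry_loadings refers to unknown module ", m)
    for (p in names(coefs))
      chem_raw[, p] <- chem_raw[, p] + coefs[[p]] * factors[, mi]
  }
  chemistry <- chem_raw
  for (p in colnames(chemistry)) {
    sc <- .CHEM_SCALE[[p]]
    chemistry[, p] <- sc[1] + sc[2] * chem_raw[, p]
  }

  truth <- structure(
    list(basis_correlation = basis_cor,
         module_assignment = setNames(load$assignment, ids$gene_id),
         latent_factors = factors,
         hub_genes = ids$gene_id[load$hub_idx]),
    class = "ground_truth")

  structure(
    list(abundance = abundance_table(counts, group = group),
         chemistry = chemistry,
         annotation = ids,
         truth = truth,
         config = config),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$abundance$counts), " samples, ",
      ncol(x$abundance$counts), " genes, ",
      length(x$config$module_sizes), " planted modules\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the abundance, metadata, chemistry and annotation TSVs in the
#' package's canonical dialects plus a ground-truth JSON.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             chemistry = file.path(dir, "chemistry.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_abundance_table(dataset$abundance, paths["abundance"])
  write_sample_metadata(dataset$abundance$group, paths["metadata"])
  write_chemistry_table(dataset$chemistry, paths["chemistry"])
  write_annotation_table(dataset$annotation, paths["annotation"])
  truth <- dataset$truth
  jsonlite::write_json(
    list(module_assignment = as.list(truth$module_assignment),
         hub_genes = truth$hub_genes,
         basis_correlation = truth$basis_correlation,
         latent_factors = truth$latent_factors),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
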