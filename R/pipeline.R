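# End-to-end orchestration: per-group filtering, SparCC, network
# construction, topology, stability and eigengene-environment analysis,
# with a Table-style cross-group summary and a reproducible report bundle.

#' Pipeline configuration
#'
#' Exactly one of \code{input} (paths to the four on-disk tables) or
#' \code{synthetic} (a \code{\link{synthetic_config}}) must be supplied.
#'
#' @param input named list with paths \code{abundance}, \code{metadata},
#'   \code{chemistry}, \code{annotation} (metadata/chemistry/annotation
#'   optional).
#' @param synthetic a \code{\link{synthetic_config}}.
#' @param output_dir directory for the report bundle.
#' @param min_count,min_prevalence low-abundance filter parameters.
#' @param n_perm SparCC permutation count.
#' @param pseudocount,exclusion_threshold,max_exclusion_rounds SparCC
#'   parameters.
#' @param threshold,alpha network edge thresholds on \eqn{|\rho|} and the
#'   BH q-value.
#' @param attack_iterations iterations for random-attack robustness.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it, so one seed fixes the whole run.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            output_dir = tempfile("cazynet_run_"),
                            min_count = 3, min_prevalence = 0.10,
                            n_perm = 1000, pseudocount = 1,
                            exclusion_threshold = 0.8,
                            max_exclusion_rounds = 10,
                            threshold = 0.6, alpha = 0.05,
                            attack_iterations = 100, seed = 1L) {
  if (is.null(input) == is.null(synthetic))
    stop("supply exactly one of `input` (file paths) or `synthetic` ",
         "(a synthetic_config)")
  if (!is.null(input) && !"abundance" %in% names(input))
    stop("`input` must at least name an abundance table path")
  structure(
    list(input = input, synthetic = synthetic, output_dir = output_dir,
         min_count = min_count, min_prevalence = min_prevalence,
         n_perm = n_perm, pseudocount = pseudocount,
         exclusion_threshold = exclusion_threshold,
         max_exclusion_rounds = max_exclusion_rounds,
         threshold = threshold, alpha = alpha,
         attack_iterations = attack_iterations, seed = as.integer(seed)),
    class = "pipeline_config")
}

# per-stage seeds derived from the master seed; offsets keep streams apart
# and every derived seed below 2^31
.stage_seed <- function(master, stage_index) {
  (as.integer(master) * 97L + stage_index * 1009L) %% 2000000011L
}

.write_stage_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full per-group network pipeline
#'
#' For each group: low-abundance filtering, SparCC correlation inference
#' with permutation significance, network construction, topology summary
#' (including modules, node roles and the power-law fit), robustness under
#' random and targeted attack, node vulnerability, per-sample cohesion,
#' module eigengenes and their chemistry correlations. Across groups:
#' shared-node partition, enzyme-class link proportions, and ANOVA + Tukey
#' comparisons of vulnerability (per node) and cohesion (per sample). All
#' artifacts are written under \code{config$output_dir}; identical
#' configurations and seeds give byte-identical reports.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose log stage progress with \code{message()}.
#' @return Invisibly, a list of class \code{pipeline_result} with all
#'   in-memory stage outputs and \code{files} (paths written).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("cazynet ", as.character(packageVersion("cazynet"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("master_seed\t", config$seed),
    paste0("params\tmin_count=", config$min_count,
           " min_prevalence=", config$min_prevalence,
           " n_perm=", config$n_perm,
           " pseudocount=", config$pseudocount,
           " exclusion_threshold=", config$exclusion_threshold,
           " threshold=", config$threshold,
           " alpha=", config$alpha,
           " attack_iterations=", config$attack_iterations))
  say <- function(...) if (verbose) message(...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----
  if (!is.null(config$synthetic)) {
    say("simulating dataset")
    ds <- stage("simulate", generate_dataset(config$synthetic))
    abund <- ds$abundance
    chemistry <- ds$chemistry
    annotation <- ds$annotation
    write_dataset(ds, file.path(out_dir, "inputs"))
  } else {
    say("reading inputs")
    abund <- stage("read", read_abundance_table(
      config$input$abundance, metadata_path = config$input$metadata))
    chemistry <- if (!is.null(config$input$chemistry))
      stage("read", read_chemistry_table(config$input$chemistry)) else NULL
    annotation <- if (!is.null(config$input$annotation))
      stage("read", read_annotation_table(config$input$annotation)) else NULL
  }

  # ---- per-group pipeline ----
  tables <- stage("split", split_by_group(abund))
  groups <- names(tables)
  per_group <- list()
  networks <- list()
  files <- character(0)
  for (gi in seq_along(groups)) {
    gname <- groups[gi]
    say("group ", gname)
    gdir <- file.path(out_dir, gname)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    tab <- stage(paste0("filter:", gname),
                 filter_low_abundance(tables[[gname]],
                                      min_count = config$min_count,
                                      min_prevalence = config$min_prevalence))
    corr <- stage(paste0("sparcc:", gname), sparcc_correlation(
      tab, n_perm = config$n_perm,
      seed = .stage_seed(config$seed, gi * 10L + 1L),
      pseudocount = config$pseudocount,
      exclusion_threshold = config$exclusion_threshold,
      max_exclusion_rounds = config$max_exclusion_rounds))
    nw <- stage(paste0("network:", gname), build_network(
      corr, annotation = annotation, threshold = config$threshold,
      alpha = config$alpha, group = gname))
    networks[[gname]] <- nw
    if (igraph::vcount(nw$graph) == 0) {
      warning("group '", gname, "' produced an empty network; ",
              "downstream stages skipped for this group")
      per_group[[gname]] <- list(table = tab, corr = corr, network = nw)
      next
    }
    modules <- stage(paste0("modules:", gname),
                     detect_modules_fast_greedy(nw))
    topo <- stage(paste0("topology:", gname), topology_summary(nw, modules))
    roles <- stage(paste0("roles:", gname), classify_node_roles(nw, modules))
    rob <- list(
      random = stage(paste0("robustness:", gname), robustness_under_attack(
        nw, "random", n_iterations = config$attack_iterations,
        seed = .stage_seed(config$seed, gi * 10L + 2L))),
      targeted = stage(paste0("robustness:", gname),
                       robustness_under_attack(nw, "targeted")))
    vuln <- if (igraph::vcount(nw$graph) >= 3)
      stage(paste0("vulnerability:", gname), node_vulnerability(nw)) else NULL
    coh <- stage(paste0("cohesion:", gname), sample_cohesion(tab, nw))
    eig <- tryCatch(module_eigengenes(tab, modules), error = function(e) {
      warning("eigengenes skipped for '", gname, "': ", conditionMessage(e))
      NULL
    })
    envcor <- if (!is.null(eig) && !is.null(chemistry))
      stage(paste0("eigengene_env:", gname),
            correlate_eigengenes_with_chemistry(
              eig, chemistry[rownames(chemistry) %in% tab$sample_ids, ,
                             drop = FALSE])) else NULL

    files <- c(files,
               write_network(nw, file.path(gdir, "network_edges.tsv"),
                             "edge_list"),
               write_network(nw, file.path(gdir, "network.graphml"),
                             "graphml"),
               .write_stage_tsv(roles, file.path(gdir, "node_roles.tsv")),
               .write_stage_tsv(rbind(
                 cbind(mode = "random", rob$random$curve),
                 cbind(mode = "targeted", rob$targeted$curve)),
                 file.path(gdir, "robustness.tsv")),
               .write_stage_tsv(coh, file.path(gdir, "cohesion.tsv")))
    if (!is.null(vuln))
      files <- c(files, .write_stage_tsv(vuln$table,
                                         file.path(gdir, "vulnerability.tsv")))
    if (!is.null(envcor))
      files <- c(files, .write_stage_tsv(
        envcor, file.path(gdir, "eigengene_chemistry.tsv")))

    per_group[[gname]] <- list(
      table = tab, corr = corr, network = nw, modules = modules,
      topology = topo, roles = roles, robustness = rob,
      vulnerability = vuln, cohesion = coh, eigengenes = eig,
      env_correlation = envcor)
  }

  # ---- cross-group ----
  nonempty <- names(networks)[vapply(networks, function(nw)
    igraph::vcount(nw$graph) > 0, logical(1))]
  shared <- if (length(nonempty) >= 2)
    stage("shared_nodes", shared_node_partition(networks[nonempty])) else NULL
  class_props <- if (!is.null(annotation)) lapply(
    networks[nonempty], function(nw)
      stage("class_links", class_link_proportions(nw, annotation))) else NULL

  vuln_all <- do.call(rbind, lapply(nonempty, function(g) {
    v <- per_group[[g]]$vulnerability
    if (is.null(v)) return(NULL)
    data.frame(group = g, value = v$table$vulnerability)
  }))
  comparisons <- list()
  if (!is.null(vuln_all) && length(unique(vuln_all$group)) >= 2 &&
      all(table(vuln_all$group) >= 2))
    comparisons$vulnerability <- compare_groups(vuln_all$value, vuln_all$group)
  coh_all <- do.call(rbind, lapply(nonempty, function(g)
    per_group[[g]]$cohesion))
  if (!is.null(coh_all) && length(unique(coh_all$group)) >= 2) {
    for (metric in c("positive", "negative", "ratio")) {
      vals <- coh_all[[metric]]
      if (sum(!is.na(vals)) >= 4 &&
          all(table(coh_all$group[!is.na(vals)]) >= 2))
        comparisons[[paste0("cohesion_", metric)]] <-
          compare_groups(vals, coh_all$group)
    }
  }

  # ---- Table-style topology report (metrics x groups) ----
  metric_names <- c("network_size", "connectivity", "average_connectivity",
                    "pct_negative_links", "average_path_length", "diameter",
                    "clustering_coefficient", "density", "centralisation",
                    "modularity", "powerlaw_r2", "powerlaw_p",
                    "pct_peripherals", "pct_connectors", "pct_module_hubs",
                    "pct_network_hubs")
  topo_tab <- data.frame(metric = metric_names, stringsAsFactors = FALSE)
  for (g in groups) {
    topo <- per_group[[g]]$topology
    topo_tab[[g]] <- if (is.null(topo)) NA_real_ else
      vapply(metric_names, function(mn)
        if (is.null(topo[[mn]])) NA_real_ else as.numeric(topo[[mn]]),
        numeric(1))
  }
  files <- c(files,
             .write_stage_tsv(topo_tab, file.path(out_dir, "topology_summary.tsv")))
  jsonlite::write_json(topo_tab, file.path(out_dir, "topology_summary.json"),
                       dataframe = "columns", digits = NA, na = "null")
  files <- c(files, file.path(out_dir, "topology_summary.json"))
  if (!is.null(shared))
    files <- c(files, .write_stage_tsv(shared,
                                       file.path(out_dir, "shared_nodes.tsv")))
  if (!is.null(class_props)) {
    cp <- do.call(rbind, lapply(names(class_props), function(g)
      cbind(group = g, class_props[[g]])))
    files <- c(files, .write_stage_tsv(cp,
                                       file.path(out_dir, "class_link_proportions.tsv")))
  }
  if (length(comparisons) > 0) {
    cmp_df <- do.call(rbind, lapply(names(comparisons), function(nm) {
      cm <- comparisons[[nm]]
      data.frame(metric = nm, group = names(cm$letters),
                 letter = unname(cm$letters), F = cm$F,
                 df_between = cm$df_between, df_within = cm$df_within,
                 p = cm$p, stringsAsFactors = FALSE)
    }))
    files <- c(files, .write_stage_tsv(cmp_df,
                                       file.path(out_dir, "group_comparisons.tsv")))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- c(files, file.path(out_dir, "run_log.txt"))

  invisible(structure(
    list(config = config, abundance = abund, chemistry = chemistry,
         annotation = annotation, per_group = per_group,
         networks = networks, shared_nodes = shared,
         class_proportions = class_props, comparisons = comparisons,
         topology_table = topo_tab, files = files),
    class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$per_group), " groups; outputs in ",
      x$config$output_dir, "\n", sep = "")
  print(x$topology_table, row.names = FALSE)
  invisible(x)
}
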