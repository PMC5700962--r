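# End-to-end orchestration: differential screens -> length-bias filter ->
# co-expression modules (in parallel with the mutation network and candidate
# modulator pool) -> module-network EM -> dosage classification -> driver
# pattern report.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default: expression EMD q-value
#' cutoff 0.1; CNV call threshold on the log2 ratio 0.3; between-group
#' CNV frequency difference 0.20; mutation frequency 0.02; 1000 resampling
#' replicates with removal at fre > 0.05; DS bounds (-0.25, 0.25); gene
#' significance cutoff 0.7.
#'
#' @param q_thresh EMD q-value cutoff for expression genes.
#' @param n_perm Label permutations for EMD q-values.
#' @param cnv_thresh Log2-ratio threshold for amplification/deletion calls.
#' @param freq_diff Minimum between-group CNV frequency difference.
#' @param mut_freq Minimum within-group mutation frequency.
#' @param resample_reps Resampling replicates for the length filter.
#' @param fre_thresh Removal threshold on the resampling frequency.
#' @param fre_aggregate Aggregation of per-sample resampling frequencies.
#' @param beta Soft-threshold power, or "auto" for scale-free selection.
#' @param min_module_size,cut_height Module detection controls.
#' @param min_vertex_weight,n_clusters,top_per_cluster Mutation network /
#'   modulator pool controls.
#' @param prior Normal-gamma prior for module-network learning.
#' @param penalty Per-node complexity penalty (NULL = 0.5 log N).
#' @param max_iter,tol,max_depth,min_leaf EM and tree controls.
#' @param ds_bounds,n_points,span,loess_degree Dosage-analysis controls.
#' @param gs_thresh Gene-significance cutoff for the comparison report.
#' @param seed Global seed, expanded into per-stage seeds.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(q_thresh = 0.1, n_perm = 1000L, cnv_thresh = 0.3,
                            freq_diff = 0.20, mut_freq = 0.02,
                            resample_reps = 1000L, fre_thresh = 0.05,
                            fre_aggregate = "mean",
                            beta = "auto", min_module_size = 20L,
                            cut_height = 0.99, min_vertex_weight = 0.02,
                            n_clusters = 20L, top_per_cluster = 40L,
                            prior = normal_gamma_prior(), penalty = NULL,
                            max_iter = 20L, tol = 1e-4, max_depth = 3L,
                            min_leaf = 5L, ds_bounds = c(-0.25, 0.25),
                            n_points = 50L, span = 0.75, loess_degree = 2L,
                            gs_thresh = 0.7, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_value("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full driver-pattern identification pipeline
#'
#' Executes, in order: EMD differential expression screening; CNV state
#' calling, segment mapping and frequency filtering; somatic mutation
#' frequency filtering; the gene-length resampling filter on the combined
#' mutation gene pool; mutation-network construction and candidate modulator
#' selection; co-expression module detection; module-network EM learning;
#' dosage-sensitivity classification of the learned modulators; and driver
#' pattern report assembly. Identical config + seed reproduce the run
#' bit-for-bit.
#'
#' @param bundle A \code{synth_bundle} or a list with elements
#'   \code{expression}, \code{cnv_log2}, \code{somatic}, \code{labels},
#'   \code{lengths} (e.g. from \code{\link{read_bundle}}).
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional directory; when given, all stage artifacts are
#'   written there.
#' @return Object of class \code{driver_report}.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), out_dir = NULL) {
  X <- bundle$expression
  labels <- bundle$labels
  check_labels(labels, colnames(X))

  counts <- c(universe = nrow(X))

  diff <- run_stage("diff_filter", {
    emd_qvalues(X, labels, n_perm = config$n_perm,
                seed = derive_seed(config$seed, "emd"))
  })
  expr_genes <- diff$gene[diff$q_value < config$q_thresh]
  counts["expression_selected"] <- length(expr_genes)

  states <- run_stage("cnv_states",
                      call_cnv_states(bundle$cnv_log2, config$cnv_thresh))
  cnv_genes <- run_stage("cnv_filter",
                         cnv_frequency_filter(states, labels, config$freq_diff))
  counts["cnv_selected"] <- length(cnv_genes)

  som_genes <- run_stage("mutation_filter",
                         mutation_frequency_filter(bundle$somatic, labels,
                                                   config$mut_freq))
  counts["somatic_selected"] <- length(som_genes)

  ## length-bias filter over the combined mutation gene pool
  mut_pool <- union(cnv_genes, som_genes)
  retained <- run_stage("length_filter", {
    if (length(mut_pool) == 0)
      stop("empty mutation gene pool before length filtering")
    ## the length model concerns somatic mutation probability per kb of
    ## cDNA, so it is fitted and resampled on somatic calls only; the
    ## removal rule is then applied to the whole mutation gene pool
    per_sample <- apply(bundle$somatic == 1L, 2,
                        function(col) rownames(bundle$somatic)[col],
                        simplify = FALSE)
    universe <- intersect(rownames(X), names(bundle$lengths))
    pwv <- fit_pwv(per_sample, universe, bundle$lengths)
    fre <- resample_frequencies(pwv, per_sample,
                                reps = config$resample_reps,
                                seed = derive_seed(config$seed, "resample"),
                                aggregate = config$fre_aggregate)
    out <- filter_by_frequency(intersect(mut_pool, universe), fre,
                               config$fre_thresh)
    if (length(out) == 0)
      stop("empty candidate pool: every mutation gene was length-explainable")
    out
  })
  counts["length_filtered"] <- length(retained)

  net_parts <- run_stage("mutation_network", {
    A <- build_mutation_matrix(states, bundle$somatic, retained)
    net <- build_network(A, config$min_vertex_weight)
    if (length(net$genes) == 0) stop("no vertices above min_vertex_weight")
    pool <- select_candidate_modulators(net,
                                        min(config$n_clusters, length(net$genes)),
                                        config$top_per_cluster)
    list(A = A, net = net, pool = pool)
  })
  counts["modulator_pool"] <- nrow(net_parts$pool)

  coexp <- run_stage("coexpression", {
    Xe <- X[expr_genes, , drop = FALSE]
    v <- apply(Xe, 1, stats::var)
    Xe <- Xe[v > 0, , drop = FALSE]
    if (nrow(Xe) < config$min_module_size)
      stop("too few differential genes for module detection")
    S <- similarity(Xe)
    beta <- if (identical(config$beta, "auto"))
      suppressWarnings(as.numeric(pick_soft_threshold(S))) else config$beta
    W <- tom(adjacency(S, beta))
    modules <- detect_modules(W, config$min_module_size, config$cut_height)
    labs <- setdiff(unique(modules$colors), "grey")
    egs <- lapply(stats::setNames(labs, labs), function(lb) {
      members <- names(modules$colors)[modules$colors == lb]
      eigengene(Xe[members, , drop = FALSE])
    })
    list(X = Xe, beta = beta, modules = modules, eigengenes = egs,
         gs = gene_significance(Xe, labels))
  })
  counts["module_genes"] <- sum(coexp$modules$colors != "grey")

  model <- run_stage("module_networks", {
    status <- t(net_parts$A[, net_parts$pool$gene, drop = FALSE])
    module_network(coexp$X, coexp$modules, status, prior = config$prior,
                   penalty = config$penalty, max_iter = config$max_iter,
                   tol = config$tol, max_depth = config$max_depth,
                   min_leaf = config$min_leaf)
  })
  modulators <- extract_modulators(model)
  counts["learned_modules"] <- length(model$programs)
  counts["modulators"] <- length(modulators)

  ds <- run_stage("dosage", {
    mods <- names(modulators)
    if (length(mods) == 0) {
      dosage_sensitivity(X, bundle$cnv_log2, genes = character(0))
    } else {
      prov <- attr(net_parts$A, "provenance")[mods]
      dos <- bundle$cnv_log2[mods, , drop = FALSE]
      som_rows <- mods[!is.na(prov) & prov == "somatic"]
      if (length(som_rows))
        dos[som_rows, ] <- bundle$somatic[som_rows, colnames(dos)]
      dosage_sensitivity(X, dos, genes = mods, span = config$span,
                         degree = config$loess_degree,
                         n_points = config$n_points,
                         bounds = config$ds_bounds)
    }
  })
  counts["dsg"] <- sum(ds$class == "DSG")
  counts["drg"] <- sum(ds$class == "DRG")

  shared <- names(modulators)[vapply(modulators, length, 1L) >= 2]
  gs_overlap <- compare_with_gs(coexp$gs, ds, config$gs_thresh)

  report <- structure(list(counts = counts, diff = diff,
                           cnv_genes = cnv_genes, somatic_genes = som_genes,
                           retained_genes = retained,
                           mutation_matrix = net_parts$A,
                           network = net_parts$net, pool = net_parts$pool,
                           beta = coexp$beta, modules = coexp$modules,
                           eigengenes = coexp$eigengenes, gs = coexp$gs,
                           model = model, modulators = modulators,
                           shared_modulators = shared, dosage = ds,
                           gs_overlap = gs_overlap, config = config),
                      class = "driver_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.driver_report <- function(x, ...) {
  cat("Driver-pattern report\n")
  cat("  gene counts by stage:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-20s %6d\n", nm, x$counts[[nm]]))
  cat(sprintf("  shared modulators (>= 2 modules): %s\n",
              if (length(x$shared_modulators))
                paste(x$shared_modulators, collapse = ", ") else "none"))
  ov <- x$gs_overlap
  cat(sprintf("  GS > %.2f genes: %d; overlap with modulators: %d (DSG %d / DRG %d)\n",
              x$config$gs_thresh, length(ov$gs_genes), ov$n_common,
              ov$n_dsg_overlap, ov$n_drg_overlap))
  invisible(x)
}

#' Compare gene-significance selection with dosage-classified modulators
#'
#' Intersects the genes passing the gene-significance cutoff with the
#' modulators identified by module-network learning, split by DSG/DRG class.
#'
#' @param gs Named gene-significance vector.
#' @param ds_results A \code{dosage_result}.
#' @param gs_thresh Cutoff (default 0.7, strict).
#' @return List with counts and gene lists.
#' @export
compare_with_gs <- function(gs, ds_results, gs_thresh = 0.7) {
  sel <- names(gs)[gs > gs_thresh]
  dsg <- ds_results$gene[ds_results$class == "DSG"]
  drg <- ds_results$gene[ds_results$class == "DRG"]
  list(gs_genes = sel,
       n_common = length(intersect(sel, c(dsg, drg))),
       n_dsg_overlap = length(intersect(sel, dsg)),
       n_drg_overlap = length(intersect(sel, drg)),
       dsg_overlap = intersect(sel, dsg),
       drg_overlap = intersect(sel, drg))
}

#' Write DSG/DRG gene lists for external enrichment tools
#'
#' One gene symbol per line, suitable for any GO/KEGG enrichment tool.
#'
#' @param ds_results A \code{dosage_result}.
#' @param out_dir Output directory.
#' @return Named vector of the two file paths.
#' @export
export_enrichment_input <- function(ds_results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dsg_path <- file.path(out_dir, "dsg_genes.txt")
  drg_path <- file.path(out_dir, "drg_genes.txt")
  writeLines(ds_results$gene[ds_results$class == "DSG"], dsg_path)
  writeLines(ds_results$gene[ds_results$class == "DRG"], drg_path)
  c(dsg = dsg_path, drg = drg_path)
}

#' Write a mutation network as GraphML
#'
#' Vertices carry the weight h, edges the mutual-exclusivity weight V;
#' pairs without a defined edge are omitted.
#'
#' @param net A \code{mutation_network}.
#' @param path Output file.
#' @export
write_network_graphml <- function(net, path) {
  V <- net$V
  V[is.na(V)] <- -1
  g <- igraph::graph_from_adjacency_matrix((V >= 0 & upper.tri(V)) * 1,
                                           mode = "upper", diag = FALSE)
  igraph::V(g)$h <- unname(net$h)
  ends <- igraph::as_edgelist(g)
  igraph::E(g)$V <- net$V[cbind(ends[, 1], ends[, 2])]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

serialize_tree <- function(node) {
  if (node$type == "leaf") return(list(type = "leaf", n = node$n))
  list(type = "split", modulator = node$modulator,
       no = serialize_tree(node$no), yes = serialize_tree(node$yes))
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(data.frame(stage = names(report$counts),
                                genes = unname(report$counts)),
                     p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$diff, p("emd_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(report$modules$colors),
                                module = unname(report$modules$colors)),
                     p("modules.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$pool, p("modulator_pool.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$dosage, p("dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$retained_genes, p("retained_genes.txt"))
  write_network_graphml(report$network, p("mutation_network.graphml"))
  model_json <- list(
    penalty = report$model$penalty,
    score = report$model$score,
    iterations = report$model$iterations,
    trace = report$model$trace,
    assignment = as.list(report$model$assignment),
    programs = lapply(report$model$programs,
                      function(pr) serialize_tree(pr$tree)),
    modulators = report$modulators)
  jsonlite::write_json(model_json, p("model.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(report$gs_overlap, p("gs_overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  export_enrichment_input(report$dosage, out_dir)
  invisible(out_dir)
}
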