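#' Synthetic multi-omics study configuration
#'
#' Defines the study conditions emulated by the synthetic generator: two
#' labeled sample groups (drug-resistant / drug-sensitive), planted modulator
#' genes whose mutation or copy-number status drives the expression of
#' co-expression module members through tree-structured programs,
#' length-biased passenger mutations, and modulators that are either
#' dosage-coupled (expression tracks copy number) or dosage-decoupled.
#'
#' Gene cDNA lengths are log-normal with median 2 kb; planted passengers are
#' drawn from the top length decile so that the length-bias filter has a
#' genuine target. Background (passenger) mutation probability is
#' proportional to cDNA length. Modulator mutation rates differ between the
#' resistant and sensitive groups so that differential screens have signal.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_resistant,n_samples_sensitive Group sample counts.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size_range Length-2 integer vector, min/max module size.
#' @param n_modulators Number of planted modulator (driver) genes; their cDNA
#'   lengths are drawn uniformly from 1--3 kb.
#' @param n_passenger_long_genes Number of planted long passenger genes.
#' @param modulator_mutation_rate Named length-2 vector with per-sample
#'   mutation probabilities for the \code{resistant} and \code{sensitive}
#'   groups.
#' @param background_mutation_rate_per_kb Per-sample somatic mutation
#'   probability per kb of cDNA for non-modulator genes.
#' @param effect_size Expression shift (log2 units) separating adjacent
#'   leaves of a planted regulatory program.
#' @param noise_sd Residual expression standard deviation (log2 units).
#' @param dosage_coupled_fraction Fraction of modulators whose expression is
#'   \code{slope * dosage + noise} (dosage-sensitive by construction).
#' @param coupled_slope_range Length-2 vector of slopes for coupled
#'   modulators.
#' @param share_first_modulator If \code{TRUE} (default) and there are at
#'   least two modules, the first modulator is also planted into the second
#'   module's program, so one modulator regulates two modules.
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_genes = 200L,
                         n_samples_resistant = 60L,
                         n_samples_sensitive = 60L,
                         n_modules = 5L,
                         module_size_range = c(20L, 30L),
                         n_modulators = 10L,
                         n_passenger_long_genes = 20L,
                         modulator_mutation_rate = c(resistant = 0.5,
                                                     sensitive = 0.2),
                         background_mutation_rate_per_kb = 0.01,
                         effect_size = 2,
                         noise_sd = 0.5,
                         dosage_coupled_fraction = 0.5,
                         coupled_slope_range = c(1, 2),
                         share_first_modulator = TRUE,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_resistant = as.integer(n_samples_resistant),
              n_samples_sensitive = as.integer(n_samples_sensitive),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              n_modulators = as.integer(n_modulators),
              n_passenger_long_genes = as.integer(n_passenger_long_genes),
              modulator_mutation_rate = modulator_mutation_rate,
              background_mutation_rate_per_kb = background_mutation_rate_per_kb,
              effect_size = effect_size,
              noise_sd = noise_sd,
              dosage_coupled_fraction = dosage_coupled_fraction,
              coupled_slope_range = as.numeric(coupled_slope_range),
              share_first_modulator = isTRUE(share_first_modulator),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  pos <- c("n_genes", "n_samples_resistant", "n_samples_sensitive",
           "n_modules", "n_modulators")
  for (f in pos)
    assert_that(length(cfg[[f]]) == 1L && !is.na(cfg[[f]]) && cfg[[f]] > 0L,
                "invalid synth_config: field '%s' must be a positive count", f)
  assert_that(cfg$n_passenger_long_genes >= 0L,
              "invalid synth_config: field 'n_passenger_long_genes' must be >= 0")
  msr <- cfg$module_size_range
  assert_that(length(msr) == 2L && all(msr >= 1L) && msr[1] <= msr[2],
              "invalid synth_config: field 'module_size_range' must be (min, max) with min <= max")
  rates <- cfg$modulator_mutation_rate
  assert_that(all(c("resistant", "sensitive") %in% names(rates)) &&
                all(rates >= 0 & rates <= 1),
              "invalid synth_config: field 'modulator_mutation_rate' must name resistant/sensitive rates in [0,1]")
  assert_that(cfg$background_mutation_rate_per_kb >= 0,
              "invalid synth_config: field 'background_mutation_rate_per_kb' must be >= 0")
  assert_that(cfg$noise_sd >= 0,
              "invalid synth_config: field 'noise_sd' must be >= 0")
  assert_that(cfg$dosage_coupled_fraction >= 0 && cfg$dosage_coupled_fraction <= 1,
              "invalid synth_config: field 'dosage_coupled_fraction' must be in [0,1]")
  assert_that(length(cfg$coupled_slope_range) == 2L,
              "invalid synth_config: field 'coupled_slope_range' must have length 2")
  needed <- cfg$n_modules * msr[2] + cfg$n_modulators + cfg$n_passenger_long_genes
  assert_that(needed <= cfg$n_genes,
              "invalid synth_config: field 'n_genes' too small (modules + modulators + passengers need up to %d genes)",
              needed)
  invisible(cfg)
}

#' Generate a synthetic multi-omics bundle with planted ground truth
#'
#' Draws gene lengths, somatic mutations, copy-number states, sample labels
#' and an expression matrix under the regulatory model described in
#' \code{\link{synth_config}}. Member-gene expression equals the leaf mean of
#' its module's planted regulatory tree evaluated on the modulator mutation
#' statuses, plus Gaussian noise; for a program over modulators
#' \eqn{(m_1, ..., m_k)} the leaf mean is
#' \eqn{e \sum_j 2^{k-j} s_{m_j}} with \eqn{e} the effect size, so every
#' status combination maps to a distinct leaf mean.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list of class \code{synth_bundle} with elements
#'   \code{expression}, \code{cnv_log2}, \code{somatic} (gene x sample
#'   matrices), \code{labels}, \code{lengths}, \code{gene_coords},
#'   \code{config} and \code{truth} (planted ground truth: modulator ids,
#'   module membership, passenger ids, dosage classes, program specs).
#' @export
generate_bundle <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  set.seed(config$seed)

  n <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  m_res <- config$n_samples_resistant
  m_sen <- config$n_samples_sensitive
  m <- m_res + m_sen
  sample_ids <- c(sprintf("R%03d", seq_len(m_res)), sprintf("S%03d", seq_len(m_sen)))
  labels <- stats::setNames(rep(c("resistant", "sensitive"), c(m_res, m_sen)),
                            sample_ids)

  ## gene roles: fixed id blocks (lengths/effects are what carry the biology)
  n_mod <- config$n_modulators
  n_pass <- config$n_passenger_long_genes
  modulator_ids <- gene_ids[seq_len(n_mod)]
  passenger_ids <- if (n_pass > 0) gene_ids[n_mod + seq_len(n_pass)] else character(0)
  sizes <- if (config$module_size_range[1] == config$module_size_range[2])
    rep(config$module_size_range[1], config$n_modules)
  else
    sample(seq(config$module_size_range[1], config$module_size_range[2]),
           config$n_modules, replace = TRUE)
  member_pool <- gene_ids[(n_mod + n_pass + 1):n]
  members <- vector("list", config$n_modules)
  off <- 0L
  for (q in seq_len(config$n_modules)) {
    members[[q]] <- member_pool[off + seq_len(sizes[q])]
    off <- off + sizes[q]
  }
  module_labels <- paste0("M", seq_len(config$n_modules))
  membership <- stats::setNames(rep("grey", n), gene_ids)
  for (q in seq_len(config$n_modules)) membership[members[[q]]] <- module_labels[q]

  ## cDNA lengths: log-normal, median 2 kb; modulators short (1-3 kb),
  ## passengers from the top decile of the same log-normal
  meanlog <- log(2000); sdlog <- 1
  lengths <- stats::setNames(stats::rlnorm(n, meanlog, sdlog), gene_ids)
  lengths[modulator_ids] <- stats::runif(n_mod, 1000, 3000)
  if (n_pass > 0)
    lengths[passenger_ids] <- stats::qlnorm(stats::runif(n_pass, 0.9, 1),
                                            meanlog, sdlog)

  ## modulator mutation status: Bernoulli with group-dependent rate
  rate <- ifelse(labels == "resistant",
                 config$modulator_mutation_rate[["resistant"]],
                 config$modulator_mutation_rate[["sensitive"]])
  status <- matrix(stats::rbinom(n_mod * m, 1L, rep(rate, each = n_mod)),
                   n_mod, m, dimnames = list(modulator_ids, sample_ids))

  ## provenance: ~70% of modulators carry their lesion as CNV, rest somatic
  n_cnv_mod <- if (n_mod == 1L) 1L else ceiling(0.7 * n_mod)
  provenance <- stats::setNames(rep(c("cnv", "somatic"),
                                    c(n_cnv_mod, n_mod - n_cnv_mod)),
                                modulator_ids)

  ## copy number: mutated CNV-modulator samples are amplified or deleted
  ## (fixed sign per gene, |log2| in 0.4-0.8); everything else near zero
  cnv_log2 <- matrix(stats::runif(n * m, -0.1, 0.1), n, m,
                     dimnames = list(gene_ids, sample_ids))
  cn_state <- matrix(0L, n, m, dimnames = list(gene_ids, sample_ids))
  cn_sign <- stats::setNames(sample(c(-1L, 1L), n_cnv_mod, replace = TRUE),
                             modulator_ids[seq_len(n_cnv_mod)])
  for (g in names(cn_sign)) {
    mut <- status[g, ] == 1L
    cn_state[g, mut] <- cn_sign[[g]]
    cnv_log2[g, mut] <- cn_sign[[g]] * stats::runif(sum(mut), 0.4, 0.8)
  }

  ## somatic calls: somatic modulators carry their status; all non-modulator
  ## genes mutate with probability proportional to cDNA length
  somatic <- matrix(0L, n, m, dimnames = list(gene_ids, sample_ids))
  som_mods <- modulator_ids[provenance == "somatic"]
  somatic[som_mods, ] <- status[som_mods, ]
  bg_genes <- setdiff(gene_ids, modulator_ids)
  p_bg <- pmin(0.9, lengths[bg_genes] / 1000 * config$background_mutation_rate_per_kb)
  somatic[bg_genes, ] <- stats::rbinom(length(bg_genes) * m, 1L, rep(p_bg, m))

  ## planted regulatory programs: modulators round-robin over modules
  program_specs <- vector("list", config$n_modules)
  names(program_specs) <- module_labels
  for (q in seq_len(config$n_modules)) {
    idx <- seq(q, n_mod, by = config$n_modules)
    mods_q <- modulator_ids[idx]
    if (q == 2L && config$share_first_modulator && config$n_modules >= 2L)
      mods_q <- c(mods_q, modulator_ids[1])
    program_specs[[q]] <- list(modulators = mods_q,
                               effect_size = config$effect_size)
  }

  ## expression
  expr <- matrix(stats::rnorm(n * m, 0, 1), n, m,
                 dimnames = list(gene_ids, sample_ids))
  for (q in seq_len(config$n_modules)) {
    mods_q <- program_specs[[q]]$modulators
    if (length(mods_q) == 0) next
    k <- length(mods_q)
    mu <- config$effect_size *
      as.vector(2^((k - 1):0) %*% status[mods_q, , drop = FALSE])
    for (g in members[[q]])
      expr[g, ] <- mu + stats::rnorm(m, 0, config$noise_sd)
  }

  ## modulator expression: coupled -> slope * dosage + noise; decoupled -> noise
  n_coupled <- round(config$dosage_coupled_fraction * n_mod)
  coupled <- modulator_ids[seq_len(n_coupled)]
  slopes <- stats::setNames(stats::runif(n_coupled, config$coupled_slope_range[1],
                                         config$coupled_slope_range[2]), coupled)
  dosage_class <- stats::setNames(rep("DRG", n_mod), modulator_ids)
  dosage_class[coupled] <- "DSG"
  for (g in modulator_ids) {
    dos <- if (provenance[[g]] == "cnv") cnv_log2[g, ] else as.numeric(status[g, ])
    if (g %in% coupled) {
      expr[g, ] <- slopes[[g]] * dos + stats::rnorm(m, 0, config$noise_sd)
    } else {
      expr[g, ] <- stats::rnorm(m, 0, max(config$noise_sd, 0.5))
    }
  }

  ## genomic coordinates: genes laid head-to-tail on 5 chromosomes, 500 bp gaps
  n_chr <- min(5L, n)
  chr_of <- sort(rep(seq_len(n_chr), length.out = n))
  starts0 <- integer(n)
  for (cc in seq_len(n_chr)) {
    on_c <- which(chr_of == cc)
    w <- ceiling(lengths[gene_ids[on_c]])
    starts0[on_c] <- cumsum(c(0, utils::head(w + 500L, -1)))
  }
  gene_coords <- data.frame(chrom = paste0("chr", chr_of),
                            start = starts0,
                            end = starts0 + ceiling(unname(lengths)),
                            gene = gene_ids,
                            stringsAsFactors = FALSE)

  truth <- list(modulator_ids = modulator_ids,
                module_membership = membership,
                passenger_ids = passenger_ids,
                dosage_class = dosage_class,
                program_specs = program_specs,
                provenance = provenance,
                modulator_status = status,
                cn_state = cn_state,
                coupled_slopes = slopes)

  structure(list(expression = expr,
                 cnv_log2 = cnv_log2,
                 somatic = somatic,
                 labels = labels,
                 lengths = lengths,
                 gene_coords = gene_coords,
                 config = config,
                 truth = truth),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synth_bundle: %d genes x %d samples (%d resistant / %d sensitive)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$labels == "resistant"), sum(x$labels == "sensitive")))
  cat(sprintf("  %d modules, %d modulators (%d dosage-coupled), %d long passengers\n",
              x$config$n_modules, x$config$n_modulators,
              sum(x$truth$dosage_class == "DSG"),
              length(x$truth$passenger_ids)))
  invisible(x)
}

#' Write a synthetic bundle to disk in pipeline input formats
#'
#' Writes the expression matrix (TSV, genes in column 1), copy-number
#' segments (SEG, 1-based inclusive, one segment per gene extended 250 bp
#' into the intergenic gaps), the gene model (BED, 0-based half-open),
#' somatic calls (MAF), sample labels and cDNA lengths (TSV), and the planted
#' ground truth (JSON).
#'
#' @param bundle A \code{synth_bundle}.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written file paths (the manifest).
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_value("cannot create output directory '%s'", out_dir)
  }
  p <- function(f) file.path(out_dir, f)

  write_expression_tsv(bundle$expression, p("expression.tsv"))

  co <- bundle$gene_coords
  seg <- do.call(rbind, lapply(colnames(bundle$cnv_log2), function(s) {
    data.frame(ID = s, chrom = co$chrom,
               loc.start = co$start + 1L - 250L,
               loc.end = co$end + 250L,
               num.mark = pmax(10L, ceiling((co$end - co$start) / 100)),
               seg.mean = bundle$cnv_log2[co$gene, s],
               stringsAsFactors = FALSE)
  }))
  seg$loc.start <- pmax(1L, seg$loc.start)
  utils::write.table(seg, p("cnv.seg"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(co[, c("chrom", "start", "end", "gene")], p("genes.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  hit <- which(bundle$somatic == 1L, arr.ind = TRUE)
  coords <- co[match(rownames(bundle$somatic)[hit[, 1]], co$gene), ]
  maf <- data.frame(Hugo_Symbol = rownames(bundle$somatic)[hit[, 1]],
                    Chromosome = coords$chrom,
                    Start_Position = coords$start + 1L,
                    End_Position = coords$start + 1L,
                    Variant_Classification = "Missense_Mutation",
                    Tumor_Sample_Barcode = colnames(bundle$somatic)[hit[, 2]],
                    stringsAsFactors = FALSE)
  maf <- maf[order(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode), ]
  utils::write.table(maf, p("mutations.maf"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(data.frame(sample = names(bundle$labels),
                                label = unname(bundle$labels)),
                     p("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = names(bundle$lengths),
                                length_bp = unname(bundle$lengths)),
                     p("lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- bundle$truth
  truth$modulator_status <- NULL
  truth$cn_state <- NULL
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)

  c(expression = p("expression.tsv"), seg = p("cnv.seg"),
    bed = p("genes.bed"), maf = p("mutations.maf"),
    labels = p("labels.tsv"), lengths = p("lengths.tsv"),
    truth = p("ground_truth.json"))
}
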