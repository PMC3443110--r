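#' Simulation configuration for a two-genotype, two-age array study
#'
#' Describes a synthetic experiment emulating a small-replicate knockout
#' microarray study: 3 WT vs 3 KO arrays at PN11 and 4 vs 4 at PN56 by
#' default. Per-gene baselines are drawn on the log2 scale, per-sample noise
#' is additive on the log2 scale (so signals are log-normal and fold ratios
#' behave multiplicatively), and a fraction of genes receives a true
#' knockout effect of `effect_log2` log2 units (default 2, i.e. 4-fold) in
#' either direction, independently per age contrast. Detection calls are
#' thresholded on the linear signal: Absent below 90% of
#' `present_threshold`, Marginal within +/-10% of it, Present above.
#'
#' Defaults place the baseline at mean 7 / sd 1.5 log2 units with a Present
#' threshold of 100, which yields roughly the 57-58% Present-call rate
#' typical of these arrays.
#'
#' @param n_genes number of genes.
#' @param design data.frame with columns `genotype` (`WT`/`KO`), `age`
#'   (`PN11`/`PN56`) and `replicates`.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline
#'   distribution on the log2 scale.
#' @param noise_sd per-sample log2 noise standard deviation.
#' @param de_fraction fraction of genes with a planted effect, per contrast.
#' @param effect_log2 magnitude of planted effects in log2 units.
#' @param present_threshold linear signal around which detection calls
#'   switch; 0 or less makes every call Present.
#' @param immune_fraction fraction of genes whose annotation text mentions
#'   an immune or inflammatory process.
#' @param seed integer seed; identical configs generate identical data.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              design = data.frame(
                                genotype = c("WT", "KO", "WT", "KO"),
                                age = c("PN11", "PN11", "PN56", "PN56"),
                                replicates = c(3L, 3L, 4L, 4L),
                                stringsAsFactors = FALSE),
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1.5,
                              noise_sd = 0.3,
                              de_fraction = 0.05,
                              effect_log2 = 2,
                              present_threshold = 100,
                              immune_fraction = 0.02,
                              seed = 1L) {
  stopifnot(n_genes >= 1, de_fraction >= 0, de_fraction <= 1,
            noise_sd >= 0, baseline_log2_sd >= 0, effect_log2 >= 0,
            immune_fraction >= 0, immune_fraction <= 1)
  if (!is.data.frame(design) ||
      !all(c("genotype", "age", "replicates") %in% names(design)))
    stop("design must have columns genotype, age, replicates")
  if (any(design$replicates < 1)) stop("replicates must be >= 1")
  if (length(setdiff(design$genotype, c("WT", "KO"))))
    stop("design genotype must be WT or KO")
  if (anyDuplicated(design[c("genotype", "age")]))
    stop("duplicated (genotype, age) group in design")
  structure(list(n_genes = as.integer(n_genes), design = design,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, de_fraction = de_fraction,
                 effect_log2 = effect_log2,
                 present_threshold = present_threshold,
                 immune_fraction = immune_fraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate an expression experiment with known ground truth
#'
#' Generates an [expression_matrix()], sample sheet and annotation table
#' following the configured design, together with the per-gene, per-contrast
#' truth (`Increased`, `Decreased` or `Unchanged`, and the true fold). The
#' planted effect for a contrast is applied to the KO samples of that age;
#' the linear signal of sample j for gene g is
#' `2^(baseline_g + effect_g * KO_indicator + noise_gj)`. A configurable
#' fraction of genes carries "immune response" / "inflammatory response"
#' annotation text so keyword scans can be exercised end to end.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_experiment` with elements `matrix`,
#'   `samples`, `annotations`, `truth` (data.frame: `gene_id`, `contrast`,
#'   `effect`, `true_fold`), and `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  des <- config$design
  sample_ids <- character(0); genotype <- character(0)
  age <- character(0); replicate <- integer(0)
  for (i in seq_len(nrow(des))) {
    reps <- seq_len(des$replicates[i])
    sample_ids <- c(sample_ids,
                    sprintf("%s_%s_%d", des$genotype[i], des$age[i], reps))
    genotype <- c(genotype, rep(des$genotype[i], length(reps)))
    age <- c(age, rep(des$age[i], length(reps)))
    replicate <- c(replicate, reps)
  }
  samples <- data.frame(sample_id = sample_ids, genotype = genotype,
                        age = age, replicate = replicate,
                        stringsAsFactors = FALSE)

  baseline <- stats::rnorm(ng, config$baseline_log2_mean,
                           config$baseline_log2_sd)

  ages <- unique(des$age[des$genotype == "KO"])
  effect <- matrix(0, ng, length(ages), dimnames = list(gene_ids, ages))
  for (a in ages) {
    n_de <- round(config$de_fraction * ng)
    if (n_de > 0) {
      idx <- sample.int(ng, n_de)
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      effect[idx, a] <- sgn * config$effect_log2
    }
  }

  log2sig <- matrix(baseline, ng, nrow(samples))
  ko <- samples$genotype == "KO"
  for (j in which(ko)) log2sig[, j] <- log2sig[, j] + effect[, samples$age[j]]
  log2sig <- log2sig + matrix(stats::rnorm(ng * nrow(samples), 0,
                                           config$noise_sd),
                              ng, nrow(samples))
  signals <- 2^log2sig
  dimnames(signals) <- list(gene_ids, samples$sample_id)

  t0 <- config$present_threshold
  calls <- if (t0 <= 0) {
    matrix("P", ng, nrow(samples))
  } else {
    matrix(ifelse(signals < 0.9 * t0, "A",
           ifelse(signals < 1.1 * t0, "M", "P")), ng, nrow(samples))
  }
  x <- expression_matrix(signals, matrix(calls, ng, nrow(samples),
                                         dimnames = dimnames(signals)))

  n_imm <- round(config$immune_fraction * ng)
  imm <- if (n_imm > 0) sample.int(ng, n_imm) else integer(0)
  go <- rep("metabolic process", ng)
  if (length(imm)) {
    half <- imm[seq_len(ceiling(length(imm) / 2))]
    go[imm] <- "inflammatory response"
    go[half] <- "immune response"
  }
  annotations <- data.frame(gene_id = gene_ids,
                            symbol = sprintf("Gene%05d", seq_len(ng)),
                            description = sprintf("synthetic gene %d",
                                                  seq_len(ng)),
                            go_bp_text = go, stringsAsFactors = FALSE)

  truth <- do.call(rbind, lapply(ages, function(a) {
    e <- effect[, a]
    data.frame(gene_id = gene_ids, contrast = paste0("KO_vs_WT@", a),
               effect = ifelse(e > 0, "Increased",
                        ifelse(e < 0, "Decreased", "Unchanged")),
               true_fold = 2^e, stringsAsFactors = FALSE)
  }))

  structure(list(matrix = x, samples = samples, annotations = annotations,
                 truth = truth, config = config),
            class = "synthetic_experiment")
}

#' Simulate a null experiment (no planted effects)
#'
#' Convenience wrapper forcing `de_fraction = 0`, for type-I-error studies.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_experiment` whose truth is all `Unchanged`.
#' @export
simulate_null <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  config$de_fraction <- 0
  simulate_experiment(config)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment: %d genes, %d samples (seed %d)\n",
              length(x$matrix$gene_ids), nrow(x$samples), x$config$seed))
  print(table(x$truth$contrast, x$truth$effect))
  invisible(x)
}

#' Write the synthetic experiment's tables to a directory
#'
#' Emits `pivot.tsv`, `samples.tsv`, `annotations.tsv` and `truth.tsv`.
#'
#' @param x a `synthetic_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pivot(x$matrix, file.path(dir, "pivot.tsv"))
  utils::write.table(x$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
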