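# Synthetic-data generators with planted ground truth. These emulate the
# statistical structure of a multi-study DE compendium (many contrasts
# sharing a concordant core with per-contrast noise and a few
# direction-inverted gain-of-function contrasts) and of two-group RNA-seq
# count matrices with mostly sub-two-fold planted effects, so recovery can
# be scored against known truth. All generators are pure functions of
# their arguments including the seed.

default_biotype_fractions <- function() {
  # loosely GENCODE-like marginal class frequencies
  c(protein_coding = 0.41, lncRNA = 0.25, pseudogene = 0.18, miRNA = 0.04,
    snRNA_snoRNA = 0.05, rRNA_tRNA = 0.02, ig_tr = 0.01, other = 0.04)
}

#' Generate a synthetic gene annotation table
#'
#' Genes are assigned one of the eight broad categories multinomially,
#' chromosomes uniformly, and a 1-based TSS uniform on [1, 2e8].
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (named chr1..chrN; default 19).
#' @param biotype_fractions Named fractions over [gene_categories()],
#'   summing to 1 (default roughly GENCODE-like with 41% protein coding).
#' @param seed RNG seed.
#' @return Annotation data.frame (gene, biotype, category, chromosome, tss).
#' @export
generate_annotation <- function(n_genes, n_chroms = 19,
                                biotype_fractions = default_biotype_fractions(),
                                seed) {
  cats <- gene_categories()
  if (!setequal(names(biotype_fractions), cats))
    stop("biotype_fractions must be named over gene_categories()", call. = FALSE)
  fr <- biotype_fractions[cats]
  if (abs(sum(fr) - 1) > 1e-9)
    stop("biotype_fractions must sum to 1", call. = FALSE)
  with_seed(seed, {
    category <- sample(cats, n_genes, replace = TRUE, prob = fr)
    data.frame(
      gene = sprintf("g%05d", seq_len(n_genes)),
      biotype = category,  # synthetic: category stands in for the fine biotype
      category = category,
      chromosome = paste0("chr", sample.int(n_chroms, n_genes, replace = TRUE)),
      tss = sample.int(2e8, n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Plant a positional gene cluster into an annotation
#'
#' Reassigns the listed genes to the given chromosome with TSS drawn
#' uniformly in [start, end] — a contiguous stretch of (say) core-up genes
#' for testing positional detection.
#'
#' @param ann Annotation data.frame.
#' @param genes Genes to relocate (must exist in `ann`).
#' @param chromosome Target chromosome name.
#' @param start,end Interval bounds (start < end, 1-based).
#' @param seed RNG seed.
#' @return The modified annotation.
#' @export
plant_positional_cluster <- function(ann, genes, chromosome, start, end, seed) {
  if (length(genes) == 0L) return(ann)
  idx <- match(genes, ann$gene)
  if (anyNA(idx)) stop("genes not present in annotation", call. = FALSE)
  if (!(start < end)) stop("need start < end", call. = FALSE)
  with_seed(seed, {
    ann$chromosome[idx] <- chromosome
    ann$tss[idx] <- as.integer(round(stats::runif(length(idx), start, end)))
  })
  ann
}

#' Generate a multi-contrast compendium with a planted consensus core
#'
#' Core genes carry a fixed sign (up or down) and are significant
#' (FDR drawn below `alpha`) in a Bernoulli(`concordance`) subset of
#' contrasts with log2 fold change `sign * Normal(mean_core_lfc,
#' noise_sd)`; the default effect size keeps most planted changes under
#' two-fold. Background genes are significant at `background_sig_rate`
#' per entry with sign-symmetric effects, but each background gene's
#' support is capped at 5% of the contrasts (excess significant entries
#' are demoted at random) so that planted truth stays identifiable —
#' a background gene significant in a tenth of all contrasts would be a
#' consensus gene by definition. Contrasts listed in `inverted_ids`
#' emulate gain-of-function models: all their true signals are
#' sign-flipped at generation, so the pipeline's direction harmonisation
#' restores them.
#'
#' @param n_genes Total genes (default 5000).
#' @param n_contrasts Number of contrasts (default 40).
#' @param n_core_up,n_core_down Planted core sizes (defaults 150 / 120).
#' @param concordance Probability a core gene is significant in a given
#'   contrast (default 0.6).
#' @param mean_core_lfc Mean |log2FC| of planted significant effects
#'   (default 0.6).
#' @param noise_sd SD of the per-entry log2FC noise (default 0.2).
#' @param background_sig_rate Per-entry significance rate for background
#'   genes (default 0.03).
#' @param inverted_ids Contrast ids generated sign-flipped; default the
#'   last two contrasts. Use character(0) for none.
#' @param alpha Significance level the FDR draws respect (default 0.01).
#' @param seed RNG seed.
#' @return List with `tables` (list of [contrast_table()]), `metadata`
#'   (data.frame in [read_metadata()] layout) and `truth` (list with
#'   core_up, core_down, concordant_contrasts, inverted_contrasts,
#'   planted_lfc).
#' @export
generate_multi_contrast <- function(n_genes = 5000, n_contrasts = 40,
                                    n_core_up = 150, n_core_down = 120,
                                    concordance = 0.6, mean_core_lfc = 0.6,
                                    noise_sd = 0.2, background_sig_rate = 0.03,
                                    inverted_ids = NULL, alpha = 0.01, seed) {
  if (n_core_up + n_core_down > n_genes)
    stop("core sizes exceed n_genes", call. = FALSE)
  stopifnot_scalar_prob(concordance, "concordance", open_upper = FALSE)
  ids <- sprintf("c%02d", seq_len(n_contrasts))
  if (is.null(inverted_ids)) inverted_ids <- utils::tail(ids, 2)
  inverted_ids <- as.character(inverted_ids)
  if (length(setdiff(inverted_ids, ids)))
    stop("inverted_ids outside the generated contrast ids", call. = FALSE)
  genes <- sprintf("g%05d", seq_len(n_genes))
  up <- genes[seq_len(n_core_up)]
  down <- genes[n_core_up + seq_len(n_core_down)]
  n_core <- n_core_up + n_core_down
  bg <- if (n_core > 0) genes[-seq_len(n_core)] else genes
  sign_g <- stats::setNames(rep(0, n_genes), genes)
  sign_g[up] <- 1; sign_g[down] <- -1
  max_bg_support <- floor(0.05 * n_contrasts)
  with_seed(seed, {
    # background significance indicator, support-capped per gene
    bg_sig <- matrix(stats::runif(length(bg) * n_contrasts) < background_sig_rate,
                     nrow = length(bg), ncol = n_contrasts)
    over <- which(rowSums(bg_sig) > max_bg_support)
    for (i in over) {
      on <- which(bg_sig[i, ])
      keep <- sample(on, max_bg_support)
      bg_sig[i, setdiff(on, keep)] <- FALSE
    }
    core_sig <- matrix(stats::runif((n_core_up + n_core_down) * n_contrasts) <
                         concordance, nrow = n_core_up + n_core_down,
                       ncol = n_contrasts)
    tables <- vector("list", n_contrasts)
    for (j in seq_len(n_contrasts)) {
      sig <- c(core_sig[, j], bg_sig[, j])
      lfc <- stats::rnorm(n_genes, 0, noise_sd)
      core_rows <- seq_len(n_core_up + n_core_down)
      lfc[core_rows][sig[core_rows]] <-
        sign_g[core_rows][sig[core_rows]] *
        stats::rnorm(sum(sig[core_rows]), mean_core_lfc, noise_sd)
      bg_rows <- (n_core_up + n_core_down) + seq_along(bg)
      nbs <- sum(sig[bg_rows])
      if (nbs) lfc[bg_rows][sig[bg_rows]] <-
          sample(c(-1, 1), nbs, replace = TRUE) *
          stats::rnorm(nbs, mean_core_lfc, noise_sd)
      fdr <- ifelse(sig, stats::runif(n_genes, 1e-6, alpha),
                    stats::runif(n_genes, alpha + 1e-9, 1))
      pvalue <- fdr * stats::runif(n_genes, 0.05, 1)
      if (ids[j] %in% inverted_ids) lfc <- -lfc
      tables[[j]] <- contrast_table(genes, lfc, pvalue, fdr, ids[j])
    }
    metadata <- data.frame(
      contrast_id = ids,
      study_id = paste0("study", rep(seq_len(ceiling(n_contrasts / 2)),
                                     each = 2)[seq_len(n_contrasts)]),
      tissue = sample(c("cortex", "forebrain", "hippocampus", "cerebellum"),
                      n_contrasts, replace = TRUE),
      cell_fraction = sample(c("whole_cell", "nucleus", "chromatin"),
                             n_contrasts, replace = TRUE,
                             prob = c(0.6, 0.25, 0.15)),
      sex = sample(c("male", "female", "mixed"), n_contrasts, replace = TRUE,
                   prob = c(0.7, 0.15, 0.15)),
      species = "mouse",
      model_class = ifelse(ids %in% inverted_ids, "gain_of_function",
                           "loss_of_function"),
      n_case = sample(3:10, n_contrasts, replace = TRUE),
      n_control = sample(3:10, n_contrasts, replace = TRUE),
      stringsAsFactors = FALSE)
    list(tables = tables, metadata = metadata,
         truth = list(core_up = up, core_down = down,
                      concordant_contrasts = setdiff(ids, inverted_ids),
                      inverted_contrasts = inverted_ids,
                      planted_lfc = stats::setNames(sign_g * mean_core_lfc, genes)))
  })
}

#' Generate a two-group NB count matrix with planted DE genes
#'
#' Baseline means are log-normal; per-gene dispersions are drawn from a
#' scaled inverse-gamma centred on `dispersion_mean`; counts are
#' NB(mean * size_factor * 2^(lfc * case), 1/dispersion). The default
#' effect-size distribution (signed half-normal, sd 0.3) keeps ~99% of
#' planted |log2FC| under 1 — the low signal-to-noise regime where most
#' dysregulation is well below two-fold and only well-replicated designs
#' detect sub-20% effects.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_per_group Samples per group (>= 2).
#' @param de_fraction Fraction of genes with planted DE (default 0.1).
#' @param lfc_distribution Function(n) returning n signed log2 fold
#'   changes; default signed half-normal with sd 0.3.
#' @param dispersion_mean Mean NB dispersion (default 0.005, typical of
#'   high-count genes in isogenic mouse bulk RNA-seq).
#' @param size_factor_sd SD of log-normal per-sample size factors
#'   (default 0.15; 0 gives equal depths).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline-mean
#'   parameters (defaults 4 and 1.5).
#' @param seed RNG seed.
#' @return List with `counts` (a [count_matrix()], case columns first) and
#'   `truth` (de_genes, planted_lfc, dispersion, size_factors).
#' @export
generate_counts <- function(n_genes = 5000, n_per_group, de_fraction = 0.1,
                            lfc_distribution = NULL, dispersion_mean = 0.005,
                            size_factor_sd = 0.15, baseline_meanlog = 4,
                            baseline_sdlog = 1.5, seed) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  stopifnot_scalar_prob(de_fraction, "de_fraction", open_lower = FALSE,
                        open_upper = FALSE)
  if (is.null(lfc_distribution))
    lfc_distribution <- function(n)
      sample(c(-1, 1), n, replace = TRUE) * abs(stats::rnorm(n, 0, 0.3))
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    shape <- 5
    disp <- (dispersion_mean * (shape - 1)) / stats::rgamma(n_genes, shape, 1)
    n_de <- round(de_fraction * n_genes)
    de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
    lfc <- stats::setNames(rep(0, n_genes), genes)
    if (n_de > 0) lfc[de_genes] <- lfc_distribution(n_de)
    nsamp <- 2L * n_per_group
    sf <- if (size_factor_sd > 0)
      stats::rlnorm(nsamp, 0, size_factor_sd) else rep(1, nsamp)
    sf <- sf / exp(mean(log(sf)))
    is_case <- rep(c(1, 0), each = n_per_group)
    mu <- outer(base, sf) * 2^(outer(lfc, is_case))
    counts <- matrix(stats::rnbinom(n_genes * nsamp, mu = mu,
                                    size = rep(1 / disp, nsamp)),
                     nrow = n_genes,
                     dimnames = list(genes, c(paste0("case", seq_len(n_per_group)),
                                              paste0("ctrl", seq_len(n_per_group)))))
    cm <- count_matrix(counts, rep(c("case", "control"), each = n_per_group))
    list(counts = cm,
         truth = list(de_genes = de_genes, planted_lfc = lfc,
                      dispersion = stats::setNames(disp, genes),
                      size_factors = sf))
  })
}

#' Write a multi-contrast simulation to disk
#'
#' Emits the same TSV dialects the readers consume: one contrast table per
#' contrast, the metadata table, and a truth table (gene, planted_lfc,
#' is_core_up, is_core_down).
#'
#' @param sim Output of [generate_multi_contrast()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_multi_contrast <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in sim$tables)
    write_contrast_table(t, file.path(dir, paste0(attr(t, "contrast_id"), ".tsv")))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  truth <- data.frame(gene = names(tr$planted_lfc),
                      planted_lfc = tr$planted_lfc,
                      is_core_up = names(tr$planted_lfc) %in% tr$core_up,
                      is_core_down = names(tr$planted_lfc) %in% tr$core_down)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
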