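#' Planted ground truth for synthetic cohorts
#'
#' Describes the differential-methylation signal planted into generated data:
#' per gene, the direction of the group difference, its size on the beta
#' scale, how many consecutive promoter CpGs carry it, the within-group
#' biological SD, and the slope coupling expression to methylation
#' (log2 expression per unit beta; negative = promoter methylation silences).
#'
#' @param gene Character vector of gene symbols (must exist in the manifest
#'   used downstream).
#' @param direction `"hyper_in_NR"` (higher methylation in non-responders) or
#'   `"hyper_in_R"`, recycled.
#' @param delta Planted group mean beta difference in (0, 1), recycled.
#' @param n_consecutive_cpgs Number of consecutive promoter CpGs carrying the
#'   signal, recycled.
#' @param sd_within Within-group biological SD on the beta scale, recycled.
#' @param expression_coupling Slope of log2 expression on methylation beta
#'   (negative), recycled.
#' @return A data frame of class `planted_truth`, one row per gene.
#' @examples
#' planted_truth(c("FERD3L", "TRIP10"), direction = "hyper_in_R", delta = 0.3)
#' @export
planted_truth <- function(gene, direction = "hyper_in_NR", delta = 0.30,
                          n_consecutive_cpgs = 4, sd_within = 0.10,
                          expression_coupling = -4) {
  stopifnot(all(direction %in% c("hyper_in_NR", "hyper_in_R")),
            all(delta >= 0 & delta < 1), all(n_consecutive_cpgs >= 1),
            all(sd_within > 0), all(expression_coupling < 0))
  out <- data.frame(gene = gene, direction = direction, delta = delta,
                    n_consecutive_cpgs = as.integer(n_consecutive_cpgs),
                    sd_within = sd_within,
                    expression_coupling = expression_coupling,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) stop("duplicated planted gene", call. = FALSE)
  class(out) <- c("planted_truth", "data.frame")
  out
}

#' Generate a 450K-style probe manifest
#'
#' Lays `n_genes` synthetic genes across chromosomes chr1-chr22. Each gene
#' receives a run of closely spaced promoter CpGs (TSS200 / TSS1500 / 5UTR /
#' 1stExon annotations; island or shore relation, 120 bp apart so they fall
#' within each other's consistency window) followed by gene-body probes in
#' open sea or shelf territory. Deterministic given the seed.
#'
#' @param n_genes,cpgs_per_gene Counts (>= 1). About half of each gene's
#'   probes form the promoter run.
#' @param islands_fraction Probability that a gene's promoter run lies in a
#'   CpG island (otherwise a shore).
#' @param seed Integer seed.
#' @return A data frame of class `probe_manifest` with columns `probe_id`,
#'   `chrom`, `pos`, `gene`, `gene_group`, `island_relation`.
#' @examples
#' m <- generate_manifest(10, 8, islands_fraction = 0.5, seed = 1)
#' @export
generate_manifest <- function(n_genes, cpgs_per_gene, islands_fraction = 0.5,
                              seed = 1) {
  stopifnot(n_genes >= 1, cpgs_per_gene >= 1,
            islands_fraction >= 0, islands_fraction <= 1)
  set.seed(seed)
  n_prom <- max(1L, ceiling(cpgs_per_gene / 2))
  n_body <- cpgs_per_gene - n_prom
  rows <- vector("list", n_genes)
  probe_counter <- 0L
  for (i in seq_len(n_genes)) {
    chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
    slot <- (i - 1L) %/% 22L
    base <- 1e6 * (slot + 1) + 1e4 * (((i - 1L) %% 22L) + 1L)
    gene <- sprintf("GENE%03d", i)
    island <- stats::runif(1) < islands_fraction
    prom_rel <- if (island) "Island" else sample(c("N_Shore", "S_Shore"), 1)
    prom <- data.frame(
      probe_id = sprintf("cg%08d", probe_counter + seq_len(n_prom)),
      chrom = chrom,
      pos = as.integer(base + (seq_len(n_prom) - 1L) * 120L),
      gene = gene,
      gene_group = sample(c("TSS200", "TSS1500", "5UTR", "1stExon"),
                          n_prom, replace = TRUE),
      island_relation = prom_rel,
      stringsAsFactors = FALSE)
    probe_counter <- probe_counter + n_prom
    if (n_body > 0) {
      body <- data.frame(
        probe_id = sprintf("cg%08d", probe_counter + seq_len(n_body)),
        chrom = chrom,
        pos = as.integer(base + 5000L + (seq_len(n_body) - 1L) * 2000L),
        gene = gene,
        gene_group = "Body",
        island_relation = sample(c("OpenSea", "N_Shelf", "S_Shelf"),
                                 n_body, replace = TRUE),
        stringsAsFactors = FALSE)
      probe_counter <- probe_counter + n_body
      rows[[i]] <- rbind(prom, body)
    } else {
      rows[[i]] <- prom
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("probe_manifest", "data.frame")
  out
}

# Per-sample latent gene-level methylation shared by all assay platforms of
# one biological cohort. Both groups sit at a gene-specific baseline; the
# planted group is shifted by delta. Deterministic given (planted, sample
# sheet, latent seed), so the array, pyrosequencing and expression
# generators observe the same biology through independent platform noise.
latent_gene_methylation <- function(planted, samples, latent_seed) {
  set.seed(latent_seed)
  n <- nrow(samples)
  lat <- matrix(NA_real_, nrow = n, ncol = nrow(planted),
                dimnames = list(samples$sample_id, planted$gene))
  is_r <- samples$response == "R"
  for (g in seq_len(nrow(planted))) {
    delta <- planted$delta[g]
    base_low <- stats::runif(1, 0.10, max(0.11, 0.90 - delta))
    mean_r <- if (planted$direction[g] == "hyper_in_R") base_low + delta else base_low
    mean_nr <- if (planted$direction[g] == "hyper_in_NR") base_low + delta else base_low
    if (mean_r > 1 || mean_nr > 1 || mean_r < 0 || mean_nr < 0) {
      warning("planted mean for ", planted$gene[g],
              " falls outside [0, 1]; values will be clamped",
              call. = FALSE)
    }
    mu <- ifelse(is_r, mean_r, mean_nr)
    lat[, g] <- pmin(1, pmax(0, stats::rnorm(n, mu, planted$sd_within[g])))
  }
  lat
}

# Promoter probes of a gene carrying the planted run, in genomic order.
planted_probe_ids <- function(manifest, gene, n_cpgs) {
  prom <- manifest[manifest_has_gene(manifest$gene, gene) &
                     manifest$gene_group %in%
                       c("TSS200", "TSS1500", "5UTR", "1stExon"), ]
  prom <- prom[order(prom$chrom, prom$pos), ]
  utils::head(prom$probe_id, n_cpgs)
}

# Matches a gene symbol against possibly semicolon-joined annotations.
manifest_has_gene <- function(annotation, gene) {
  vapply(strsplit(annotation, ";", fixed = TRUE),
         function(g) gene %in% g, logical(1))
}

#' Generate a synthetic patient cohort (beta matrix + sample sheet)
#'
#' Unplanted probes draw a per-probe baseline from a bimodal Beta mixture
#' (half hypomethylated around 0.17, half hypermethylated around 0.83,
#' mimicking the bimodal marginal distribution of array beta values); every
#' sample observes that baseline plus Gaussian noise of SD `noise_sd`,
#' clamped to \[0, 1\]. Planted genes instead receive, on their first
#' `n_consecutive_cpgs` promoter probes, the latent per-sample gene-level
#' methylation (group means separated by `delta`, within-group SD
#' `sd_within`) plus a small probe-level array noise.
#'
#' @param manifest A `probe_manifest`.
#' @param n_r,n_nr Number of responder (RCB = 0) and non-responder samples.
#' @param planted A `planted_truth` (may have zero rows).
#' @param noise_sd Per-probe noise SD on the beta scale for unplanted probes.
#' @param seed Integer seed (also seeds the latent biology shared with the
#'   pyrosequencing and expression generators).
#' @param cohort `"discovery"` or `"validation"` label written into the
#'   sample sheet.
#' @param probe_noise_sd Probe-level array noise added on top of the latent
#'   gene methylation of planted probes.
#' @return List with `beta` (numeric matrix, probes x samples), `samples`
#'   (data frame of class `sample_sheet`), and `planted`.
#' @examples
#' m <- generate_manifest(5, 6, seed = 1)
#' truth <- planted_truth("GENE001", direction = "hyper_in_R", delta = 0.3)
#' cohort <- generate_cohort(m, n_r = 10, n_nr = 14, planted = truth, seed = 2)
#' @export
generate_cohort <- function(manifest, n_r, n_nr, planted = planted_truth(character(0)),
                            noise_sd = 0.10, seed = 1, cohort = "discovery",
                            probe_noise_sd = 0.02) {
  stopifnot(inherits(manifest, "probe_manifest"), n_r >= 2, n_nr >= 2,
            noise_sd > 0, cohort %in% c("discovery", "validation"))
  missing_genes <- setdiff(planted$gene, unlist(strsplit(manifest$gene, ";")))
  if (length(missing_genes)) {
    stop("planted gene(s) absent from manifest: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  samples <- make_sample_sheet(n_r, n_nr, cohort, seed)
  n <- nrow(samples)

  set.seed(seed + 104729L)  # platform/array stream, distinct from biology
  p <- nrow(manifest)
  hyper <- stats::runif(p) < 0.5
  baseline <- ifelse(hyper, stats::rbeta(p, 10, 2), stats::rbeta(p, 2, 10))
  beta <- matrix(stats::rnorm(p * n, mean = rep(baseline, times = n),
                              sd = noise_sd),
                 nrow = p, ncol = n,
                 dimnames = list(manifest$probe_id, samples$sample_id))

  if (nrow(planted) > 0) {
    lat <- latent_gene_methylation(planted, samples, latent_seed = seed)
    for (g in seq_len(nrow(planted))) {
      ids <- planted_probe_ids(manifest, planted$gene[g],
                               planted$n_consecutive_cpgs[g])
      for (pid in ids) {
        beta[pid, ] <- lat[, planted$gene[g]] + stats::rnorm(n, 0, probe_noise_sd)
      }
    }
  }
  beta[beta < 0] <- 0
  beta[beta > 1] <- 1
  list(beta = beta, samples = samples, planted = planted)
}

make_sample_sheet <- function(n_r, n_nr, cohort, seed) {
  set.seed(seed + 7919L)
  n <- n_r + n_nr
  prefix <- if (cohort == "discovery") "DC" else "VC"
  rcb <- c(rep(0L, n_r), sample(1:3, n_nr, replace = TRUE))
  samples <- data.frame(
    sample_id = sprintf("%s%03d", prefix, seq_len(n)),
    cohort = cohort,
    rcb_class = rcb,
    response = ifelse(rcb == 0L, "R", "NR"),
    age = round(stats::rnorm(n, 48, 11), 1),
    ct_stage = sample(c("cT1-2", "cT3-4", "cTx"), n, replace = TRUE,
                      prob = c(0.75, 0.17, 0.08)),
    cn_stage = sample(c("cN0", "cN+", "cNx"), n, replace = TRUE,
                      prob = c(0.60, 0.33, 0.07)),
    ki67 = ifelse(stats::runif(n) < 0.15, NA_real_,
                  round(stats::runif(n, 5, 95), 0)),
    stringsAsFactors = FALSE)
  attr(samples, "latent_seed") <- as.integer(seed)
  class(samples) <- c("sample_sheet", "data.frame")
  samples
}

latent_seed_of <- function(samples) {
  s <- attr(samples, "latent_seed")
  if (is.null(s)) {
    stop("sample sheet carries no latent seed; generate it with ",
         "generate_cohort()/make_sample_sheet() before simulating assays",
         call. = FALSE)
  }
  s
}

#' Generate a pyrosequencing-style methylation table
#'
#' Emulates technical validation of the planted genes: each sample's latent
#' gene-level methylation (the same biology underlying the array draw of
#' `generate_cohort` for the same sample sheet) is read out at
#' `cpgs_per_assay` CpG positions on the percentage scale with independent
#' assay noise, clamped to \[0, 100\].
#'
#' @param planted A `planted_truth`.
#' @param samples A `sample_sheet` produced by [generate_cohort()].
#' @param cpgs_per_assay CpGs per pyrosequencing assay (>= 1).
#' @param assay_noise_sd Per-CpG assay noise SD in percentage points; 0 gives
#'   exactly 100 * latent beta.
#' @param seed Integer seed of the assay noise.
#' @return Data frame with columns `sample_id`, `gene`, `cpg_index`,
#'   `pct_methylation`.
#' @export
generate_pyro_table <- function(planted, samples, cpgs_per_assay = 4,
                                assay_noise_sd = 3, seed = 1) {
  stopifnot(cpgs_per_assay >= 1, assay_noise_sd >= 0)
  lat <- latent_gene_methylation(planted, samples, latent_seed_of(samples))
  set.seed(seed + 15485863L)
  out <- expand.grid(cpg_index = seq_len(cpgs_per_assay),
                     gene = planted$gene, sample_id = samples$sample_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("sample_id", "gene", "cpg_index")]
  truth_pct <- 100 * lat[cbind(out$sample_id, out$gene)]
  noise <- if (assay_noise_sd > 0) {
    stats::rnorm(nrow(out), 0, assay_noise_sd)
  } else 0
  out$pct_methylation <- pmin(100, pmax(0, truth_pct + noise))
  rownames(out) <- NULL
  out
}

#' Generate a qPCR Ct table with methylation-coupled expression
#'
#' Produces triplicate Ct values per sample for each planted gene plus the
#' endogenous-control gene. Target Ct rises with latent promoter methylation:
#' Ct_target = reference_ct + dct_base - coupling_g * beta, so with negative
#' coupling a more methylated sample yields a higher Ct and hence a lower
#' relative expression (fold change 2^-ddCt).
#'
#' @inheritParams generate_pyro_table
#' @param reference_ct Mean Ct of the endogenous control (default 20).
#' @param coupling Optional single negative slope overriding each gene's
#'   `expression_coupling`.
#' @param reference_gene Name of the endogenous control (default `"GAPDH"`).
#' @param dct_base Baseline target-minus-reference Ct at zero methylation.
#' @param tech_sd Technical SD of a single Ct replicate.
#' @param n_replicates Replicates per reaction (the assay design uses 3).
#' @return Data frame with columns `sample_id`, `gene`, `replicate`, `ct`.
#' @export
generate_expression <- function(planted, samples, reference_ct = 20,
                                coupling = NULL, reference_gene = "GAPDH",
                                dct_base = 4, tech_sd = 0.15,
                                n_replicates = 3, seed = 1) {
  if (!is.null(coupling) && coupling >= 0) {
    stop("coupling must be negative (methylation silences expression)",
         call. = FALSE)
  }
  lat <- latent_gene_methylation(planted, samples, latent_seed_of(samples))
  set.seed(seed + 32452843L)
  rows <- list()
  for (s in samples$sample_id) {
    for (g in seq_len(nrow(planted))) {
      slope <- if (is.null(coupling)) planted$expression_coupling[g] else coupling
      mu <- reference_ct + dct_base - slope * lat[s, planted$gene[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = planted$gene[g],
        replicate = seq_len(n_replicates),
        ct = stats::rnorm(n_replicates, mu, tech_sd),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, gene = reference_gene, replicate = seq_len(n_replicates),
      ct = stats::rnorm(n_replicates, reference_ct, tech_sd),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
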