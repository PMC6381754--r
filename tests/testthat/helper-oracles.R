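# Independent brute-force oracles, deliberately naive implementations.

# Two-sided rank-sum p by full enumeration of all C(n1+n2, n1) assignments
# of the pooled ranks (valid for tie-free data).
enum_rank_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Youden-optimal threshold by exhaustive scan over +/-Inf and every
# observed score, predicted positive = score > t, ties toward smallest t.
brute_youden <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  ts <- c(-Inf, sort(unique(scores)), Inf)
  j <- vapply(ts, function(t) mean(pos > t) + mean(neg <= t) - 1, numeric(1))
  list(cutoff = ts[which(j >= max(j) - 1e-12)[1]], j = max(j))
}

# Tiny manifest for hand-built cascade fixtures: one row per probe.
tiny_manifest <- function(probe_id, chrom, pos, gene, gene_group,
                          island_relation) {
  out <- data.frame(probe_id = probe_id, chrom = chrom, pos = as.integer(pos),
                    gene = gene, gene_group = gene_group,
                    island_relation = island_relation,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_manifest", "data.frame")
  out
}

# Minimal sample sheet for hand-built cohorts.
tiny_samples <- function(ids, response, cohort = "discovery") {
  out <- data.frame(sample_id = ids, cohort = cohort,
                    rcb_class = ifelse(response == "R", 0L, 2L),
                    response = response, stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}
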