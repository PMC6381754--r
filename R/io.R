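#' Read and write the pipeline's tabular formats
#'
#' The pipeline exchanges plain-text tables: a probe manifest CSV with
#' Illumina-style column names (`IlmnID`, `CHR`, `MAPINFO`,
#' `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#' `Relation_to_UCSC_CpG_Island`), a beta-matrix TSV (probes in rows,
#' samples in columns), a sample-sheet CSV, a pyrosequencing CSV
#' (`sample_id`, `gene`, `cpg_index`, `pct_methylation`) and a Ct CSV
#' (`sample_id`, `gene`, `replicate`, `ct`). Missing values are empty cells
#' ("NA" is accepted on read, never written). All invariants (beta range,
#' unique probe ids, label cross-references) are enforced at load time.
#'
#' @param path File path.
#' @return The typed object (`probe_manifest`, beta matrix, `sample_sheet`,
#'   or plain data frame for pyro/Ct tables).
#' @name io
NULL

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' @rdname io
#' @export
read_manifest <- function(path) {
  d <- .read_csv(path)
  need <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
            "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island")
  if (!all(need %in% names(d))) {
    stop("manifest is missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$IlmnID)) {
    stop("duplicate probe_id in manifest: ",
         d$IlmnID[anyDuplicated(d$IlmnID)], call. = FALSE)
  }
  if (any(d$MAPINFO < 1)) stop("manifest positions must be >= 1",
                               call. = FALSE)
  out <- data.frame(probe_id = d$IlmnID, chrom = as.character(d$CHR),
                    pos = as.integer(d$MAPINFO),
                    gene = d$UCSC_RefGene_Name,
                    gene_group = d$UCSC_RefGene_Group,
                    island_relation = d$Relation_to_UCSC_CpG_Island,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_manifest", "data.frame")
  out
}

#' @rdname io
#' @param manifest A `probe_manifest` to write.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(IlmnID = manifest$probe_id, CHR = manifest$chrom,
                    MAPINFO = manifest$pos,
                    UCSC_RefGene_Name = manifest$gene,
                    UCSC_RefGene_Group = manifest$gene_group,
                    Relation_to_UCSC_CpG_Island = manifest$island_relation)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param samples Optional sample sheet to cross-check column labels.
#' @export
read_beta_matrix <- function(path, samples = NULL) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                         na.strings = c("", "NA"))
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [0, 1] at probe %s, sample %s: %g",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate probe rows in beta matrix", call. = FALSE)
  }
  if (!is.null(samples)) {
    unknown <- setdiff(colnames(m), samples$sample_id)
    if (length(unknown)) {
      stop("beta matrix contains sample(s) not in the sample sheet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  m
}

#' @rdname io
#' @param beta Probe x sample matrix to write.
#' @export
write_beta_matrix <- function(beta, path) {
  d <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname io
#' @export
read_sample_sheet <- function(path) {
  d <- .read_csv(path)
  need <- c("sample_id", "cohort", "rcb_class")
  if (!all(need %in% names(d))) {
    stop("sample sheet is missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (!all(d$cohort %in% c("discovery", "validation"))) {
    stop("cohort must be 'discovery' or 'validation'", call. = FALSE)
  }
  if (!all(d$rcb_class %in% 0:3)) {
    stop("rcb_class must be 0, 1, 2 or 3", call. = FALSE)
  }
  d$response <- ifelse(d$rcb_class == 0, "R", "NR")
  if ("latent_seed" %in% names(d)) {
    attr(d, "latent_seed") <- d$latent_seed[1]
    d$latent_seed <- NULL
  }
  class(d) <- c("sample_sheet", "data.frame")
  d
}

#' @rdname io
#' @export
write_sample_sheet <- function(samples, path) {
  out <- as.data.frame(samples)
  ls <- attr(samples, "latent_seed")
  if (!is.null(ls)) out$latent_seed <- ls
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_pyro <- function(path) {
  d <- .read_csv(path)
  need <- c("sample_id", "gene", "cpg_index", "pct_methylation")
  if (!all(need %in% names(d))) {
    stop("pyro table is missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(d$pct_methylation) &
                 (d$pct_methylation < 0 | d$pct_methylation > 100))
  if (length(bad)) {
    stop(sprintf("pct_methylation out of [0, 100] at row %d (%s / %s)",
                 bad[1], d$sample_id[bad[1]], d$gene[bad[1]]),
         call. = FALSE)
  }
  d
}

#' @rdname io
#' @param x Data frame to write (pyro or Ct table).
#' @export
write_pyro <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_ct <- function(path) {
  d <- .read_csv(path)
  need <- c("sample_id", "gene", "replicate", "ct")
  if (!all(need %in% names(d))) {
    stop("Ct table is missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  d
}

#' @rdname io
#' @export
write_ct <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Convert manifest probe positions to BED intervals and back
#'
#' Manifest coordinates are 1-based single-base positions; BED uses 0-based
#' half-open intervals, so a CpG at position p becomes `[p - 1, p)`. The two
#' converters are exact inverses.
#'
#' @param manifest A `probe_manifest` (optionally subset to chosen probes).
#' @return `manifest_to_bed`: data frame `chrom`, `start`, `end`, `name`;
#'   `bed_to_positions`: integer vector of 1-based positions.
#' @export
manifest_to_bed <- function(manifest) {
  data.frame(chrom = manifest$chrom, start = manifest$pos - 1L,
             end = manifest$pos, name = manifest$probe_id,
             stringsAsFactors = FALSE)
}

#' @rdname manifest_to_bed
#' @param bed A BED data frame from [manifest_to_bed()].
#' @export
bed_to_positions <- function(bed) {
  stopifnot(all(bed$end == bed$start + 1L))
  as.integer(bed$start + 1L)
}

#' @rdname manifest_to_bed
#' @param path Output file.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
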