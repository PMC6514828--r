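# Phased VCF v4.2 + ancestor FASTA + TSV sidecars are the on-disk interchange
# for alignments. The writer emits plain text; reading goes through vcfR.

#' Write and read phased haplotype alignments as VCF
#'
#' `write_alignment_vcf()` emits a phased VCF v4.2 (GT with `|` separators,
#' 1-based positions, REF = ancestor base) pairing consecutive haplotypes into
#' diploid samples. `read_alignment_vcf()` reads it back together with the
#' ancestor FASTA and optional quality-mask / sample-metadata sidecars; the
#' round trip reproduces the haplotype matrix, positions and phases exactly.
#' Unphased (`/`-separated) genotypes are rejected, naming the sample and site.
#'
#' @param alignment A `hap_alignment` with at least one variant site and an
#'   even number of haplotypes.
#' @param path,vcf_path Output / input file path.
#' @param ancestor_fasta Path to the ancestor FASTA written by
#'   [write_ancestor_fasta()]; its header carries the region coordinates.
#' @param mask Optional path to the quality-mask TSV (columns CHROM, POS,
#'   HIGH_QUALITY); if `NULL` all sites are treated as high quality.
#' @param metadata Optional path to the haplotype-metadata TSV written by
#'   [write_haplotype_metadata()].
#' @return `write_*` return the path invisibly; `read_alignment_vcf()` returns
#'   a `hap_alignment`.
#' @export
write_alignment_vcf <- function(alignment, path) {
  stopifnot(inherits(alignment, "hap_alignment"))
  if (ncol(alignment$haplotypes) < 1) {
    abort("Alignment has no variant sites; refusing to write an empty VCF.")
  }
  n_hap <- nrow(alignment$haplotypes)
  if (n_hap %% 2 != 0) {
    abort("VCF export pairs haplotypes into diploid samples; need an even number of haplotypes.")
  }
  anc <- ancestor_at_variants(alignment)
  samples <- sprintf("s%03d", seq_len(n_hap / 2))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", alignment$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(alignment$pos), function(j) {
    obs <- alignment$haplotypes[, j]
    ref <- anc[j]
    alts <- setdiff(unique(obs[!is.na(obs)]), ref)
    alleles <- c(ref, alts)
    code <- function(b) if (is.na(b)) "." else as.character(match(b, alleles) - 1L)
    gt <- vapply(seq(1, n_hap, by = 2), function(i) {
      paste0(code(obs[i]), "|", code(obs[i + 1]))
    }, character(1))
    paste(c(alignment$chrom, alignment$pos[j], ".", ref,
            if (length(alts)) paste(alts, collapse = ",") else ".",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_alignment_vcf
#' @export
write_ancestor_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "hap_alignment"))
  hdr <- sprintf(">ancestor %s:%d-%d", alignment$chrom, alignment$region_start,
                 alignment$region_start + length(alignment$hq_mask) - 1L)
  seq <- paste(alignment$ancestor_full, collapse = "")
  writeLines(c(hdr, substring(seq, seq(1, nchar(seq), 70),
                              pmin(nchar(seq), seq(70, nchar(seq) + 69, 70)))),
             path)
  invisible(path)
}

#' @rdname write_alignment_vcf
#' @export
write_quality_mask <- function(alignment, path) {
  stopifnot(inherits(alignment, "hap_alignment"))
  pos <- alignment$region_start + seq_along(alignment$hq_mask) - 1L
  utils::write.table(
    data.frame(CHROM = alignment$chrom, POS = pos,
               HIGH_QUALITY = as.integer(alignment$hq_mask)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_vcf
#' @export
write_haplotype_metadata <- function(alignment, path) {
  stopifnot(inherits(alignment, "hap_alignment"))
  n_hap <- nrow(alignment$meta)
  df <- data.frame(sample = sprintf("s%03d", ceiling(seq_len(n_hap) / 2)),
                   hap_index = (seq_len(n_hap) + 1L) %% 2L,
                   haplotype = alignment$meta$haplotype,
                   cluster = alignment$meta$cluster)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_vcf
#' @export
read_alignment_vcf <- function(vcf_path, ancestor_fasta, mask = NULL,
                               metadata = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt[, -1, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(v@gt)[-1]
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[1, "CHROM"]

  # grepl() drops the matrix dims; restore them so arr.ind works
  unphased <- which(matrix(grepl("/", gt), nrow = nrow(gt)), arr.ind = TRUE)
  if (nrow(unphased)) {
    i <- unphased[1, ]
    abort(sprintf("Unphased genotype ('/' separator) for sample %s at %s:%s; phased data required.",
                  samples[i[2]], chrom, fix[i[1], "POS"]))
  }

  alleles <- lapply(seq_along(pos), function(j) {
    alt <- fix[j, "ALT"]
    c(fix[j, "REF"], if (!is.na(alt) && alt != ".") strsplit(alt, ",")[[1]])
  })
  n_hap <- 2L * length(samples)
  mat <- matrix(NA_character_, nrow = n_hap, ncol = length(pos))
  for (j in seq_along(pos)) {
    parts <- strsplit(gt[j, ], "|", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      abort(sprintf("Genotype for sample %s at %s:%d is not a phased diploid call.",
                    samples[bad[1]], chrom, pos[j]))
    }
    idx <- suppressWarnings(as.integer(unlist(parts)))
    base <- rep(NA_character_, length(idx))
    ok <- !is.na(idx)
    base[ok] <- alleles[[j]][idx[ok] + 1L]
    mat[, j] <- base
  }

  fa <- readLines(ancestor_fasta)
  hdr <- fa[1]
  region <- regmatches(hdr, regexec("([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)", hdr))[[1]]
  if (length(region) != 4) abort("Ancestor FASTA header must carry 'chrom:start-end'.")
  ancestor_full <- strsplit(toupper(paste(fa[-1], collapse = "")), "")[[1]]
  region_start <- as.integer(region[3])

  hq_mask <- rep(TRUE, length(ancestor_full))
  if (!is.null(mask)) {
    mk <- utils::read.delim(mask)
    hq_mask <- rep(FALSE, length(ancestor_full))
    hq_mask[mk$POS - region_start + 1L] <- mk$HIGH_QUALITY == 1
  }

  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    meta <- as_tibble(md[, c("haplotype", "cluster")])
    rownames(mat) <- md$haplotype
  } else {
    ids <- as.vector(t(outer(samples, 0:1, function(s, h) paste0(s, "_", h))))
    meta <- tibble(haplotype = ids, cluster = NA_character_)
    rownames(mat) <- ids
  }
  colnames(mat) <- as.character(pos)
  new_hap_alignment(mat, pos, chrom, ancestor_full, region_start, hq_mask, meta)
}
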