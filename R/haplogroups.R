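#' Classify haplotypes into haplogroups by the tag SNP
#'
#' Assigns each haplotype `ancestral` or `derived` from its base at the tag
#' SNP (default rs174537 at chr11:61,552,680: T = ancestral, shared with
#' nonhuman primates; G = derived, human-unique). Any other or missing base
#' gives `unclassified`.
#'
#' @param alignment A `hap_alignment` containing the tag position among its
#'   variant sites.
#' @param tag A list like [fads_tag_snp()] with `pos`, `ancestral_allele`,
#'   `derived_allele`.
#' @return The alignment's metadata tibble with an added `haplogroup` column.
#' @export
classify_haplotypes <- function(alignment, tag = fads_tag_snp()) {
  stopifnot(inherits(alignment, "hap_alignment"))
  j <- match(tag$pos, alignment$pos)
  if (is.na(j)) {
    abort(sprintf("Tag SNP at %s:%d is absent from the alignment's variant sites.",
                  tag$chrom %||% alignment$chrom, tag$pos))
  }
  base <- alignment$haplotypes[, j]
  haplogroup <- dplyr::case_when(
    base == tag$ancestral_allele ~ "ancestral",
    base == tag$derived_allele ~ "derived",
    TRUE ~ "unclassified")
  n_uncl <- sum(haplogroup == "unclassified")
  if (n_uncl > 0) {
    inform(sprintf("%d haplotype(s) unclassified at the tag SNP (missing or third allele).", n_uncl))
  }
  mutate(alignment$meta, haplogroup = haplogroup)
}

#' Haplogroup proportions by group
#'
#' Counts ancestral and derived haplotypes per group and their fractions of
#' the classified total (unclassified haplotypes are excluded from the
#' denominator and reported as a count). With `unambiguous_only = TRUE` only
#' haplotypes from samples whose two haplotypes share a single value of the
#' grouping variable are kept (e.g. homozygous local ancestry), which
#' requires a `sample` column.
#'
#' @param labeled A tibble with columns `haplogroup` and the grouping column
#'   (as from [classify_haplotypes()], optionally joined to sample metadata).
#' @param group Name of the grouping column (string; default `"cluster"`).
#' @param unambiguous_only Keep only samples homozygous for the grouping
#'   label.
#' @return A tibble with one row per group: counts, `prop_ancestral`,
#'   `prop_derived`, and the same proportions as percentages rounded to two
#'   decimals (`pct_ancestral`, `pct_derived`).
#' @export
haplogroup_proportions <- function(labeled, group = "cluster",
                                   unambiguous_only = FALSE) {
  if (!all(c("haplogroup", group) %in% names(labeled))) {
    abort(sprintf("`labeled` must have columns 'haplogroup' and '%s'.", group))
  }
  if (unambiguous_only) {
    if (!"sample" %in% names(labeled)) {
      abort("`unambiguous_only = TRUE` requires a `sample` column.")
    }
    keep <- labeled |>
      group_by(.data$sample) |>
      filter(dplyr::n_distinct(.data[[group]]) == 1) |>
      ungroup()
    labeled <- keep
  }
  out <- labeled |>
    group_by(group = .data[[group]]) |>
    summarise(n_haplotypes = n(),
              n_ancestral = sum(.data$haplogroup == "ancestral"),
              n_derived = sum(.data$haplogroup == "derived"),
              n_unclassified = sum(.data$haplogroup == "unclassified"),
              .groups = "drop")
  empty <- out$n_ancestral + out$n_derived == 0
  if (any(empty)) {
    warn(sprintf("Omitting group(s) with no classified haplotypes: %s",
                 paste(out$group[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  out |>
    mutate(prop_ancestral = .data$n_ancestral / (.data$n_ancestral + .data$n_derived),
           prop_derived = .data$n_derived / (.data$n_ancestral + .data$n_derived),
           pct_ancestral = round(100 * .data$prop_ancestral, 2),
           pct_derived = round(100 * .data$prop_derived, 2))
}

#' Core (consensus) haplotype strings per category
#'
#' For each category and each variant position in the region, emits the base
#' as a capital letter if every non-missing haplotype of the category agrees
#' (down to `threshold`, default 1 = all), and lower-case `"n"` otherwise.
#' Positions are ordered left-to-right by coordinate. Sites missing in more
#' than half of a category's haplotypes are emitted as `"n"` with a warning.
#'
#' @param x A `hap_alignment`, or a character matrix of haplotypes x sites
#'   (column order taken as position order).
#' @param categories Named character vector mapping haplotype id to category
#'   (haplotypes not named are dropped).
#' @param region Optional `"chr:start-end"` restriction on variant positions
#'   (alignments only).
#' @param threshold Minimum agreement fraction among non-missing bases for a
#'   position to be emitted as fixed (default 1, i.e. found in all).
#' @return A tibble with columns `category`, `sequence`, `n_positions`.
#' @export
core_haplotypes <- function(x, categories, region = NULL, threshold = 1) {
  if (inherits(x, "hap_alignment")) {
    mat <- x$haplotypes
    if (!is.null(region)) {
      r <- parse_region(region)
      keep <- x$chrom == r$chrom & x$pos >= r$start & x$pos <= r$end
      mat <- mat[, keep, drop = FALSE]
    }
  } else if (is.matrix(x)) {
    mat <- x
  } else {
    abort("`x` must be a hap_alignment or a character matrix.")
  }
  if (is.null(names(categories))) {
    if (length(categories) != nrow(mat)) {
      abort("Unnamed `categories` must have one entry per haplotype row.")
    }
    names(categories) <- rownames(mat)
  }
  cats <- split(names(categories), unname(categories))
  missing_ids <- setdiff(names(categories), rownames(mat))
  if (length(missing_ids)) {
    abort(sprintf("Haplotype id(s) not in the alignment: %s",
                  paste(utils::head(missing_ids, 3), collapse = ", ")))
  }
  purrr::imap(cats, function(ids, cat) {
    if (length(ids) == 0) abort(sprintf("Category '%s' has zero haplotypes.", cat))
    sub <- mat[ids, , drop = FALSE]
    chars <- vapply(seq_len(ncol(sub)), function(j) {
      b <- sub[, j]
      obs <- b[!is.na(b)]
      if (length(obs) < length(b) / 2) {
        warn(sprintf("Category '%s', position %d: missing in over half the haplotypes; emitted as 'n'.",
                     cat, j))
        return("n")
      }
      if (length(obs) == 0) return("n")
      tab <- table(obs)
      if (max(tab) / length(obs) >= threshold) names(tab)[which.max(tab)] else "n"
    }, character(1))
    tibble(category = cat, sequence = paste(chars, collapse = ""),
           n_positions = ncol(sub))
  }) |> bind_rows()
}

#' Reference FADS core-haplotype strings
#'
#' The packaged consensus strings over the 38 SNPs of the low-coverage FADS
#' haplogroup block (chr11:61,543,499-61,591,636): capital bases are fixed in
#' all haplotypes of the category, `"n"` marks a variable base. Base number
#' 10 (left to right) is the tag SNP rs174537.
#'
#' @return A tibble with columns `category` and `sequence`.
#' @examples
#' fads_core_haplotypes()
#' @export
fads_core_haplotypes <- function() {
  path <- system.file("extdata", "fads_core_haplotypes.tsv", package = "fadsevo",
                      mustWork = TRUE)
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Index of the tag SNP within the packaged core-haplotype strings
#' @return The 1-based base number of rs174537 in [fads_core_haplotypes()].
#' @export
fads_tag_index <- function() 10L

#' Sites fixed in opposite directions between two core haplotypes
#'
#' Compares two equal-length core-haplotype strings position by position.
#' Positions where both strings carry a capital (fixed) base and the bases
#' differ are oppositely fixed -- candidate causal variants. Positions fixed
#' in exactly one string (capital vs `"n"`) are returned as weaker
#' candidates.
#'
#' @param core_a,core_b Core-haplotype strings (or single-row tibbles from
#'   [core_haplotypes()]).
#' @param exclude Integer positions to drop from the results (e.g. the tag
#'   SNP itself, base [fads_tag_index()]).
#' @return A list with integer vectors `opposite` (fixed differently in
#'   both) and `one_sided` (fixed in exactly one).
#' @examples
#' core <- fads_core_haplotypes()
#' opposite_fixed_sites(core$sequence[core$category == "Ancestral"],
#'                      core$sequence[core$category == "Derived"],
#'                      exclude = fads_tag_index())
#' @export
opposite_fixed_sites <- function(core_a, core_b, exclude = integer(0)) {
  pick <- function(x) if (is.data.frame(x)) x$sequence[1] else x
  a <- strsplit(pick(core_a), "")[[1]]
  b <- strsplit(pick(core_b), "")[[1]]
  if (length(a) != length(b)) {
    abort(sprintf("Core haplotypes have different lengths (%d vs %d).",
                  length(a), length(b)))
  }
  fixed_a <- a != "n"
  fixed_b <- b != "n"
  opposite <- which(fixed_a & fixed_b & a != b)
  one_sided <- which(xor(fixed_a, fixed_b))
  list(opposite = setdiff(opposite, exclude),
       one_sided = setdiff(one_sided, exclude))
}
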