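# Region and tag-SNP defaults for the FADS haplogroup block (hg19).

#' Default coordinates and tag SNP for the FADS haplogroup region
#'
#' The FADS1/FADS2 haplogroup block on chromosome 11 (hg19). The tag SNP
#' rs174537 separates the ancestral (T, shared with nonhuman primates) and
#' derived (G, human-unique) haplogroups. `fads_region()` returns the
#' coordinates used throughout the package; the haplogroup block spans
#' 48,408 bases of which 47,820 have a high-quality ancestral reconstruction.
#'
#' @return `fads_region()`: a named list with `chrom`, `start`, `end`
#'   (1-based inclusive), `length_total` and `length_high_quality`.
#'   `fads_tag_snp()`: a list with `chrom`, `pos`, `ancestral_allele`,
#'   `derived_allele` and `id`.
#' @examples
#' fads_region()
#' fads_tag_snp()
#' @export
fads_region <- function() {
  list(
    chrom = "chr11",
    start = 61543499L,
    end = 61543499L + 48408L - 1L,
    length_total = 48408L,
    length_high_quality = 47820L
  )
}

#' @rdname fads_region
#' @export
fads_tag_snp <- function() {
  list(
    chrom = "chr11",
    pos = 61552680L,
    ancestral_allele = "T",
    derived_allele = "G",
    id = "rs174537"
  )
}

# Derive a reproducible child seed (< 2^31) from a master seed and a label.
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1], got %s.", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

DNA_BASES <- c("A", "C", "G", "T")

random_bases <- function(n) sample(DNA_BASES, n, replace = TRUE)

# A base different from `base`, one per element.
mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

parse_region <- function(x) {
  if (is.list(x)) return(list(chrom = x$chrom, start = as.integer(x$start), end = as.integer(x$end)))
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) abort(sprintf("Cannot parse region '%s'; expected 'chr:start-end'.", x))
  list(chrom = m[2],
       start = as.integer(gsub(",", "", m[3])),
       end = as.integer(gsub(",", "", m[4])))
}
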